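#' Transition/transversion counts for one aligned pair
#'
#' Sites where either sequence has a gap, \code{?} or an ambiguity code
#' are skipped (pairwise deletion). Transitions are A<->G and C<->T;
#' all other differences are transversions.
#'
#' @param a,b aligned nucleotide strings of equal length.
#' @return list \code{overlap} (sites compared), \code{ts}, \code{tv}.
#' @export
pairwise_counts <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences differ in aligned length")
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  va <- code[strsplit(toupper(a), "", fixed = TRUE)[[1]]]
  vb <- code[strsplit(toupper(b), "", fixed = TRUE)[[1]]]
  .counts_encoded(va, vb)
}

## encoded integer vectors (NA = missing); purines {1,3}, pyrimidines {2,4}
.counts_encoded <- function(va, vb) {
  ok <- !is.na(va) & !is.na(vb)
  va <- va[ok]; vb <- vb[ok]
  diff <- va != vb
  ts <- sum(diff & (va + vb == 4L | va + vb == 6L) & (va %% 2L == vb %% 2L))
  list(overlap = length(va), ts = ts, tv = sum(diff) - ts)
}

#' Kimura 2-parameter distance from pair counts
#'
#' With P = ts/overlap and Q = tv/overlap,
#' d = -1/2 log((1 - 2P - Q) sqrt(1 - 2Q)). Returns \code{NA}
#' (undefined) at saturation (log argument <= 0) or zero overlap.
#'
#' @param pc a list as returned by \code{\link{pairwise_counts}}.
#' @return distance in substitutions/site, or \code{NA}.
#' @export
k2p <- function(pc) {
  if (pc$overlap < 1) return(NA_real_)
  P <- pc$ts / pc$overlap
  Q <- pc$tv / pc$overlap
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1 * sqrt(w2))
}

#' Uncorrected p-distance from pair counts
#'
#' @inheritParams k2p
#' @return proportion of differing sites, or \code{NA} at zero overlap.
#' @export
p_distance <- function(pc) {
  if (pc$overlap < 1) return(NA_real_)
  (pc$ts + pc$tv) / pc$overlap
}

#' Pairwise distance matrix for a barcode alignment
#'
#' Computes all pairwise distances under pairwise deletion. Pairs whose
#' overlap falls below \code{min_overlap}, or that are saturated under
#' K2P, are recorded as \code{NA} (undefined).
#'
#' @param aln a \code{barcode_alignment} with >= 2 records.
#' @param model \code{"k2p"} (default) or \code{"p"}.
#' @param min_overlap minimum shared unambiguous sites (bp), default 100.
#' @return object of class \code{barcode_dist}: list with \code{ids},
#'   \code{d} (symmetric matrix, \code{NA} = undefined), \code{overlap}
#'   (bp per pair), \code{model}, \code{min_overlap}.
#' @export
distance_matrix <- function(aln, model = c("k2p", "p"), min_overlap = 100) {
  model <- match.arg(model)
  enc <- .encode_alignment(aln)
  n <- nrow(enc)
  d <- matrix(0, n, n, dimnames = list(aln$id, aln$id))
  ov <- matrix(0L, n, n, dimnames = list(aln$id, aln$id))
  fun <- if (model == "k2p") k2p else p_distance
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        pc <- .counts_encoded(enc[i, ], enc[j, ])
        ov[i, j] <- ov[j, i] <- pc$overlap
        dij <- if (pc$overlap < min_overlap) NA_real_ else fun(pc)
        d[i, j] <- d[j, i] <- dij
      }
    }
  }
  structure(list(ids = aln$id, d = d, overlap = ov, model = model,
                 min_overlap = min_overlap),
            class = "barcode_dist")
}

#' @export
print.barcode_dist <- function(x, ...) {
  nd <- sum(is.na(x$d[upper.tri(x$d)]))
  cat(sprintf("%s distance matrix: %d records, %d undefined pairs\n",
              toupper(x$model), length(x$ids), nd))
  invisible(x)
}

#' @export
as.matrix.barcode_dist <- function(x, ...) x$d

## Most specific shared rank per pair; "between_orders" = subclass only.
.pair_level <- function(tax_i, tax_j) {
  if (tax_i$species == tax_j$species) return("within_species")
  if (nzchar(tax_i$genus) && tax_i$genus == tax_j$genus)
    return("within_genus")
  if (nzchar(tax_i$family) && tax_i$family == tax_j$family)
    return("within_family")
  if (nzchar(tax_i$order) && tax_i$order == tax_j$order)
    return("within_order")
  "between_orders"
}

#' Distance summaries by taxonomic level
#'
#' Each defined pair is binned at its most specific shared rank:
#' within-species, within-genus (different species), within-family,
#' within-order, or between-orders. Undefined pairs are excluded and
#' counted.
#'
#' @param dm a \code{barcode_dist}.
#' @param aln the \code{barcode_alignment} the matrix was built from
#'   (taxonomy source).
#' @return list with \code{levels} (named list: each has \code{values},
#'   \code{n_pairs}, \code{mean}, \code{median}, \code{min}, \code{max})
#'   and \code{n_undefined}.
#' @export
level_summaries <- function(dm, aln) {
  if (!identical(dm$ids, aln$id))
    stop("distance matrix and alignment ids do not match")
  n <- length(dm$ids)
  lev_names <- c("within_species", "within_genus", "within_family",
                 "within_order", "between_orders")
  vals <- stats::setNames(vector("list", length(lev_names)), lev_names)
  for (k in lev_names) vals[[k]] <- numeric(0)
  n_undef <- 0L
  for (i in seq_len(n - 1)) {
    ti <- list(species = aln$species[i], genus = aln$genus[i],
               family = aln$family[i], order = aln$order[i])
    for (j in (i + 1):n) {
      dij <- dm$d[i, j]
      if (is.na(dij)) { n_undef <- n_undef + 1L; next }
      tj <- list(species = aln$species[j], genus = aln$genus[j],
                 family = aln$family[j], order = aln$order[j])
      lev <- .pair_level(ti, tj)
      vals[[lev]] <- c(vals[[lev]], dij)
    }
  }
  levels <- lapply(vals, function(v) {
    if (!length(v))
      list(values = v, n_pairs = 0L, mean = NA_real_, median = NA_real_,
           min = NA_real_, max = NA_real_)
    else
      list(values = v, n_pairs = length(v), mean = mean(v),
           median = stats::median(v), min = min(v), max = max(v))
  })
  list(levels = levels, n_undefined = n_undef)
}

#' Mann-Whitney U test (exact enumeration for small samples)
#'
#' For combined sample sizes up to \code{exact_max} the permutation
#' distribution of U is enumerated completely (ties handled exactly);
#' larger samples use the normal approximation with tie correction and
#' continuity correction. Two-sided p-values.
#'
#' @param x,y numeric vectors.
#' @param exact_max enumeration cutoff on \code{length(x)+length(y)},
#'   default 12.
#' @return list \code{U} (statistic for \code{x}), \code{p},
#'   \code{method} (\code{"exact"} or \code{"normal"}).
#' @export
mann_whitney_u <- function(x, y, exact_max = 12) {
  if (!length(x) || !length(y)) stop("empty input")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 + n2 <= exact_max) {
    combs <- utils::combn(n1 + n2, n1)
    Us <- apply(combs, 2, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
    list(U = U, p = p, method = "exact")
  } else {
    N <- n1 + n2
    ties <- table(pooled)
    sig <- sqrt(n1 * n2 / 12 *
                  ((N + 1) - sum(ties^3 - ties) / (N * (N - 1))))
    ## lower tail of the symmetric U distribution, with continuity and
    ## Edgeworth kurtosis corrections (gamma2 of U without ties)
    g2 <- -(6 / 5) * (n1^2 + n2^2 + n1 * n2 + n1 + n2) /
      (n1 * n2 * (N + 1))
    z <- (min(U, n1 * n2 - U) + 0.5 - mu) / sig
    F_lo <- stats::pnorm(z) - g2 / 24 * (z^3 - 3 * z) * stats::dnorm(z)
    p <- min(1, max(0, 2 * F_lo))
    list(U = U, p = p, method = "normal")
  }
}

#' Per-species barcode-gap report
#'
#' For each species: the largest intraspecific distance, the smallest
#' distance to any heterospecific record, and their difference (the
#' barcode gap). Species with a single record get \code{NA} max_intra.
#'
#' @param dm a \code{barcode_dist}.
#' @param species character vector of species labels in \code{dm$ids} order.
#' @return data.frame (species, n_records, max_intra, min_inter, gap)
#'   with attribute \code{n_no_gap} = species with gap <= 0.
#' @export
barcode_gap_report <- function(dm, species) {
  if (length(species) != length(dm$ids))
    stop("species vector must match matrix ids")
  sps <- unique(species)
  out <- data.frame(species = sps, n_records = NA_integer_,
                    max_intra = NA_real_, min_inter = NA_real_,
                    gap = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(sps)) {
    idx <- which(species == sps[k])
    out$n_records[k] <- length(idx)
    if (length(idx) > 1) {
      sub <- dm$d[idx, idx, drop = FALSE]
      iv <- sub[upper.tri(sub)]
      iv <- iv[!is.na(iv)]
      if (length(iv)) out$max_intra[k] <- max(iv)
    }
    inter <- dm$d[idx, -idx, drop = FALSE]
    inter <- inter[!is.na(inter)]
    if (length(inter)) out$min_inter[k] <- min(inter)
    out$gap[k] <- out$min_inter[k] - out$max_intra[k]
  }
  attr(out, "n_no_gap") <- sum(out$gap <= 0, na.rm = TRUE)
  out
}

#' Sliding-window nucleotide diversity
#'
#' Nucleotide diversity (pi) per site is the mean pairwise difference
#' among the non-missing residues at that site
#' (1 - sum n_i(n_i-1) / (n(n-1))); a window's pi averages its sites
#' (sites with fewer than two residues are excluded from the average).
#' Windows advance by \code{step}; a trailing partial window is dropped.
#'
#' @param aln a \code{barcode_alignment}.
#' @param window window length in bp.
#' @param step step size in bp, default 10.
#' @return list with \code{windows} (data.frame \code{start} [1-based],
#'   \code{end}, \code{pi}) and \code{mean_pi} (whole-fragment pi).
#' @export
sliding_window_pi <- function(aln, window, step = 10) {
  L <- aln$aligned_length
  if (window > L) stop("window longer than alignment")
  enc <- .encode_alignment(aln)
  site_pi <- vapply(seq_len(L), function(s) {
    col <- enc[, s]
    col <- col[!is.na(col)]
    n <- length(col)
    if (n < 2) return(NA_real_)
    cnt <- tabulate(col, nbins = 4)
    1 - sum(cnt * (cnt - 1)) / (n * (n - 1))
  }, numeric(1))
  starts <- seq(1, L - window + 1, by = step)
  wpi <- vapply(starts, function(s) {
    v <- site_pi[s:(s + window - 1)]
    mean(v, na.rm = TRUE)
  }, numeric(1))
  list(windows = data.frame(start = starts, end = starts + window - 1,
                            pi = wpi),
       mean_pi = mean(site_pi, na.rm = TRUE))
}

#' Distance frequency table by taxonomic level
#'
#' Bins distances into [k*w, (k+1)*w) intervals and reports the
#' percentage of pairs per bin per level; percentages sum to 100 within
#' each level.
#'
#' @param summaries output of \code{\link{level_summaries}}.
#' @param bin_width bin width in substitutions/site, default 0.01.
#' @return data.frame (level, bin_lower, bin_upper, percent).
#' @export
distance_histogram <- function(summaries, bin_width = 0.01) {
  rows <- list()
  for (lev in names(summaries$levels)) {
    v <- summaries$levels[[lev]]$values
    if (!length(v)) next
    bins <- floor(v / bin_width)
    tab <- table(bins)
    rows[[lev]] <- data.frame(
      level = lev,
      bin_lower = as.numeric(names(tab)) * bin_width,
      bin_upper = (as.numeric(names(tab)) + 1) * bin_width,
      percent = 100 * as.numeric(tab) / length(v),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
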