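#' Collapse identical sequences into haplotypes with per-group counts
#'
#' Identical sequences (missing data and ambiguity codes compare as
#' written) share a haplotype id; counts are tabulated per group.
#'
#' @param aln a \code{barcode_alignment}.
#' @param groups character vector of group labels, one per record
#'   (e.g. sampling localities); a single label is used if omitted.
#' @return list with \code{table} (data.frame haplotype, sequence, and
#'   one count column per group) and \code{haplotype_of} (named vector
#'   record id -> haplotype id).
#' @export
collapse_haplotypes <- function(aln, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", length(aln$id))
  if (length(groups) != length(aln$id))
    stop("groups must have one label per record")
  key <- aln$seq
  first <- !duplicated(key)
  hap_ids <- paste0("H", seq_len(sum(first)))
  hap_of <- hap_ids[match(key, key[first])]
  glev <- sort(unique(groups))
  counts <- sapply(glev, function(g)
    as.integer(table(factor(hap_of[groups == g], levels = hap_ids))))
  counts <- matrix(counts, nrow = length(hap_ids),
                   dimnames = list(NULL, glev))
  tab <- data.frame(haplotype = hap_ids, sequence = key[first],
                    counts, stringsAsFactors = FALSE, check.names = FALSE)
  list(table = tab,
       haplotype_of = stats::setNames(hap_of, aln$id))
}

## AMOVA variance components from squared distances for one grouping
.phi_from_groups <- function(d2, grp) {
  N <- length(grp)
  G <- length(unique(grp))
  ssd_total <- sum(d2[upper.tri(d2)]) / N
  ssd_within <- 0
  ns <- integer(G)
  for (k in seq_along(unique(grp))) {
    idx <- which(grp == unique(grp)[k])
    ns[k] <- length(idx)
    sub <- d2[idx, idx, drop = FALSE]
    ssd_within <- ssd_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ssd_among <- ssd_total - ssd_within
  df_among <- G - 1
  df_within <- N - G
  sigma_w <- ssd_within / df_within
  n_bar <- (N - sum(ns^2) / N) / df_among
  sigma_a <- (ssd_among / df_among - sigma_w) / n_bar
  sigma_a / (sigma_a + sigma_w)
}

#' PhiST between sample groups from a distance matrix
#'
#' Distance-based AMOVA fixation index: the among-group fraction of the
#' total molecular variance computed from squared pairwise distances.
#' Significance by permutation of group labels, with add-one smoothing
#' of the p-value.
#'
#' @param dm a \code{barcode_dist} restricted to the records of
#'   interest (typically one species); no undefined entries allowed.
#' @param groups character vector of group labels in \code{dm$ids}
#'   order; >= 2 groups with >= 2 records each.
#' @param n_perms label permutations, default 1000.
#' @param seed RNG seed.
#' @return list \code{phi_st}, \code{p_value}, \code{n_perms}.
#' @export
phi_st <- function(dm, groups, n_perms = 1000, seed = 1) {
  d <- dm$d
  if (anyNA(d[upper.tri(d)]))
    stop("undefined distances within PhiST scope")
  if (length(groups) != length(dm$ids))
    stop("groups must match matrix ids")
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 groups with >= 2 records each")
  d2 <- d^2
  obs <- .phi_from_groups(d2, groups)
  ge <- .with_seed(seed, {
    g <- 0L
    for (b in seq_len(n_perms)) {
      if (.phi_from_groups(d2, sample(groups)) >= obs - 1e-12) g <- g + 1L
    }
    g
  })
  list(phi_st = obs, p_value = (ge + 1) / (n_perms + 1), n_perms = n_perms)
}
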