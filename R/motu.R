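#' Pairwise sequence-difference graph for MOTU clustering
#'
#' For every record pair, counts differing unambiguous positions over
#' the shared (non-gap, non-missing) region. An edge is retained only
#' when the overlap reaches \code{min_overlap} and the percent identity
#' reaches \code{identity_filter} — the analogue of a BLAST candidate
#' filter on an exact all-pairs comparison.
#'
#' @param aln a \code{barcode_alignment}.
#' @param min_overlap minimum shared bp, default 100.
#' @param identity_filter minimum percent identity, default 85.
#' @return object of class \code{difference_graph}: list with
#'   \code{ids}, \code{edges} (data.frame i, j, abs_diff, overlap,
#'   identity), \code{mean_ungapped_length}.
#' @export
build_difference_graph <- function(aln, min_overlap = 100,
                                   identity_filter = 85) {
  enc <- .encode_alignment(aln)
  n <- nrow(enc)
  ii <- integer(0); jj <- integer(0)
  dd <- integer(0); oo <- integer(0)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        ok <- !is.na(enc[i, ]) & !is.na(enc[j, ])
        ov <- sum(ok)
        if (ov < min_overlap) next
        ad <- sum(enc[i, ok] != enc[j, ok])
        if (100 * (1 - ad / ov) < identity_filter) next
        ii <- c(ii, i); jj <- c(jj, j); dd <- c(dd, ad); oo <- c(oo, ov)
      }
    }
  }
  edges <- data.frame(i = aln$id[ii], j = aln$id[jj], abs_diff = dd,
                      overlap = oo, identity = 100 * (1 - dd / oo),
                      stringsAsFactors = FALSE)
  structure(list(ids = aln$id, edges = edges,
                 mean_ungapped_length = mean(ungapped_length(aln))),
            class = "difference_graph")
}

## convert a percent cutoff to bp on the dataset's mean ungapped length,
## rounding half-up
.cutoff_bp <- function(g, cutoff, cutoff_unit) {
  if (cutoff_unit == "bp") return(cutoff)
  floor(cutoff / 100 * g$mean_ungapped_length + 0.5)
}

#' Single-linkage MOTU clustering at a difference cutoff
#'
#' MOTUs are the connected components of the difference graph restricted
#' to edges with \code{abs_diff <= cutoff}; isolated records are
#' singleton MOTUs.
#'
#' @param g a \code{difference_graph}.
#' @param cutoff difference cutoff, in bp or percent (of mean ungapped
#'   dataset length, rounded half-up to bp).
#' @param cutoff_unit \code{"bp"} or \code{"percent"}.
#' @return object of class \code{motu_partition}: list with
#'   \code{assignment} (named integer vector record -> MOTU id),
#'   \code{n_motus}, \code{cutoff}, \code{cutoff_bp}, \code{params}.
#' @export
threshold_clusters <- function(g, cutoff, cutoff_unit = c("bp", "percent")) {
  cutoff_unit <- match.arg(cutoff_unit)
  cut_bp <- .cutoff_bp(g, cutoff, cutoff_unit)
  n <- length(g$ids)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  keep <- g$edges$abs_diff <= cut_bp
  ei <- match(g$edges$i[keep], g$ids)
  ej <- match(g$edges$j[keep], g$ids)
  for (e in seq_along(ei)) {
    ri <- find(ei[e]); rj <- find(ej[e])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  assignment <- stats::setNames(match(roots, unique(roots)), g$ids)
  structure(list(assignment = assignment,
                 n_motus = length(unique(assignment)),
                 cutoff = cutoff, cutoff_bp = cut_bp,
                 params = list(unit = cutoff_unit)),
            class = "motu_partition")
}

#' @export
print.motu_partition <- function(x, ...) {
  cat(sprintf("MOTU partition: %d MOTUs over %d records (cutoff %s = %d bp)\n",
              x$n_motus, length(x$assignment), format(x$cutoff), x$cutoff_bp))
  invisible(x)
}

#' MOTU counts across a grid of cutoffs
#'
#' @param g a \code{difference_graph}.
#' @param cutoffs numeric vector of cutoffs.
#' @inheritParams threshold_clusters
#' @return data.frame (cutoff, cutoff_bp, n_motus); \code{n_motus} is
#'   non-increasing in the cutoff.
#' @export
motu_curve <- function(g, cutoffs, cutoff_unit = c("bp", "percent")) {
  cutoff_unit <- match.arg(cutoff_unit)
  res <- lapply(cutoffs, function(ct)
    threshold_clusters(g, ct, cutoff_unit = cutoff_unit))
  data.frame(cutoff = cutoffs,
             cutoff_bp = vapply(res, `[[`, numeric(1), "cutoff_bp"),
             n_motus = vapply(res, `[[`, numeric(1), "n_motus"))
}

#' Dataset-calibrated intraspecific distance threshold
#'
#' Percentile of the pooled within-species distance distribution; the
#' conventional flexible threshold for best-close-match assignment.
#'
#' @param dm a \code{barcode_dist}.
#' @param species species labels in \code{dm$ids} order.
#' @param percentile percentile (0-100), default 95.
#' @return threshold distance (substitutions/site).
#' @export
intraspecific_threshold <- function(dm, species, percentile = 95) {
  intra <- numeric(0)
  for (sp in unique(species)) {
    idx <- which(species == sp)
    if (length(idx) < 2) next
    sub <- dm$d[idx, idx, drop = FALSE]
    v <- sub[upper.tri(sub)]
    intra <- c(intra, v[!is.na(v)])
  }
  if (!length(intra))
    stop("no species with >= 2 records: cannot calibrate threshold")
  unname(stats::quantile(intra, percentile / 100, type = 7))
}

#' Best-close-match species assignment
#'
#' Each query is assigned by its nearest reference(s) within a
#' distance threshold. Verdicts: \code{correct} when all nearest-tied
#' references are conspecific, \code{incorrect} when all are
#' heterospecific, \code{ambiguous} for a mixed tie, and \code{no_id}
#' when no reference lies within the threshold (or no distance is
#' defined).
#'
#' @param dm a \code{barcode_dist}.
#' @param species species labels in \code{dm$ids} order.
#' @param threshold maximum acceptable nearest distance (e.g. from
#'   \code{\link{intraspecific_threshold}}).
#' @param mode \code{"leave_one_out"} (every record queried against all
#'   others) or \code{"reference"} (queries given by \code{query_ids}
#'   against the remaining records).
#' @param query_ids record ids to treat as queries in reference mode.
#' @param tie_tol distances within \code{tie_tol} of the minimum count
#'   as tied, default 1e-12.
#' @return data.frame (query, nearest_ids, nearest_distance, verdict).
#' @export
best_close_match <- function(dm, species, threshold,
                             mode = c("leave_one_out", "reference"),
                             query_ids = NULL, tie_tol = 1e-12) {
  mode <- match.arg(mode)
  ids <- dm$ids
  queries <- if (mode == "leave_one_out") seq_along(ids)
             else match(query_ids, ids)
  refs_for <- function(q) {
    if (mode == "leave_one_out") setdiff(seq_along(ids), q)
    else setdiff(seq_along(ids), match(query_ids, ids))
  }
  out <- data.frame(query = ids[queries], nearest_ids = NA_character_,
                    nearest_distance = NA_real_, verdict = NA_character_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(queries)) {
    q <- queries[k]
    refs <- refs_for(q)
    dq <- dm$d[q, refs]
    ok <- !is.na(dq)
    if (!any(ok)) { out$verdict[k] <- "no_id"; next }
    dmin <- min(dq[ok])
    if (dmin > threshold) {
      out$nearest_distance[k] <- dmin
      out$verdict[k] <- "no_id"
      next
    }
    near <- refs[ok][dq[ok] <= dmin + tie_tol]
    near_sp <- unique(species[near])
    out$nearest_ids[k] <- paste(ids[near], collapse = ",")
    out$nearest_distance[k] <- dmin
    out$verdict[k] <-
      if (length(near_sp) == 1 && near_sp == species[q]) "correct"
      else if (!(species[q] %in% near_sp)) "incorrect"
      else "ambiguous"
  }
  out
}

#' MOTU/OTU concordance report
#'
#' Compares a molecular partition (MOTUs, from threshold clustering or
#' tree-based delimitation) with morphological species labels (OTUs).
#' An exact match is a MOTU whose record set coincides with exactly one
#' OTU; a split OTU spans several MOTUs; a lumped MOTU contains several
#' OTUs.
#'
#' @param partition a \code{motu_partition}, \code{ptp_delimitation}, or
#'   named vector record -> part id.
#' @param species named character vector record -> species label, or a
#'   plain vector in the same order as the partition.
#' @return list: \code{n_motus}, \code{n_otus}, \code{n_exact_matches},
#'   \code{n_split_otus}, \code{n_lumped_motus}, \code{lumped_sets}
#'   (list of OTU sets per lumped MOTU).
#' @export
concordance <- function(partition, species) {
  part <- if (is.list(partition)) partition$assignment %||% partition$partition
          else partition
  if (!is.null(names(part)) && !is.null(names(species)))
    species <- species[names(part)]
  tab <- table(motu = as.character(part), otu = as.character(species))
  motus_per_otu <- apply(tab > 0, 2, sum)
  otus_per_motu <- apply(tab > 0, 1, sum)
  exact <- 0L
  for (m in rownames(tab)) {
    otus <- colnames(tab)[tab[m, ] > 0]
    if (length(otus) == 1 && motus_per_otu[otus] == 1) exact <- exact + 1L
  }
  lumped <- which(otus_per_motu >= 2)
  list(n_motus = nrow(tab), n_otus = ncol(tab),
       n_exact_matches = exact,
       n_split_otus = sum(motus_per_otu >= 2),
       n_lumped_motus = length(lumped),
       lumped_sets = lapply(lumped, function(m)
         colnames(tab)[tab[m, ] > 0]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
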