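#' Neighbour-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration on the Q criterion. The result is
#' an unrooted \code{ape::phylo} tree (degree-3 basal node). Ties in Q
#' are broken deterministically toward the lowest (row, column) index
#' pair. Negative branch lengths are clamped to zero with the deficit
#' moved to the sibling branch, so sibling lengths still sum to the
#' pair's distance (disable with \code{clamp_negative = FALSE}).
#'
#' @param dm a \code{barcode_dist} or a plain symmetric numeric matrix
#'   with row/column names; no undefined (\code{NA}) entries allowed.
#' @param clamp_negative clamp negative branch lengths (default TRUE).
#' @return an unrooted \code{phylo} tree.
#' @export
neighbor_joining <- function(dm, clamp_negative = TRUE) {
  d <- if (inherits(dm, "barcode_dist")) dm$d else as.matrix(dm)
  if (anyNA(d)) {
    bad <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
    stop("undefined distances for pair(s): ",
         paste(sprintf("%s-%s", rownames(d)[bad[, 1]],
                       colnames(d)[bad[, 2]]), collapse = ", "))
  }
  n <- nrow(d)
  if (n < 3) stop("need at least 3 records")
  labels <- rownames(d)
  ## each active node holds a newick fragment
  frag <- labels
  active <- seq_len(n)
  D <- d
  fmt <- function(x) sprintf("%.15g", x)
  while (length(active) > 3) {
    m <- length(active)
    Dm <- D[active, active, drop = FALSE]
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, `+`)
    diag(Q) <- Inf
    ## lowest (i,j) pair among ties, row-major
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    dij <- Dm[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    if (clamp_negative) {
      if (li < 0) { li <- 0; lj <- dij }
      if (lj < 0) { lj <- 0; li <- dij }
    }
    ai <- active[i]; aj <- active[j]
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[ai], fmt(li), frag[aj], fmt(lj))
    ## distances from the new node u to remaining k
    rest <- active[-c(i, j)]
    du <- (D[ai, rest] + D[aj, rest] - dij) / 2
    ## reuse slot ai for u
    D[ai, rest] <- du; D[rest, ai] <- du
    frag[ai] <- newfrag
    active <- setdiff(active, aj)
  }
  a <- active[1]; b <- active[2]; c3 <- active[3]
  la <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  lb <- D[a, b] - la
  lc <- D[a, c3] - la
  if (clamp_negative) { la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0) }
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[a], fmt(la), frag[b], fmt(lb),
                 frag[c3], fmt(lc))
  ape::read.tree(text = nwk)
}

#' Bootstrap support for an alignment-derived tree
#'
#' Resamples alignment columns with replacement, rebuilds the distance
#' matrix and tree per replicate, and annotates each internal edge of
#' the reference tree with the percentage of replicates containing its
#' bipartition.
#'
#' @param aln a \code{barcode_alignment}.
#' @param n_reps number of bootstrap replicates.
#' @param model,min_overlap passed to \code{\link{distance_matrix}}.
#' @param seed RNG seed (deterministic supports for a fixed seed).
#' @return the reference NJ tree with \code{node.label} set to supports
#'   (0-100, \code{NA} for the basal node).
#' @export
bootstrap_support <- function(aln, n_reps = 100, model = "k2p",
                              min_overlap = 1, seed = 1) {
  ref <- neighbor_joining(distance_matrix(aln, model = model,
                                          min_overlap = min_overlap))
  L <- aln$aligned_length
  boot <- .with_seed(seed, {
    reps <- vector("list", n_reps)
    for (b in seq_len(n_reps)) {
      cols <- sample.int(L, L, replace = TRUE)
      baln <- aln
      baln$seq <- vapply(strsplit(aln$seq, "", fixed = TRUE),
                         function(s) paste(s[cols], collapse = ""),
                         character(1))
      reps[[b]] <- neighbor_joining(
        distance_matrix(baln, model = model, min_overlap = min_overlap))
    }
    reps
  })
  counts <- ape::prop.clades(ref, boot, rooted = FALSE)
  ref$node.label <- 100 * counts / n_reps
  ref
}

#' Read a rooted or unrooted tree from a newick file
#'
#' @param path newick file path.
#' @return a \code{phylo} tree.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("malformed newick: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("malformed newick: no tree parsed")
  tr
}

#' Write a tree to a newick file
#'
#' @param tree a \code{phylo} tree.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Root a tree at its midpoint
#'
#' Thin wrapper over \code{phangorn::midpoint}, the default rooting used
#' before species delimitation when no outgroup-rooted tree is supplied.
#'
#' @param tree an unrooted \code{phylo} tree.
#' @return a rooted \code{phylo} tree.
#' @export
midpoint_root <- function(tree) phangorn::midpoint(tree)

#' Classify each species as mono-, para- or polyphyletic on a tree
#'
#' On the rooted tree, a species is monophyletic when the clade of its
#' MRCA contains exactly its leaves; if the intruding leaves themselves
#' form a single clade the species is paraphyletic, otherwise
#' polyphyletic. Single-record species are reported as singletons.
#'
#' @param tree a rooted \code{phylo} tree.
#' @param species named character vector: names are leaf labels, values
#'   species labels; every leaf must be present.
#' @return data.frame (species, n_leaves, status).
#' @export
monophyly_check <- function(tree, species) {
  tips <- tree$tip.label
  if (!all(tips %in% names(species)))
    stop("species label missing for leaf/leaves: ",
         paste(setdiff(tips, names(species)), collapse = ", "))
  sp_of <- species[tips]
  sps <- unique(sp_of)
  n_tip <- length(tips)
  status <- character(length(sps))
  n_leaves <- integer(length(sps))
  for (k in seq_along(sps)) {
    leaves <- tips[sp_of == sps[k]]
    n_leaves[k] <- length(leaves)
    if (length(leaves) == 1) { status[k] <- "singleton"; next }
    mrca <- ape::getMRCA(tree, leaves)
    clade <- ape::extract.clade(tree, mrca)$tip.label
    if (setequal(clade, leaves)) { status[k] <- "monophyletic"; next }
    intruders <- setdiff(clade, leaves)
    if (length(intruders) == 1) { status[k] <- "paraphyletic"; next }
    mrca_in <- ape::getMRCA(tree, intruders)
    clade_in <- ape::extract.clade(tree, mrca_in)$tip.label
    status[k] <- if (setequal(clade_in, intruders)) "paraphyletic"
                 else "polyphyletic"
  }
  data.frame(species = sps, n_leaves = n_leaves, status = status,
             stringsAsFactors = FALSE)
}
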