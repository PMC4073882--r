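# Shared fixtures and independent oracles.

## quick alignment builder: sequences + species, ids auto-generated
make_aln <- function(seqs, species, genus = NULL, family = NULL,
                     order = NULL, ids = NULL, variant = "original") {
  n <- length(seqs)
  if (is.null(ids)) ids <- sprintf("r%02d", seq_len(n))
  barcode_alignment(ids, seqs, species, genus, family, order,
                    variant = variant)
}

## random gap-free alignment of n sequences over length L
random_aln <- function(n, L, n_species = max(2, n %/% 3), seed = 1,
                       missing_frac = 0) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  seqs <- replicate(n, {
    s <- sample(bases, L, replace = TRUE)
    if (missing_frac > 0) {
      k <- rbinom(1, L, missing_frac)
      if (k > 0) s[sample.int(L, k)] <- sample(c("-", "?", "N"), k,
                                               replace = TRUE)
    }
    paste(s, collapse = "")
  })
  make_aln(seqs, species = sprintf("sp%02d",
                                   sample.int(n_species, n, replace = TRUE)))
}

## character-level oracle for transition/transversion counts
oracle_pair_counts <- function(a, b) {
  va <- strsplit(toupper(a), "")[[1]]
  vb <- strsplit(toupper(b), "")[[1]]
  overlap <- 0L; ts <- 0L; tv <- 0L
  pur <- c("A", "G"); pyr <- c("C", "T")
  for (k in seq_along(va)) {
    x <- va[k]; y <- vb[k]
    if (!(x %in% c(pur, pyr)) || !(y %in% c(pur, pyr))) next
    overlap <- overlap + 1L
    if (x == y) next
    if ((x %in% pur && y %in% pur) || (x %in% pyr && y %in% pyr))
      ts <- ts + 1L
    else tv <- tv + 1L
  }
  list(overlap = overlap, ts = ts, tv = tv)
}

## closed-form K2P evaluated independently
oracle_k2p <- function(overlap, ts, tv) {
  P <- ts / overlap; Q <- tv / overlap
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) return(NA_real_)
  0.5 * log(1 / (1 - 2 * P - Q)) + 0.25 * log(1 / (1 - 2 * Q))
}

## Mann-Whitney U by direct pair counting (ties count 1/2)
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

## exact-match / split / lump counts by direct set comparison
oracle_concordance <- function(part, species) {
  motus <- split(names(part), part)
  otus <- split(names(species), species)
  exact <- sum(vapply(motus, function(m)
    any(vapply(otus, function(o) setequal(m, o), logical(1))), logical(1)))
  splits <- sum(vapply(otus, function(o)
    length(unique(part[o])) >= 2, logical(1)))
  lumps <- sum(vapply(motus, function(m)
    length(unique(species[m])) >= 2, logical(1)))
  list(n_exact_matches = exact, n_split_otus = splits,
       n_lumped_motus = lumps)
}

## PhiST by explicit AMOVA sums (Excoffier-style), written independently
oracle_phi_st <- function(d, groups) {
  N <- length(groups)
  gl <- unique(groups)
  G <- length(gl)
  ssd_tot <- 0
  for (i in 1:(N - 1)) for (j in (i + 1):N) ssd_tot <- ssd_tot + d[i, j]^2
  ssd_tot <- ssd_tot / N
  ssd_wp <- 0; ns <- integer(G)
  for (k in seq_len(G)) {
    idx <- which(groups == gl[k]); ns[k] <- length(idx)
    s <- 0
    if (length(idx) > 1)
      for (a in 1:(length(idx) - 1)) for (b in (a + 1):length(idx))
        s <- s + d[idx[a], idx[b]]^2
    ssd_wp <- ssd_wp + s / ns[k]
  }
  ssd_ap <- ssd_tot - ssd_wp
  sig_w <- ssd_wp / (N - G)
  nbar <- (N - sum(ns^2) / N) / (G - 1)
  sig_a <- (ssd_ap / (G - 1) - sig_w) / nbar
  sig_a / (sig_a + sig_w)
}

## random rooted two-rate delimitation tree as newick text:
## species-tree branches ~ Exp(mean_between), within-species coalescent
## branches ~ Exp(mean_within); returns list(tree, truth partition)
sim_two_rate_tree <- function(n_species, leaves_per_species,
                              mean_between = 0.05, mean_within = 0.002,
                              between_floor = 0) {
  subtree <- function(labels, lenf) {
    while (length(labels) > 1) {
      i <- sample(length(labels), 2)
      merged <- sprintf("(%s:%.8f,%s:%.8f)", labels[i[1]], lenf(),
                        labels[i[2]], lenf())
      labels <- c(labels[-i], merged)
    }
    labels
  }
  len_w <- function() rexp(1, 1 / mean_within)
  len_b <- function() between_floor + rexp(1, 1 / mean_between)
  sp_frag <- character(n_species)
  truth <- integer(0)
  for (s in seq_len(n_species)) {
    tips <- sprintf("s%02dt%02d", s, seq_len(leaves_per_species))
    truth <- c(truth, stats::setNames(rep(s, length(tips)), tips))
    sp_frag[s] <- if (leaves_per_species == 1) tips
                  else subtree(tips, len_w)
  }
  nwk <- paste0(subtree(sp_frag, len_b), ";")
  list(tree = ape::read.tree(text = nwk), truth = truth)
}

## write an alignment to a temp FASTA and return the path
tmp_fasta <- function(aln, ...) {
  path <- tempfile(fileext = ".fas")
  write_fasta_alignment(aln, path, ...)
  path
}
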