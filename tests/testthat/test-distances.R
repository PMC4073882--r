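test_that("pairwise counts follow pairwise deletion and ts/tv definitions", {
  expect_equal(pairwise_counts("ACGT", "ACGT"),
               list(overlap = 4L, ts = 0L, tv = 0L))
  expect_equal(pairwise_counts("ACGT", "GCGT"),
               list(overlap = 4L, ts = 1L, tv = 0L))  # A<->G transition
  expect_equal(pairwise_counts("AC-T", "ACGT"),
               list(overlap = 3L, ts = 0L, tv = 0L))  # gap column skipped
  expect_equal(pairwise_counts("ACGT", "TCGA"),
               list(overlap = 4L, ts = 0L, tv = 2L))  # A<->T both ways
  expect_equal(pairwise_counts("NNNN", "ACGT"),
               list(overlap = 0L, ts = 0L, tv = 0L))  # ambiguity = missing
})

test_that("pairwise counts match a character-level oracle on random pairs", {
  set.seed(12)
  alph <- c("A", "C", "G", "T", "-", "?", "N", "R")
  for (rep in 1:25) {
    a <- paste(sample(alph, 60, TRUE), collapse = "")
    b <- paste(sample(alph, 60, TRUE), collapse = "")
    expect_equal(pairwise_counts(a, b), oracle_pair_counts(a, b))
  }
})

test_that("K2P evaluates its closed form and returns NA at saturation", {
  expect_equal(k2p(list(overlap = 50, ts = 0, tv = 0)), 0)
  expect_equal(k2p(list(overlap = 20, ts = 2, tv = 1)),
               -0.5 * log((1 - 0.2 - 0.05) * sqrt(1 - 0.1)))
  expect_equal(round(k2p(list(overlap = 20, ts = 2, tv = 1)), 4), 0.1702)
  expect_true(is.na(k2p(list(overlap = 10, ts = 5, tv = 0))))  # log(0)
  expect_true(is.na(k2p(list(overlap = 0, ts = 0, tv = 0))))
  ## correction is non-negative: k2p >= p whenever defined
  set.seed(3)
  for (rep in 1:50) {
    ov <- sample(20:200, 1)
    ts <- sample(0:floor(ov / 4), 1); tv <- sample(0:floor(ov / 5), 1)
    pc <- list(overlap = ov, ts = ts, tv = tv)
    if (!is.na(k2p(pc))) expect_gte(k2p(pc), p_distance(pc) - 1e-12)
  }
})

test_that("distance matrix equals brute-force per-pair recomputation", {
  aln <- random_aln(20, 120, seed = 8, missing_frac = 0.1)
  dm <- distance_matrix(aln, model = "k2p", min_overlap = 50)
  for (i in 1:19) for (j in (i + 1):20) {
    pc <- oracle_pair_counts(aln$seq[i], aln$seq[j])
    exp_d <- if (pc$overlap < 50) NA_real_
             else oracle_k2p(pc$overlap, pc$ts, pc$tv)
    expect_equal(dm$d[i, j], exp_d, tolerance = 1e-12)
    expect_equal(dm$overlap[i, j], pc$overlap)
    expect_equal(dm$d[j, i], dm$d[i, j])
  }
  expect_true(all(diag(dm$d) == 0))
})

test_that("distance matrix agrees with ape::dist.dna on clean alignments", {
  sim <- simulate_dataset(sim_config(n_species_per_genus = 3,
                                     n_seqs_per_species = 3, seed = 14))
  aln <- sim$alignment
  dm <- distance_matrix(aln, model = "k2p", min_overlap = 100)
  bin <- ape::as.DNAbin(lapply(strsplit(tolower(aln$seq), ""), identity))
  names(bin) <- aln$id
  ref <- as.matrix(ape::dist.dna(ape::as.matrix.DNAbin(bin), model = "K80",
                                 pairwise.deletion = TRUE))
  expect_equal(unname(dm$d), unname(ref[aln$id, aln$id]), tolerance = 1e-9)
  dp <- distance_matrix(aln, model = "p", min_overlap = 100)
  refp <- as.matrix(ape::dist.dna(ape::as.matrix.DNAbin(bin), model = "raw",
                                  pairwise.deletion = TRUE))
  expect_equal(unname(dp$d), unname(refp[aln$id, aln$id]), tolerance = 1e-9)
})

test_that("pairs bin at the most specific shared rank", {
  aln <- make_aln(c("ACGTACGTACGT", "ACGAACGTACGT", "AGGAACGTACGT"),
                  species = c("s1", "s1", "s2"),
                  genus = rep("g1", 3), family = rep("f1", 3),
                  order = rep("o1", 3))
  dm <- distance_matrix(aln, min_overlap = 5)
  ls <- level_summaries(dm, aln)
  expect_equal(ls$levels$within_species$n_pairs, 1L)
  expect_equal(ls$levels$within_genus$n_pairs, 2L)
  expect_equal(ls$levels$within_family$n_pairs, 0L)
  total <- sum(vapply(ls$levels, `[[`, integer(1), "n_pairs"))
  expect_equal(total + ls$n_undefined, choose(3, 2))
})

test_that("level means increase with rank on simulated data", {
  sim <- simulate_dataset(sim_config(n_orders = 2, n_families_per_order = 2,
                                     n_genera_per_family = 2,
                                     n_species_per_genus = 2,
                                     n_seqs_per_species = 2, seed = 9))
  dm <- distance_matrix(sim$alignment, min_overlap = 100)
  ls <- level_summaries(dm, sim$alignment)
  m <- vapply(ls$levels, `[[`, numeric(1), "mean")
  defined <- m[!is.na(m)]
  expect_true(all(diff(defined) > 0))
  expect_gte(length(defined), 4)
})

test_that("Mann-Whitney U: exact enumeration, ties, and wilcox agreement", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)      # 2/20 labelings as extreme
  expect_identical(r$method, "exact")

  same <- mann_whitney_u(c(1, 2, 2, 3), c(1, 2, 2, 3))
  expect_gte(same$p, 0.99)

  ## U statistic equals direct pair counting, with and without ties
  set.seed(7)
  for (rep in 1:20) {
    x <- sample(1:8, sample(2:5, 1), TRUE)
    y <- sample(1:8, sample(2:5, 1), TRUE)
    expect_equal(mann_whitney_u(x, y)$U, oracle_u(x, y))
  }
  ## tie-free exact p matches wilcox.test's exact distribution
  for (rep in 1:10) {
    x <- sample(seq(0.01, 1, by = 0.01), 5)
    y <- sample(setdiff(seq(0.01, 1, by = 0.01), x), 6)
    expect_equal(mann_whitney_u(x, y)$p,
                 wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  expect_error(mann_whitney_u(numeric(0), 1), "empty")
})

test_that("exact and normal Mann-Whitney paths agree near the crossover", {
  set.seed(11)
  for (rep in 1:12) {
    x <- rnorm(6); y <- rnorm(6, mean = 0.8)
    pe <- mann_whitney_u(x, y, exact_max = 12)$p
    pn <- mann_whitney_u(x, y, exact_max = 0)$p
    expect_lte(abs(pe - pn), 0.01)
  }
})

test_that("barcode gap report handles zero-distance pairs and singletons", {
  sim <- simulate_dataset(sim_config(n_species_per_genus = 5,
                                     n_seqs_per_species = 4,
                                     n_zero_pairs = 1, seed = 17))
  dm <- distance_matrix(sim$alignment, min_overlap = 100)
  gap <- barcode_gap_report(dm, sim$alignment$species)
  zp <- sim$truth$zero_pairs
  sp_zero <- sim$truth$records$species[
    sim$truth$records$id %in% c(zp$donor, zp$receiver)]
  for (sp in sp_zero) {
    expect_equal(gap$min_inter[gap$species == sp], 0)
    expect_lt(gap$gap[gap$species == sp], 0)
  }
  ## well-separated species keep positive gaps
  others <- setdiff(gap$species, sp_zero)
  expect_true(all(gap$gap[gap$species %in% others] > 0))

  ## singleton species: undefined max_intra, defined min_inter
  aln <- make_aln(c("ACGTACGTACGT", "ACGTACGTACGA", "TTTTACGTACGA"),
                  species = c("s1", "s1", "s2"))
  g2 <- barcode_gap_report(distance_matrix(aln, min_overlap = 5), aln$species)
  expect_true(is.na(g2$max_intra[g2$species == "s2"]))
  expect_false(is.na(g2$min_inter[g2$species == "s2"]))
})

test_that("sliding-window pi matches hand counts and whole-fragment mean", {
  ident <- make_aln(rep(paste(rep("ACGT", 5), collapse = ""), 4),
                    species = rep("s", 4))
  res <- sliding_window_pi(ident, window = 10, step = 5)
  expect_true(all(res$windows$pi == 0))
  expect_equal(res$mean_pi, 0)

  two <- make_aln(c("AAAAAAAAAA", "AAAAAAAACC"), species = c("s", "s"))
  r2 <- sliding_window_pi(two, window = 10, step = 10)
  expect_equal(nrow(r2$windows), 1L)
  expect_equal(r2$windows$pi, 0.2)

  ## mean over disjoint windows equals whole-fragment pi (gap-free data)
  aln <- random_aln(6, 120, seed = 23)
  r3 <- sliding_window_pi(aln, window = 10, step = 10)
  expect_equal(mean(r3$windows$pi), r3$mean_pi, tolerance = 1e-12)
  expect_equal(nrow(r3$windows), 12L)     # trailing partials dropped

  expect_error(sliding_window_pi(two, window = 50), "window")
})

test_that("distance histograms are per-level percentages summing to 100", {
  sim <- simulate_dataset(sim_config(n_species_per_genus = 4,
                                     n_seqs_per_species = 3, seed = 19))
  dm <- distance_matrix(sim$alignment, min_overlap = 100)
  hist <- distance_histogram(level_summaries(dm, sim$alignment),
                             bin_width = 0.01)
  for (lev in unique(hist$level))
    expect_equal(sum(hist$percent[hist$level == lev]), 100, tolerance = 1e-9)
  one <- distance_histogram(
    list(levels = list(within_species = list(values = 0.013))), 0.01)
  expect_equal(one$percent, 100)
  expect_equal(one$bin_lower, 0.01)
})
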