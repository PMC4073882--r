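test_that("difference graph applies overlap and identity gates", {
  set.seed(1)
  L <- 400
  s <- function(x) paste(x, collapse = "")
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  v40 <- base; v40[1:40] <- ifelse(base[1:40] == "A", "C", "A")
  short <- base; short[81:L] <- "?"
  aln <- make_aln(c(s(base), s(base), s(v40), s(short)),
                  species = c("x", "x", "y", "z"))
  g <- build_difference_graph(aln, min_overlap = 100, identity_filter = 85)
  e <- g$edges
  pick <- function(i, j) e[e$i == i & e$j == j, ]
  expect_equal(pick("r01", "r02")$abs_diff, 0)
  expect_equal(pick("r01", "r02")$identity, 100)
  expect_equal(pick("r01", "r03")$abs_diff, 40)
  expect_equal(pick("r01", "r03")$identity, 90)
  ## 80 bp overlap fails the 100 bp gate: no edges to r04
  expect_false(any(e$i == "r04" | e$j == "r04"))
})

test_that("threshold clustering is single-linkage on the bp cutoff", {
  ## diffs: AB=1, BC=2, AC=3
  aln <- make_aln(c(paste(rep("A", 120), collapse = ""),
                    paste(c("C", rep("A", 119)), collapse = ""),
                    paste(c("C", "C", "C", rep("A", 117)), collapse = "")),
                  species = c("a", "b", "c"))
  g <- build_difference_graph(aln, min_overlap = 10, identity_filter = 50)
  p2 <- threshold_clusters(g, 2)
  expect_equal(p2$n_motus, 1L)      # chaining A-B-C
  p0 <- threshold_clusters(g, 0)
  expect_equal(p0$n_motus, 3L)
  ## cutoff 0 groups exactly the identical sequences
  aln2 <- make_aln(rep(c("ACGTACGTACGT", "ACGAACGTACGT"), 2),
                   species = rep("s", 4))
  g2 <- build_difference_graph(aln2, min_overlap = 5, identity_filter = 50)
  q <- threshold_clusters(g2, 0)
  expect_equal(q$n_motus, 2L)
  expect_equal(unname(q$assignment[1]), unname(q$assignment[3]))
})

test_that("MOTU curves are monotone with correct endpoints", {
  sim <- simulate_dataset(sim_config(n_species_per_genus = 5,
                                     n_seqs_per_species = 4, seed = 12))
  g <- build_difference_graph(sim$alignment, min_overlap = 100,
                              identity_filter = 50)
  maxdiff <- max(g$edges$abs_diff)
  curve <- motu_curve(g, c(seq(0, 60, by = 2), maxdiff),
                      cutoff_unit = "bp")
  expect_true(all(diff(curve$n_motus) <= 0))
  expect_equal(curve$n_motus[curve$cutoff == 0],
               length(unique(sim$alignment$seq)))
  expect_equal(curve$n_motus[curve$cutoff >= maxdiff][1], 1L)
})

test_that("percent cutoffs convert via mean ungapped length, half-up", {
  aln <- make_aln(c(paste(c(rep("A", 200), "?"), collapse = ""),
                    paste(rep("A", 201), collapse = "")),
                  species = c("a", "b"))
  g <- build_difference_graph(aln, min_overlap = 10, identity_filter = 50)
  expect_equal(g$mean_ungapped_length, 200.5)
  p <- threshold_clusters(g, 3, cutoff_unit = "percent")
  expect_equal(p$cutoff_bp, floor(0.03 * 200.5 + 0.5))  # 6 bp
})

test_that("plateau at the true species count under clear separation", {
  sim <- simulate_dataset(sim_config(n_species_per_genus = 10,
                                     n_genera_per_family = 2,
                                     n_seqs_per_species = 5,
                                     d_within = 0.01, d_species = 0.05,
                                     seed = 42))
  g <- build_difference_graph(sim$alignment, min_overlap = 100,
                              identity_filter = 85)
  curve <- motu_curve(g, c(1.5, 2, 2.5, 3, 3.5, 4), cutoff_unit = "percent")
  ## exact species count across the central plateau; at the tight 1.5%
  ## edge the intra-distance tail may over-split but never lump
  expect_true(all(curve$n_motus[curve$cutoff >= 2] == sim$truth$n_species))
  expect_true(all(curve$n_motus >= sim$truth$n_species))
  cc <- concordance(threshold_clusters(g, 3, "percent"),
                    stats::setNames(sim$alignment$species,
                                    sim$alignment$id))
  expect_equal(cc$n_exact_matches, sim$truth$n_species)
})

test_that("intraspecific threshold is the pooled-intra percentile", {
  sp <- c(rep("a", 100), "b")
  d <- matrix(0, 101, 101,
              dimnames = list(sprintf("r%03d", 1:101), sprintf("r%03d", 1:101)))
  ## species a: 100 records; fill intra distances deterministically
  vals <- c(rep(0.01, 99))
  k <- 0
  for (i in 1:100) for (j in i:100) if (i != j) {
    d[i, j] <- d[j, i] <- 0.01
  }
  d[1, 2] <- d[2, 1] <- 0.50            # one aberrant intra pair
  dm <- structure(list(ids = rownames(d), d = d,
                       overlap = d * 0 + 400, model = "k2p",
                       min_overlap = 100), class = "barcode_dist")
  thr <- intraspecific_threshold(dm, sp, percentile = 95)
  expect_equal(thr, 0.01)               # p95 of {0.01 x4949, 0.5 x1}
  ## monotone in percentile
  expect_lte(thr, intraspecific_threshold(dm, sp, percentile = 100))
  expect_error(intraspecific_threshold(dm, sprintf("u%03d", 1:101)),
               "cannot calibrate")
})

test_that("best close match verdicts follow the threshold and tie rules", {
  ids <- c("q", "c1", "h1", "h2")
  d <- matrix(c(0, 0.01, 0.02, 0.3,
                0.01, 0, 0.025, 0.3,
                0.02, 0.025, 0, 0.3,
                0.3, 0.3, 0.3, 0), 4, 4, dimnames = list(ids, ids))
  dm <- structure(list(ids = ids, d = d, overlap = d * 0 + 400,
                       model = "k2p", min_overlap = 100),
                  class = "barcode_dist")
  sp <- c("A", "A", "B", "C")
  r <- best_close_match(dm, sp, threshold = 0.03)
  expect_equal(r$verdict[r$query == "q"], "correct")
  expect_equal(r$verdict[r$query == "h2"], "no_id")   # nearest 0.3 > thr

  ## nearest heterospecific at distance zero: the only failure mode
  d2 <- d; d2["q", "h1"] <- d2["h1", "q"] <- 0
  dm2 <- dm; dm2$d <- d2
  r2 <- best_close_match(dm2, sp, threshold = 0.03)
  expect_equal(r2$verdict[r2$query == "q"], "incorrect")
  ## conspecific also at zero -> ambiguous
  d3 <- d2; d3["q", "c1"] <- d3["c1", "q"] <- 0
  dm3 <- dm; dm3$d <- d3
  r3 <- best_close_match(dm3, sp, threshold = 0.03)
  expect_equal(r3$verdict[r3$query == "q"], "ambiguous")
})

test_that("leave-one-out BCM has no false positives on separated species", {
  sim <- simulate_dataset(sim_config(n_species_per_genus = 8,
                                     n_seqs_per_species = 4,
                                     d_within = 0.01, d_species = 0.05,
                                     seed = 9))
  dm <- distance_matrix(sim$alignment, min_overlap = 100)
  thr <- intraspecific_threshold(dm, sim$alignment$species, 95)
  r <- best_close_match(dm, sim$alignment$species, thr)
  expect_equal(sum(r$verdict == "incorrect"), 0L)
  expect_gt(mean(r$verdict == "correct"), 0.8)
})

test_that("reference/query split mode excludes all queries from references", {
  sim <- simulate_dataset(sim_config(n_species_per_genus = 4,
                                     n_seqs_per_species = 3, seed = 15))
  dm <- distance_matrix(sim$alignment, min_overlap = 100)
  queries <- sim$alignment$id[seq(1, 24, by = 6)]
  r <- best_close_match(dm, sim$alignment$species, threshold = 0.05,
                        mode = "reference", query_ids = queries)
  expect_setequal(r$query, queries)
  for (k in seq_len(nrow(r))) {
    if (is.na(r$nearest_ids[k])) next
    near <- strsplit(r$nearest_ids[k], ",")[[1]]
    expect_false(any(near %in% queries))
  }
})

test_that("concordance counts match the brute-force oracle", {
  ## identity partition
  sp <- stats::setNames(rep(c("A", "B", "C"), each = 3), sprintf("r%d", 1:9))
  ident <- stats::setNames(as.integer(factor(sp)), names(sp))
  cc <- concordance(ident, sp)
  expect_equal(cc$n_exact_matches, 3L)
  expect_equal(cc$n_split_otus, 0L)
  expect_equal(cc$n_lumped_motus, 0L)

  ## one species split in two
  split1 <- ident; split1[1] <- 99L
  cc2 <- concordance(split1, sp)
  expect_equal(cc2$n_split_otus, 1L)
  expect_equal(cc2$n_exact_matches, 2L)

  ## random partitions vs oracle
  set.seed(6)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    ids <- sprintf("x%02d", seq_len(n))
    sp_r <- stats::setNames(sample(LETTERS[1:6], n, TRUE), ids)
    part <- stats::setNames(sample.int(7, n, TRUE), ids)
    got <- concordance(part, sp_r)
    want <- oracle_concordance(part, sp_r)
    expect_equal(got$n_exact_matches, want$n_exact_matches)
    expect_equal(got$n_split_otus, want$n_split_otus)
    expect_equal(got$n_lumped_motus, want$n_lumped_motus)
    ## invariance to MOTU id relabeling
    relab <- stats::setNames(match(part, unique(part)) + 100L, ids)
    expect_equal(concordance(relab, sp_r)$n_exact_matches,
                 got$n_exact_matches)
  }
})
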