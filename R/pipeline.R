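#' Configuration for a full barcode-identification assessment
#'
#' @param input path to an aligned FASTA with taxonomy headers, or
#'   \code{NULL} to simulate a dataset.
#' @param sim a \code{\link{sim_config}} used when \code{input} is
#'   \code{NULL}.
#' @param variants which alignment variants to analyse, a subset of
#'   \code{c("original", "standard", "unique")}.
#' @param min_len,strict standard-variant length filter.
#' @param window_start,window_end unique-variant trimming window.
#' @param min_overlap minimum pairwise overlap (bp) for distances and
#'   the difference graph.
#' @param identity_filter difference-graph identity gate (percent).
#' @param numt_z_cut robust-SD multiplier for numt divergence flagging.
#' @param cutoff_grid percent cutoffs for the MOTU curve.
#' @param motu_cutoff percent cutoff for the reported MOTU partition.
#' @param bcm_percentile percentile of intraspecific distances used as
#'   the best-close-match threshold.
#' @param tree \code{NULL} (build NJ internally), a newick path for an
#'   externally estimated rooted tree, or \code{FALSE} to skip the
#'   tree/PTP stage.
#' @param seed root RNG seed for every stochastic stage.
#' @return a \code{run_config} list.
#' @export
run_config <- function(input = NULL, sim = sim_config(),
                       variants = c("original", "standard", "unique"),
                       min_len = 500, strict = TRUE,
                       window_start = 96, window_end = 497,
                       min_overlap = 100, identity_filter = 85,
                       numt_z_cut = 5,
                       cutoff_grid = seq(0, 6, by = 0.5),
                       motu_cutoff = 3, bcm_percentile = 95,
                       tree = NULL, seed = 1) {
  cfg <- as.list(environment())
  cfg$variants <- match.arg(variants, several.ok = TRUE)
  class(cfg) <- "run_config"
  cfg
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full barcode species-identification assessment
#'
#' Ingests (or simulates) a taxonomy-annotated barcode alignment,
#' screens and removes putative numts, builds the requested alignment
#' variants, and for each variant computes length summaries, taxon
#' censuses, distance-level summaries, a barcode-gap report, MOTU
#' curves and a threshold partition with OTU concordance, and
#' best-close-match verdict tallies. Sliding-window nucleotide
#' diversity and (optionally) NJ+PTP delimitation run on the unique
#' variant. Deterministic for a fixed config and seed.
#'
#' @param cfg a \code{\link{run_config}}.
#' @param out_dir output directory for the report (JSON) and TSV
#'   intermediates; \code{NULL} writes nothing.
#' @return an \code{assessment_report} list (see fields in the JSON).
#' @export
run_assessment <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  truth <- NULL
  if (is.null(cfg$input)) {
    cfg$sim$seed <- cfg$seed
    sim <- simulate_dataset(cfg$sim)
    aln0 <- sim$alignment
    truth <- sim$truth
  } else {
    aln0 <- read_fasta_alignment(cfg$input)
  }

  numt_rep <- screen_numts(aln0, z_cut = cfg$numt_z_cut,
                           min_overlap = cfg$min_overlap)
  aln <- if (any(numt_rep$decision == "remove"))
    subset_records(aln0, numt_rep$decision == "keep") else aln0

  report <- list(
    n_input = length(aln0$id),
    n_removed_numts = sum(numt_rep$decision == "remove"),
    length_summary = length_summary(aln, gold_min = cfg$min_len),
    taxa_census = as.list(taxa_census(aln)),
    variants = list()
  )

  make_variant <- function(v) {
    switch(v,
      original = aln,
      standard = build_standard_subset(aln, min_len = cfg$min_len,
                                       strict = cfg$strict),
      unique = build_unique_subset(
        aln, start = min(cfg$window_start, aln$aligned_length - 1),
        end = min(cfg$window_end, aln$aligned_length)))
  }

  for (v in cfg$variants) {
    va <- make_variant(v)
    dm <- distance_matrix(va, model = "k2p", min_overlap = cfg$min_overlap)
    ls <- level_summaries(dm, va)
    gap <- barcode_gap_report(dm, va$species)
    g <- build_difference_graph(va, min_overlap = cfg$min_overlap,
                                identity_filter = cfg$identity_filter)
    curve <- motu_curve(g, cfg$cutoff_grid, cutoff_unit = "percent")
    part <- threshold_clusters(g, cfg$motu_cutoff, cutoff_unit = "percent")
    conc <- concordance(part, stats::setNames(va$species, va$id))
    thr <- tryCatch(intraspecific_threshold(dm, va$species,
                                            cfg$bcm_percentile),
                    error = function(e) NA_real_)
    bcm_tally <- NULL
    if (!is.na(thr)) {
      bcm <- best_close_match(dm, va$species, threshold = thr)
      bcm_tally <- as.list(table(factor(bcm$verdict,
        levels = c("correct", "incorrect", "ambiguous", "no_id"))))
      if (!is.null(out_dir))
        .write_tsv(bcm, file.path(out_dir, paste0("bcm_", v, ".tsv")))
    }
    block <- list(
      n_records = length(va$id),
      level_means = lapply(ls$levels, `[[`, "mean"),
      n_undefined_pairs = ls$n_undefined,
      n_species_no_gap = attr(gap, "n_no_gap"),
      motu_curve = curve,
      n_motus_at_cutoff = part$n_motus,
      concordance = conc[c("n_motus", "n_otus", "n_exact_matches",
                           "n_split_otus", "n_lumped_motus")],
      bcm_threshold = thr,
      bcm_verdicts = bcm_tally
    )
    if (v == "unique") {
      win <- min(100, va$aligned_length)
      pi_res <- sliding_window_pi(va, window = win, step = 10)
      block$mean_pi <- pi_res$mean_pi
      if (!is.null(out_dir))
        .write_tsv(pi_res$windows, file.path(out_dir, "pi_unique.tsv"))
      if (!isFALSE(cfg$tree) && length(va$id) >= 3 &&
          !anyNA(dm$d)) {
        tr <- if (is.character(cfg$tree)) read_newick(cfg$tree)
              else midpoint_root(neighbor_joining(dm))
        ptp <- ptp_delimit(tr, seed = cfg$seed)
        block$ptp_n_parts <- ptp$n_parts
        block$ptp_concordance <- concordance(
          ptp, stats::setNames(va$species, va$id))[
            c("n_motus", "n_otus", "n_exact_matches")]
      }
    }
    report$variants[[v]] <- block
    if (!is.null(out_dir)) {
      .write_tsv(curve, file.path(out_dir, paste0("motu_curve_", v, ".tsv")))
      .write_tsv(data.frame(id = names(part$assignment),
                            motu = part$assignment),
                 file.path(out_dir, paste0("motus_", v, ".tsv")))
      .write_tsv(gap, file.path(out_dir, paste0("gap_", v, ".tsv")))
    }
  }
  if (!is.null(truth)) report$truth_n_species <- truth$n_species
  if (!is.null(out_dir)) {
    .write_tsv(numt_rep, file.path(out_dir, "numt_report.tsv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns", force = TRUE)
  }
  class(report) <- "assessment_report"
  report
}

#' @export
print.assessment_report <- function(x, ...) {
  cat(sprintf("Barcode assessment: %d records in (%d numts removed)\n",
              x$n_input, x$n_removed_numts))
  for (v in names(x$variants)) {
    b <- x$variants[[v]]
    cat(sprintf("  %-9s %4d records, %d MOTUs at cutoff, %d/%d exact OTU matches\n",
                v, b$n_records, b$n_motus_at_cutoff,
                b$concordance$n_exact_matches, b$concordance$n_otus))
  }
  invisible(x)
}
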