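#' Configuration for the barcode dataset simulator
#'
#' Defines a balanced 4-level taxonomy evolved under a
#' transition/transversion-biased (K2P-type) per-site substitution
#' process, with within-species haplotype variation, optional read
#' truncation, numt contamination, zero-distance heterospecific pairs,
#' and deep conspecific (cryptic) splits.
#'
#' Expected divergences are cumulative down the taxonomy: each rank's
#' ancestor sits \code{d_<rank>} expected substitutions/site from its
#' parent ancestor, and haplotypes sit \code{d_within} from the species
#' ancestor. The defaults emulate a COI barcode survey: 658 bp
#' sequences, kappa = 4, about 1% haplotype variation within species
#' and >= 5% divergence between congeneric species.
#'
#' @param n_orders,n_families_per_order,n_genera_per_family,n_species_per_genus
#'   taxonomy shape.
#' @param n_seqs_per_species records per species: a single integer, a
#'   vector recycled over species, or \code{"geometric"} for a skewed
#'   draw (mean ~4, min 1) emulating unbalanced sampling.
#' @param seq_len alignment length in bp, default 658.
#' @param kappa transition/transversion rate ratio, default 4.
#' @param d_within expected pairwise intra-species distance, default 0.01.
#' @param d_species,d_genus,d_family,d_order expected divergence added at
#'   each rank; must increase strictly with rank.
#' @param truncation \code{NULL} for full-length reads, or a list
#'   \code{list(p = , min_len = )}: each record is independently
#'   truncated with probability \code{p} to a uniform length in
#'   \code{[min_len, seq_len]} by masking flanks with \code{?}.
#' @param p_numt probability a record is replaced by a numt paralog.
#' @param n_zero_pairs heterospecific record pairs forced to distance 0
#'   (a congener's record receives a copy of another species' haplotype).
#' @param n_cryptic species split into two lineages ~5-7% apart.
#' @param seed RNG seed; fixed seed gives identical output.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_orders = 1, n_families_per_order = 1,
                       n_genera_per_family = 2, n_species_per_genus = 5,
                       n_seqs_per_species = 5, seq_len = 658, kappa = 4,
                       d_within = 0.01, d_species = 0.05, d_genus = 0.10,
                       d_family = 0.15, d_order = 0.20,
                       truncation = NULL, p_numt = 0, n_zero_pairs = 0,
                       n_cryptic = 0, seed = 1) {
  cfg <- as.list(environment())
  dd <- c(d_within, d_species, d_genus, d_family, d_order)
  if (any(dd < 0) || any(diff(dd) <= 0))
    stop("divergences must satisfy d_within < d_species < d_genus ",
         "< d_family < d_order, all >= 0")
  if (p_numt < 0 || p_numt > 1) stop("p_numt must lie in [0,1]")
  class(cfg) <- "sim_config"
  cfg
}

## K80 substitution probabilities after expected distance d (subs/site).
## Rates scaled so alpha + 2 beta = 1: alpha = kappa/(kappa+2).
.k80_probs <- function(d, kappa) {
  a <- kappa / (kappa + 2)
  b <- 1 / (kappa + 2)
  p_ts <- 0.25 + 0.25 * exp(-4 * b * d) - 0.5 * exp(-2 * (a + b) * d)
  p_tv <- 0.25 - 0.25 * exp(-4 * b * d)   # each of the two transversions
  c(same = 1 - p_ts - 2 * p_tv, ts = p_ts, tv = p_tv)
}

## Evolve an encoded sequence (ints 1:4) by expected distance d.
## Transitions: 1<->3 (A<->G), 2<->4 (C<->T).
.evolve <- function(seq, d, kappa) {
  p <- .k80_probs(d, kappa)
  n <- length(seq)
  u <- stats::runif(n)
  out <- seq
  ts_partner <- c(3L, 4L, 1L, 2L)
  tv1 <- c(2L, 1L, 2L, 1L)   # one transversion target per base
  tv2 <- c(4L, 3L, 4L, 3L)
  hit_ts <- u < p["ts"]
  hit_tv1 <- u >= p["ts"] & u < p["ts"] + p["tv"]
  hit_tv2 <- u >= p["ts"] + p["tv"] & u < p["ts"] + 2 * p["tv"]
  out[hit_ts] <- ts_partner[seq[hit_ts]]
  out[hit_tv1] <- tv1[seq[hit_tv1]]
  out[hit_tv2] <- tv2[seq[hit_tv2]]
  out
}

## stop codons TAA/TAG (invertebrate mito code) on encoded ints: T=4 A=1 G=3
.stop_codon_starts <- function(v) {
  nc <- length(v) %/% 3
  if (nc == 0) return(integer(0))
  s <- seq_len(nc) * 3 - 2
  first <- v[s]; second <- v[s + 1]; third <- v[s + 2]
  s[first == 4L & second == 1L & (third == 1L | third == 3L)]
}

## Deterministic stop repair for emitted records: a frame-1 TAA/TAG is
## rewritten at its second position (TAA -> TCA, TAG -> TCG, both Ser),
## emulating the purifying constraint that keeps real barcodes readable.
## Identical inherited stops repair identically, so the repair does not
## perturb distances between records sharing the ancestral codon.
.repair_stops <- function(v) {
  s <- .stop_codon_starts(v)
  if (length(s)) v[s + 1L] <- 2L
  v
}

## random coding root: uniform bases with stop codons rejected
.random_coding_root <- function(L) {
  v <- sample.int(4L, L, replace = TRUE)
  repeat {
    bad <- .stop_codon_starts(v)
    if (!length(bad)) return(v)
    for (s in bad) v[s:(s + 2)] <- sample.int(4L, 3L, replace = TRUE)
  }
}

.decode <- function(v) {
  chars <- c("A", "C", "G", "T", "?")
  v[is.na(v)] <- 5L
  paste(chars[v], collapse = "")
}

#' Simulate a taxonomy-structured barcode dataset with known truth
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{alignment} (a \code{barcode_alignment}) and
#'   \code{truth}: \code{records} (data.frame id, species, lineage,
#'   is_numt, numt_mode, in_zero_pair), \code{zero_pairs} (data.frame of
#'   forced pairs), \code{n_species}.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, .simulate_dataset_impl(cfg))
}

.simulate_dataset_impl <- function(cfg) {
  L <- cfg$seq_len
  root <- .random_coding_root(L)

  ids <- character(0); orders <- character(0); families <- character(0)
  genera <- character(0); species <- character(0)
  lineage <- character(0)
  seqs <- list()
  sp_counter <- 0L

  n_total_sp <- cfg$n_orders * cfg$n_families_per_order *
    cfg$n_genera_per_family * cfg$n_species_per_genus
  cryptic_sp <- if (cfg$n_cryptic > 0)
    sort(sample.int(n_total_sp, min(cfg$n_cryptic, n_total_sp))) else integer(0)

  nseq_for <- function(k) {
    v <- cfg$n_seqs_per_species
    if (identical(v, "geometric")) max(1L, stats::rgeom(1, 0.25))
    else as.integer(v[((k - 1) %% length(v)) + 1])
  }

  for (o in seq_len(cfg$n_orders)) {
    anc_o <- .evolve(root, cfg$d_order, cfg$kappa)
    for (f in seq_len(cfg$n_families_per_order)) {
      anc_f <- .evolve(anc_o, cfg$d_family, cfg$kappa)
      for (g in seq_len(cfg$n_genera_per_family)) {
        anc_g <- .evolve(anc_f, cfg$d_genus, cfg$kappa)
        for (s in seq_len(cfg$n_species_per_genus)) {
          sp_counter <- sp_counter + 1L
          anc_s <- .evolve(anc_g, cfg$d_species, cfg$kappa)
          sp_name <- sprintf("sp%03d", sp_counter)
          is_cryptic <- sp_counter %in% cryptic_sp
          if (is_cryptic) {
            ## two lineages ~6% apart (3% each from the species ancestor)
            lin_anc <- list(.evolve(anc_s, 0.03, cfg$kappa),
                            .evolve(anc_s, 0.03, cfg$kappa))
          }
          nk <- nseq_for(sp_counter)
          for (r in seq_len(nk)) {
            lin <- if (is_cryptic) ((r - 1L) %% 2L) + 1L else 1L
            base <- if (is_cryptic) lin_anc[[lin]] else anc_s
            ## haplotypes sit d_within/2 from the ancestor so the expected
            ## pairwise intra-species distance is d_within
            hap <- .repair_stops(.evolve(base, cfg$d_within / 2,
                                         cfg$kappa))
            ids <- c(ids, sprintf("%s_r%02d", sp_name, r))
            orders <- c(orders, sprintf("order%02d", o))
            families <- c(families, sprintf("family%02d_%02d", o, f))
            genera <- c(genera, sprintf("genus%02d_%02d_%02d", o, f, g))
            species <- c(species, sp_name)
            lineage <- c(lineage, sprintf("%s_L%d", sp_name, lin))
            seqs[[length(seqs) + 1L]] <- hap
          }
        }
      }
    }
  }
  n <- length(ids)
  is_numt <- rep(FALSE, n)
  numt_mode <- rep(NA_character_, n)
  in_zero_pair <- rep(FALSE, n)

  ## zero-distance heterospecific pairs: copy a haplotype from one species
  ## into a record of a different species (before truncation/numts)
  zero_pairs <- data.frame(donor = character(0), receiver = character(0),
                           stringsAsFactors = FALSE)
  if (cfg$n_zero_pairs > 0) {
    sp_list <- unique(species)
    if (length(sp_list) < 2) stop("zero pairs need >= 2 species")
    for (z in seq_len(cfg$n_zero_pairs)) {
      for (attempt in 1:1000) {
        pair_sp <- sample(sp_list, 2)
        di <- which(species == pair_sp[1] & !in_zero_pair)
        ri <- which(species == pair_sp[2] & !in_zero_pair)
        if (length(di) && length(ri)) break
      }
      if (!length(di) || !length(ri))
        stop("cannot place requested zero-distance pairs")
      di <- di[1]; ri <- ri[1]
      seqs[[ri]] <- seqs[[di]]
      in_zero_pair[c(di, ri)] <- TRUE
      zero_pairs <- rbind(zero_pairs,
                          data.frame(donor = ids[di], receiver = ids[ri],
                                     stringsAsFactors = FALSE))
    }
  }

  ## truncation: mask flanks with '?' (NA in encoding), keeping columns
  if (!is.null(cfg$truncation)) {
    p_tr <- cfg$truncation$p
    min_len <- cfg$truncation$min_len
    for (i in seq_len(n)) {
      if (stats::runif(1) < p_tr) {
        keep <- sample(min_len:L, 1)
        start <- sample.int(L - keep + 1L, 1)
        v <- seqs[[i]]
        v[-(start:(start + keep - 1L))] <- NA_integer_
        seqs[[i]] <- v
      }
    }
  }

  aln <- barcode_alignment(ids, vapply(seqs, .decode, character(1)),
                           species, genera, families, orders,
                           variant = "original")
  truth <- list(records = data.frame(id = ids, species = species,
                                     lineage = lineage, is_numt = is_numt,
                                     numt_mode = numt_mode,
                                     in_zero_pair = in_zero_pair,
                                     stringsAsFactors = FALSE),
                zero_pairs = zero_pairs,
                n_species = sp_counter)
  out <- list(alignment = aln, truth = truth)
  if (cfg$p_numt > 0)
    out <- inject_numts(out$alignment, out$truth, p_numt = cfg$p_numt,
                        kappa = cfg$kappa,
                        seed = NULL)  # continue the seeded stream
  out
}

#' Replace records with numt paralogs
#'
#' Selected records are replaced by pseudogene-like copies: 15% added
#' divergence, and (in the default \code{"stops"} mode) a TAA stop codon
#' written into each of the three reading frames of the unmasked region,
#' so the paralog has internal stops in every frame. The
#' \code{"divergent"} mode adds divergence only and resamples until the
#' best frame stays stop-free, emulating numts that pass translation
#' filters.
#'
#' @param aln a \code{barcode_alignment}.
#' @param truth a truth list as produced by \code{\link{simulate_dataset}}.
#' @param p_numt per-record replacement probability (ignored when
#'   \code{records} is given).
#' @param records optional character vector of record ids to replace
#'   deterministically instead of sampling.
#' @param mode \code{"stops"} (default) or \code{"divergent"}.
#' @param kappa transition/transversion ratio for the added divergence.
#' @param seed RNG seed (\code{NULL} to continue the current stream).
#' @return list \code{alignment}, \code{truth} with updated numt flags.
#' @export
inject_numts <- function(aln, truth, p_numt = 0, records = NULL,
                         mode = "stops", kappa = 4, seed = NULL) {
  .with_seed(seed, .inject_numts_impl(aln, truth, p_numt, records, mode,
                                      kappa))
}

.inject_numts_impl <- function(aln, truth, p_numt, records, mode, kappa) {
  mode <- match.arg(mode, c("stops", "divergent"))
  n <- length(aln$id)
  pick <- if (!is.null(records)) match(records, aln$id)
          else which(stats::runif(n) < p_numt & !truth$records$in_zero_pair)
  if (!length(pick)) return(list(alignment = aln, truth = truth))
  enc <- .encode_alignment(aln)
  code_T <- 4L; code_A <- 1L
  for (i in pick) {
    v <- enc[i, ]
    present <- which(!is.na(v))
    if (mode == "stops") {
      v[present] <- .evolve(v[present], 0.15, kappa)
      ## one TAA per frame, in non-overlapping mid-sequence codons
      np <- length(present)
      m <- max(1L, floor(np / 12))
      for (f in 1:3) {
        k <- f + 3L * (m + 2L * (f - 1L))    # codon start, frame f
        if (k + 2 > np - 3) k <- f           # fall back for short reads
        pos <- present[k:(k + 2)]
        v[pos] <- c(code_T, code_A, code_A)
      }
    } else {
      ## resample until the paralog still reads through cleanly in some
      ## frame (emulating numts that pass translation filters)
      for (try in 1:200) {
        w <- v
        w[present] <- .evolve(v[present], 0.15, kappa)
        fr <- determine_reading_frame(.decode(w))
        if (fr$min_stops == 0) break
      }
      v <- w
    }
    enc[i, ] <- v
    truth$records$is_numt[i] <- TRUE
    truth$records$numt_mode[i] <- mode
  }
  seqs <- apply(enc, 1, .decode)
  aln2 <- barcode_alignment(aln$id, seqs, aln$species, aln$genus,
                            aln$family, aln$order, variant = aln$variant)
  list(alignment = aln2, truth = truth)
}
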