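## Stop-codon counting under the invertebrate mitochondrial genetic code
## (seqinr numcode 5): stops are TAA and TAG; AGA/AGG encode serine.

.count_internal_stops <- function(nt, frame) {
  ## nt: character vector of residues (ungapped); frame: 1..3 offset
  s <- nt[frame:length(nt)]
  ncod <- length(s) %/% 3
  if (ncod < 2) return(0L)
  aa <- seqinr::translate(s[1:(ncod * 3)], numcode = 5, ambiguous = FALSE)
  sum(aa[-length(aa)] == "*")
}

.ungapped_chars <- function(seq) {
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  s[s %in% c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V", "N")]
}

.revcomp_chars <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
           W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
           N = "N")
  rev(unname(map[s]))
}

#' Determine the protein-coding reading frame of a barcode sequence
#'
#' Translates the ungapped sequence in all three frames under the
#' invertebrate mitochondrial genetic code and picks the frame with the
#' fewest internal stop codons (ties broken toward the lowest frame).
#' A correctly sequenced COI barcode has a stop-free frame; numts
#' typically do not.
#'
#' @param seq a nucleotide string (gaps and \code{?} are removed first).
#' @param search_both_strands also scan the reverse complement; if the
#'   best frame lies there, \code{strand} is \code{"minus"}.
#' @return list with \code{best_frame} (1-3), \code{stops_per_frame}
#'   (named numeric, plus-strand frames), \code{strand}, and
#'   \code{min_stops} (stop count of the returned frame).
#' @export
determine_reading_frame <- function(seq, search_both_strands = FALSE) {
  nt <- .ungapped_chars(seq)
  if (sum(nt %in% c("A", "C", "G", "T")) == 0)
    stop("untranslatable: no unambiguous nucleotides")
  if (length(nt) < 9) stop("sequence too short to frame (<9 bp)")
  stops <- vapply(1:3, function(f) .count_internal_stops(nt, f), integer(1))
  names(stops) <- paste0("frame", 1:3)
  best <- which.min(stops)              # ties -> lowest index
  strand <- "plus"
  min_stops <- stops[[best]]
  if (search_both_strands) {
    rc <- .revcomp_chars(nt)
    stops_rc <- vapply(1:3, function(f) .count_internal_stops(rc, f),
                       integer(1))
    if (min(stops_rc) < min_stops) {
      best <- which.min(stops_rc)
      min_stops <- stops_rc[[best]]
      strand <- "minus"
    }
  }
  list(best_frame = as.integer(best), stops_per_frame = stops,
       strand = strand, min_stops = as.integer(min_stops))
}

#' Screen an alignment for putative numts
#'
#' Nuclear pseudogene copies of COI (numts) betray themselves either by
#' internal stop codons in their best reading frame or by aberrant
#' divergence from conspecifics. A record is flagged divergent when its
#' median K2P distance to conspecifics exceeds the species' median
#' intraspecific distance by \code{z_cut} robust SDs (MAD, floored at
#' 1e-3 substitutions/site). Records without conspecifics cannot be
#' divergence-flagged.
#'
#' @param aln a \code{barcode_alignment}.
#' @param z_cut robust-SD multiplier for the divergence flag, default 5.
#' @param min_overlap minimum pairwise overlap (bp) for distances.
#' @return data.frame with columns \code{record_id},
#'   \code{stop_codons_best_frame}, \code{best_frame},
#'   \code{divergence_flag}, \code{decision} (\code{"keep"}/\code{"remove"}).
#' @export
screen_numts <- function(aln, z_cut = 5, min_overlap = 100) {
  n <- length(aln$id)
  frames <- lapply(aln$seq, determine_reading_frame)
  stops <- vapply(frames, `[[`, integer(1), "min_stops")
  best <- vapply(frames, `[[`, integer(1), "best_frame")

  dm <- distance_matrix(aln, model = "k2p", min_overlap = min_overlap)
  d <- dm$d
  div_flag <- rep(FALSE, n)
  for (sp in unique(aln$species)) {
    idx <- which(aln$species == sp)
    if (length(idx) < 2) next
    sub <- d[idx, idx, drop = FALSE]
    intra <- sub[upper.tri(sub)]
    intra <- intra[!is.na(intra)]
    if (!length(intra)) next
    med <- stats::median(intra)
    thr <- med + z_cut * max(stats::mad(intra), 1e-3)
    for (k in seq_along(idx)) {
      di <- sub[k, -k]
      di <- di[!is.na(di)]
      if (length(di) && stats::median(di) > thr) div_flag[idx[k]] <- TRUE
    }
  }
  decision <- ifelse(stops > 0 | div_flag, "remove", "keep")
  if (all(decision == "remove") && n > 0)
    warning("all records flagged as putative numts")
  data.frame(record_id = aln$id, stop_codons_best_frame = stops,
             best_frame = best, divergence_flag = div_flag,
             decision = decision, stringsAsFactors = FALSE)
}
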