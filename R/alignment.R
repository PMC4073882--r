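#' Construct a barcode alignment object
#'
#' A \code{barcode_alignment} holds a rectangular set of aligned barcode
#' sequences together with a four-level taxonomy (order, family, genus,
#' species) per record. Sequences are upper-case strings over the DNA
#' alphabet plus IUPAC ambiguity codes, \code{-} for alignment gaps and
#' \code{?} for missing data.
#'
#' @param id character vector of unique record identifiers.
#' @param seq character vector of aligned sequences, all the same length.
#' @param species character vector of species labels (required, non-empty).
#' @param genus,family,order character vectors of higher-rank labels;
#'   recycled from \code{""} if omitted.
#' @param variant alignment provenance: \code{"original"}, \code{"standard"}
#'   (length-filtered) or \code{"unique"} (trimmed, haplotype-collapsed).
#' @return an object of class \code{barcode_alignment} with fields
#'   \code{id}, \code{order}, \code{family}, \code{genus}, \code{species},
#'   \code{seq}, \code{variant}, \code{aligned_length}.
#' @export
barcode_alignment <- function(id, seq, species, genus = NULL, family = NULL,
                              order = NULL, variant = "original") {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  species <- as.character(species)
  n <- length(id)
  if (length(seq) != n || length(species) != n)
    stop("id, seq and species must have equal length")
  if (anyDuplicated(id))
    stop("duplicate record id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(!nzchar(species)))
    stop("empty species label for record(s): ",
         paste(id[!nzchar(species)], collapse = ", "))
  lens <- nchar(seq)
  if (n > 0 && length(unique(lens)) != 1L)
    stop("not aligned: sequences differ in length (",
         paste(range(lens), collapse = "-"), ")")
  blank <- function(x) if (is.null(x)) rep("", n) else as.character(x)
  variant <- match.arg(variant, c("original", "standard", "unique"))
  structure(list(
    id = id, order = blank(order), family = blank(family),
    genus = blank(genus), species = species, seq = seq,
    variant = variant,
    aligned_length = if (n) lens[1L] else 0L,
    collapse_map = NULL
  ), class = "barcode_alignment")
}

#' @export
print.barcode_alignment <- function(x, ...) {
  cat(sprintf("Barcode alignment (%s variant): %d records x %d columns\n",
              x$variant, length(x$id), x$aligned_length))
  cat(sprintf("  %d species, %d genera, %d families, %d orders\n",
              length(unique(x$species)),
              length(unique(x$genus[nzchar(x$genus)])),
              length(unique(x$family[nzchar(x$family)])),
              length(unique(x$order[nzchar(x$order)]))))
  invisible(x)
}

#' @export
length.barcode_alignment <- function(x) length(x$id)

#' Subset a barcode alignment by record index or id
#'
#' @param aln a \code{barcode_alignment}.
#' @param i integer, logical or character (ids) index of records to keep.
#' @param variant variant tag for the result; defaults to the input's.
#' @return a \code{barcode_alignment} with the selected records.
#' @export
subset_records <- function(aln, i, variant = aln$variant) {
  if (is.character(i)) i <- match(i, aln$id)
  out <- barcode_alignment(aln$id[i], aln$seq[i], aln$species[i],
                           aln$genus[i], aln$family[i], aln$order[i],
                           variant = variant)
  out
}

## Characters counted as real residues for length / overlap purposes.
## Ambiguity codes and '?' count as missing; '-' is a gap.
.RESIDUES <- c("A", "C", "G", "T")

#' Ungapped length of each record
#'
#' Number of unambiguous nucleotide positions (A/C/G/T) per record;
#' gaps, \code{?} and IUPAC ambiguity codes do not count.
#'
#' @param aln a \code{barcode_alignment}.
#' @return integer vector, one entry per record.
#' @export
ungapped_length <- function(aln) {
  vapply(strsplit(aln$seq, "", fixed = TRUE),
         function(s) sum(s %in% .RESIDUES), integer(1))
}

## Integer-encode an alignment: n x L matrix, A=1 C=2 G=3 T=4, NA otherwise.
.encode_alignment <- function(aln) {
  L <- aln$aligned_length
  m <- matrix(NA_integer_, length(aln$id), L,
              dimnames = list(aln$id, NULL))
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  rows <- strsplit(aln$seq, "", fixed = TRUE)
  for (i in seq_along(rows)) {
    v <- code[rows[[i]]]
    m[i, ] <- ifelse(is.na(v), NA_integer_, v)
  }
  m
}

#' Read an aligned barcode FASTA with taxonomy-bearing headers
#'
#' Definition lines carry the record identifier and the four taxonomy
#' labels in delimited fields, by default \code{id|order|family|genus|species}.
#' The file must be a true alignment: all sequences the same length.
#'
#' @param path path to a FASTA file.
#' @param header_convention character vector naming the header fields in
#'   order; must contain \code{"id"} and \code{"species"}.
#' @param delimiter single-character field delimiter, default \code{"|"}.
#' @return a \code{barcode_alignment} with \code{variant = "original"}.
#' @export
read_fasta_alignment <- function(path,
                                 header_convention = c("id", "order", "family",
                                                       "genus", "species"),
                                 delimiter = "|") {
  if (!all(c("id", "species") %in% header_convention))
    stop("header_convention must include 'id' and 'species'")
  fas <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                            whole.header = TRUE)
  headers <- vapply(fas, function(s) attr(s, "Annot"), character(1))
  headers <- sub("^>", "", headers)
  seqs <- toupper(unlist(fas, use.names = FALSE))
  fields <- strsplit(headers, delimiter, fixed = TRUE)
  bad <- which(lengths(fields) != length(header_convention))
  if (length(bad))
    stop("unparseable header(s): ",
         paste(sprintf("line '>%s'", headers[bad]), collapse = "; "))
  tab <- do.call(rbind, fields)
  colnames(tab) <- header_convention
  get <- function(f) if (f %in% colnames(tab)) tab[, f] else NULL
  barcode_alignment(id = tab[, "id"], seq = seqs, species = tab[, "species"],
                    genus = get("genus"), family = get("family"),
                    order = get("order"), variant = "original")
}

#' Write a barcode alignment to FASTA
#'
#' Headers are emitted under the same delimited convention accepted by
#' \code{\link{read_fasta_alignment}}; sequences wrap at 60 columns.
#'
#' @inheritParams read_fasta_alignment
#' @param aln a \code{barcode_alignment}.
#' @export
write_fasta_alignment <- function(aln, path,
                                  header_convention = c("id", "order",
                                                        "family", "genus",
                                                        "species"),
                                  delimiter = "|") {
  tab <- cbind(id = aln$id, order = aln$order, family = aln$family,
               genus = aln$genus, species = aln$species)
  names <- apply(tab[, header_convention, drop = FALSE], 1, paste,
                 collapse = delimiter)
  seqinr::write.fasta(as.list(aln$seq), names = names, file.out = path,
                      nbchar = 60)
  invisible(path)
}

#' Summarise sequence lengths against a gold-standard minimum
#'
#' Reports the distribution of ungapped sequence lengths and how many
#' records reach the "gold standard" barcode length (conventionally
#' 500 bp for COI).
#'
#' @param aln a \code{barcode_alignment} with at least one record.
#' @param gold_min minimum length in bp, default 500.
#' @return list with \code{n}, \code{mean}, \code{sd} (sample sd, \code{NA}
#'   for a single record), \code{min}, \code{max}, \code{n_ge_gold},
#'   \code{pct_ge_gold}.
#' @export
length_summary <- function(aln, gold_min = 500) {
  if (length(aln$id) == 0) stop("empty alignment")
  len <- ungapped_length(aln)
  n_ge <- sum(len >= gold_min)
  list(n = length(len), mean = mean(len),
       sd = if (length(len) > 1) stats::sd(len) else NA_real_,
       min = min(len), max = max(len),
       n_ge_gold = n_ge, pct_ge_gold = 100 * n_ge / length(len))
}

#' Length-filtered "standard barcode" subset
#'
#' Keeps records whose ungapped length exceeds \code{min_len}
#' (strictly by default). Columns are unchanged.
#'
#' @param aln an original-variant \code{barcode_alignment}.
#' @param min_len length threshold in bp, default 500.
#' @param strict if \code{TRUE} (default) require \code{> min_len},
#'   otherwise \code{>= min_len}.
#' @return a \code{barcode_alignment} with \code{variant = "standard"}.
#' @export
build_standard_subset <- function(aln, min_len = 500, strict = TRUE) {
  len <- ungapped_length(aln)
  keep <- if (strict) len > min_len else len >= min_len
  if (!any(keep))
    stop(sprintf("no records pass the length filter (%d of %d removed)",
                 sum(!keep), length(keep)))
  subset_records(aln, keep, variant = "standard")
}

#' Trimmed, haplotype-unique subset
#'
#' Trims the alignment to a column window (1-based, inclusive), drops
#' records with missing data inside the window (optional), and collapses
#' records with identical windowed sequences \emph{within the same
#' species} to a single first-seen representative. The collapse map is
#' attached as \code{$collapse_map} (data.frame \code{id},
#' \code{representative}).
#'
#' @param aln an original-variant \code{barcode_alignment}.
#' @param start,end window columns, 1-based inclusive.
#' @param drop_missing drop records containing \code{-}, \code{?} or
#'   ambiguity codes inside the window (default \code{TRUE}).
#' @return a \code{barcode_alignment} with \code{variant = "unique"}.
#' @export
build_unique_subset <- function(aln, start = 96, end = 497,
                                drop_missing = TRUE) {
  if (start < 1 || end > aln$aligned_length || start >= end)
    stop("window outside alignment")
  win <- substr(aln$seq, start, end)
  keep <- rep(TRUE, length(win))
  if (drop_missing)
    keep <- !grepl(sprintf("[^%s]", paste(.RESIDUES, collapse = "")), win)
  ids <- aln$id[keep]; wins <- win[keep]; sp <- aln$species[keep]
  key <- paste(sp, wins, sep = "\r")
  rep_idx <- match(key, key)            # first-seen representative per key
  collapse_map <- data.frame(id = ids, representative = ids[rep_idx],
                             stringsAsFactors = FALSE)
  sel <- which(!duplicated(key))
  out <- barcode_alignment(ids[sel], wins[sel], sp[sel],
                           aln$genus[keep][sel], aln$family[keep][sel],
                           aln$order[keep][sel], variant = "unique")
  out$collapse_map <- collapse_map
  out
}

#' Census of distinct taxa per rank
#'
#' @param aln a \code{barcode_alignment}.
#' @return named integer vector: species, genera, families, orders
#'   (distinct non-empty labels).
#' @export
taxa_census <- function(aln) {
  cnt <- function(x) length(unique(x[nzchar(x)]))
  c(species = cnt(aln$species), genera = cnt(aln$genus),
    families = cnt(aln$family), orders = cnt(aln$order))
}
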