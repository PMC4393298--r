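#' Quality filter: longest high-quality run
#'
#' A read is retained when it contains at least `min_run` consecutive bases
#' with Phred score strictly above `min_q` (i.e. Q >= min_q + 1). The defaults
#' (34 consecutive bases above Q20) are the high-quality criterion used for
#' mapping-grade reads.
#'
#' @param reads Tibble with a `qual` list column (integer Phred scores), or a
#'   single integer vector of qualities.
#' @param min_run Required run length.
#' @param min_q Phred threshold; bases must be strictly above it.
#' @return For a tibble, the tibble with logical column `qc_pass`; for a
#'   vector, a single logical.
#' @export
#' @examples
#' quality_filter(rep(21L, 34))
#' quality_filter(c(rep(21L, 33), 10L))
quality_filter <- function(reads, min_run = 34L, min_q = 20L) {
  one <- function(q) longest_true_run(q > min_q) >= min_run
  if (is.numeric(reads)) return(one(reads))
  reads$qc_pass <- vapply(reads$qual, one, logical(1))
  reads
}

longest_true_run <- function(flag) {
  if (!any(flag)) return(0L)
  r <- rle(flag)
  max(r$lengths[r$values])
}

#' Match and trim a 5' barcode
#'
#' Compares the read prefix against every barcode of the set; an "intact"
#' barcode means 0 mismatches (the default). On a match the barcode is
#' trimmed. `N` calls never match.
#'
#' @param reads Tibble with a `sequence` column, or a character vector of
#'   sequences.
#' @param barcodes Character vector of equal-length barcodes.
#' @param max_mismatch Mismatches tolerated (default 0 = exact).
#' @return For a tibble, the tibble with added `barcode` (matched barcode or
#'   `NA`) and `trimmed` (read with the barcode removed; unchanged when no
#'   match). For a vector, a tibble with `sequence`, `barcode`, `trimmed`.
#' @export
#' @examples
#' match_barcode("TCGAGGTAGTAACGT", bless_barcodes())
match_barcode <- function(reads, barcodes, max_mismatch = 0L) {
  if (length(unique(nchar(barcodes))) != 1L) {
    abort("all barcodes in a set must have the same length",
          class = "templateseq_config_error")
  }
  vec_in <- is.character(reads)
  seqs <- if (vec_in) reads else reads$sequence
  bl <- nchar(barcodes[1])
  if (any(nchar(seqs) < bl)) {
    abort("reads must be at least as long as the barcodes",
          class = "templateseq_config_error")
  }
  prefix <- substr(seqs, 1L, bl)
  matched <- rep(NA_character_, length(seqs))
  for (bc in barcodes) {
    mm <- mismatch_count(prefix, bc)
    hit <- is.na(matched) & mm <= max_mismatch
    matched[hit] <- bc
  }
  trimmed <- ifelse(is.na(matched), seqs, substr(seqs, bl + 1L, nchar(seqs)))
  if (vec_in) {
    tibble(sequence = seqs, barcode = matched, trimmed = trimmed)
  } else {
    reads$barcode <- matched
    reads$trimmed <- trimmed
    reads
  }
}

# vectorised mismatch count of equal-length strings against one pattern
mismatch_count <- function(strings, pattern) {
  n <- nchar(pattern)
  mm <- integer(length(strings))
  for (i in seq_len(n)) {
    mm <- mm + (substr(strings, i, i) != substr(pattern, i, i))
  }
  mm
}

#' Hamming distance between equal-length sequences
#'
#' @param a,b Character scalars (or equal-length vectors, compared
#'   elementwise) of equal string length.
#' @return Integer vector of position-wise mismatch counts.
#' @export
#' @examples
#' hamming_distance("TCGAGGTAGTA", "TCGAGACGACG")
hamming_distance <- function(a, b) {
  if (any(nchar(a) != nchar(b))) {
    abort("sequences must have equal length", class = "templateseq_config_error")
  }
  mapply(function(x, y) {
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  }, a, b, USE.NAMES = FALSE)
}

#' Minimum pairwise Hamming distance of a barcode set
#'
#' @param barcodes Character vector of equal-length barcodes.
#' @return Smallest Hamming distance over all pairs.
#' @export
min_pairwise_hamming <- function(barcodes) {
  stopifnot(length(barcodes) >= 2L)
  pairs <- utils::combn(barcodes, 2L)
  min(hamming_distance(pairs[1L, ], pairs[2L, ]))
}

#' Design diverse 5' barcodes on the AasI recognition site
#'
#' The AasI restriction enzyme recognises `GACNNNNNNGTC` and cuts inside the
#' degenerate centre, so primers can carry different variable dinucleotides
#' while remaining cuttable by the same enzyme. Using all four bases in the
#' first variable position yields four distinct 5-mer barcodes whose first
#' cycle is perfectly base-balanced, removing the low-initial-diversity
#' problem at the design stage. Within each primer the two variable
#' dinucleotides are reverse complements of each other, preserving the
#' palindromic pairing of the site.
#'
#' @return List with `primers`, `barcodes` (both character vectors of 4) and
#'   `enzyme_site` (`"GACNNNNNNGTC"`).
#' @export
#' @examples
#' design_aasi_barcodes()$barcodes
design_aasi_barcodes <- function() {
  primers <- c("GACGTGCACGTC", "GACAGGCCTGTC", "GACCAGCTGGTC", "GACTCGCGAGTC")
  barcodes <- c("ACGTC", "CTGTC", "TGGTC", "GAGTC")
  site <- "GACNNNNNNGTC"
  stopifnot(all(grepl("^GAC[ACGT]{6}GTC$", primers)))
  # variable dinucleotides (positions 4-5 and 8-9) are reverse complements
  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                                 collapse = ""))
  v1 <- substr(primers, 4L, 5L)
  v2 <- substr(primers, 8L, 9L)
  stopifnot(all(vapply(v1, rc, character(1)) == v2))
  list(primers = primers, barcodes = barcodes, enzyme_site = site)
}

#' Per-cycle base balance of a barcode set
#'
#' Quantifies sequence diversity per position as the Shannon entropy of the
#' base frequencies divided by 2 bits: 1 means all four bases equally
#' frequent, 0 means a single base.
#'
#' @param barcodes Character vector of equal-length barcodes.
#' @return Numeric vector, one balance value in \[0, 1\] per position.
#' @export
#' @examples
#' per_cycle_base_balance(design_aasi_barcodes()$barcodes)
per_cycle_base_balance <- function(barcodes) {
  stopifnot(length(barcodes) >= 1L)
  if (length(unique(nchar(barcodes))) != 1L) {
    abort("barcodes must have equal length", class = "templateseq_config_error")
  }
  n <- nchar(barcodes[1])
  vapply(seq_len(n), function(i) {
    p <- table(factor(substr(barcodes, i, i), levels = DNA_BASES))
    p <- p / sum(p)
    p <- p[p > 0]
    -sum(p * log2(p)) / 2
  }, numeric(1))
}

#' Normalise a barcoded-read percentage by the low-diversity sample share
#'
#' When only a fraction of the lane is the barcoded sample, the raw
#' percentage of barcode-carrying reads is divided by that fraction so that
#' runs with different spike-in levels are comparable (10% barcoded reads in
#' a 10% barcoded lane normalises to 100%).
#'
#' @param raw_pct Raw percentage of reads with an intact barcode.
#' @param lowdiv_sample_fraction Fraction of the lane that is the barcoded
#'   sample, in (0, 1].
#' @return Normalised percentage.
#' @export
#' @examples
#' normalized_barcode_pct(10, 0.10)
normalized_barcode_pct <- function(raw_pct, lowdiv_sample_fraction) {
  if (any(lowdiv_sample_fraction <= 0) || any(lowdiv_sample_fraction > 1)) {
    abort("lowdiv_sample_fraction must lie in (0, 1]",
          class = "templateseq_config_error")
  }
  raw_pct / lowdiv_sample_fraction
}
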