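#' Convert a Phred score to an error probability
#'
#' `10^(-q/10)`; Q23 corresponds to the conventional 0.5% per-base failure
#' rate, Q30 to 0.1%.
#'
#' @param q Phred score(s), >= 0.
#' @return Error probability/ies.
#' @export
#' @examples
#' phred_to_error(23)
phred_to_error <- function(q) {
  stopifnot(all(q >= 0))
  10^(-q / 10)
}

#' Binomial index-morphing null model
#'
#' Probability that sequencing errors morph one multiplexing index into
#' another valid one, for an index of length `n` and a set whose minimum
#' pairwise Hamming distance is `d`, at per-base error rate `p`.
#'
#' Two modes:
#' \describe{
#'   \item{`any_errors`}{Upper-tail binomial `P(X >= d)` with
#'     `X ~ Binomial(n, p)`: at least `d` base errors occur somewhere in the
#'     index. This is the conventional back-of-envelope null for index
#'     misassignment.}
#'   \item{`specific_substitutions`}{`(p/3)^d * (1-p)^(n-d)`: the `d`
#'     mismatched positions must each be misread as one specific alternative
#'     base and the rest read correctly — the probability of morphing into
#'     one particular index at distance exactly `d`. Provided for sensitivity
#'     analysis; it is orders of magnitude smaller.}
#' }
#'
#' @param n Index length in nt.
#' @param d Minimum pairwise Hamming distance of the index set (1 <= d <= n).
#' @param p Per-base error probability in (0, 1); see [phred_to_error()].
#' @param mode `"any_errors"` (default) or `"specific_substitutions"`.
#' @return Probability.
#' @export
#' @examples
#' index_morph_prob(6, 4, phred_to_error(23))  # ~9.3e-9
#' index_morph_prob(6, 3, 1e-3)                # < 2e-8
index_morph_prob <- function(n, d, p,
                             mode = c("any_errors", "specific_substitutions")) {
  mode <- match.arg(mode)
  if (d < 1 || d > n) {
    abort("d must satisfy 1 <= d <= n", class = "templateseq_config_error")
  }
  if (p <= 0 || p >= 1) {
    abort("p must lie in (0, 1)", class = "templateseq_config_error")
  }
  switch(mode,
    any_errors = pbinom(d - 1, n, p, lower.tail = FALSE),
    specific_substitutions = (p / 3)^d * (1 - p)^(n - d)
  )
}

#' Observed sample bleeding rate
#'
#' The fraction of a sample's quality-filtered reads that map (without
#' mismatches) only to the other sample's reference.
#'
#' @param n_cross Number of cross-mapped reads.
#' @param n_total Total quality-filtered reads of the sample (> 0).
#' @return `n_cross / n_total`.
#' @export
#' @examples
#' observed_bleeding(35, 1e5)
observed_bleeding <- function(n_cross, n_total) {
  if (n_total <= 0) {
    abort("n_total must be positive", class = "templateseq_config_error")
  }
  if (n_cross < 0 || n_cross > n_total) {
    abort("n_cross must lie in [0, n_total]",
          class = "templateseq_config_error")
  }
  n_cross / n_total
}

#' Observed / expected bleeding ratio
#'
#' @param observed Observed bleeding rate.
#' @param expected Expected rate under the null (> 0).
#' @param round_to_integer Round half away from zero, as in summary tables.
#' @return The ratio (rounded if requested).
#' @export
#' @examples
#' obs_exp_ratio(3.5e-4, 8.5e-7)
obs_exp_ratio <- function(observed, expected, round_to_integer = TRUE) {
  if (any(expected <= 0)) {
    abort("expected must be positive", class = "templateseq_config_error")
  }
  r <- observed / expected
  if (round_to_integer) round_half_up(r) else r
}

#' Count reads cross-mapping to the other sample's reference
#'
#' A read is cross-mapped when it (or its reverse complement) occurs exactly
#' (0 mismatches) as a substring of the other sample's reference and does not
#' occur in its own. Mapping here is exact substring search against compact
#' references, preserving the 0-mismatch criterion of alignment-based
#' bleeding estimation at desk scale. Reads containing `N` never match.
#'
#' @param reads Character vector of read sequences (pre-filtered with
#'   [quality_filter()]), assigned to the sample whose reference is `ref_own`.
#' @param ref_own Reference sequence (string) of the sample the reads are
#'   assigned to.
#' @param ref_other Reference sequence of the other multiplexed sample.
#' @param expected Expected bleeding rate under the binomial null (used for
#'   the obs/exp ratio); see [index_morph_prob()].
#' @return A `bleeding_estimate`: list with `n_cross`, `n_total`, `observed`,
#'   `expected`, `ratio` and the logical vector `cross_mapped`.
#' @export
cross_map <- function(reads, ref_own, ref_other, expected = NA_real_) {
  if (nchar(ref_own) == 0L || nchar(ref_other) == 0L) {
    abort("references must be non-empty", class = "templateseq_config_error")
  }
  n_total <- length(reads)
  if (n_total == 0L) {
    abort("no reads to map", class = "templateseq_config_error")
  }
  own <- maps_exact(reads, ref_own)
  other <- maps_exact(reads, ref_other)
  cross <- !own & other
  observed <- sum(cross) / n_total
  ratio <- if (is.na(expected) || expected <= 0) NA_real_ else observed / expected
  structure(list(n_cross = sum(cross), n_total = n_total,
                 observed = observed, expected = expected, ratio = ratio,
                 cross_mapped = cross),
            class = "bleeding_estimate")
}

# exact occurrence (either strand) of each read in a reference string
maps_exact <- function(reads, ref) {
  subject <- Biostrings::DNAString(ref)
  vapply(reads, function(s) {
    if (grepl("N", s, fixed = TRUE)) return(FALSE)
    p <- Biostrings::DNAString(s)
    Biostrings::countPattern(p, subject) > 0 ||
      Biostrings::countPattern(Biostrings::reverseComplement(p), subject) > 0
  }, logical(1), USE.NAMES = FALSE)
}

#' @export
print.bleeding_estimate <- function(x, ...) {
  cat(sprintf("<bleeding_estimate> %d / %d cross-mapped: observed %.3g",
              x$n_cross, x$n_total, x$observed))
  if (!is.na(x$expected)) {
    cat(sprintf(", expected %.3g, obs/exp %.3g", x$expected, x$ratio))
  }
  cat("\n")
  invisible(x)
}

#' Simulate one multiplexed lane and measure sample bleeding
#'
#' Two samples share a tile: a barcoded, low-initial-diversity sample whose
#' inserts come from `ref_own`-like synthetic DNA, and a diverse control
#' sample from an unrelated reference. Each carries its own multiplexing
#' index, read in dedicated index cycles with an independently drawn cluster
#' amplitude (the index read is primed and imaged separately on the
#' instrument). The lane is template-called at the requested template
#' length(s), reads are demultiplexed by exact index match, quality-filtered,
#' and cross-mapped; bleeding is measured in the barcoded sample.
#'
#' Because both insert and index calls come from intensities at template
#' positions, merged clusters are the bleeding mechanism: a template position
#' shared by two clusters can be dominated by one sample's cluster in the
#' insert read and by the other's in the index read, producing a cleanly
#' called read assigned to the wrong sample.
#'
#' @param seed Integer seed for the lane.
#' @param template_cycle_counts Integer vector of template lengths to call
#'   the same lane with (e.g. `c(4, 7)` for standard vs long template).
#' @param control_fraction Fraction of clusters from the diverse control.
#' @param density_fraction Cluster density as a fraction of optimal.
#' @param barcode 5' prefix of the barcoded sample.
#' @param genomic_length Insert bases after the barcode.
#' @param index_length Multiplexing index length.
#' @param ref_length Length of each synthetic reference.
#' @param tile_px Tile side in pixels.
#' @param indices Length-2 character vector: barcoded-sample index, control
#'   index.
#' @param min_run,min_q Quality-filter parameters for mapped reads.
#' @return Tibble with one row per template length: `template_cycle_count`,
#'   `protocol`, `n_assigned`, `n_filtered`, `n_cross`, `observed`,
#'   `expected`, `ratio`, plus a list column `estimate` with the underlying
#'   `bleeding_estimate`.
#' @export
bleeding_lane <- function(seed,
                          template_cycle_counts = c(4L, 7L),
                          control_fraction = 0.5,
                          density_fraction = 1,
                          barcode = "TCGAG",
                          genomic_length = 36L,
                          index_length = 6L,
                          ref_length = 30000L,
                          tile_px = 512L,
                          indices = c("ATCACG", "TAGCTT"),
                          min_run = 34L,
                          min_q = 20L) {
  insert_len <- nchar(barcode) + genomic_length
  refs <- with_seed(seed * 2L + 1L,
                    list(own = random_dna(ref_length),
                         other = random_dna(ref_length)))
  sheet <- tibble(
    sample_label = c("barcoded", "control"),
    fraction = c(1 - control_fraction, control_fraction),
    prefix = c(barcode, NA_character_),
    reference = c(refs$own, refs$other),
    index = indices
  )
  cfg <- sim_config(
    tile_width_px = tile_px, tile_height_px = tile_px,
    density_fraction = density_fraction,
    n_cycles = insert_len + index_length,
    index_cycles = index_length,
    sample_sheet = sheet,
    seed = seed
  )
  run <- simulate_run(cfg)

  # all template lengths share one detection pass over the longest window
  base_tcfg <- template_config(
    template_cycle_count = max(template_cycle_counts))
  spot_cache <- lapply(run$images[seq_len(max(template_cycle_counts))],
                       detect_spots, cfg = base_tcfg)

  rows <- lapply(template_cycle_counts, function(K) {
    est <- measure_lane_bleeding(run, K, refs, barcode, insert_len,
                                 index_length, indices, min_run, min_q,
                                 spot_cache = spot_cache)
    tibble(
      template_cycle_count = as.integer(K),
      protocol = if (K <= 4L) "standard" else "long_template",
      n_assigned = est$n_assigned,
      n_filtered = est$n_total,
      n_cross = est$n_cross,
      observed = est$observed,
      expected = est$expected,
      ratio = est$ratio,
      estimate = list(est)
    )
  })
  list_rbind(rows)
}

measure_lane_bleeding <- function(run, template_cycle_count, refs, barcode,
                                  insert_len, index_length, indices,
                                  min_run, min_q, spot_cache = NULL) {
  tcfg <- template_config(template_cycle_count = template_cycle_count)
  tpl <- build_template(run$images, tcfg, spot_cache = spot_cache)
  reads <- call_run(run, tcfg, template = tpl, insert_cycles = insert_len)

  reads$index_called <- substr(reads$sequence, insert_len + 1L,
                               insert_len + index_length)
  reads$insert <- substr(reads$sequence, 1L, insert_len)
  reads$insert_qual <- lapply(reads$qual, function(q) q[seq_len(insert_len)])

  assigned <- reads |>
    filter(.data$purity_pass, !.data$out_of_image,
           .data$index_called == indices[1])
  n_assigned <- nrow(assigned)

  keep <- vapply(assigned$insert_qual, function(q) {
    quality_filter(q, min_run = min_run, min_q = min_q)
  }, logical(1))
  assigned <- assigned[keep, ]

  # reads with the intact 5' barcode are trimmed before mapping; reads
  # without it are mapped full-length
  bc <- match_barcode(assigned$insert, barcode)
  mapped_seq <- ifelse(is.na(bc$barcode), bc$sequence, bc$trimmed)

  expected <- index_morph_prob(index_length,
                               hamming_distance(indices[1], indices[2]),
                               phred_to_error(23))
  if (length(mapped_seq) == 0L) {
    est <- structure(list(n_cross = 0L, n_total = 0L, observed = NA_real_,
                          expected = expected, ratio = NA_real_,
                          cross_mapped = logical(0)),
                     class = "bleeding_estimate")
  } else {
    est <- cross_map(mapped_seq, refs$own, refs$other, expected = expected)
  }
  est$n_assigned <- n_assigned
  est$reads <- assigned
  est
}

#' Bleeding comparison across seeds and template lengths
#'
#' Runs [bleeding_lane()] for several seeds and summarises observed bleeding
#' per template length.
#'
#' @param seeds Integer vector of lane seeds.
#' @param template_cycle_counts Template lengths compared on each lane.
#' @param ... Passed to [bleeding_lane()].
#' @return Tibble with one row per (seed, template length).
#' @export
bleeding_experiment <- function(seeds, template_cycle_counts = c(4L, 7L), ...) {
  rows <- lapply(seeds, function(s) {
    bleeding_lane(s, template_cycle_counts = template_cycle_counts, ...) |>
      mutate(seed = s, .before = 1L) |>
      select(-"estimate")
  })
  list_rbind(rows)
}
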