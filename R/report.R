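#' Run a simulate-template-call-QC experiment grid
#'
#' Orchestrates the full pipeline over a grid of conditions (template length
#' x cluster density x low-diversity fraction) and emits one summary row per
#' cell, shaped like a run comparison table: read counts, percentage of bases
#' at Q30+, and raw/normalised intact-barcode percentages.
#'
#' @details
#' Per cell: a tile is simulated at the requested density and diversity, a
#' template of the requested length is built, reads are called and
#' purity-filtered. Reported metrics:
#' \describe{
#'   \item{`n_reads`}{purity-passing reads (the reads that would reach the
#'     FASTQ).}
#'   \item{`pct_q30`}{percentage of called bases with Q >= 30 among
#'     purity-passing reads (base-level, a documented choice).}
#'   \item{`pct_barcoded_raw`}{percentage of reads with an intact (0
#'     mismatch) 5' barcode among purity-passing reads that also pass the
#'     high-quality-run filter; for inserts shorter than the standard 34 nt
#'     run the required run shrinks to the insert length.}
#'   \item{`pct_barcoded_norm`}{`pct_barcoded_raw` divided by the
#'     low-diversity sample fraction ([normalized_barcode_pct()]).}
#'   \item{`n_barcoded_matched`}{barcode-intact reads whose trimmed insert
#'     reproduces the matched ground-truth cluster's sequence exactly (the
#'     simulation analogue of "barcoded and mapped with 0 errors").}
#' }
#'
#' @param grid Tibble with columns `template_cycle_count`,
#'   `density_fraction`, `lowdiv_fraction` and optionally `seed` and
#'   `sample` (a label). An empty grid returns an empty report.
#' @param barcode 5' prefix carried by low-diversity clusters.
#' @param n_cycles Cycles to simulate (insert length).
#' @param tile_px Tile side in pixels.
#' @param qc_min_run High-quality run length for the barcode denominator;
#'   `NULL` means `min(34, n_cycles)`.
#' @param qc_min_q Phred threshold of the run filter (strictly above).
#' @param base_seed Seed used for rows without their own `seed` column.
#' @return Tibble (class `run_report`), one row per grid cell.
#' @export
run_experiment <- function(grid,
                           barcode = "TCGAG",
                           n_cycles = 12L,
                           tile_px = 512L,
                           qc_min_run = NULL,
                           qc_min_q = 20L,
                           base_seed = 1L) {
  cols <- c("sample", "protocol", "template_cycle_count", "pct_lowdiv",
            "density_fraction", "n_reads", "pct_q30", "pct_barcoded_raw",
            "pct_barcoded_norm", "n_barcoded_matched")
  if (is.null(grid) || nrow(grid) == 0L) {
    out <- tibble(sample = character(), protocol = character(),
                  template_cycle_count = integer(), pct_lowdiv = numeric(),
                  density_fraction = numeric(), n_reads = integer(),
                  pct_q30 = numeric(), pct_barcoded_raw = numeric(),
                  pct_barcoded_norm = numeric(), n_barcoded_matched = integer())
    class(out) <- c("run_report", class(out))
    return(out)
  }
  qc_min_run <- qc_min_run %||% min(34L, n_cycles)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    seed <- if ("seed" %in% names(g)) g$seed else base_seed + i - 1L
    label <- if ("sample" %in% names(g)) g$sample else sprintf("cell_%d", i)
    report_cell(label, g$template_cycle_count, g$density_fraction,
                g$lowdiv_fraction, barcode, n_cycles, tile_px,
                qc_min_run, qc_min_q, seed)
  })
  out <- list_rbind(rows)
  class(out) <- c("run_report", class(out))
  out
}

report_cell <- function(label, template_cycle_count, density_fraction,
                        lowdiv_fraction, barcode, n_cycles, tile_px,
                        qc_min_run, qc_min_q, seed) {
  cfg <- sim_config(tile_width_px = tile_px, tile_height_px = tile_px,
                    density_fraction = density_fraction,
                    n_cycles = n_cycles,
                    lowdiv_fraction = lowdiv_fraction,
                    prefix_sequences = barcode,
                    seed = seed)
  run <- simulate_run(cfg)
  tcfg <- template_config(template_cycle_count = template_cycle_count)
  reads <- call_run(run, tcfg)

  pass <- reads |> filter(.data$purity_pass, !.data$out_of_image)
  n_reads <- nrow(pass)
  pct_q30 <- if (n_reads == 0L) NA_real_ else {
    100 * mean(unlist(pass$qual) >= 30L)
  }

  qcpass <- pass[vapply(pass$qual, function(q) {
    quality_filter(q, min_run = qc_min_run, min_q = qc_min_q)
  }, logical(1)), ]
  if (nrow(qcpass) > 0L) {
    bc <- match_barcode(qcpass$sequence, barcode)
    barcoded <- !is.na(bc$barcode)
    raw <- 100 * mean(barcoded)
    # "mapped with 0 errors": trimmed read equals the true suffix
    true_suffix <- substr(qcpass$true_sequence, nchar(barcode) + 1L, n_cycles)
    matched <- barcoded & !is.na(qcpass$true_sequence) &
      bc$trimmed == true_suffix
    n_matched <- sum(matched)
  } else {
    raw <- NA_real_
    n_matched <- 0L
  }
  norm <- if (lowdiv_fraction > 0 && !is.na(raw)) {
    normalized_barcode_pct(raw, lowdiv_fraction)
  } else raw

  tibble(
    sample = label,
    protocol = if (template_cycle_count <= 4L) "standard" else "long_template",
    template_cycle_count = as.integer(template_cycle_count),
    pct_lowdiv = 100 * lowdiv_fraction,
    density_fraction = density_fraction,
    n_reads = n_reads,
    pct_q30 = pct_q30,
    pct_barcoded_raw = raw,
    pct_barcoded_norm = norm,
    n_barcoded_matched = as.integer(n_matched)
  )
}

#' Fold change between two report values
#'
#' @param value,reference Numeric values (e.g. normalised barcoded
#'   percentages of two runs).
#' @param round_to_integer Round half away from zero for table-style output.
#' @return `value / reference`.
#' @export
#' @examples
#' fold_change(77.0, 1.1)
fold_change <- function(value, reference, round_to_integer = TRUE) {
  if (any(reference == 0)) {
    abort("reference must be nonzero", class = "templateseq_config_error")
  }
  r <- value / reference
  if (round_to_integer) round_half_up(r) else r
}

#' Bundled reference run summaries (standard vs long template)
#'
#' Summary table of real HiSeq runs of BLESS (11 nt 5'-barcoded,
#' low-initial-diversity) libraries, comparing the instrument's standard
#' 4-cycle template protocol with 20-cycle Long Template Protocol runs:
#' sample share, cluster density (percent of optimal), read counts, percent
#' of reads at Q30+, normalised intact-barcode percentage and
#' barcoded-and-mapped counts. Bundled as plain TSV for examples and summary
#' statistics (e.g. the normalised-barcode fold change between protocols).
#'
#' @return Tibble, one row per sequencing run.
#' @export
#' @examples
#' bless_run_summary()
bless_run_summary <- function() {
  path <- system.file("extdata", "bless_run_summary.tsv",
                      package = "templateseq", mustWork = TRUE)
  as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Bundled reference sample-bleeding rates
#'
#' Observed and expected (binomial-null) sample-bleeding rates from
#' multiplexed and control HiSeq lanes: human samples multiplexed with yeast
#' or PhiX under the standard protocol or the Long Template Protocol, plus
#' non-multiplexed control lanes that estimate the false-positive mapping
#' rate. The observed/expected ratio is recomputed with [obs_exp_ratio()].
#'
#' @return Tibble, one row per lane.
#' @export
#' @examples
#' rates <- sample_bleeding_rates()
#' obs_exp_ratio(rates$observed[1], rates$expected[1])
sample_bleeding_rates <- function() {
  path <- system.file("extdata", "sample_bleeding_rates.tsv",
                      package = "templateseq", mustWork = TRUE)
  as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}
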