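#' The two 11 nt BLESS 5' barcodes
#'
#' Fixed 5'-proximal sequences marking reads from the BLESS double-strand-break
#' labelling protocol; the archetypal low-initial-diversity prefix. Reads that
#' begin with either barcode concentrate first-cycle signal in the `T` channel.
#'
#' @return Character vector of the two 11 nt barcodes.
#' @export
#' @examples
#' bless_barcodes()
bless_barcodes <- function() {
  c("TCGAGGTAGTA", "TCGAGACGACG")
}

#' Simulation configuration for a flowcell tile
#'
#' Collects the run geometry, cluster density, library diversity structure,
#' optics and noise parameters for [generate_clusters()], [render_cycle()] and
#' [simulate_run()]. All spatial quantities are in pixels; coordinates are
#' 0-based with x along columns and y along rows.
#'
#' @details
#' Cluster density is expressed as a fraction of `optimal_density`, the
#' manufacturer-style reference density for the simulated tile (clusters per
#' square pixel; the default 0.0085 puts the mean nearest-neighbour spacing
#' near 2.7 PSF sigma, i.e. optimal density sits just above the detector's
#' resolution limit, as on a real flowcell). Exceeding `density_fraction = 1`
#' is allowed up to 1.5 to emulate overloaded lanes.
#'
#' The library is described either by `lowdiv_fraction` + `prefix_sequences`
#' (that share of clusters carries one of the fixed 5' prefixes followed by a
#' random suffix, the rest are i.i.d. uniform bases) or by an explicit
#' `sample_sheet` tibble with columns `sample_label`, `fraction`, and
#' optionally `prefix`, `reference` (a sequence string from which insert
#' bases are copied) and `index` (a multiplexing index read in the final
#' `index_cycles` cycles). `n_cycles` always equals the full per-cluster
#' sequence length, i.e. insert cycles plus `index_cycles`.
#'
#' Each cluster's integrated spot intensity is log-normal with mean
#' `amplitude_mean` and coefficient of variation `amplitude_cv`; the index
#' read, which on the instrument is primed and imaged separately, gets an
#' independent amplitude draw from the same distribution.
#'
#' @param tile_width_px,tile_height_px Tile size in pixels.
#' @param optimal_density Reference cluster density (clusters / px^2).
#' @param density_fraction Fraction of optimal density in \[0, 1.5\]. 0 gives
#'   an empty tile.
#' @param n_cycles Total number of sequencing cycles (= sequence length).
#' @param index_cycles How many of the final cycles read the multiplexing
#'   index (0 = no index read).
#' @param lowdiv_fraction Fraction of clusters carrying a fixed 5' prefix.
#' @param prefix_sequences Candidate 5' prefixes for low-diversity clusters.
#' @param sample_sheet Optional tibble describing samples explicitly (see
#'   Details); overrides `lowdiv_fraction`/`prefix_sequences`.
#' @param psf_sigma_px Isotropic Gaussian PSF sigma in pixels.
#' @param amplitude_mean,amplitude_cv Log-normal amplitude mean and CV.
#' @param background_level Constant background added to every pixel.
#' @param read_noise_sd SD of additive Gaussian read noise (0 = noiseless).
#' @param shot_noise If `TRUE`, Poisson shot noise is applied to
#'   signal + background before read noise (off by default so that closed-form
#'   oracles hold exactly).
#' @param crosstalk 4x4 row-stochastic channel mixing matrix, rows/columns in
#'   A, C, G, T order (identity by default).
#' @param drift_px Per-cycle stage drift: offsets are uniform in
#'   \[-drift_px, drift_px\] for cycles > 1 (cycle 1 is the reference at 0,0).
#' @param exclusion_radius_px Optional minimum distance between clusters
#'   (Matern-style thinning of the Poisson process); 0 disables it.
#' @param seed Integer seed; the whole run is reproducible from it.
#'
#' @return An object of class `sim_config` (a named list).
#' @seealso [simulate_run()], [generate_clusters()], [render_cycle()]
#' @export
#' @examples
#' cfg <- sim_config(tile_width_px = 128, tile_height_px = 128, n_cycles = 6,
#'                   seed = 7)
#' cfg$density_fraction
sim_config <- function(tile_width_px = 512L,
                       tile_height_px = 512L,
                       optimal_density = 0.0085,
                       density_fraction = 1,
                       n_cycles = 12L,
                       index_cycles = 0L,
                       lowdiv_fraction = 0,
                       prefix_sequences = bless_barcodes(),
                       sample_sheet = NULL,
                       psf_sigma_px = 2,
                       amplitude_mean = 8000,
                       amplitude_cv = 0.35,
                       background_level = 400,
                       read_noise_sd = 30,
                       shot_noise = FALSE,
                       crosstalk = diag(4),
                       drift_px = 2,
                       exclusion_radius_px = 0,
                       seed = 1L) {
  cfg <- list(
    tile_width_px = as.integer(tile_width_px),
    tile_height_px = as.integer(tile_height_px),
    optimal_density = optimal_density,
    density_fraction = density_fraction,
    n_cycles = as.integer(n_cycles),
    index_cycles = as.integer(index_cycles),
    lowdiv_fraction = lowdiv_fraction,
    prefix_sequences = prefix_sequences,
    sample_sheet = sample_sheet,
    psf_sigma_px = psf_sigma_px,
    amplitude_mean = amplitude_mean,
    amplitude_cv = amplitude_cv,
    background_level = background_level,
    read_noise_sd = read_noise_sd,
    shot_noise = isTRUE(shot_noise),
    crosstalk = crosstalk,
    drift_px = drift_px,
    exclusion_radius_px = exclusion_radius_px,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$tile_width_px <= 0L || cfg$tile_height_px <= 0L) {
    abort("tile dimensions must be positive", class = "templateseq_config_error")
  }
  if (!is.finite(cfg$density_fraction) || cfg$density_fraction < 0 ||
      cfg$density_fraction > 1.5) {
    abort("density_fraction must lie in [0, 1.5]",
          class = "templateseq_config_error")
  }
  if (cfg$optimal_density <= 0) {
    abort("optimal_density must be positive", class = "templateseq_config_error")
  }
  if (cfg$n_cycles < 1L) {
    abort("n_cycles must be >= 1", class = "templateseq_config_error")
  }
  if (cfg$index_cycles < 0L || cfg$index_cycles >= cfg$n_cycles) {
    abort("index_cycles must be in [0, n_cycles)",
          class = "templateseq_config_error")
  }
  if (cfg$lowdiv_fraction < 0 || cfg$lowdiv_fraction > 1) {
    abort("lowdiv_fraction must lie in [0, 1]",
          class = "templateseq_config_error")
  }
  if (length(cfg$prefix_sequences) > 0 &&
      any(grepl("[^ACGT]", cfg$prefix_sequences))) {
    abort("prefix_sequences must be over the alphabet {A,C,G,T}",
          class = "templateseq_config_error")
  }
  if (cfg$psf_sigma_px <= 0 || cfg$amplitude_mean <= 0 || cfg$amplitude_cv < 0) {
    abort("psf_sigma_px and amplitude parameters must be positive",
          class = "templateseq_config_error")
  }
  if (cfg$background_level < 0 || cfg$read_noise_sd < 0) {
    abort("background_level and read_noise_sd must be nonnegative",
          class = "templateseq_config_error")
  }
  ct <- cfg$crosstalk
  if (!is.matrix(ct) || any(dim(ct) != c(4L, 4L)) ||
      any(abs(rowSums(ct) - 1) > 1e-9)) {
    abort("crosstalk must be a 4x4 row-stochastic matrix",
          class = "templateseq_config_error")
  }
  if (!is.null(cfg$sample_sheet)) {
    sh <- cfg$sample_sheet
    req <- c("sample_label", "fraction")
    if (!all(req %in% names(sh))) {
      abort("sample_sheet needs columns sample_label and fraction",
            class = "templateseq_config_error")
    }
    if (abs(sum(sh$fraction) - 1) > 1e-9 || any(sh$fraction < 0)) {
      abort("sample_sheet fractions must be nonnegative and sum to 1",
            class = "templateseq_config_error")
    }
    if ("index" %in% names(sh) && cfg$index_cycles > 0L) {
      idx <- sh$index[!is.na(sh$index)]
      if (any(nchar(idx) != cfg$index_cycles)) {
        abort("sample_sheet index length must equal index_cycles",
              class = "templateseq_config_error")
      }
    }
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  tile: %d x %d px, %d cycles (%d index)\n",
              x$tile_width_px, x$tile_height_px, x$n_cycles, x$index_cycles))
  cat(sprintf("  density: %.3g x optimal (%.4g clusters/px^2)\n",
              x$density_fraction, x$optimal_density))
  cat(sprintf("  low-diversity fraction: %.2f; PSF sigma %.2f px; seed %d\n",
              x$lowdiv_fraction, x$psf_sigma_px, x$seed))
  invisible(x)
}
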