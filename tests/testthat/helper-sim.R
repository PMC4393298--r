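# Shared fixtures, built once per test run. Everything is generated in code;
# sizes are kept small so the whole suite stays fast.

# sparse, noiseless, drift-free tile with well-separated clusters: the
# setting where every stage of the pipeline should be exact
sparse_noiseless_config <- function(seed = 7, n_cycles = 6) {
  sim_config(
    tile_width_px = 160, tile_height_px = 160,
    optimal_density = 0.0012, density_fraction = 1,
    n_cycles = n_cycles,
    read_noise_sd = 0, background_level = 0, drift_px = 0,
    exclusion_radius_px = 12,
    seed = seed
  )
}

sparse_noiseless_run <- simulate_run(sparse_noiseless_config())

# build a ground-truth cluster tibble by hand (for engineered geometries)
manual_clusters <- function(x, y, sequence, amplitude,
                            amplitude_index = amplitude,
                            sample_label = "manual",
                            index_sequence = NA_character_) {
  tibble::tibble(
    id = seq_along(x), x = x, y = y, sequence = sequence,
    amplitude = amplitude, amplitude_index = amplitude_index,
    sample_label = sample_label, index_sequence = index_sequence
  )
}

# render a full run from a hand-built cluster table (no drift)
manual_run <- function(clusters, config) {
  images <- lapply(seq_len(config$n_cycles), function(cy) {
    render_cycle(clusters, cy, config, c(0, 0))
  })
  structure(list(images = images, clusters = clusters, config = config),
            class = "fc_run")
}

expect_tibble <- function(x) testthat::expect_s3_class(x, "tbl_df")
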