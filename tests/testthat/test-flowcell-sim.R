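test_that("cluster generation respects density, diversity and determinism", {
  base <- sim_config(tile_width_px = 256, tile_height_px = 256, n_cycles = 6,
                     seed = 11)

  # zero density gives an empty tile; negative density is a config error
  empty <- generate_clusters(sim_config(tile_width_px = 256,
                                        tile_height_px = 256,
                                        density_fraction = 0, n_cycles = 6))
  expect_tibble(empty)
  expect_equal(nrow(empty), 0L)
  expect_error(sim_config(density_fraction = -0.1),
               class = "templateseq_config_error")

  # forced prefix: every sequence starts with one of the prefixes
  lowdiv <- generate_clusters(sim_config(tile_width_px = 256,
                                         tile_height_px = 256,
                                         n_cycles = 14, lowdiv_fraction = 1,
                                         seed = 3))
  expect_true(all(substr(lowdiv$sequence, 1, 11) %in% bless_barcodes()))
  expect_true(all(nchar(lowdiv$sequence) == 14L))

  # Poisson cluster count: expected 2000, so the seeded draw must fall
  # within 3 * sqrt(2000) of the mean
  cfg2k <- sim_config(tile_width_px = 512, tile_height_px = 512,
                      optimal_density = 2000 / 512^2, density_fraction = 1,
                      n_cycles = 4, seed = 123)
  n <- nrow(generate_clusters(cfg2k))
  expect_lt(abs(n - 2000), 3 * sqrt(2000))

  # identical config (incl. seed) gives identical truth
  expect_identical(generate_clusters(base), generate_clusters(base))
})

test_that("rendering is deterministic, linear, and channel-faithful", {
  cfg <- sim_config(tile_width_px = 128, tile_height_px = 128,
                    optimal_density = 0.004, n_cycles = 3, seed = 5)

  # same seed twice: bit-identical images
  run_a <- simulate_run(cfg)
  run_b <- simulate_run(cfg)
  expect_identical(run_a$images[[2]]$channels, run_b$images[[2]]$channels)
  expect_equal(length(run_a$images), 3L)

  # drift disabled: all offsets are (0, 0); cycle 1 is always the reference
  no_drift <- simulate_run(sim_config(tile_width_px = 96, tile_height_px = 96,
                                      n_cycles = 3, drift_px = 0, seed = 5))
  for (img in no_drift$images) expect_equal(img$offset, c(0, 0))
  expect_equal(run_a$images[[1]]$offset, c(0, 0))

  # noiseless linearity: doubling every amplitude doubles every pixel
  cfg0 <- sim_config(tile_width_px = 96, tile_height_px = 96,
                     optimal_density = 0.004, n_cycles = 2,
                     read_noise_sd = 0, background_level = 0, seed = 8)
  cl <- generate_clusters(cfg0)
  img1 <- render_cycle(cl, 1, cfg0)
  cl2 <- dplyr::mutate(cl, amplitude = amplitude * 2,
                       amplitude_index = amplitude_index * 2)
  img2 <- render_cycle(cl2, 1, cfg0)
  for (b in c("A", "C", "G", "T")) {
    expect_equal(img2$channels[[b]], 2 * img1$channels[[b]])
  }

  # no clusters, zero background, zero noise: four all-zero images
  blank <- render_cycle(cl[0, ], 1, cfg0)
  expect_true(all(vapply(blank$channels, function(m) all(m == 0), logical(1))))
})

test_that("noiseless channel signal tracks amplitude-weighted base composition", {
  cfg <- sim_config(tile_width_px = 200, tile_height_px = 200,
                    optimal_density = 0.003, n_cycles = 4,
                    read_noise_sd = 0, background_level = 0, drift_px = 0,
                    seed = 21)
  cl <- generate_clusters(cfg)
  # keep clusters away from the border so no flux is clipped
  cl <- dplyr::filter(cl, x > 10, x < 190, y > 10, y < 190)
  for (cy in c(1L, 3L)) {
    img <- render_cycle(cl, cy, cfg)
    totals <- vapply(img$channels, sum, numeric(1))
    frac <- totals / sum(totals)
    base <- substr(cl$sequence, cy, cy)
    expected <- vapply(c("A", "C", "G", "T"), function(b) {
      sum(cl$amplitude[base == b])
    }, numeric(1)) / sum(cl$amplitude)
    expect_lt(max(abs(frac - expected)), 0.02)
  }

  # all clusters share base T at cycle 1: >= 99% of the signal in channel T
  clT <- dplyr::mutate(cl, sequence = paste0("T", substr(sequence, 2, 4)))
  imgT <- render_cycle(clT, 1, cfg)
  totals <- vapply(imgT$channels, sum, numeric(1))
  expect_gt(totals[["T"]] / sum(totals), 0.99)
})

test_that("a single spot integrates to its amplitude", {
  cfg <- sim_config(tile_width_px = 64, tile_height_px = 64,
                    optimal_density = 1e-9, n_cycles = 1,
                    read_noise_sd = 0, background_level = 0, seed = 1)
  cl <- manual_clusters(x = 31.3, y = 30.7, sequence = "G", amplitude = 5000)
  img <- render_cycle(cl, 1, cfg)
  expect_lt(abs(sum(img$channels$G) - 5000) / 5000, 0.01)
  expect_equal(sum(img$channels$A), 0)
})

test_that("runs round-trip through TIFF + manifest on disk", {
  dir <- withr::local_tempdir()
  run <- simulate_run(sim_config(tile_width_px = 64, tile_height_px = 48,
                                 optimal_density = 0.003, n_cycles = 2,
                                 seed = 9))
  write_run(run, dir)
  expect_true(file.exists(file.path(dir, "C1_A.tif")))
  expect_true(file.exists(file.path(dir, "C2_T.tif")))
  back <- read_run_images(dir)
  expect_equal(length(back$images), 2L)
  # 16-bit quantisation: per-pixel error bounded by half an ADU
  expect_lt(max(abs(back$images[[1]]$channels$C - run$images[[1]]$channels$C)),
            1.01)
  expect_equal(back$images[[2]]$offset, run$images[[2]]$offset,
               tolerance = 1e-6)
  gt <- read.delim(file.path(dir, "ground_truth.tsv"))
  expect_equal(nrow(gt), nrow(run$clusters))
})
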