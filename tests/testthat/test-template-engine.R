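test_that("golden/silver ranking follows counts with early-cycle tie-break", {
  expect_equal(rank_cycles(c(100, 120, 90, 110)), list(golden = 2L, silver = 4L))
  expect_equal(rank_cycles(c(50, 50)), list(golden = 1L, silver = 2L))
  expect_error(rank_cycles(100L), class = "templateseq_config_error")
  expect_error(template_config(template_cycle_count = 1),
               class = "templateseq_config_error")
})

test_that("spot detection resolves separated spots and merges overlapping ones", {
  cfg <- sim_config(tile_width_px = 64, tile_height_px = 64,
                    optimal_density = 1e-9, n_cycles = 1,
                    read_noise_sd = 5, background_level = 200, seed = 2)
  sigma <- cfg$psf_sigma_px

  # two equal spots 6 sigma apart: both found, each within 0.5 px
  cl2 <- manual_clusters(x = c(20, 20 + 6 * sigma), y = c(30, 30),
                         sequence = c("A", "A"), amplitude = c(8000, 8000))
  set.seed(1)
  sp <- detect_spots(render_cycle(cl2, 1, cfg))
  expect_equal(nrow(sp), 2L)
  m <- sapply(seq_len(2), function(i) {
    min(sqrt((sp$x - cl2$x[i])^2 + (sp$y - cl2$y[i])^2))
  })
  expect_true(all(m < 0.5))

  # two equal spots 0.8 sigma apart in the same channel: a single merged spot
  # (the summed profile has one maximum; brute-force evaluation of
  # 2-Gaussian sums shows a dip only appears beyond 2 sigma)
  cl_close <- manual_clusters(x = c(30, 30 + 0.8 * sigma), y = c(30, 30),
                              sequence = c("C", "C"), amplitude = c(8000, 8000))
  set.seed(1)
  sp_close <- detect_spots(render_cycle(cl_close, 1, cfg))
  expect_equal(nrow(sp_close), 1L)

  # empty image: no spots, not an error
  blank <- render_cycle(cl2[0, ], 1,
                        sim_config(tile_width_px = 64, tile_height_px = 64,
                                   n_cycles = 1, read_noise_sd = 0,
                                   background_level = 0, seed = 1))
  expect_equal(nrow(detect_spots(blank)), 0L)
})

test_that("templates recover well-separated clusters and stay immutable", {
  run <- sparse_noiseless_run
  tpl <- build_template(run$images, template_config(4))
  expect_error(build_template(run$images, template_config(20)),
               class = "templateseq_config_error")

  # position count within 2% of the true cluster count
  expect_lte(abs(nrow(tpl$positions) - nrow(run$clusters)),
             max(1, ceiling(0.02 * nrow(run$clusters))))
  rec <- template_recovery(tpl, run$clusters, run$config)
  expect_gt(rec$recovered, 0.97)

  # the template is never corrected: calling leaves positions untouched
  before <- tpl$positions
  invisible(call_run(run, template = tpl))
  expect_identical(tpl$positions, before)

  # tidy/glance accessors
  expect_equal(nrow(tidy(tpl)), nrow(tpl$positions))
  g <- glance(tpl)
  expect_equal(g$template_cycle_count, 4L)
  expect_true(g$golden_cycle %in% 1:4 && g$silver_cycle %in% 1:4)
})

test_that("low-diversity runs push golden and silver into diverse cycles", {
  cfg <- sim_config(tile_width_px = 320, tile_height_px = 320,
                    n_cycles = 7, lowdiv_fraction = 1,
                    prefix_sequences = "TCGAG", seed = 31)
  run <- simulate_run(cfg)
  tpl <- build_template(run$images, template_config(7))
  # barcode occupies cycles 1-5; the best-populated cycles are the diverse ones
  expect_true(all(c(tpl$golden_cycle, tpl$silver_cycle) %in% 6:7))
})

test_that("per-cycle detected counts drop when all clusters share one base", {
  # paired design: identical positions/amplitudes, only the sequences differ
  cfg <- sim_config(tile_width_px = 256, tile_height_px = 256,
                    optimal_density = 0.0085, density_fraction = 0.8,
                    n_cycles = 1, seed = 0)
  diffs <- numeric(20)
  for (k in seq_len(20)) {
    cl <- generate_clusters(sim_config(tile_width_px = 256,
                                       tile_height_px = 256,
                                       optimal_density = 0.0085,
                                       density_fraction = 0.8,
                                       n_cycles = 1, seed = k))
    cl_same <- dplyr::mutate(cl, sequence = "T")
    set.seed(k)
    n_diverse <- nrow(detect_spots(render_cycle(cl, 1, cfg)))
    set.seed(k)
    n_same <- nrow(detect_spots(render_cycle(cl_same, 1, cfg)))
    diffs[k] <- n_diverse - n_same
  }
  # monotone on average, strictly fewer in a shared-base cycle at this density
  expect_true(all(diffs >= 0))
  expect_gt(mean(diffs), 0)
})

test_that("cycle registration recovers applied offsets", {
  run <- sparse_noiseless_run
  cfg <- run$config
  tpl <- build_template(run$images, template_config(4))

  # identity
  off0 <- register_offset(run$images[[1]], tpl)
  expect_lt(max(abs(off0 - c(0, 0))), 0.25)

  # known integer offset: exact at integer resolution
  img_int <- render_cycle(run$clusters, 2, cfg, offset = c(2, -1))
  off_int <- register_offset(img_int, tpl)
  expect_equal(round(off_int), c(2, -1))
  expect_lt(max(abs(off_int - c(2, -1))), 0.25)

  # known half-pixel offset: within 0.25 px after quadratic refinement
  img_half <- render_cycle(run$clusters, 3, cfg, offset = c(1.5, 0.5))
  off_half <- register_offset(img_half, tpl)
  expect_lt(max(abs(off_half - c(1.5, 0.5))), 0.25)

  expect_error(register_offset(run$images[[1]],
                               structure(list(positions = tibble::tibble()),
                                         class = "fc_template")),
               class = "templateseq_config_error")
})

test_that("memory model scales linearly and bounds template length", {
  m <- memory_model()
  one <- estimate_template_memory(m, 1)
  expect_equal(one$bytes, 4 * 2048 * 160000 * 2)
  expect_lt(abs(one$gb - 2.6) / 2.6, 0.01)
  expect_lt(abs(estimate_template_memory(m, 4)$gb - 10.4) / 10.4, 0.01)
  expect_lt(abs(estimate_template_memory(m, 20)$gb - 52) / 52, 0.01)
  # exact linearity
  for (L in c(2, 7, 16)) {
    expect_identical(estimate_template_memory(m, L)$bytes, L * one$bytes)
  }
  expect_identical(max_template_length(48, 4), 12L)
  expect_identical(max_template_length(192, 4), 48L)
  expect_identical(max_template_length(4, 4), 1L)
  expect_error(max_template_length(0, 4), class = "templateseq_config_error")
})
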