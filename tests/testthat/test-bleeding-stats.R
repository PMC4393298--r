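test_that("Phred conversion matches its definition", {
  expect_equal(signif(phred_to_error(23), 2), 0.0050)
  expect_equal(phred_to_error(30), 1e-3)
  expect_equal(phred_to_error(0), 1)
})

test_that("index-morphing probabilities match independent enumeration", {
  # oracle: distribution of the error count from explicit convolution of n
  # Bernoulli(p) variables, independent of the closed-form binomial tail
  enum_tail <- function(n, d, p) {
    dist <- 1
    for (i in seq_len(n)) {
      dist <- c(dist * (1 - p), 0) + c(0, dist * p)
    }
    sum(dist[(d + 1):(n + 1)])
  }
  for (n in c(2, 4, 6, 7, 8)) {
    for (d in unique(c(1, 2, min(3, n), n))) {
      for (p in c(0.005, 0.001, 1e-4)) {
        expect_lt(abs(index_morph_prob(n, d, p) - enum_tail(n, d, p)), 1e-12)
      }
    }
  }
  # closed form for d = 1
  expect_equal(index_morph_prob(5, 1, 0.01), 1 - (1 - 0.01)^5)
  # specific-substitution mode
  expect_equal(index_morph_prob(6, 4, 0.005, "specific_substitutions"),
               (0.005 / 3)^4 * (1 - 0.005)^2)
  expect_error(index_morph_prob(4, 5, 0.01),
               class = "templateseq_config_error")
})

test_that("morphing probability is monotone in d, p and n", {
  p <- 0.005
  probs_d <- vapply(1:6, function(d) index_morph_prob(6, d, p), numeric(1))
  expect_true(all(diff(probs_d) <= 0))
  probs_p <- vapply(c(1e-4, 1e-3, 5e-3, 1e-2),
                    function(p) index_morph_prob(6, 3, p), numeric(1))
  expect_true(all(diff(probs_p) >= 0))
  probs_n <- vapply(3:8, function(n) index_morph_prob(n, 3, p), numeric(1))
  expect_true(all(diff(probs_n) >= 0))
})

test_that("observed bleeding and obs/exp ratios follow their definitions", {
  expect_equal(observed_bleeding(0, 1e6), 0)
  expect_equal(observed_bleeding(35, 1e5), 3.5e-4)
  expect_equal(observed_bleeding(81, 1e8), 8.1e-7)
  expect_error(observed_bleeding(1, 0), class = "templateseq_config_error")
  expect_error(observed_bleeding(5, 3), class = "templateseq_config_error")

  expect_equal(obs_exp_ratio(0.5, 0.5), 1)
  expect_equal(obs_exp_ratio(3.5e-4, 8.5e-7, round_to_integer = FALSE),
               3.5e-4 / 8.5e-7)
  expect_error(obs_exp_ratio(1, 0), class = "templateseq_config_error")
})

test_that("cross-mapping counts exact-substring hits on the other reference only", {
  set.seed(5)
  ref_a <- paste(sample(c("A","C","G","T"), 5000, TRUE), collapse = "")
  ref_b <- paste(sample(c("A","C","G","T"), 5000, TRUE), collapse = "")
  starts <- seq(1, 4000, by = 200)
  reads_a <- substring(ref_a, starts, starts + 35)

  est <- cross_map(reads_a, ref_a, ref_b, expected = 1e-8)
  expect_s3_class(est, "bleeding_estimate")
  expect_equal(est$n_cross, 0L)
  expect_equal(est$observed, 0)
  expect_equal(tidy(est)$n_total, length(reads_a))

  # reverse-complement occurrences count as mapped
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(reads_a[1])))
  est_rc <- cross_map(rc, ref_b, ref_a, expected = 1e-8)
  expect_equal(est_rc$n_cross, 1L)
  expect_equal(est_rc$ratio, est_rc$observed / 1e-8)

  # reads with N never map anywhere
  nn <- paste0("N", substr(reads_a[1], 2, 36))
  expect_equal(cross_map(nn, ref_b, ref_a)$n_cross, 0L)

  expect_error(cross_map(reads_a, "", ref_b),
               class = "templateseq_config_error")
})

test_that("merged two-sample clusters bleed; long templates remove the bleeding", {
  # A lane built by hand around the bleeding mechanism. Each engineered pair
  # holds a bright barcoded-sample cluster and a dimmer control cluster
  # 3.4 px apart whose inserts share the 5' barcode and the next 29 bases
  # (linker/homology carry-over) and then diverge, so that:
  #   * in every barcode cycle the pair shares a channel and coalesces into
  #     one spot, so a 4-cycle template yields a single merged position
  #     between the clusters;
  #   * the merged read's insert is dominated by the bright cluster (the
  #     shared 34-cycle stretch keeps it quality-clean) while the control
  #     cluster, brighter in the separately-primed index read, wins the
  #     index cycles: a cleanly called barcoded-sample insert demultiplexed
  #     into the control sample — sample bleeding;
  #   * a (barcode+2)-cycle template sees the diverging cycles, resolves the
  #     pair into two positions, and each position's index is won by its own
  #     cluster: the chimera disappears.
  barcode <- "TCGAG"
  idx_h <- "ATCACG"; idx_y <- "TAGCTT"
  genomic <- 36L
  insert_len <- nchar(barcode) + genomic
  set.seed(99)
  ref_h <- paste(sample(c("A","C","G","T"), 4000, TRUE), collapse = "")
  ref_y <- paste(sample(c("A","C","G","T"), 4000, TRUE), collapse = "")

  n_pairs <- 6L
  gx <- seq(30, 170, length.out = n_pairs)
  hum_seq <- vapply(seq_len(n_pairs), function(i) {
    paste0(barcode, substr(ref_h, 50 * i, 50 * i + genomic - 1L), idx_h)
  }, character(1))
  yst_seq <- vapply(seq_len(n_pairs), function(i) {
    # diverges from its partner exactly at insert cycle 6 (base-swapped, so
    # the pair never shares a channel there); cycles 7-41 are shared, which
    # keeps a >= 34-cycle clean run for the quality filter and at most one
    # low-chastity cycle for the purity filter
    paste0(barcode, chartr("ACGT", "CATG",
                           substr(ref_h, 50 * i, 50 * i)),
           substr(ref_h, 50 * i + 1L, 50 * i + genomic - 1L), idx_y)
  }, character(1))
  cl <- manual_clusters(
    x = c(gx, gx + 3.4), y = rep(60, 2 * n_pairs),
    sequence = c(hum_seq, yst_seq),
    amplitude = c(rep(4000, n_pairs), rep(2600, n_pairs)),
    amplitude_index = c(rep(2000, n_pairs), rep(3200, n_pairs)),
    sample_label = rep(c("barcoded", "control"), each = n_pairs)
  )
  cfg <- sim_config(tile_width_px = 200, tile_height_px = 120,
                    n_cycles = insert_len + 6L, index_cycles = 6L,
                    read_noise_sd = 0, background_level = 100, drift_px = 0,
                    seed = 1)
  run <- manual_run(cl, cfg)

  observe <- function(K) {
    reads <- call_run(run, template_config(K), insert_cycles = insert_len,
                      match_radius = 2.5)
    reads$index_called <- substr(reads$sequence, insert_len + 1L,
                                 insert_len + 6L)
    assigned <- dplyr::filter(reads, purity_pass,
                              index_called == idx_y)   # control sample
    keep <- vapply(assigned$qual, function(q) {
      quality_filter(q[seq_len(insert_len)])
    }, logical(1))
    assigned <- assigned[keep, ]
    bc <- match_barcode(substr(assigned$sequence, 1, insert_len), barcode)
    mapped <- ifelse(is.na(bc$barcode), bc$sequence, bc$trimmed)
    est <- cross_map(mapped, ref_y, ref_h)
    list(est = est, reads = assigned)
  }

  short <- observe(4L)
  long <- observe(7L)
  # A lane built by hand: cross-sample pairs 3.5 px apart whose inserts share
  # a 5 nt prefix (so the pair coalesces in every barcode cycle) but diverge
  # afterwards. Insert amplitudes favour the control cluster, index
  # amplitudes favour the barcoded cluster: a 4-cycle template merges the
  # pair into one position and emits a cleanly called control read carrying
  # the barcoded sample's index (sample bleeding); a (barcode+2)-cycle
  # template resolves the pair and the chimera disappears.
  # bleeding occurs with the 4-cycle template and every cross-mapped read
  # comes from a merged template position
  expect_gt(short$est$n_cross, 0L)
  expect_true(all(short$reads$merged[short$est$cross_mapped]))
  # raising the template length to barcode + 2 strictly decreases bleeding
  expect_lt(long$est$n_cross, short$est$n_cross)
  expect_equal(long$est$n_cross, 0L)
})
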