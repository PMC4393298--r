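#' Generate ground-truth clusters for a tile
#'
#' Places clusters as a homogeneous Poisson process on the tile (optionally
#' thinned to enforce a minimum spacing), assigns each a sequence according to
#' the diversity structure of the configuration, and draws log-normal spot
#' amplitudes. This tibble is the hidden truth against which every downstream
#' stage is evaluated.
#'
#' @param config A [sim_config()].
#' @return Tibble with one row per cluster: `id`, `x`, `y` (0-based pixel
#'   coordinates), `sequence` (length `n_cycles`), `amplitude`,
#'   `amplitude_index` (independent amplitude used during index cycles),
#'   `sample_label`, `index_sequence`.
#' @export
#' @examples
#' cl <- generate_clusters(sim_config(tile_width_px = 96, tile_height_px = 96,
#'                                    n_cycles = 6, seed = 3))
#' nrow(cl)
generate_clusters <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, generate_clusters_impl(config))
}

generate_clusters_impl <- function(config) {
  w <- config$tile_width_px
  h <- config$tile_height_px
  lambda <- config$optimal_density * config$density_fraction * w * h
  n <- if (lambda == 0) 0L else rpois(1L, lambda)
  empty <- tibble(
    id = integer(), x = numeric(), y = numeric(), sequence = character(),
    amplitude = numeric(), amplitude_index = numeric(),
    sample_label = character(), index_sequence = character()
  )
  if (n == 0L) return(empty)

  x <- runif(n, 0, w)
  y <- runif(n, 0, h)
  if (config$exclusion_radius_px > 0 && n > 1L) {
    keep <- thin_min_distance(x, y, config$exclusion_radius_px)
    x <- x[keep]; y <- y[keep]; n <- length(x)
    if (n == 0L) return(empty)
  }

  sdlog <- sqrt(log(1 + config$amplitude_cv^2))
  meanlog <- log(config$amplitude_mean) - sdlog^2 / 2
  amplitude <- rlnorm(n, meanlog, sdlog)
  amplitude_index <- rlnorm(n, meanlog, sdlog)

  sheet <- config$sample_sheet %||% default_sample_sheet(config)
  si <- if (nrow(sheet) == 1L) rep(1L, n) else {
    sample(seq_len(nrow(sheet)), n, replace = TRUE, prob = sheet$fraction)
  }

  insert_len <- config$n_cycles - config$index_cycles
  sequence <- character(n)
  for (k in seq_len(n)) {
    row <- sheet[si[k], ]
    prefix <- if ("prefix" %in% names(row) && !is.na(row$prefix)) row$prefix else ""
    body_len <- insert_len - nchar(prefix)
    if (body_len < 0) {
      abort("prefix longer than the insert read", class = "templateseq_config_error")
    }
    body <- if ("reference" %in% names(row) && !is.na(row$reference)) {
      ref <- row$reference
      start <- sample.int(nchar(ref) - body_len + 1L, 1L)
      substr(ref, start, start + body_len - 1L)
    } else if (body_len > 0L) {
      random_dna(body_len)
    } else ""
    idx <- if (config$index_cycles > 0L) {
      if ("index" %in% names(row) && !is.na(row$index)) row$index
      else random_dna(config$index_cycles)
    } else ""
    sequence[k] <- paste0(prefix, body, idx)
  }

  index_sequence <- if (config$index_cycles > 0L) {
    substr(sequence, insert_len + 1L, config$n_cycles)
  } else NA_character_

  tibble(
    id = seq_len(n), x = x, y = y, sequence = sequence,
    amplitude = amplitude, amplitude_index = amplitude_index,
    sample_label = sheet$sample_label[si], index_sequence = index_sequence
  )
}

default_sample_sheet <- function(config) {
  if (config$lowdiv_fraction > 0) {
    np <- length(config$prefix_sequences)
    if (np == 0L) {
      abort("lowdiv_fraction > 0 requires prefix_sequences",
            class = "templateseq_config_error")
    }
    tibble(
      sample_label = c(paste0("lowdiv_", seq_len(np)), "diverse"),
      fraction = c(rep(config$lowdiv_fraction / np, np),
                   1 - config$lowdiv_fraction),
      prefix = c(config$prefix_sequences, NA_character_)
    ) |>
      filter(.data$fraction > 0)
  } else {
    tibble(sample_label = "diverse", fraction = 1, prefix = NA_character_)
  }
}

# Matern-II style thinning: visit points in order, drop any within `r` of an
# already kept point.
thin_min_distance <- function(x, y, r) {
  n <- length(x)
  keep <- logical(n)
  kept_x <- numeric(0)
  kept_y <- numeric(0)
  for (k in seq_len(n)) {
    if (length(kept_x) == 0L ||
        min((kept_x - x[k])^2 + (kept_y - y[k])^2) >= r^2) {
      keep[k] <- TRUE
      kept_x <- c(kept_x, x[k])
      kept_y <- c(kept_y, y[k])
    }
  }
  which(keep)
}

#' Render the four channel images for one cycle
#'
#' Each cluster contributes an isotropic Gaussian spot with integrated
#' intensity equal to its amplitude into the channel of its base at position
#' `cycle`, centred at `(x + dx, y + dy)`. Channels are then mixed by the
#' crosstalk matrix, background and (optionally) shot and read noise are
#' added, and pixel values are clamped to the 16-bit range \[0, 65535\].
#'
#' Noise draws consume the current RNG stream; [simulate_run()] seeds it from
#' the configuration so full runs are reproducible.
#'
#' @param clusters Tibble from [generate_clusters()].
#' @param cycle 1-based cycle index (<= `n_cycles`).
#' @param config The [sim_config()].
#' @param offset Numeric `(dx, dy)` translation applied to the whole cycle.
#' @return A `cycle_images` object: list with `cycle`, `channels` (named list
#'   of A/C/G/T matrices) and `offset`.
#' @export
render_cycle <- function(clusters, cycle, config, offset = c(0, 0)) {
  validate_sim_config(config)
  if (cycle < 1L || cycle > config$n_cycles) {
    abort("cycle out of range", class = "templateseq_config_error")
  }
  w <- config$tile_width_px
  h <- config$tile_height_px
  sigma <- config$psf_sigma_px
  rad <- ceiling(4 * sigma)
  insert_len <- config$n_cycles - config$index_cycles

  raw <- setNames(vector("list", 4L), DNA_BASES)
  for (b in DNA_BASES) raw[[b]] <- matrix(0, nrow = h, ncol = w)

  if (nrow(clusters) > 0L) {
    base <- substr(clusters$sequence, cycle, cycle)
    amp <- if (cycle > insert_len) clusters$amplitude_index else clusters$amplitude
    cx <- clusters$x + offset[1]
    cy <- clusters$y + offset[2]
    px <- round(cx)
    py <- round(cy)
    fx <- cx - px
    fy <- cy - py
    offs <- -rad:rad
    # pixel-sampled separable Gaussian, normalised over the render window so
    # each spot integrates to its amplitude
    gx <- vapply(offs, function(du) exp(-(du - fx)^2 / (2 * sigma^2)),
                 numeric(length(fx)))
    gy <- vapply(offs, function(dv) exp(-(dv - fy)^2 / (2 * sigma^2)),
                 numeric(length(fy)))
    if (is.null(dim(gx))) gx <- matrix(gx, nrow = 1L)
    if (is.null(dim(gy))) gy <- matrix(gy, nrow = 1L)
    norm <- rowSums(gx) * rowSums(gy)

    noff <- length(offs)
    for (b in DNA_BASES) {
      sel <- which(base == b)
      if (length(sel) == 0L) next
      img <- raw[[b]]
      for (k in sel) {
        patch <- (amp[k] / norm[k]) * tcrossprod(gy[k, ], gx[k, ])
        rows <- (py[k] - rad):(py[k] + rad) + 1
        cols <- (px[k] - rad):(px[k] + rad) + 1
        rok <- rows >= 1 & rows <= h
        cok <- cols >= 1 & cols <= w
        if (all(rok) && all(cok)) {
          img[rows, cols] <- img[rows, cols] + patch
        } else if (any(rok) && any(cok)) {
          img[rows[rok], cols[cok]] <- img[rows[rok], cols[cok]] +
            patch[rok, cok, drop = FALSE]
        }
      }
      raw[[b]] <- img
    }
  }

  ct <- config$crosstalk
  identity_ct <- all(abs(ct - diag(4)) < 1e-12)
  channels <- setNames(vector("list", 4L), DNA_BASES)
  for (ci in seq_along(DNA_BASES)) {
    sig <- if (identity_ct) raw[[ci]] else {
      ct[1L, ci] * raw[[1L]] + ct[2L, ci] * raw[[2L]] +
        ct[3L, ci] * raw[[3L]] + ct[4L, ci] * raw[[4L]]
    }
    img <- sig + config$background_level
    if (config$shot_noise) {
      img[] <- rpois(length(img), pmax(img, 0))
    }
    if (config$read_noise_sd > 0) {
      img <- img + rnorm(length(img), 0, config$read_noise_sd)
    }
    channels[[DNA_BASES[ci]]] <- pmin(pmax(img, 0), 65535)
  }

  structure(list(cycle = as.integer(cycle), channels = channels,
                 offset = as.numeric(offset)),
            class = "cycle_images")
}

#' @export
print.cycle_images <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<cycle_images> cycle %d, 4 x %d x %d px, offset (%.2f, %.2f)\n",
              x$cycle, d[2], d[1], x$offset[1], x$offset[2]))
  invisible(x)
}

#' Simulate a complete sequencing run on one tile
#'
#' Generates ground-truth clusters, draws per-cycle stage offsets (cycle 1 is
#' the reference at (0, 0); later cycles drift uniformly in
#' `[-drift_px, drift_px]`) and renders one four-channel image set per cycle.
#' Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return An `fc_run` object: list with `images` (list of `cycle_images`),
#'   `clusters` (ground-truth tibble) and `config`.
#' @export
#' @examples
#' run <- simulate_run(sim_config(tile_width_px = 96, tile_height_px = 96,
#'                                n_cycles = 4, seed = 5))
#' length(run$images)
simulate_run <- function(config) {
  validate_sim_config(config)
  clusters <- generate_clusters(config)
  images <- with_seed(config$seed + 1L, {
    offsets <- matrix(0, nrow = config$n_cycles, ncol = 2L)
    if (config$n_cycles > 1L && config$drift_px > 0) {
      offsets[-1L, ] <- runif(2L * (config$n_cycles - 1L),
                              -config$drift_px, config$drift_px)
    }
    lapply(seq_len(config$n_cycles), function(cy) {
      render_cycle(clusters, cy, config, offsets[cy, ])
    })
  })
  structure(list(images = images, clusters = clusters, config = config),
            class = "fc_run")
}

#' @export
print.fc_run <- function(x, ...) {
  cat(sprintf("<fc_run> %d cycles, %d clusters, %d x %d px tile\n",
              length(x$images), nrow(x$clusters),
              x$config$tile_width_px, x$config$tile_height_px))
  invisible(x)
}

#' Write a simulated run to disk
#'
#' Writes each channel image as a single-page 16-bit grayscale little-endian
#' TIFF named `C{cycle}_{base}.tif`, the ground truth as a TSV, and a YAML
#' manifest recording geometry, seed and the applied per-cycle offsets.
#'
#' @param run An `fc_run` from [simulate_run()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "fc_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (img in run$images) {
    for (b in DNA_BASES) {
      path <- file.path(dir, sprintf("C%d_%s.tif", img$cycle, b))
      tiff::writeTIFF(img$channels[[b]] / 65535, path,
                      bits.per.sample = 16L, compression = "none")
    }
  }
  gt <- run$clusters |>
    select("id", "x", "y", "sequence", "amplitude", "sample_label",
           "index_sequence")
  write.table(gt, file.path(dir, "ground_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- list(
    tile_width_px = run$config$tile_width_px,
    tile_height_px = run$config$tile_height_px,
    n_cycles = run$config$n_cycles,
    index_cycles = run$config$index_cycles,
    seed = run$config$seed,
    psf_sigma_px = run$config$psf_sigma_px,
    offsets = lapply(run$images, function(i) as.list(setNames(i$offset,
                                                              c("dx", "dy"))))
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a run's channel images back from disk
#'
#' Counterpart of [write_run()]: reads the TIFF channel images and the YAML
#' manifest (ground truth is not required).
#'
#' @param dir Directory written by [write_run()].
#' @return List with `images` (list of `cycle_images`) and `manifest`.
#' @export
read_run_images <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  images <- lapply(seq_len(manifest$n_cycles), function(cy) {
    channels <- setNames(lapply(DNA_BASES, function(b) {
      tiff::readTIFF(file.path(dir, sprintf("C%d_%s.tif", cy, b))) * 65535
    }), DNA_BASES)
    off <- unlist(manifest$offsets[[cy]])
    structure(list(cycle = cy, channels = channels,
                   offset = as.numeric(off)),
              class = "cycle_images")
  })
  list(images = images, manifest = manifest)
}

# max-over-channels image used by the detector and registration
max_channel_image <- function(image_set) {
  ch <- image_set$channels
  pmax(ch$A, ch$C, ch$G, ch$T)
}
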