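#' Extract per-cluster channel intensities at the template positions
#'
#' For every template position and cycle, samples each channel with a
#' PSF-matched filter: background (per-channel median) is subtracted and
#' pixels within `3 * psf_sigma` of the offset-corrected position are combined
#' with Gaussian weights, normalised so that an isolated noiseless spot
#' returns its amplitude. Negative estimates are clamped to zero. Positions
#' whose extraction window leaves the image are flagged and return zeros.
#'
#' @param template An `fc_template`.
#' @param image_sets List of `cycle_images` (one per cycle).
#' @param config The [sim_config()] of the run (for `psf_sigma_px`).
#' @param offsets Optional n_cycles x 2 matrix of per-cycle offsets. By
#'   default each cycle is registered against the template with
#'   [register_offset()].
#' @return List with `intensities` (array `n_positions x 4 x n_cycles`,
#'   channel order A, C, G, T), `offsets` (the per-cycle offsets used) and
#'   `out_of_image` (logical flag per position).
#' @export
extract_intensities <- function(template, image_sets, config, offsets = NULL) {
  if (!inherits(template, "fc_template") || nrow(template$positions) == 0L) {
    abort("template is empty", class = "templateseq_config_error")
  }
  n_cycles <- length(image_sets)
  if (is.null(offsets)) {
    offsets <- t(vapply(image_sets, register_offset, numeric(2),
                        template = template))
  }
  stopifnot(nrow(offsets) == n_cycles)

  sigma <- config$psf_sigma_px
  rad <- ceiling(3 * sigma)
  offs <- -rad:rad
  tx <- template$positions$x
  ty <- template$positions$y
  n <- length(tx)
  h <- config$tile_height_px
  w <- config$tile_width_px

  out <- array(0, dim = c(n, 4L, n_cycles),
               dimnames = list(NULL, DNA_BASES, NULL))
  flagged <- logical(n)

  for (cy in seq_len(n_cycles)) {
    cx <- tx + offsets[cy, 1L]
    cyy <- ty + offsets[cy, 2L]
    px <- round(cx); py <- round(cyy)
    fx <- cx - px; fy <- cyy - py
    inb <- px - rad >= 0 & px + rad <= w - 1 & py - rad >= 0 & py + rad <= h - 1
    flagged <- flagged | !inb
    sel <- which(inb)
    if (length(sel) == 0L) next

    gx <- vapply(offs, function(du) exp(-(du - fx[sel])^2 / (2 * sigma^2)),
                 numeric(length(sel)))
    gy <- vapply(offs, function(dv) exp(-(dv - fy[sel])^2 / (2 * sigma^2)),
                 numeric(length(sel)))
    if (is.null(dim(gx))) gx <- matrix(gx, nrow = 1L)
    if (is.null(dim(gy))) gy <- matrix(gy, nrow = 1L)
    norm <- rowSums(gx) * rowSums(gy)

    imgs <- image_sets[[cy]]$channels
    bgs <- vapply(imgs, median, numeric(1))
    num <- matrix(0, nrow = length(sel), ncol = 4L)
    den <- numeric(length(sel))
    base_lin <- px[sel] * h + py[sel] + 1  # 0-based (px, py) -> linear index
    for (ia in seq_along(offs)) {
      row_off <- offs[ia]
      for (ib in seq_along(offs)) {
        lin <- base_lin + offs[ib] * h + row_off
        wgt <- gy[, ia] * gx[, ib] / norm
        den <- den + wgt * wgt
        for (b in 1:4) {
          num[, b] <- num[, b] + wgt * (imgs[[b]][lin] - bgs[b])
        }
      }
    }
    for (b in 1:4) {
      out[sel, b, cy] <- pmax(num[, b] / den, 0)
    }
  }
  list(intensities = out, offsets = offsets, out_of_image = flagged)
}

#' Call bases and per-cycle chastity from channel intensities
#'
#' The base at each cycle is the channel with the largest intensity; the
#' chastity of the call is `I1 / (I1 + I2)` with `I1 >= I2` the two largest
#' channel intensities. An all-zero intensity vector yields an `N` call with
#' chastity 0.25 (the uninformative value of a four-channel system).
#'
#' @param intensities Array `n_positions x 4 x n_cycles` (channel order
#'   A, C, G, T), e.g. from [extract_intensities()].
#' @return Tibble with `position_id`, `sequence`, and `chastity` (list column
#'   of per-cycle numeric vectors).
#' @export
call_bases <- function(intensities) {
  stopifnot(length(dim(intensities)) == 3L, dim(intensities)[2L] == 4L)
  n <- dim(intensities)[1L]
  n_cycles <- dim(intensities)[3L]
  seq_mat <- matrix("N", nrow = n, ncol = n_cycles)
  chast <- matrix(0.25, nrow = n, ncol = n_cycles)
  for (cy in seq_len(n_cycles)) {
    I <- intensities[, , cy, drop = FALSE]
    dim(I) <- c(n, 4L)
    top <- max.col(I, ties.method = "first")
    i1 <- I[cbind(seq_len(n), top)]
    I2 <- I
    I2[cbind(seq_len(n), top)] <- -Inf
    second <- max.col(I2, ties.method = "first")
    i2 <- I[cbind(seq_len(n), second)]
    informative <- i1 > 0
    seq_mat[informative, cy] <- DNA_BASES[top[informative]]
    chast[informative, cy] <- i1[informative] /
      (i1[informative] + i2[informative])
  }
  tibble(
    position_id = seq_len(n),
    sequence = apply(seq_mat, 1L, paste, collapse = ""),
    chastity = lapply(seq_len(n), function(i) chast[i, ])
  )
}

#' Map chastity to Phred quality scores
#'
#' A documented piecewise-linear convention (the instrument's quality model is
#' not public): chastity 0.5 maps to Q2 and chastity 1.0 to Q40, linearly in
#' between; chastity below 0.5 (only possible for `N` calls) stays at Q2.
#' The map is monotone non-decreasing in chastity.
#'
#' @param reads Tibble from [call_bases()] (needs the `chastity` list column).
#' @param q_min,q_max Endpoints of the linear map.
#' @return `reads` with added list column `qual` (integer Phred scores per
#'   cycle) and character column `qual_string` (Phred+33).
#' @export
assign_quality <- function(reads, q_min = 2L, q_max = 40L) {
  reads$qual <- lapply(reads$chastity, function(ch) {
    q <- q_min + (q_max - q_min) * (ch - 0.5) / 0.5
    as.integer(pmin(pmax(round(q), q_min), q_max))
  })
  reads$qual_string <- vapply(reads$qual, function(q) {
    intToUtf8(q + 33L)
  }, character(1))
  reads
}

#' Chastity (purity) filter
#'
#' A read passes if no more than one cycle among the first `window` cycles has
#' chastity below `min_chastity`. Merged ("mixed") clusters show strong
#' intensity in two channels across many cycles and fail this filter.
#'
#' @param reads Tibble with a `chastity` list column, or a single numeric
#'   chastity vector.
#' @param min_chastity Chastity threshold (conventional default 0.6).
#' @param window Number of leading cycles examined (conventional default 25;
#'   shorter reads use all their cycles).
#' @param max_failures Number of sub-threshold cycles tolerated.
#' @return For a tibble input, the tibble with a logical `purity_pass` column;
#'   for a vector input, a single logical.
#' @export
#' @examples
#' purity_filter(c(1, 1, 0.55, 1))
#' purity_filter(c(1, 0.5, 0.5, 1))
purity_filter <- function(reads, min_chastity = 0.6, window = 25L,
                          max_failures = 1L) {
  one <- function(ch) {
    k <- seq_len(min(window, length(ch)))
    sum(ch[k] < min_chastity) <= max_failures
  }
  if (is.numeric(reads)) return(one(reads))
  reads$purity_pass <- vapply(reads$chastity, one, logical(1))
  reads
}

#' Run the full base-calling stage on a simulated run
#'
#' Builds (or reuses) a template, registers every cycle, extracts intensities,
#' calls bases with chastity, assigns qualities and applies the purity filter.
#' Reads are annotated with their nearest ground-truth cluster so that
#' simulation studies can score them against the truth.
#'
#' @param run An `fc_run` from [simulate_run()].
#' @param template_cfg A [template_config()]; ignored when `template` given.
#' @param template Optionally a pre-built `fc_template`.
#' @param insert_cycles Restrict chastity filtering to the first insert
#'   cycles; defaults to `n_cycles - index_cycles` of the run configuration.
#' @param min_chastity,purity_window Purity filter parameters.
#' @param match_radius Radius for matching template positions to ground truth.
#' @return Tibble of reads: `position_id`, `x`, `y`, `sequence`, `chastity`,
#'   `qual`, `qual_string`, `purity_pass`, `out_of_image`, plus ground-truth
#'   annotation `true_id`, `sample_label_true`, `true_sequence` and `merged`
#'   (TRUE when two or more true clusters fall within `match_radius` of the
#'   position).
#' @export
call_run <- function(run, template_cfg = template_config(), template = NULL,
                     insert_cycles = NULL, min_chastity = 0.6,
                     purity_window = 25L, match_radius = 2) {
  stopifnot(inherits(run, "fc_run"))
  if (is.null(template)) template <- build_template(run$images, template_cfg)
  ext <- extract_intensities(template, run$images, run$config)
  reads <- call_bases(ext$intensities)
  insert_cycles <- insert_cycles %||%
    (run$config$n_cycles - run$config$index_cycles)

  reads$x <- template$positions$x
  reads$y <- template$positions$y
  reads$out_of_image <- ext$out_of_image
  reads <- assign_quality(reads)
  reads$purity_pass <- vapply(reads$chastity, function(ch) {
    purity_filter(ch[seq_len(min(insert_cycles, length(ch)))],
                  min_chastity = min_chastity, window = purity_window)
  }, logical(1))

  reads <- annotate_reads(reads, run$clusters, match_radius)
  reads
}

# attach nearest ground-truth cluster and a merged flag to called reads;
# template positions live in the golden cycle's (drifted) frame, so the truth
# is registered onto them first
annotate_reads <- function(reads, clusters, match_radius = 2) {
  n <- nrow(reads)
  if (nrow(clusters) == 0L || n == 0L) {
    reads$true_id <- NA_integer_
    reads$sample_label_true <- NA_character_
    reads$true_sequence <- NA_character_
    reads$merged <- FALSE
    return(reads)
  }
  shift <- register_points(reads$x, reads$y, clusters$x, clusters$y,
                           radius = match_radius, max_shift = 4L)
  cx <- clusters$x + shift[1]
  cy <- clusters$y + shift[2]
  nn <- nearest_within(reads$x, reads$y, cx, cy, match_radius)
  reads$true_id <- clusters$id[nn$index]
  reads$sample_label_true <- clusters$sample_label[nn$index]
  reads$true_sequence <- clusters$sequence[nn$index]
  # a position is "merged" when >= 2 true clusters sit within match_radius
  cand <- neighbor_candidates(reads$x, reads$y, cx, cy, match_radius)
  cnt <- integer(n)
  if (nrow(cand) > 0L) {
    tab <- table(cand$i)
    cnt[as.integer(names(tab))] <- as.integer(tab)
  }
  reads$merged <- cnt >= 2L
  reads
}

#' Write called reads to FASTQ
#'
#' Writes purity-passing reads (optionally all reads) as FASTQ with Phred+33
#' qualities. Read names encode the tile label and position id.
#'
#' @param reads Tibble from [call_run()] (or [assign_quality()]).
#' @param path Output FASTQ path.
#' @param tile Tile label embedded in read names.
#' @param include_fail Include purity-failing reads too.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, tile = "tile1", include_fail = FALSE) {
  if (!include_fail && "purity_pass" %in% names(reads)) {
    reads <- reads[reads$purity_pass, ]
  }
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  flag <- if ("purity_pass" %in% names(reads)) {
    ifelse(reads$purity_pass, "pass", "fail")
  } else "pass"
  names(seqs) <- sprintf("%s:%d:%d:%d %s", tile, reads$position_id,
                         round(reads$x), round(reads$y), flag)
  quals <- Biostrings::PhredQuality(reads$qual_string)
  qs <- Biostrings::QualityScaledDNAStringSet(seqs, quals)
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}
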