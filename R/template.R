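#' Template-generation configuration
#'
#' Parameters of the template engine. `template_cycle_count` is the number of
#' initial cycles whose images are examined for template generation (the
#' instrument default is 4; larger values are the Long Template Protocol).
#' `first_template_cycle` is retained for completeness: it shifts the start of
#' the template window, mirroring a deprecated instrument switch.
#'
#' @param template_cycle_count Number of cycles used for template generation
#'   (>= 2, so that a golden and a silver cycle exist).
#' @param first_template_cycle First cycle of the template window (default 1).
#' @param detection_threshold_sd Spot threshold in robust background-noise SDs
#'   above each channel's background level.
#' @param merge_radius_px Local maxima closer than this are collapsed into one
#'   spot (intensity-weighted centroid).
#' @param dedup_radius_px Cross-cycle duplicate radius used when golden and
#'   silver spot lists are combined.
#' @param max_shift_px Largest integer translation searched during
#'   registration.
#' @param shoulder_radius_px,shoulder_ratio A maximum is discarded when a
#'   maximum of the same channel within `shoulder_radius_px` is more than
#'   `shoulder_ratio` times brighter. Two same-channel Gaussians closer than
#'   about 2 PSF sigma form a single maximum, so a second, weaker maximum
#'   inside that scale is noise riding on the first spot's wing, not a
#'   resolvable cluster; the defaults (radius just under 2 sigma, ratio 1)
#'   therefore apply non-maximum suppression per channel at the detector's
#'   own resolution scale.
#' @return An object of class `template_config`.
#' @export
#' @examples
#' template_config(template_cycle_count = 7)
template_config <- function(template_cycle_count = 4L,
                            first_template_cycle = 1L,
                            detection_threshold_sd = 4,
                            merge_radius_px = 1.5,
                            dedup_radius_px = 1.5,
                            max_shift_px = 4L,
                            shoulder_radius_px = 3.5,
                            shoulder_ratio = 1) {
  if (template_cycle_count < 2L) {
    abort("template_cycle_count must be >= 2 (golden and silver must exist)",
          class = "templateseq_config_error")
  }
  if (first_template_cycle < 1L) {
    abort("first_template_cycle must be >= 1",
          class = "templateseq_config_error")
  }
  if (merge_radius_px <= 0 || dedup_radius_px <= 0) {
    abort("radii must be positive", class = "templateseq_config_error")
  }
  structure(list(template_cycle_count = as.integer(template_cycle_count),
                 first_template_cycle = as.integer(first_template_cycle),
                 detection_threshold_sd = detection_threshold_sd,
                 merge_radius_px = merge_radius_px,
                 dedup_radius_px = dedup_radius_px,
                 max_shift_px = as.integer(max_shift_px),
                 shoulder_radius_px = shoulder_radius_px,
                 shoulder_ratio = shoulder_ratio),
            class = "template_config")
}

#' Detect cluster spots in one cycle's images
#'
#' Each channel image is searched separately for local maxima exceeding
#' `background + detection_threshold_sd * noise SD` (background and noise
#' estimated robustly as the median and MAD of that channel); each maximum is
#' refined to sub-pixel precision by an intensity-weighted centroid over a
#' small window of its own channel. The per-channel spot lists are then
#' pooled and maxima within `merge_radius_px` of each other — duplicates from
#' channel crosstalk, or genuinely unresolved clusters — are collapsed to
#' their intensity-weighted centroid.
#'
#' Per-channel detection is what makes low initial sequence diversity harmful:
#' in a cycle where many clusters share one base, that channel is crowded and
#' neighbouring clusters coalesce into single maxima, while in a diverse cycle
#' the same clusters fall into different channels and stay separable.
#'
#' @param image_set A `cycle_images` object.
#' @param cfg A [template_config()].
#' @return Tibble with columns `x`, `y` (0-based sub-pixel coordinates) and
#'   `intensity` (background-subtracted peak height). All-zero images give an
#'   empty tibble.
#' @export
detect_spots <- function(image_set, cfg = template_config()) {
  per_channel <- lapply(DNA_BASES, function(b) {
    channel_spots(image_set$channels[[b]], cfg)
  })
  spots <- list_rbind(per_channel)
  if (nrow(spots) == 0L) {
    return(tibble(x = numeric(), y = numeric(), intensity = numeric()))
  }
  merged <- merge_points(spots$x, spots$y, spots$intensity,
                         cfg$merge_radius_px)
  tibble(x = merged$x, y = merged$y, intensity = merged$w)
}

# local maxima + centroid refinement on a single channel image
channel_spots <- function(M, cfg) {
  h <- nrow(M); w <- ncol(M)
  bg <- median(M)
  noise_sd <- mad(M)
  thr <- bg + cfg$detection_threshold_sd * noise_sd
  if (thr <= 0) thr <- .Machine$double.eps
  if (h < 3L || w < 3L) {
    return(tibble(x = numeric(), y = numeric(), intensity = numeric()))
  }

  # strict > towards N/W/NW/SW neighbours, >= towards the others, so plateau
  # ties resolve to a single, deterministic pixel
  core <- M[2:(h - 1), 2:(w - 1)]
  is_max <- core > M[1:(h - 2), 2:(w - 1)] &   # north
    core >= M[3:h, 2:(w - 1)] &                # south
    core > M[2:(h - 1), 1:(w - 2)] &           # west
    core >= M[2:(h - 1), 3:w] &                # east
    core > M[1:(h - 2), 1:(w - 2)] &           # NW
    core >= M[1:(h - 2), 3:w] &                # NE
    core > M[3:h, 1:(w - 2)] &                 # SW
    core >= M[3:h, 3:w] &                      # SE
    core > thr
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(tibble(x = numeric(), y = numeric(), intensity = numeric()))
  }
  r0 <- idx[, 1L] + 1L   # back to full-image row/col
  c0 <- idx[, 2L] + 1L

  # sub-pixel refinement: background-subtracted intensity-weighted centroid
  # over a (2*cw+1)^2 window
  cw <- 2L
  S <- pmax(M - bg, 0)
  num_x <- numeric(length(r0)); num_y <- numeric(length(r0))
  den <- numeric(length(r0))
  for (du in -cw:cw) {
    cc <- pmin(pmax(c0 + du, 1L), w)
    for (dv in -cw:cw) {
      rr <- pmin(pmax(r0 + dv, 1L), h)
      v <- S[cbind(rr, cc)]
      den <- den + v
      num_x <- num_x + v * (cc - 1L)
      num_y <- num_y + v * (rr - 1L)
    }
  }
  ok <- den > 0
  # flux confirmation: a real spot concentrates far more integrated signal in
  # its 3x3 core than a noise excursion whose single pixel clears the
  # threshold; the 3x3 sum of pure noise has SD 3 * noise_sd
  flux3 <- numeric(length(r0))
  for (du in -1:1) {
    cc <- pmin(pmax(c0 + du, 1L), w)
    for (dv in -1:1) {
      rr <- pmin(pmax(r0 + dv, 1L), h)
      flux3 <- flux3 + S[cbind(rr, cc)]
    }
  }
  confirmed <- flux3 > cfg$detection_threshold_sd * 3 * noise_sd
  out <- tibble(x = ifelse(ok, num_x / den, c0 - 1)[confirmed],
                y = ifelse(ok, num_y / den, r0 - 1)[confirmed],
                intensity = S[cbind(r0, c0)][confirmed])

  # shoulder suppression: drop maxima dominated by a much brighter maximum of
  # the same channel nearby (noise on a bright spot's wing)
  if (nrow(out) > 1L && cfg$shoulder_radius_px > 0) {
    cand <- neighbor_candidates(out$x, out$y, out$x, out$y,
                                cfg$shoulder_radius_px)
    cand <- cand[cand$i != cand$j, , drop = FALSE]
    if (nrow(cand) > 0L) {
      dominated <- unique(cand$i[out$intensity[cand$j] >
                                   cfg$shoulder_ratio * out$intensity[cand$i]])
      if (length(dominated) > 0L) out <- out[-dominated, ]
    }
  }
  out
}

#' Rank template cycles by detected cluster count
#'
#' The cycle with the highest spot count is the golden cycle and the second
#' highest the silver cycle; ties break to the earlier cycle.
#'
#' @param per_cycle_counts Integer vector of spot counts (length >= 2).
#' @return List with 1-based elements `golden` and `silver`.
#' @export
#' @examples
#' rank_cycles(c(100, 120, 90, 110))
rank_cycles <- function(per_cycle_counts) {
  if (length(per_cycle_counts) < 2L) {
    abort("need counts for at least two cycles",
          class = "templateseq_config_error")
  }
  golden <- which.max(per_cycle_counts)
  rest <- per_cycle_counts
  rest[golden] <- -Inf
  silver <- which.max(rest)
  list(golden = golden, silver = silver)
}

#' Build the cluster template from the first template cycles
#'
#' Runs [detect_spots()] on every cycle in the template window, picks golden
#' and silver cycles with [rank_cycles()], registers the silver spot list onto
#' the golden one (integer shift maximising matches, refined by the mean
#' residual displacement of matched pairs), and returns the union of golden
#' spots and silver spots not within `dedup_radius_px` of a golden spot. The
#' template is fixed from then on: no later stage modifies it.
#'
#' @param image_sets List of `cycle_images`, covering at least the template
#'   window `first_template_cycle ... first_template_cycle +
#'   template_cycle_count - 1`.
#' @param cfg A [template_config()].
#' @param spot_cache Optional precomputed list of [detect_spots()] results for
#'   the cycles starting at `first_template_cycle` (at least
#'   `template_cycle_count` of them); lets several template lengths share one
#'   detection pass.
#' @return An `fc_template`: list with `positions` (tibble `x`, `y`),
#'   `golden_cycle`, `silver_cycle` (absolute cycle numbers),
#'   `per_cycle_spot_counts`, `source_cycles` and `cfg`.
#' @export
build_template <- function(image_sets, cfg = template_config(),
                           spot_cache = NULL) {
  first <- cfg$first_template_cycle
  last <- first + cfg$template_cycle_count - 1L
  if (last > length(image_sets)) {
    abort("template window exceeds available cycles",
          class = "templateseq_config_error")
  }
  window <- image_sets[first:last]
  spots <- spot_cache %||% lapply(window, detect_spots, cfg = cfg)
  spots <- spots[seq_len(cfg$template_cycle_count)]
  counts <- vapply(spots, nrow, integer(1))
  rk <- rank_cycles(counts)
  golden <- spots[[rk$golden]]
  silver <- spots[[rk$silver]]

  if (nrow(silver) > 0L && nrow(golden) > 0L) {
    shift <- register_points(golden$x, golden$y, silver$x, silver$y,
                             radius = cfg$dedup_radius_px,
                             max_shift = cfg$max_shift_px)
    positions <- combine_golden_silver(golden, silver, shift,
                                       cfg$dedup_radius_px)
  } else if (nrow(golden) > 0L) {
    positions <- tibble(x = golden$x, y = golden$y)
  } else {
    positions <- tibble(x = silver$x, y = silver$y)
  }

  structure(list(
    positions = positions,
    golden_cycle = first + rk$golden - 1L,
    silver_cycle = first + rk$silver - 1L,
    per_cycle_spot_counts = counts,
    source_cycles = first:last,
    cfg = cfg
  ), class = "fc_template")
}

#' @export
print.fc_template <- function(x, ...) {
  cat(sprintf(
    "<fc_template> %d positions; golden cycle %d, silver cycle %d (window %d-%d)\n",
    nrow(x$positions), x$golden_cycle, x$silver_cycle,
    min(x$source_cycles), max(x$source_cycles)))
  invisible(x)
}

# Max-resolution union of the golden and (offset-registered) silver spot
# lists: pooled spots are grouped by single linkage at the dedup radius and
# each group is represented by the spots of the cycle that resolved it into
# more maxima (ties favour the golden cycle). This keeps both members of a
# pair that one cycle separated, instead of a stale merged centroid from the
# other cycle, and avoids duplicate positions for clusters seen in both.
combine_golden_silver <- function(golden, silver, shift, dedup_radius) {
  x <- c(golden$x, silver$x + shift[1])
  y <- c(golden$y, silver$y + shift[2])
  from_golden <- c(rep(TRUE, nrow(golden)), rep(FALSE, nrow(silver)))
  n <- length(x)
  pairs <- neighbor_candidates(x, y, x, y, dedup_radius)
  pairs <- pairs[pairs$i < pairs$j, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  if (nrow(pairs) > 0L) {
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs$i[k]); rb <- find(pairs$j[k])
      if (ra != rb) parent[rb] <- ra
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  n_gold <- tapply(from_golden, root, sum)
  n_silv <- tapply(!from_golden, root, sum)
  silver_wins <- n_silv > n_gold
  take_silver <- silver_wins[as.character(root)]
  keep <- ifelse(take_silver, !from_golden, from_golden)
  tibble(x = x[keep], y = y[keep])
}

# Translation aligning point set (bx, by) onto (ax, ay): exhaustive integer
# search counting points that land within `radius` of a reference point, then
# sub-pixel refinement by the mean displacement of matched pairs.
register_points <- function(ax, ay, bx, by, radius, max_shift = 4L) {
  # reference occupancy mask dilated by `radius`
  pad <- max_shift + ceiling(radius) + 2L
  w <- ceiling(max(c(ax, bx))) + pad
  h <- ceiling(max(c(ay, by))) + pad
  mask <- matrix(FALSE, nrow = h + pad, ncol = w + pad)
  rr <- ceiling(radius)
  disc <- expand.grid(du = -rr:rr, dv = -rr:rr)
  disc <- disc[disc$du^2 + disc$dv^2 <= radius^2 + 1e-9, ]
  arx <- round(ax) + pad; ary <- round(ay) + pad
  for (k in seq_len(nrow(disc))) {
    rows <- ary + disc$dv[k]
    cols <- arx + disc$du[k]
    mask[cbind(rows, cols)] <- TRUE
  }
  brx <- round(bx) + pad; bry <- round(by) + pad
  best <- c(0L, 0L); best_score <- -1L
  for (dx in -max_shift:max_shift) {
    for (dy in -max_shift:max_shift) {
      score <- sum(mask[cbind(bry + dy, brx + dx)])
      if (score > best_score) {
        best_score <- score
        best <- c(dx, dy)
      }
    }
  }
  nn <- nearest_within(bx + best[1], by + best[2], ax, ay, radius)
  m <- which(!is.na(nn$index))
  if (length(m) > 0L) {
    resid_x <- mean(ax[nn$index[m]] - (bx[m] + best[1]))
    resid_y <- mean(ay[nn$index[m]] - (by[m] + best[2]))
    best <- best + c(resid_x, resid_y)
  }
  as.numeric(best)
}

#' Estimate the cycle-specific offset of an image against the template
#'
#' Translation-only registration: the background-subtracted max-over-channels
#' image is sampled (bilinearly) at the template positions shifted by every
#' integer offset in `[-max_shift, max_shift]^2`; the offset maximising the
#' summed intensity wins and is refined to sub-pixel precision by quadratic
#' interpolation of the score surface.
#'
#' @param image_set A `cycle_images` object.
#' @param template An `fc_template` (must be non-empty).
#' @param max_shift Largest integer shift searched (defaults to the template
#'   configuration's `max_shift_px`).
#' @param max_points Registration uses at most this many template positions
#'   (a deterministic evenly spaced subsample); the score is an average over
#'   hundreds of spots, so subsampling does not cost accuracy.
#' @return Numeric `(dx, dy)`.
#' @export
register_offset <- function(image_set, template, max_shift = NULL,
                            max_points = 500L) {
  if (!inherits(template, "fc_template") || nrow(template$positions) == 0L) {
    abort("template is empty", class = "templateseq_config_error")
  }
  max_shift <- max_shift %||% template$cfg$max_shift_px
  M <- max_channel_image(image_set)
  M <- M - median(M)
  tx <- template$positions$x
  ty <- template$positions$y
  if (length(tx) > max_points) {
    keep <- unique(round(seq(1L, length(tx), length.out = max_points)))
    tx <- tx[keep]
    ty <- ty[keep]
  }

  shifts <- -max_shift:max_shift
  nS <- length(shifts)
  score <- matrix(0, nrow = nS, ncol = nS)  # [dx index, dy index]
  for (ix in seq_len(nS)) {
    for (iy in seq_len(nS)) {
      score[ix, iy] <- sum(bilinear_sample(M, tx + shifts[ix], ty + shifts[iy]))
    }
  }
  best <- which(score == max(score), arr.ind = TRUE)[1L, ]
  dx <- shifts[best[1L]]
  dy <- shifts[best[2L]]

  # quadratic (parabola) sub-pixel refinement along each axis
  refine <- function(i, along) {
    if (i <= 1L || i >= nS) return(0)
    s0 <- score[best[1L], best[2L]]
    if (along == "x") {
      sm <- score[i - 1L, best[2L]]; sp <- score[i + 1L, best[2L]]
    } else {
      sm <- score[best[1L], i - 1L]; sp <- score[best[1L], i + 1L]
    }
    denom <- sm - 2 * s0 + sp
    if (denom >= 0) return(0)  # not a peak
    max(min(0.5 * (sm - sp) / denom, 0.5), -0.5)
  }
  c(dx + refine(best[1L], "x"), dy + refine(best[2L], "y"))
}

# bilinear interpolation of matrix M at 0-based coordinates (x, y); zero
# outside the image
bilinear_sample <- function(M, x, y) {
  h <- nrow(M); w <- ncol(M)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  val <- numeric(length(x))
  for (k in 0:3) {
    du <- k %% 2L; dv <- k %/% 2L
    cc <- x0 + du + 1L
    rr <- y0 + dv + 1L
    wgt <- (if (du == 0L) 1 - fx else fx) * (if (dv == 0L) 1 - fy else fy)
    ok <- cc >= 1L & cc <= w & rr >= 1L & rr <= h
    if (any(ok)) {
      val[ok] <- val[ok] + wgt[ok] * M[cbind(rr[ok], cc[ok])]
    }
  }
  val
}

#' Fraction of true clusters recovered by a template
#'
#' Matches template positions one-to-one to ground-truth clusters within
#' `match_radius` (greedy, closest pairs first) and reports the matched
#' fraction of true clusters. Clusters within `edge_margin` of the tile border
#' are excluded from the denominator, since their spots are clipped.
#'
#' The template's coordinates live in the golden cycle's (drifted) frame, so
#' the template is first registered onto the truth frame with a global
#' translation ([register_points()]) before matching.
#'
#' @param template An `fc_template`.
#' @param clusters Ground-truth tibble from [generate_clusters()].
#' @param config The [sim_config()] of the run (for the tile geometry).
#' @param match_radius Matching radius in pixels.
#' @param edge_margin Border exclusion zone in pixels.
#' @return A list with `recovered` (fraction), `n_true`, `n_matched` and
#'   `n_positions`.
#' @export
template_recovery <- function(template, clusters, config,
                              match_radius = 2, edge_margin = 8) {
  inside <- clusters$x >= edge_margin &
    clusters$x <= config$tile_width_px - edge_margin &
    clusters$y >= edge_margin &
    clusters$y <= config$tile_height_px - edge_margin
  truth <- clusters[inside, ]
  px <- template$positions$x
  py <- template$positions$y
  if (nrow(truth) > 0L && length(px) > 0L) {
    shift <- register_points(truth$x, truth$y, px, py,
                             radius = match_radius,
                             max_shift = template$cfg$max_shift_px)
    px <- px + shift[1]
    py <- py + shift[2]
  }
  m <- match_points(truth$x, truth$y, px, py, match_radius)
  list(recovered = mean(!is.na(m)),
       n_true = nrow(truth),
       n_matched = sum(!is.na(m)),
       n_positions = nrow(template$positions))
}
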