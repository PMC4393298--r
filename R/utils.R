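# Internal geometry helpers shared by the detector, the template builder and
# the evaluation code. Coordinates are 0-based, x = column, y = row; matrix
# element [r, c] holds the pixel centred at (x = c - 1, y = r - 1).

DNA_BASES <- c("A", "C", "G", "T")

# Candidate point pairs (query i, reference j) closer than `radius`, found by
# bucketing both sets on a grid of cell size `radius` and joining the 3x3
# cell neighbourhood; avoids the O(n^2) distance matrix.
neighbor_candidates <- function(qx, qy, rx, ry, radius) {
  if (length(qx) == 0L || length(rx) == 0L) {
    return(tibble(i = integer(), j = integer(), dist = numeric()))
  }
  key <- function(cx, cy) cx + 1e5 * cy
  ref <- tibble(j = seq_along(rx),
                cell = key(floor(rx / radius), floor(ry / radius)))
  qcx <- floor(qx / radius)
  qcy <- floor(qy / radius)
  off <- expand.grid(dx = -1:1, dy = -1:1)
  nq <- length(qx)
  qry <- tibble(
    i = rep(seq_len(nq), times = nrow(off)),
    cell = key(rep(qcx, times = nrow(off)) + rep(off$dx, each = nq),
               rep(qcy, times = nrow(off)) + rep(off$dy, each = nq))
  )
  cand <- inner_join(qry, ref, by = "cell", relationship = "many-to-many")
  if (nrow(cand) == 0L) {
    return(tibble(i = integer(), j = integer(), dist = numeric()))
  }
  d <- sqrt((qx[cand$i] - rx[cand$j])^2 + (qy[cand$i] - ry[cand$j])^2)
  keep <- d <= radius
  tibble(i = cand$i[keep], j = cand$j[keep], dist = d[keep])
}

# For each query point the nearest reference point within `radius` (NA if none).
nearest_within <- function(qx, qy, rx, ry, radius) {
  cand <- neighbor_candidates(qx, qy, rx, ry, radius)
  out <- rep(NA_integer_, length(qx))
  dist <- rep(NA_real_, length(qx))
  if (nrow(cand) > 0L) {
    best <- cand |>
      group_by(.data$i) |>
      slice_min(.data$dist, n = 1L, with_ties = FALSE) |>
      ungroup()
    out[best$i] <- best$j
    dist[best$i] <- best$dist
  }
  list(index = out, dist = dist)
}

# Greedy one-to-one matching by increasing distance; returns for each query the
# matched reference index or NA. Used for truth/template recovery metrics.
match_points <- function(qx, qy, rx, ry, radius) {
  cand <- neighbor_candidates(qx, qy, rx, ry, radius)
  match <- rep(NA_integer_, length(qx))
  if (nrow(cand) == 0L) return(match)
  cand <- arrange(cand, .data$dist)
  used_r <- logical(length(rx))
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (is.na(match[i]) && !used_r[j]) {
      match[i] <- j
      used_r[j] <- TRUE
    }
  }
  match
}

# Single-linkage merge of weighted points within `radius`: connected components
# of the proximity graph collapse to their weight-centroid.
merge_points <- function(x, y, w, radius) {
  n <- length(x)
  if (n == 0L) return(tibble(x = numeric(), y = numeric(), w = numeric()))
  pairs <- neighbor_candidates(x, y, x, y, radius)
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
  tibble(x = x, y = y, w = w, root = root) |>
    group_by(.data$root) |>
    summarise(xm = sum(.data$x * .data$w) / sum(.data$w),
              ym = sum(.data$y * .data$w) / sum(.data$w),
              wm = sum(.data$w), .groups = "drop") |>
    transmute(x = .data$xm, y = .data$ym, w = .data$wm)
}

# Evaluate a seeded expression without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

random_dna <- function(n_bases) {
  paste(sample(DNA_BASES, n_bases, replace = TRUE), collapse = "")
}

round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)
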