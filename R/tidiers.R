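#' Tidy a cluster template
#'
#' @param x An `fc_template`.
#' @param ... Unused.
#' @return Tibble of template positions (`position_id`, `x`, `y`).
#' @export
tidy.fc_template <- function(x, ...) {
  pos <- x$positions
  tibble(position_id = seq_len(nrow(pos)), x = pos$x, y = pos$y)
}

#' One-row summary of a cluster template
#'
#' @param x An `fc_template`.
#' @param ... Unused.
#' @return Tibble with position count, golden/silver cycles and the spot
#'   counts they were chosen from.
#' @export
glance.fc_template <- function(x, ...) {
  tibble(
    n_positions = nrow(x$positions),
    golden_cycle = x$golden_cycle,
    silver_cycle = x$silver_cycle,
    template_cycle_count = x$cfg$template_cycle_count,
    first_template_cycle = x$cfg$first_template_cycle,
    max_spot_count = max(x$per_cycle_spot_counts),
    min_spot_count = min(x$per_cycle_spot_counts)
  )
}

#' Tidy a bleeding estimate
#'
#' @param x A `bleeding_estimate` from [cross_map()].
#' @param ... Unused.
#' @return One-row tibble with counts, observed and expected rates and the
#'   obs/exp ratio.
#' @export
tidy.bleeding_estimate <- function(x, ...) {
  tibble(n_cross = x$n_cross, n_total = x$n_total,
         observed = x$observed, expected = x$expected, ratio = x$ratio)
}

#' @rdname tidy.bleeding_estimate
#' @export
glance.bleeding_estimate <- function(x, ...) {
  tidy(x)
}
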