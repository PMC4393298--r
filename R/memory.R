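#' Memory model for template generation
#'
#' Template generation must hold all channel images of every template cycle in
#' RAM at once, so memory scales linearly with the template length. The model
#' describes one cycle's image payload per surface per swath.
#'
#' @param image_width_px,image_height_px Image dimensions in pixels (defaults:
#'   the full-swath 2048 x 160000 geometry of a HiSeq-class instrument).
#' @param bytes_per_pixel Bytes per pixel (2 for 16-bit grayscale).
#' @param channels_per_cycle Images per cycle (4, one per base).
#' @return A `memory_model` object; its `gb_per_template_cycle` field is the
#'   decimal-GB payload of one template cycle.
#' @export
#' @examples
#' memory_model()$gb_per_template_cycle
memory_model <- function(image_width_px = 2048L,
                         image_height_px = 160000L,
                         bytes_per_pixel = 2L,
                         channels_per_cycle = 4L) {
  if (image_width_px <= 0 || image_height_px <= 0 ||
      bytes_per_pixel <= 0 || channels_per_cycle <= 0) {
    abort("all memory model fields must be positive",
          class = "templateseq_config_error")
  }
  bytes <- as.numeric(channels_per_cycle) * image_width_px *
    image_height_px * bytes_per_pixel
  structure(list(image_width_px = image_width_px,
                 image_height_px = image_height_px,
                 bytes_per_pixel = bytes_per_pixel,
                 channels_per_cycle = channels_per_cycle,
                 bytes_per_template_cycle = bytes,
                 gb_per_template_cycle = bytes / 1e9),
            class = "memory_model")
}

#' @export
print.memory_model <- function(x, ...) {
  cat(sprintf("<memory_model> %d x %d px, %d channels, %d B/px: %.3f GB/cycle\n",
              x$image_width_px, x$image_height_px, x$channels_per_cycle,
              x$bytes_per_pixel, x$gb_per_template_cycle))
  invisible(x)
}

#' Memory required to generate a template of a given length
#'
#' Linear scaling: per-cycle bytes times the number of template cycles.
#' Gigabytes are decimal (1 GB = 1e9 bytes), matching the convention used in
#' instrument documentation.
#'
#' @param model A [memory_model()].
#' @param template_cycle_count Template length in cycles.
#' @return List with `bytes` and `gb`.
#' @export
#' @examples
#' estimate_template_memory(memory_model(), 4)$gb
estimate_template_memory <- function(model, template_cycle_count) {
  stopifnot(inherits(model, "memory_model"), template_cycle_count >= 0)
  bytes <- model$bytes_per_template_cycle * template_cycle_count
  list(bytes = bytes, gb = bytes / 1e9)
}

#' Longest template that fits in a given amount of RAM
#'
#' With memory scaling at about `gb_per_cycle` decimal GB per template cycle,
#' the longest feasible template is `floor(ram_gb / gb_per_cycle)`.
#'
#' @param ram_gb Available RAM in decimal GB.
#' @param gb_per_cycle Memory per template cycle in decimal GB (the empirical
#'   rule of thumb is about 4 GB per cycle).
#' @return Integer template length.
#' @export
#' @examples
#' max_template_length(48, 4)
#' max_template_length(192, 4)
max_template_length <- function(ram_gb, gb_per_cycle = 4) {
  if (ram_gb <= 0 || gb_per_cycle <= 0) {
    abort("ram_gb and gb_per_cycle must be positive",
          class = "templateseq_config_error")
  }
  as.integer(floor(ram_gb / gb_per_cycle))
}
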