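#' Wrap phase values into the principal interval
#'
#' Elementwise 2*pi-modulation: maps any finite phase to `[-pi, pi)` via
#' `((v + pi) mod 2*pi) - pi`. The interval is half-open, so `wrap_phase(pi)`
#' is `-pi`. This operator is applied after every arithmetic step that can
#' push a wrapped phase image out of range (resizing, rotation, bias).
#'
#' @param values Numeric vector, matrix or array of phases in radians.
#' @return Object of the same shape with all values in `[-pi, pi)`.
#' @examples
#' wrap_phase(c(0, pi, 2.5 * pi))
#' @export
wrap_phase <- function(values) {
  if (!all(is.finite(values))) {
    stop("wrap_phase: non-finite values", call. = FALSE)
  }
  ((values + pi) %% (2 * pi)) - pi
}

#' Wrapped quantitative phase image (WQPI)
#'
#' A 2D phase map confined to `[-pi, pi)` radians, optionally carrying a
#' class label and the pixel pitch it was reconstructed at. This is the
#' atomic record of the pipeline: reconstruction produces one per field of
#' view, segmentation produces one per object, and augmentation consumes
#' and produces them.
#'
#' @param phase Numeric matrix of wrapped phases in radians.
#' @param class_id Optional integer class label (`NA` when unassigned).
#' @param pixel_pitch Pixel pitch in metres (`NA` if unknown).
#' @return An object of class `wqpi`.
#' @export
wqpi <- function(phase, class_id = NA_integer_, pixel_pitch = NA_real_) {
  stopifnot(is.matrix(phase), is.numeric(phase))
  if (any(!is.finite(phase))) stop("wqpi: non-finite phase", call. = FALSE)
  if (any(phase < -pi | phase >= pi)) {
    stop("wqpi: phase values outside [-pi, pi); apply wrap_phase() first",
         call. = FALSE)
  }
  structure(list(phase = phase, class_id = as.integer(class_id),
                 pixel_pitch = pixel_pitch),
            class = "wqpi")
}

#' @export
print.wqpi <- function(x, ...) {
  cat(sprintf("<wqpi> %d x %d px%s\n", nrow(x$phase), ncol(x$phase),
              if (is.na(x$class_id)) "" else
                sprintf(", class %d", x$class_id)))
  invisible(x)
}

#' Write / read a WQPI as float TIFF
#'
#' Phase in `[-pi, pi)` maps linearly onto `[0, 1)` for storage; reading
#' inverts the map. An optional 8-bit PNG-style export for classifier
#' consumption is handled by the augmentation writer.
#'
#' @param x A [wqpi()].
#' @param path TIFF path.
#' @param class_id,pixel_pitch Metadata to attach on read.
#' @return `write_wqpi()` returns `path` invisibly; `read_wqpi()` a `wqpi`.
#' @export
write_wqpi <- function(x, path) {
  stopifnot(inherits(x, "wqpi"))
  tiff::writeTIFF((x$phase + pi) / (2 * pi), path, bits.per.sample = 32L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_wqpi
#' @export
read_wqpi <- function(path, class_id = NA_integer_, pixel_pitch = NA_real_) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  wqpi(wrap_phase(m * 2 * pi - pi), class_id = class_id,
       pixel_pitch = pixel_pitch)
}

#' Display a wrapped phase image
#'
#' @param object A [wqpi()].
#' @param ... Unused.
#' @return A ggplot object mapping wrapped phase to a cyclic-ish fill scale.
#' @export
autoplot.wqpi <- function(object, ...) {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(object$phase)), times = ncol(object$phase)),
    col = rep(seq_len(ncol(object$phase)), each = nrow(object$phase)),
    phase = as.vector(object$phase)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$phase)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradientn(
      colours = c("#2c115f", "#51c56a", "#fde725", "#2c115f"),
      limits = c(-pi, pi), name = "phase (rad)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
}
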