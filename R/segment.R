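#' Otsu threshold of an image
#'
#' Builds a 256-bin histogram spanning the image's value range and returns
#' the bin edge maximizing the between-class variance
#' `w0 w1 (mu0 - mu1)^2` of the induced two-class split — Otsu's criterion.
#'
#' @param image Numeric matrix or vector with at least two distinct values.
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold (a value strictly inside the image's range);
#'   pixels `> threshold` form the foreground.
#' @examples
#' otsu_threshold(c(rep(0, 50), rep(10, 50)))
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  v <- sort(as.numeric(image))
  n <- length(v)
  lo <- v[1]; hi <- v[n]
  if (!(hi > lo)) stop("otsu_threshold: constant image", call. = FALSE)
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  cand <- edges[2:n_bins]            # interior bin edges as candidate cuts
  cs <- cumsum(v)
  i0 <- findInterval(cand, v)        # pixels <= candidate edge
  valid <- i0 > 0L & i0 < n
  w0 <- i0 / n
  mu0 <- cs[pmax(i0, 1L)] / pmax(i0, 1L)
  mu1 <- (cs[n] - cs[pmax(i0, 1L)]) / pmax(n - i0, 1L)
  sigma_b <- ifelse(valid, w0 * (1 - w0) * (mu0 - mu1)^2, -Inf)
  cand[which.max(sigma_b)]
}

# Fill interior holes of a binary mask (EBImage::fillHull).
fill_holes <- function(mask) {
  filled <- EBImage::fillHull(matrix(as.numeric(mask), nrow(mask),
                                     ncol(mask)))
  filled > 0.5
}

# 8-connected component labeling. EBImage::bwlabel is 4-connected, so
# labels that touch diagonally are merged afterwards with a union-find
# pass over the label adjacency pairs.
label_components <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  ny <- nrow(lab); nx <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-ny, -nx]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -nx]), as.vector(lab[-ny, -1]))    # up-right
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}

#' Segment individual objects from a full-field WQPI
#'
#' Thresholds the absolute wrapped phase with [otsu_threshold()], closes
#' the binary map with a small disc, fills interior holes, labels
#' 8-connected components, discards those smaller than `min_area_px`, and
#' crops each survivor with `pad_px` pixels of zero-phase padding. Objects
#' come back sorted by bounding-box position (`row0`, then `col0`) —
#' reading order on the slide.
#'
#' Both the closing and the filling deal with phase wrapping: wherever the
#' object's phase passes through a multiple of 2*pi, the wrapped map dips
#' to zero, producing below-threshold rings (holes — filled) and, when a
#' wrap contour crosses the whole object, open bands that split the mask
#' (bridged by the closing).
#'
#' @param full_wqpi A [wqpi()] covering the whole field of view.
#' @param min_area_px Minimum component area in pixels (default 100).
#' @param pad_px Zero-phase padding around each crop (default 8).
#' @param close_px Diameter in pixels of the disc used for binary closing
#'   (default 5; 0 disables closing). Must stay below the smallest gap
#'   between distinct objects.
#' @return A list of `segmented_object`s, each with `mask` (crop-local
#'   logical matrix), `bbox` (`row0, col0, row1, col1`, half-open, in
#'   global 0-based coordinates), `wqpi_crop`, `area_px`,
#'   `centroid` (global row/col) and `class_id` (`NA` until assigned).
#'   Empty list when nothing survives.
#' @export
segment_slide <- function(full_wqpi, min_area_px = 100L, pad_px = 8L,
                          close_px = 5L) {
  stopifnot(inherits(full_wqpi, "wqpi"), min_area_px >= 1, pad_px >= 0)
  mag <- abs(full_wqpi$phase)
  if (max(mag) == min(mag)) return(list())
  thr <- otsu_threshold(mag)
  mask <- mag > thr
  if (!any(mask)) return(list())
  if (close_px > 0) {
    kern <- EBImage::makeBrush(as.integer(close_px), shape = "disc")
    mask <- EBImage::closing(matrix(as.numeric(mask), nrow(mask),
                                    ncol(mask)), kern) > 0.5
  }
  mask <- fill_holes(mask)
  lab <- label_components(mask)
  n <- max(lab)
  if (n == 0L) return(list())
  objs <- list()
  for (k in seq_len(n)) {
    idx <- which(lab == k, arr.ind = TRUE)
    area <- nrow(idx)
    if (area < min_area_px) next
    r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
    hr <- (r1 - r0 + 1L) + 2L * pad_px
    hc <- (c1 - c0 + 1L) + 2L * pad_px
    crop_phase <- matrix(0, hr, hc)
    crop_mask <- matrix(FALSE, hr, hc)
    local_r <- idx[, 1] - r0 + 1L + pad_px
    local_c <- idx[, 2] - c0 + 1L + pad_px
    crop_mask[cbind(local_r, local_c)] <- TRUE
    crop_phase[cbind(local_r, local_c)] <-
      full_wqpi$phase[cbind(idx[, 1], idx[, 2])]
    objs[[length(objs) + 1L]] <- structure(
      list(mask = crop_mask,
           bbox = c(row0 = r0 - 1L - pad_px, col0 = c0 - 1L - pad_px,
                    row1 = r1 + pad_px, col1 = c1 + pad_px),
           wqpi_crop = wqpi(crop_phase,
                            pixel_pitch = full_wqpi$pixel_pitch),
           area_px = area,
           centroid = c(row = mean(idx[, 1]), col = mean(idx[, 2])),
           class_id = NA_integer_),
      class = "segmented_object")
  }
  if (length(objs) == 0L) return(objs)
  ord <- order(vapply(objs, function(o) o$bbox[["row0"]], numeric(1)),
               vapply(objs, function(o) o$bbox[["col0"]], numeric(1)))
  objs[ord]
}

#' @export
print.segmented_object <- function(x, ...) {
  cat(sprintf("<segmented_object> area %d px, bbox [%d,%d)x[%d,%d)%s\n",
              x$area_px, x$bbox[["row0"]], x$bbox[["row1"]],
              x$bbox[["col0"]], x$bbox[["col1"]],
              if (is.na(x$class_id)) "" else
                sprintf(", class %d", x$class_id)))
  invisible(x)
}

#' Assign class labels to segmented objects
#'
#' With ground truth available (a [make_phantom_slide()] result), performs
#' a one-to-one greedy nearest-centroid assignment between segmented
#' objects and the slide's true objects. Without ground truth, labels
#' follow slide-layout (reading) order `1..n`, the convention used to
#' number species on a physical test slide.
#'
#' @param objects List of `segmented_object`s from [segment_slide()].
#' @param slide Optional `phantom_slide` providing true centroids/classes.
#' @return The list with `class_id` filled in on each object.
#' @export
assign_classes <- function(objects, slide = NULL) {
  if (length(objects) == 0L) return(objects)
  if (is.null(slide)) {
    for (i in seq_along(objects)) objects[[i]]$class_id <- i
    return(objects)
  }
  truth <- slide$objects
  d <- outer(seq_along(objects), seq_len(nrow(truth)),
             Vectorize(function(i, j) {
               sqrt((objects[[i]]$centroid[["row"]] - truth$centroid_row[j])^2 +
                    (objects[[i]]$centroid[["col"]] - truth$centroid_col[j])^2)
             }))
  used_o <- rep(FALSE, length(objects)); used_t <- rep(FALSE, nrow(truth))
  for (step in seq_len(min(length(objects), nrow(truth)))) {
    d_open <- d
    d_open[used_o, ] <- Inf; d_open[, used_t] <- Inf
    ij <- arrayInd(which.min(d_open), dim(d))
    objects[[ij[1]]]$class_id <- truth$class_id[ij[2]]
    objects[[ij[1]]]$centroid_error_px <- d[ij[1], ij[2]]
    used_o[ij[1]] <- TRUE; used_t[ij[2]] <- TRUE
  }
  objects
}

#' Tabulate a segmentation
#'
#' @param objects List of `segmented_object`s.
#' @return A tibble with one row per object: class id, bbox, area,
#'   centroid.
#' @export
segmentation_manifest <- function(objects) {
  tibble::tibble(
    class_id = vapply(objects, function(o) o$class_id, integer(1)),
    row0 = vapply(objects, function(o) o$bbox[["row0"]], numeric(1)),
    col0 = vapply(objects, function(o) o$bbox[["col0"]], numeric(1)),
    row1 = vapply(objects, function(o) o$bbox[["row1"]], numeric(1)),
    col1 = vapply(objects, function(o) o$bbox[["col1"]], numeric(1)),
    area_px = vapply(objects, function(o) o$area_px, integer(1)),
    centroid_row = vapply(objects, function(o) o$centroid[["row"]],
                          numeric(1)),
    centroid_col = vapply(objects, function(o) o$centroid[["col"]],
                          numeric(1))
  )
}

#' Write segmented objects to a directory
#'
#' One float TIFF per object named `class_NN.tif` plus a `manifest.csv`
#' (class id, bbox, area, centroid).
#'
#' @param objects List of `segmented_object`s (class ids assigned).
#' @param dir Output directory (created if missing).
#' @return The manifest tibble, invisibly.
#' @export
write_segmentation <- function(objects, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- segmentation_manifest(objects)
  man$path <- file.path(dir, sprintf("class_%02d.tif", man$class_id))
  for (i in seq_along(objects)) {
    write_wqpi(objects[[i]]$wqpi_crop, man$path[i])
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
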