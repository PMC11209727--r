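# Crop geometry: pod-centred training crops, fixed-stride inference
# tiling, coordinate remapping, and the split-before-crop protocol.
# Windows are always exactly crop_size x crop_size; at image borders the
# window is shifted inward, never shrunk or padded, because the model
# input size is fixed.

#' Fixed-stride tiling of an image
#'
#' Produces the row-major grid of `crop_size`-square windows at the
#' given stride; the final row/column is shifted inward so that no
#' window exceeds the image, and every pixel is covered by at least one
#' window. Images smaller than `crop_size` yield a single window equal
#' to the image, with a warning.
#'
#' @param width,height Image size in pixels.
#' @param crop_size Window side length, px (default 400).
#' @param stride Grid stride, px (default 300, i.e. 100 px overlap);
#'   must not exceed `crop_size`.
#' @return Tibble of windows: `window`, `x_min`, `y_min`, `x_max`,
#'   `y_max`.
#' @export
tile_image <- function(width, height, crop_size = 400, stride = 300) {
  stopifnot(stride > 0, crop_size > 0)
  if (stride > crop_size) abort("`stride` must not exceed `crop_size`.")
  if (width < crop_size || height < crop_size) {
    warn(sprintf(
      "Image (%g x %g) smaller than crop_size %g: using a single full-image window.",
      width, height, crop_size))
    return(tibble(window = "w001", x_min = 0, y_min = 0,
                  x_max = width, y_max = height))
  }
  axis_starts <- function(extent) {
    s <- seq(0, extent - crop_size, by = stride)
    if (max(s) < extent - crop_size) s <- c(s, extent - crop_size)
    s
  }
  xs <- axis_starts(width)
  ys <- axis_starts(height)
  grid <- tidyr::expand_grid(y_min = ys, x_min = xs)
  tibble(
    window = sprintf("w%03d", seq_len(nrow(grid))),
    x_min = grid$x_min, y_min = grid$y_min,
    x_max = grid$x_min + crop_size, y_max = grid$y_min + crop_size
  )
}

#' Sample a pod-centred training crop
#'
#' Draws a `crop_size`-square window that fully contains the chosen
#' pod: the window is the pod's minimum bounding rectangle expanded in
#' all four directions, with the horizontal and vertical slack each
#' split uniformly at random between the two sides, then shifted inward
#' if it would leave the image. All pods with at least one seed inside
#' the window are remapped to window coordinates; their out-of-window
#' seeds are dropped and such pods flagged truncated.
#'
#' @param ann A [pod_annotation()].
#' @param pod_id Which pod to centre on.
#' @param crop_size Window side length, px (default 400).
#' @return List with `window` (one-row tibble as in [tile_image()]) and
#'   `annotation` (remapped [pod_annotation()] in window coordinates).
#' @export
sample_pod_crop <- function(ann, pod_id, crop_size = 400) {
  stopifnot(inherits(ann, "pod_annotation"))
  seeds <- ann$seeds[ann$seeds$pod_id == pod_id, , drop = FALSE]
  if (nrow(seeds) == 0) abort(sprintf("Pod %s not found.", pod_id))
  box <- pod_bounding_box(seeds)
  bw <- box$x_max - box$x_min
  bh <- box$y_max - box$y_min
  if (bw > crop_size || bh > crop_size) {
    abort(sprintf("Pod %s bounding box (%.0f x %.0f) exceeds crop_size %g.",
                  pod_id, bw, bh, crop_size))
  }
  left <- runif(1, 0, crop_size - bw)
  top <- runif(1, 0, crop_size - bh)
  x0 <- box$x_min - left
  y0 <- box$y_min - top
  # shift inward, never shrink
  x0 <- min(max(x0, 0), max(0, ann$width - crop_size))
  y0 <- min(max(y0, 0), max(0, ann$height - crop_size))
  window <- tibble(window = sprintf("pod%s", pod_id),
                   x_min = x0, y_min = y0,
                   x_max = x0 + crop_size, y_max = y0 + crop_size)
  list(window = window,
       annotation = crop_annotation(ann, window))
}

#' Remap an annotation into a crop window
#'
#' Keeps every pod with at least one seed inside the window, translates
#' coordinates to the window frame, drops out-of-window seeds and flags
#' the affected pods truncated (their declared `n_seeds` is kept - the
#' missing seeds are treated as sealed).
#'
#' @param ann A [pod_annotation()].
#' @param window One-row window tibble (`x_min`, `y_min`, `x_max`,
#'   `y_max`).
#' @return A [pod_annotation()] in window coordinates.
#' @export
crop_annotation <- function(ann, window) {
  stopifnot(inherits(ann, "pod_annotation"), nrow(window) == 1)
  s <- ann$seeds
  inside <- s$x >= window$x_min & s$x < window$x_max &
    s$y >= window$y_min & s$y < window$y_max
  s <- s[inside, , drop = FALSE]
  s$x <- s$x - window$x_min
  s$y <- s$y - window$y_min
  pod_annotation(s, image_id = paste0(ann$image_id, "/", window$window),
                 width = window$x_max - window$x_min,
                 height = window$y_max - window$y_min)
}

#' Crop an image raster to a window
#'
#' @param image Height x width numeric matrix.
#' @param window One-row window tibble.
#' @return The cropped matrix.
#' @export
crop_image <- function(image, window) {
  rows <- (floor(window$y_min) + 1):floor(window$y_max)
  cols <- (floor(window$x_min) + 1):floor(window$x_max)
  image[rows, cols, drop = FALSE]
}

#' Remap window-frame detections to the full-image frame
#'
#' Translates detection coordinates by the window origin; scores are
#' unchanged and the source window id is recorded for the merging step.
#'
#' @param dets Detections tibble in window coordinates.
#' @param window One-row window tibble.
#' @return Detections tibble in full-image coordinates with a `window`
#'   column.
#' @export
remap_to_full <- function(dets, window) {
  stopifnot(nrow(window) == 1)
  dets <- as_detections(dets)
  dets$x <- dets$x + window$x_min
  dets$y <- dets$y + window$y_min
  dets$window <- window$window
  dets
}

#' Inverse of [remap_to_full()]
#'
#' @inheritParams remap_to_full
#' @return Detections tibble in window coordinates.
#' @export
remap_to_window <- function(dets, window) {
  stopifnot(nrow(window) == 1)
  dets <- as_detections(dets)
  dets$x <- dets$x - window$x_min
  dets$y <- dets$y - window$y_min
  dets
}

#' Plant-level train/test split
#'
#' Partitions whole-plant images into training and testing sets before
#' any cropping, so that no pod can appear on both sides of the split.
#'
#' @param image_ids Character vector of plant image identifiers.
#' @param test_fraction Fraction of plants assigned to the test set,
#'   in (0, 1).
#' @param rng_seed Integer seed; the split is deterministic given it.
#' @return List with character vectors `train` and `test`.
#' @export
split_plants <- function(image_ids, test_fraction = 0.2, rng_seed = 1L) {
  if (!(test_fraction > 0 && test_fraction < 1)) {
    abort("`test_fraction` must lie strictly between 0 and 1.")
  }
  image_ids <- unique(as.character(image_ids))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(rng_seed)
  n_test <- max(1, round(test_fraction * length(image_ids)))
  test <- sort(sample(image_ids, n_test))
  list(train = setdiff(image_ids, test), test = test)
}
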