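# Prediction-tensor layout and ground-truth target rendering.
#
# The output grid has K = 5 seed-type heatmap channels plus one
# background channel (6 heatmaps), and a 10-channel offset field: at a
# supervised cell, slots (2k-1, 2k) hold the displacement (in output
# cells) from the cell centre to the pod's k-th seed. Pods with n < 5
# seeds have slots n+1..5 "sealed": masked out of supervision.

#' Construct prediction tensors
#'
#' @param heatmaps `H' x W' x 6` array (channels 1-5 seed types,
#'   channel 6 background).
#' @param offsets `H' x W' x 10` array.
#' @param stride Input-to-output ratio.
#' @return A list of class `prediction_tensors`.
#' @export
prediction_tensors <- function(heatmaps, offsets, stride = 4) {
  stopifnot(length(dim(heatmaps)) == 3, dim(heatmaps)[3] == 6,
            length(dim(offsets)) == 3, dim(offsets)[3] == 10,
            all(dim(heatmaps)[1:2] == dim(offsets)[1:2]),
            all(is.finite(heatmaps)), all(is.finite(offsets)))
  structure(list(heatmaps = heatmaps, offsets = offsets, stride = stride),
            class = "prediction_tensors")
}

#' Render ground-truth target tensors for an annotation
#'
#' Each seed splats a Gaussian peak (SD `gaussian_sd`, in output cells)
#' on its type channel, max-combined where pods overlap; the background
#' channel is one minus the max over type channels. Offset targets are
#' written at every cell within a per-pod radius of the pod centre (the
#' centroid of its present seeds); the radius adapts to the pod extent
#' (max centre-to-seed distance plus `offset_radius`) so the supervised
#' disk covers the pod's own seed peaks, where decoding later reads
#' candidate offsets. Cells claimed by several pods go to the nearest
#' centre. Offset-mask entries are `1 / Z` for supervised slots (`Z` the
#' pod scale in cells, normalising the regression loss per pod size),
#' and 0 for sealed slots (beyond the pod's seed count, or seeds missing
#' from a truncated pod).
#'
#' @param ann A [pod_annotation()].
#' @param stride Input-to-output ratio (default 4).
#' @param gaussian_sd Peak SD in output cells.
#' @param offset_radius Margin added to each pod's supervision radius,
#'   cells.
#' @param heat_pos_weight Extra weight on positive heatmap cells:
#'   `heat_weights = 1 + heat_pos_weight * target` on type channels
#'   (background gets weight 1). Peaks are sparse, so training needs
#'   the up-weighting; set 0 for uniform weights.
#' @return A list of class `target_tensors`: `heatmaps`, `offsets`,
#'   `heat_weights`, `offset_mask`, `stride`.
#' @export
render_targets <- function(ann, stride = 4, gaussian_sd = 2,
                           offset_radius = 4, heat_pos_weight = 25) {
  stopifnot(inherits(ann, "pod_annotation"))
  Hp <- ceiling(ann$height / stride)
  Wp <- ceiling(ann$width / stride)
  heat <- array(0, dim = c(Hp, Wp, 6))
  offs <- array(0, dim = c(Hp, Wp, 10))
  mask <- array(0, dim = c(Hp, Wp, 10))

  seeds <- ann$seeds
  # type-channel peaks
  if (nrow(seeds) > 0) {
    for (i in seq_len(nrow(seeds))) {
      k <- seeds$seed_index[i]
      u <- seeds$x[i] / stride
      v <- seeds$y[i] / stride
      r <- ceiling(3 * gaussian_sd)
      cols <- max(1, floor(u) - r + 1):min(Wp, floor(u) + r + 1)
      rows <- max(1, floor(v) - r + 1):min(Hp, floor(v) + r + 1)
      g <- exp(-outer((rows - 0.5 - v)^2, (cols - 0.5 - u)^2, "+") /
                 (2 * gaussian_sd^2))
      heat[rows, cols, k] <- pmax(heat[rows, cols, k], g)
    }
  }
  heat[, , 6] <- 1 - apply(heat[, , 1:5, drop = FALSE], c(1, 2), max)

  # up-weight every type channel over the whole blob support (the max
  # across type channels), not just its own positives: otherwise a
  # false peak on the wrong ordinal's channel costs far less than a
  # missed peak and the channels collapse to generic blob detectors
  hw <- array(1, dim = dim(heat))
  blob <- apply(heat[, , 1:5, drop = FALSE], c(1, 2), max)
  for (k in 1:5) hw[, , k] <- 1 + heat_pos_weight * blob

  # offset field: each pod supervises the cells within offset_radius of
  # any of its seeds or of its centroid (candidates later arise at seed
  # peaks, so every candidate cell must carry its own pod's offsets);
  # contested cells go to the pod with the nearest anchor
  if (nrow(seeds) > 0) {
    best <- matrix(Inf, Hp, Wp)
    for (pid in unique(seeds$pod_id)) {
      s <- seeds[seeds$pod_id == pid, , drop = FALSE]
      u <- s$x / stride
      v <- s$y / stride
      anchors_u <- c(u, mean(u))
      anchors_v <- c(v, mean(v))
      span <- pod_bounding_box(s)
      z <- max(1, sqrt((span$x_max - span$x_min) *
                         (span$y_max - span$y_min)) / stride)
      cols <- max(1, floor(min(anchors_u) - offset_radius)):
        min(Wp, ceiling(max(anchors_u) + offset_radius) + 1)
      rows <- max(1, floor(min(anchors_v) - offset_radius)):
        min(Hp, ceiling(max(anchors_v) + offset_radius) + 1)
      for (cc in cols) for (rr in rows) {
        d <- min(sqrt((cc - 0.5 - anchors_u)^2 + (rr - 0.5 - anchors_v)^2))
        if (d > offset_radius || d >= best[rr, cc]) next
        best[rr, cc] <- d
        offs[rr, cc, ] <- 0
        mask[rr, cc, ] <- 0
        for (j in seq_len(nrow(s))) {
          k <- s$seed_index[j]
          offs[rr, cc, 2 * k - 1] <- u[j] - (cc - 0.5)
          offs[rr, cc, 2 * k] <- v[j] - (rr - 0.5)
          mask[rr, cc, 2 * k - 1] <- 1 / z
          mask[rr, cc, 2 * k] <- 1 / z
        }
      }
    }
  }
  structure(list(heatmaps = heat, offsets = offs, heat_weights = hw,
                 offset_mask = mask, stride = stride),
            class = "target_tensors")
}
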