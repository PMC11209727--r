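# The structural-prior branch: per-seed channel vectors are sampled
# from a feature map, their pairwise cosine-similarity matrix A is
# compared against the binary same-pod matrix A' with an L2 loss. The
# prior is a training-time-only term; inference never evaluates it.

#' Construct a feature map
#'
#' @param values `H x W x C` numeric array of features.
#' @param stride Image pixels per feature cell (input-to-feature ratio).
#' @return A list of class `feature_map` with elements `values` and
#'   `stride`.
#' @export
feature_map <- function(values, stride = 1) {
  if (!(is.array(values) && length(dim(values)) == 3)) {
    abort("`values` must be an H x W x C array.")
  }
  if (!all(is.finite(values))) abort("Feature values must be finite.")
  stopifnot(stride > 0)
  structure(list(values = values, stride = stride), class = "feature_map")
}

#' Extract per-seed point vectors from a feature map
#'
#' Maps each seed's image coordinates to the feature grid by dividing by
#' the stride and reads the full C-channel vector at that cell
#' (nearest-cell lookup by default; set `bilinear = TRUE` for bilinear
#' interpolation between the four neighbouring cells). Seeds mapping
#' outside the grid are clamped to the nearest cell with a warning.
#'
#' @param fmap A [feature_map()].
#' @param seeds Tibble with columns `x`, `y`, `pod_id` (image-frame
#'   coordinates), e.g. the `seeds` slot of a [pod_annotation()].
#' @param bilinear Use bilinear sampling instead of nearest-cell.
#' @return A list of class `point_vectors`: `vectors` (`N x C` matrix)
#'   and `membership` (length-N pod ids).
#' @export
extract_point_vectors <- function(fmap, seeds, bilinear = FALSE) {
  stopifnot(inherits(fmap, "feature_map"))
  seeds <- as_tibble(seeds)
  H <- dim(fmap$values)[1]; W <- dim(fmap$values)[2]; C <- dim(fmap$values)[3]
  n <- nrow(seeds)
  V <- matrix(0, nrow = n, ncol = C)
  u <- seeds$x / fmap$stride
  v <- seeds$y / fmap$stride
  if (any(u < 0 | u >= W | v < 0 | v >= H)) {
    warn("Some seeds map outside the feature grid; clamping to nearest cell.")
  }
  if (!bilinear) {
    cc <- pmin(pmax(floor(u) + 1, 1), W)
    rr <- pmin(pmax(floor(v) + 1, 1), H)
    for (i in seq_len(n)) V[i, ] <- fmap$values[rr[i], cc[i], ]
  } else {
    # cell centres at (c - 0.5, r - 0.5) in grid units
    uc <- pmin(pmax(u - 0.5, 0), W - 1)
    vc <- pmin(pmax(v - 0.5, 0), H - 1)
    c0 <- pmin(floor(uc) + 1, W - 1); r0 <- pmin(floor(vc) + 1, H - 1)
    fx <- uc - (c0 - 1); fy <- vc - (r0 - 1)
    for (i in seq_len(n)) {
      V[i, ] <-
        (1 - fx[i]) * (1 - fy[i]) * fmap$values[r0[i], c0[i], ] +
        fx[i] * (1 - fy[i]) * fmap$values[r0[i], c0[i] + 1, ] +
        (1 - fx[i]) * fy[i] * fmap$values[r0[i] + 1, c0[i], ] +
        fx[i] * fy[i] * fmap$values[r0[i] + 1, c0[i] + 1, ]
    }
  }
  structure(list(vectors = V, membership = seeds$pod_id),
            class = "point_vectors")
}

#' Cosine-affinity matrix of point vectors
#'
#' `A[i, j] = v_i . v_j / (||v_i|| ||v_j|| + eps)`; the small `eps`
#' makes the cosine of a zero vector well-defined (0) rather than NaN.
#'
#' @param V A `point_vectors` object or an `N x C` matrix.
#' @param eps Norm-product guard (default 1e-8).
#' @return Symmetric `N x N` matrix with entries in `[-1, 1]`.
#' @export
cosine_affinity <- function(V, eps = 1e-8) {
  M <- if (inherits(V, "point_vectors")) V$vectors else as.matrix(V)
  if (nrow(M) < 1) abort("Need at least one vector.")
  nrm <- sqrt(rowSums(M^2))
  G <- M %*% t(M)
  A <- G / (outer(nrm, nrm) + eps)
  (A + t(A)) / 2
}

#' Structural-prior target matrix
#'
#' The binary same-pod matrix: `A'[i, j] = 1` iff seeds i and j belong
#' to the same pod (so the diagonal is 1). It is the block-diagonal
#' indicator of the pod partition - a valid equivalence relation.
#'
#' @param membership Length-N vector of pod ids (or a `point_vectors`
#'   object).
#' @return `N x N` binary matrix.
#' @export
sprior_target <- function(membership) {
  if (inherits(membership, "point_vectors")) {
    membership <- membership$membership
  }
  if (length(membership) < 1) abort("Need at least one seed.")
  outer(membership, membership, "==") * 1
}

#' Structural-prior loss
#'
#' Squared Frobenius norm of `A - A'` (sum of squared entrywise
#' differences), without normalisation by N^2. Set `normalize = TRUE`
#' to divide by the number of entries, giving a scale-stable variant
#' for training.
#'
#' @param A Cosine-affinity matrix.
#' @param target Structural-prior target matrix of the same shape.
#' @param normalize Divide by `length(A)`.
#' @return Non-negative scalar; 0 iff `A == target`.
#' @export
sprior_loss <- function(A, target, normalize = FALSE) {
  if (!all(dim(A) == dim(target))) {
    abort("`A` and `target` must have identical shapes.")
  }
  l <- sum((A - target)^2)
  if (normalize) l <- l / length(A)
  l
}

smooth_l1 <- function(x, beta = 1) {
  a <- abs(x)
  q <- pmin(a, beta)
  0.5 * q^2 / beta + (a - q)
}

#' Detection losses: weighted heatmap loss, offset regression loss
#'
#' `l_heatmaps` is the weighted entrywise squared-error norm between
#' predicted and target heatmaps. `l_p` is a smooth-L1 loss on the
#' offset field, evaluated only where `offset_mask` is non-zero
#' (sealed seed slots and cells far from any pod are masked out) and
#' normalised by the number of active entries; mask values other than
#' 1 act as per-entry weights, which is how per-pod scale normalisation
#' is applied. The combined loss is `l_heatmaps + gamma * l_p` with the
#' trade-off weight `gamma` defaulting to 0.03.
#'
#' @param heatmap_pred,heatmap_true Arrays of identical shape.
#' @param heat_weights Per-entry heatmap weights (same shape; use 1 for
#'   uniform weighting).
#' @param offsets_pred,offsets_true Offset arrays of identical shape.
#' @param offset_mask Non-negative per-entry weights, 0 where
#'   unsupervised.
#' @param gamma Offset-loss trade-off weight.
#' @param beta Smooth-L1 knee.
#' @return List with `l_heatmaps`, `l_p`, `combined`.
#' @export
dekr_loss <- function(heatmap_pred, heatmap_true, heat_weights = 1,
                      offsets_pred, offsets_true, offset_mask,
                      gamma = 0.03, beta = 1) {
  stopifnot(all(dim(heatmap_pred) == dim(heatmap_true)),
            all(dim(offsets_pred) == dim(offsets_true)))
  l_heatmaps <- sum(heat_weights * (heatmap_pred - heatmap_true)^2)
  active <- sum(offset_mask > 0)
  l_p <- if (active == 0) 0 else {
    sum(smooth_l1((offsets_pred - offsets_true) * offset_mask,
                  beta = beta)) / active
  }
  list(l_heatmaps = l_heatmaps, l_p = l_p,
       combined = l_heatmaps + gamma * l_p)
}

#' Combined training loss with the structural prior
#'
#' `total = combined_dekr + rho * l_sprior`. The default `rho = 0.2` is
#' the weight at which the prior's benefit peaks in ablation; `rho = 0`
#' recovers the plain detection loss.
#'
#' @param combined_dekr Scalar detection loss (see [dekr_loss()]).
#' @param l_sprior Scalar structural-prior loss (see [sprior_loss()]).
#' @param rho Non-negative prior weight.
#' @return Scalar total loss.
#' @export
total_loss <- function(combined_dekr, l_sprior, rho = 0.2) {
  stopifnot(rho >= 0)
  combined_dekr + rho * l_sprior
}
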