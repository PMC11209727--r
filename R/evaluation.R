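# Object-keypoint-similarity evaluation adapted to pods. The pod
# variant scores the n seeds of a ground-truth pod with a Gaussian
# falloff whose width is the object scale s times the constant k = 2
# sigma, corrected by a per-seed-count area coefficient lambda_n so
# that 1- to 5-seeded pods are scored on an equal footing: lambda_n is
# the mean bounding-box-area ratio of 3-seeded pods to n-seeded pods,
# hence lambda_3 = 1.

#' OKS parameters
#'
#' @param sigma Relative localisation SD; the falloff constant is
#'   `k = 2 * sigma`. The default 0.05 corresponds to careful point
#'   annotation; calibrate on relabelled data with [estimate_sigma()].
#' @param lambda Length-5 area-correction coefficients for 1..5-seeded
#'   pods. The default `c(4.752, 1.353, 1, 0.782, 0.673)` comes from
#'   bounding-box-area ratios measured on annotated plant images;
#'   `lambda[3] = 1` by construction. Re-estimate with
#'   [estimate_lambda()].
#' @return A list of class `oks_params` with `sigma`, `k`, `lambda`.
#' @export
oks_params <- function(sigma = 0.05,
                       lambda = c(4.752, 1.353, 1, 0.782, 0.673)) {
  stopifnot(sigma > 0, length(lambda) == 5, all(lambda > 0))
  structure(list(sigma = sigma, k = 2 * sigma, lambda = lambda),
            class = "oks_params")
}

#' Object scale of a pod
#'
#' The square root of the area of the pod's seed bounding rectangle
#' expanded by `pad` pixels per side (point annotations have no box, so
#' a nominal seed radius supplies the missing extent).
#'
#' @param seeds Seed tibble of one pod (columns `x`, `y`).
#' @param pad Padding per side, px (default 6, a nominal seed radius).
#' @return Positive scalar.
#' @export
pod_scale <- function(seeds, pad = 6) {
  b <- pod_bounding_box(dplyr::mutate(as_tibble(seeds), pod_id = 1), pad = pad)
  sqrt(b$area[1])
}

#' Pod-level object keypoint similarity
#'
#' `OKS_pod = (1/n) * sum_i exp(-d_i^2 / (2 * lambda_n * s^2 * k^2))`
#' over the ground-truth pod's n seeds, with `d_i` the Euclidean error
#' of the prediction for ordinal i. A seed with no predicted coordinate
#' contributes 0 (as if infinitely far), keeping the `1/n`
#' normalisation stable. The value is scale-invariant: rescaling all
#' coordinates and `s` jointly leaves it unchanged.
#'
#' @param pred Predicted seeds: tibble with `seed_index`, `x`, `y`
#'   (extra ordinals beyond the ground truth are ignored).
#' @param gt Ground-truth seeds of one pod: tibble with `seed_index`,
#'   `x`, `y`, `n_seeds`.
#' @param s Object scale (> 0), see [pod_scale()].
#' @param params An [oks_params()].
#' @return Scalar in `[0, 1]`.
#' @export
oks_pod <- function(pred, gt, s, params = oks_params()) {
  if (s <= 0) abort("Object scale `s` must be positive.")
  gt <- as_tibble(gt)
  pred <- as_tibble(pred)
  n <- gt$n_seeds[1] %||% nrow(gt)
  lam <- params$lambda[n]
  denom <- 2 * lam * s^2 * params$k^2
  tot <- 0
  for (i in seq_len(nrow(gt))) {
    k <- gt$seed_index[i]
    j <- which(pred$seed_index == k)
    if (length(j) == 1) {
      d2 <- (pred$x[j] - gt$x[i])^2 + (pred$y[j] - gt$y[i])^2
      tot <- tot + exp(-d2 / denom)
    }
  }
  tot / n
}

#' Original object keypoint similarity
#'
#' The COCO-style formulation with per-keypoint falloff constants and
#' visibility flags: only visible seeds enter, each with its own `k_i`.
#'
#' @param pred,gt Seed tibbles as in [oks_pod()].
#' @param s Object scale.
#' @param k_per_seed Per-ordinal falloff constants (recycled to the
#'   number of ground-truth seeds).
#' @param visibility Integer/logical visibility flags per ground-truth
#'   seed; seeds with flag 0 are ignored.
#' @return Scalar in `[0, 1]`; error if no seed is visible.
#' @export
oks_original <- function(pred, gt, s, k_per_seed = 0.1,
                         visibility = NULL) {
  if (s <= 0) abort("Object scale `s` must be positive.")
  gt <- as_tibble(gt)
  pred <- as_tibble(pred)
  if (is.null(visibility)) visibility <- rep(1L, nrow(gt))
  k_per_seed <- rep_len(k_per_seed, nrow(gt))
  vis <- visibility > 0
  if (!any(vis)) abort("OKS undefined: no visible ground-truth seed.")
  tot <- 0
  for (i in which(vis)) {
    kk <- gt$seed_index[i]
    j <- which(pred$seed_index == kk)
    e <- 0
    if (length(j) == 1) {
      d2 <- (pred$x[j] - gt$x[i])^2 + (pred$y[j] - gt$y[i])^2
      e <- exp(-d2 / (2 * s^2 * k_per_seed[i]^2))
    }
    tot <- tot + e
  }
  tot / sum(vis)
}

#' Estimate the relative annotation error sigma
#'
#' Given refined (carefully relabelled) and original positions of the
#' same seeds, `sigma^2 = E[d^2 / s^2]` with `d` the pairwise distance
#' and `s` the per-image (or per-pod) object scale; the falloff
#' constant follows as `k = 2 * sigma`.
#'
#' @param refined,original Matrices or tibbles of paired positions
#'   (columns `x`, `y`), same number of rows.
#' @param s Object scale per pair (recycled).
#' @return List with `sigma` and `k`.
#' @export
estimate_sigma <- function(refined, original, s) {
  refined <- as.matrix(as_tibble(refined)[, c("x", "y")])
  original <- as.matrix(as_tibble(original)[, c("x", "y")])
  if (nrow(refined) == 0 || nrow(refined) != nrow(original)) {
    abort("`refined` and `original` must be non-empty and paired.")
  }
  s <- rep_len(s, nrow(refined))
  d2 <- rowSums((refined - original)^2)
  sigma <- sqrt(mean(d2 / s^2))
  list(sigma = sigma, k = 2 * sigma)
}

#' Estimate the per-seed-count area coefficients lambda
#'
#' For each n, the mean over images of (mean bounding-box area of
#' 3-seeded pods) / (mean bounding-box area of n-seeded pods), using
#' only images that contain both a 3-seeded and an n-seeded pod.
#' `lambda[3] = 1` identically. Entries with no qualifying image keep
#' the supplied default and are flagged.
#'
#' @param annotations List of [pod_annotation()]s.
#' @param pad Bounding-box padding per side, px (see [pod_scale()]).
#' @param default Fallback coefficients.
#' @return Tibble with columns `n`, `lambda`, `images_used`,
#'   `estimated`.
#' @export
estimate_lambda <- function(annotations, pad = 6,
                            default = c(4.752, 1.353, 1, 0.782, 0.673)) {
  per_image <- purrr::map(annotations, function(ann) {
    seeds <- if (inherits(ann, "pod_annotation")) ann$seeds else as_tibble(ann)
    if (nrow(seeds) == 0) return(NULL)
    pod_bounding_box(seeds, pad = pad) |>
      dplyr::left_join(pods(seeds)[c("pod_id", "n_seeds")], by = "pod_id") |>
      dplyr::summarise(mean_area = mean(.data$area), .by = "n_seeds")
  })
  ratios <- purrr::map(per_image, function(tab) {
    if (is.null(tab) || !3 %in% tab$n_seeds) return(NULL)
    a3 <- tab$mean_area[tab$n_seeds == 3]
    tibble(n = tab$n_seeds, ratio = a3 / tab$mean_area)
  }) |> dplyr::bind_rows()

  out <- tibble(n = 1:5, lambda = default, images_used = 0L,
                estimated = FALSE)
  if (nrow(ratios) > 0) {
    est <- ratios |>
      dplyr::summarise(lambda = mean(.data$ratio),
                       images_used = dplyr::n(), .by = "n")
    for (i in seq_len(nrow(est))) {
      r <- est$n[i]
      out$lambda[r] <- est$lambda[i]
      out$images_used[r] <- est$images_used[i]
      out$estimated[r] <- TRUE
    }
  }
  out$lambda[3] <- 1
  if (any(!out$estimated)) {
    inform(sprintf(
      "lambda for n = %s kept at default (no qualifying image).",
      paste(out$n[!out$estimated], collapse = ", ")))
  }
  out
}
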