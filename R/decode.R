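# Decoding prediction tensors into scored pod detections.

#' Decode prediction tensors into pods
#'
#' Candidate centres are the 3x3 local maxima of `1 - background` above
#' `heatmap_thresh`. Each candidate regresses five seed positions via
#' its offset vector; a regressed seed survives when the value of its
#' type channel at the regressed location is at least `heatmap_thresh`,
#' and the detected seed count `n` is the length of the surviving
#' prefix chain starting at seed 1 (ordinals count from the pod base,
#' so an interior gap ends the chain). The pod score is the mean
#' surviving-seed confidence. Pose-level non-maximum suppression then
#' removes any lower-scoring pod whose mean per-ordinal seed distance
#' to an already-kept pod is below `nms_radius`; candidates scoring
#' below `nms_thresh` are discarded outright. Coordinates are returned
#' in input pixels.
#'
#' @param pred A [prediction_tensors()] (or `target_tensors`, whose
#'   heatmaps/offsets follow the same layout).
#' @param heatmap_thresh Heatmap threshold (default 0.3).
#' @param nms_thresh Minimum pod score (default 0.05).
#' @param nms_radius Duplicate-suppression radius in input pixels
#'   (default 10).
#' @param image_id Identifier stamped on the detections.
#' @return Detections tibble (possibly empty).
#' @export
decode <- function(pred, heatmap_thresh = 0.3, nms_thresh = 0.05,
                   nms_radius = 10, image_id = "image") {
  stopifnot(inherits(pred, c("prediction_tensors", "target_tensors")))
  hm <- pred$heatmaps
  off <- pred$offsets
  stride <- pred$stride
  Hp <- dim(hm)[1]; Wp <- dim(hm)[2]

  empty <- as_detections(tibble(image_id = character(), pod_id = integer(),
                                n_seeds = integer(), seed_index = integer(),
                                x = numeric(), y = numeric(),
                                seed_score = numeric(), pod_score = numeric()))

  centerness <- 1 - hm[, , 6]
  cand <- local_maxima(centerness, heatmap_thresh)
  if (nrow(cand) == 0) return(empty)

  pods <- purrr::pmap(as.list(cand), function(row, col, value) {
    conf <- numeric(5); px <- numeric(5); py <- numeric(5)
    for (k in 1:5) {
      u <- (col - 0.5) + off[row, col, 2 * k - 1]
      v <- (row - 0.5) + off[row, col, 2 * k]
      rr <- min(max(floor(v) + 1, 1), Hp)
      cc <- min(max(floor(u) + 1, 1), Wp)
      conf[k] <- hm[rr, cc, k]
      px[k] <- u * stride
      py[k] <- v * stride
    }
    n <- 0
    for (k in 1:5) {
      if (conf[k] >= heatmap_thresh) n <- k else break
    }
    if (n == 0) return(NULL)
    tibble(seed_index = 1:n, x = px[1:n], y = py[1:n],
           seed_score = conf[1:n], pod_score = mean(conf[1:n]))
  })
  pods <- purrr::compact(pods)
  if (length(pods) == 0) return(empty)

  scores <- vapply(pods, function(p) p$pod_score[1], numeric(1))
  ord <- order(scores, decreasing = TRUE)
  kept <- list()
  for (i in ord) {
    if (scores[i] < nms_thresh) next
    p <- pods[[i]]
    dup <- FALSE
    for (q in kept) {
      m <- min(nrow(p), nrow(q))
      d <- mean(sqrt((p$x[1:m] - q$x[1:m])^2 + (p$y[1:m] - q$y[1:m])^2))
      if (d < nms_radius) { dup <- TRUE; break }
    }
    if (!dup) kept[[length(kept) + 1]] <- p
  }
  if (length(kept) == 0) return(empty)

  out <- dplyr::bind_rows(
    purrr::imap(kept, function(p, i) {
      dplyr::mutate(p, image_id = image_id, pod_id = i,
                    n_seeds = nrow(p), .before = 1)
    })
  )
  as_detections(out)
}

# 3x3 local maxima at or above `thresh`; returns tibble(row, col, value)
local_maxima <- function(m, thresh) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(-Inf, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  is_max <- matrix(TRUE, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
    is_max <- is_max & (m >= nb)
  }
  keep <- which(is_max & m >= thresh, arr.ind = TRUE)
  tibble(row = as.integer(keep[, 1]), col = as.integer(keep[, 2]),
         value = m[keep])
}
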