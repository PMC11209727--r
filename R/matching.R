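# Detection-to-truth matching and the AP / count reports built on it.

#' Pairwise OKS_pod matrix between detections and ground truth
#'
#' @param dets Detections tibble for one image.
#' @param gt_ann A [pod_annotation()] (same image).
#' @param params An [oks_params()].
#' @param scale_pad Padding used for the per-pod object scale, px.
#' @return List: `oks` (det x gt matrix), `det` (tibble `pod_id`,
#'   `pod_score`, `n_seeds`), `gt` (tibble `pod_id`, `n_seeds`).
#' @export
oks_matrix <- function(dets, gt_ann, params = oks_params(), scale_pad = 6) {
  stopifnot(inherits(gt_ann, "pod_annotation"))
  dets <- as_detections(dets)
  det_tab <- dets |>
    dplyr::summarise(pod_score = .data$pod_score[1],
                     n_seeds = .data$n_seeds[1], .by = "pod_id")
  gt_tab <- pods(gt_ann)
  M <- matrix(0, nrow = nrow(det_tab), ncol = nrow(gt_tab))
  if (nrow(det_tab) > 0 && nrow(gt_tab) > 0) {
    gt_split <- split(gt_ann$seeds, gt_ann$seeds$pod_id)
    det_split <- split(dets, dets$pod_id)
    gt_ids <- as.character(gt_tab$pod_id)
    det_ids <- as.character(det_tab$pod_id)
    scales <- vapply(gt_split, pod_scale, numeric(1), pad = scale_pad)
    for (i in seq_along(det_ids)) {
      for (j in seq_along(gt_ids)) {
        M[i, j] <- oks_pod(det_split[[det_ids[i]]], gt_split[[gt_ids[j]]],
                           s = scales[[gt_ids[j]]], params = params)
      }
    }
  }
  list(oks = M, det = det_tab, gt = gt_tab)
}

#' Greedy score-ordered matching
#'
#' Detections are processed in descending pod score; each claims the
#' still-unmatched ground-truth pod with the highest `OKS_pod`, provided
#' it reaches `oks_threshold`; ties break toward the lower ground-truth
#' index. Each ground-truth pod is matched at most once.
#'
#' @param dets Detections tibble (one image).
#' @param gt_ann A [pod_annotation()].
#' @param params An [oks_params()].
#' @param oks_threshold Minimum OKS_pod for a match (default 0.5).
#' @param scale_pad Scale padding, px.
#' @return A `match_table`: list with `detections` (tibble `pod_id`,
#'   `pod_score`, `n_seeds`, `gt_id`, `oks`, matched rows have non-NA
#'   `gt_id`) and `gts` (tibble `pod_id`, `n_seeds`, `matched`).
#' @export
greedy_match <- function(dets, gt_ann, params = oks_params(),
                         oks_threshold = 0.5, scale_pad = 6) {
  om <- oks_matrix(dets, gt_ann, params = params, scale_pad = scale_pad)
  match_from_oks(om, oks_threshold)
}

# core greedy matcher on a precomputed OKS matrix
match_from_oks <- function(om, oks_threshold) {
  det <- om$det
  gt <- om$gt
  det$gt_id <- rep(NA_integer_, nrow(det))
  det$oks <- rep(NA_real_, nrow(det))
  gt$matched <- rep(FALSE, nrow(gt))
  if (nrow(det) > 0 && nrow(gt) > 0) {
    for (i in order(det$pod_score, decreasing = TRUE)) {
      cand <- om$oks[i, ]
      cand[gt$matched] <- -Inf
      j <- which.max(cand)
      if (length(j) == 1 && cand[j] >= oks_threshold) {
        det$gt_id[i] <- gt$pod_id[j]
        det$oks[i] <- om$oks[i, j]
        gt$matched[j] <- TRUE
      }
    }
  }
  structure(list(detections = det, gts = gt), class = "match_table")
}

all_point_ap <- function(tp, score, n_gt) {
  if (n_gt == 0) return(NA_real_)
  if (length(tp) == 0) return(0)
  ord <- order(score, decreasing = TRUE)
  tp <- tp[ord]
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  recall <- cum_tp / n_gt
  precision <- cum_tp / (cum_tp + cum_fp)
  # precision envelope (all-point interpolation)
  for (i in rev(seq_along(precision))[-1]) {
    precision[i] <- max(precision[i], precision[i + 1])
  }
  sum(diff(c(0, recall)) * precision)
}

#' Average precision over OKS_pod thresholds
#'
#' Matches detections to ground truth per image at each threshold in
#' `thresholds` and summarises: `ap` is the mean over the COCO-style
#' threshold grid 0.50:0.05:0.95, `ap50` the value at 0.50, and the
#' per-type APs restrict the ground truth to pods of each seed count n
#' (detections kept for type n are those matched to an n-seeded pod,
#' plus unmatched detections whose detected seed count is n). The PR
#' curve is reported at threshold 0.50 with all-point interpolation.
#'
#' @param dets Detections tibble covering one or more images
#'   (`image_id` column).
#' @param gt_anns List of [pod_annotation()]s (names or `image_id`s
#'   must match the detections).
#' @param params An [oks_params()].
#' @param thresholds OKS thresholds (default `seq(0.5, 0.95, 0.05)`).
#' @param scale_pad Scale padding, px.
#' @return An `ap_report`: list with `ap`, `ap50`, `per_type` (tibble
#'   `n`, `ap`, `n_gt`), `pr_curve` (tibble `recall`, `precision`,
#'   `score`), `thresholds`, `n_images`.
#' @export
average_precision <- function(dets, gt_anns, params = oks_params(),
                              thresholds = seq(0.5, 0.95, by = 0.05),
                              scale_pad = 6) {
  if (inherits(gt_anns, "pod_annotation")) gt_anns <- list(gt_anns)
  ids <- vapply(gt_anns, function(a) a$image_id, character(1))
  names(gt_anns) <- ids
  dets <- as_detections(dets)

  oms <- purrr::map(ids, function(id) {
    d <- dets[dets$image_id == id, , drop = FALSE]
    oks_matrix(d, gt_anns[[id]], params = params, scale_pad = scale_pad)
  })

  eval_at <- function(thr, type = NULL) {
    recs <- purrr::map(oms, function(om) {
      mt <- match_from_oks(om, thr)
      d <- mt$detections
      g <- mt$gts
      if (!is.null(type)) {
        keep_gt <- g$n_seeds == type
        n_gt <- sum(keep_gt)
        gt_type_ids <- g$pod_id[keep_gt]
        keep_det <- (!is.na(d$gt_id) & d$gt_id %in% gt_type_ids) |
          (is.na(d$gt_id) & d$n_seeds == type)
        d <- d[keep_det, , drop = FALSE]
      } else {
        n_gt <- nrow(g)
      }
      list(tp = !is.na(d$gt_id), score = d$pod_score, n_gt = n_gt)
    })
    tp <- unlist(purrr::map(recs, "tp"))
    score <- unlist(purrr::map(recs, "score"))
    n_gt <- sum(unlist(purrr::map(recs, "n_gt")))
    list(ap = all_point_ap(tp, score, n_gt), tp = tp, score = score,
         n_gt = n_gt)
  }

  per_thr <- purrr::map(thresholds, eval_at)
  aps <- vapply(per_thr, function(x) x$ap, numeric(1))
  ap50_idx <- which(abs(thresholds - 0.5) < 1e-9)

  # PR curve at 0.50
  base <- if (length(ap50_idx) == 1) per_thr[[ap50_idx]] else eval_at(0.5)
  ord <- order(base$score, decreasing = TRUE)
  tp <- base$tp[ord]
  pr <- tibble(
    score = base$score[ord],
    recall = cumsum(tp) / max(1, base$n_gt),
    precision = cumsum(tp) / seq_along(tp)
  )

  per_type <- purrr::map(1:4, function(t) {
    aps_t <- vapply(thresholds, function(thr) eval_at(thr, type = t)$ap,
                    numeric(1))
    n_gt_t <- eval_at(thresholds[1], type = t)$n_gt
    tibble(n = t, ap = mean(aps_t), ap50 = aps_t[ap50_idx],
           n_gt = n_gt_t)
  }) |> dplyr::bind_rows()

  structure(list(
    ap = mean(aps), ap50 = if (length(ap50_idx) == 1) aps[ap50_idx] else NA,
    per_type = per_type, pr_curve = pr, thresholds = thresholds,
    ap_by_threshold = tibble(threshold = thresholds, ap = aps),
    n_images = length(gt_anns)
  ), class = "ap_report")
}

#' @export
print.ap_report <- function(x, ...) {
  cat(sprintf("<ap_report> AP %.3f | AP50 %.3f | %d image(s)\n",
              x$ap, x$ap50, x$n_images))
  for (i in seq_len(nrow(x$per_type))) {
    if (x$per_type$n_gt[i] > 0) {
      cat(sprintf("  AP(%d-seeded) %.3f\n", x$per_type$n[i],
                  x$per_type$ap[i]))
    }
  }
  invisible(x)
}

#' Count-level error metrics
#'
#' Mean absolute error and Pearson correlation between per-image
#' predicted and true counts.
#'
#' @param pred_counts,true_counts Equal-length numeric vectors, one
#'   entry per image.
#' @return List with `mae` and `pcc` (`pcc` is NA, with a warning, for
#'   zero-variance series or fewer than two images).
#' @export
count_metrics <- function(pred_counts, true_counts) {
  stopifnot(length(pred_counts) == length(true_counts),
            length(pred_counts) >= 1)
  mae <- mean(abs(pred_counts - true_counts))
  pcc <- if (length(pred_counts) < 2 ||
             stats::sd(pred_counts) == 0 || stats::sd(true_counts) == 0) {
    warn("PCC undefined for constant or single-image series.")
    NA_real_
  } else {
    cor(pred_counts, true_counts)
  }
  list(mae = mae, pcc = pcc)
}

#' Descriptive statistics of an annotation set
#'
#' Image count, pod and seed totals, per-image averages (reported to
#' two decimals, rounding half up) and the histogram of pods by seed
#' count.
#'
#' @param annotations List of [pod_annotation()]s.
#' @return One-row tibble with columns `n_images`, `total_pods`,
#'   `total_seeds`, `avg_pods`, `avg_seeds`, `pods_1` .. `pods_5`.
#' @export
dataset_statistics <- function(annotations) {
  if (length(annotations) == 0) {
    return(tibble(n_images = 0L, total_pods = 0L, total_seeds = 0L,
                  avg_pods = 0, avg_seeds = 0, pods_1 = 0L, pods_2 = 0L,
                  pods_3 = 0L, pods_4 = 0L, pods_5 = 0L))
  }
  per <- purrr::map(annotations, function(ann) {
    p <- pods(ann)
    tibble(n_pods = nrow(p), n_seeds = sum(p$n_present),
           hist = list(tabulate(p$n_seeds, nbins = 5)))
  }) |> dplyr::bind_rows()
  hist <- Reduce("+", per$hist)
  stats <- split_averages(length(annotations), sum(per$n_pods),
                          sum(per$n_seeds))
  tibble(n_images = length(annotations),
         total_pods = sum(per$n_pods), total_seeds = sum(per$n_seeds),
         avg_pods = stats$avg_pods, avg_seeds = stats$avg_seeds,
         pods_1 = hist[1], pods_2 = hist[2], pods_3 = hist[3],
         pods_4 = hist[4], pods_5 = hist[5])
}

#' Per-image averages from split totals
#'
#' Computes the average pods and seeds per image from a split's printed
#' totals, rounded half-up to two decimals as such tables convention-
#' ally report them.
#'
#' @param n_images,total_pods,total_seeds Split totals.
#' @return List with `avg_pods`, `avg_seeds`.
#' @export
split_averages <- function(n_images, total_pods, total_seeds) {
  if (n_images == 0) return(list(avg_pods = 0, avg_seeds = 0))
  list(avg_pods = round_half_up(total_pods / n_images, 2),
       avg_seeds = round_half_up(total_seeds / n_images, 2))
}
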