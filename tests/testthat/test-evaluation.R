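gt3 <- tibble::tibble(pod_id = 1L, n_seeds = 3L, seed_index = 1:3,
                      x = c(0, 25, 50), y = 0)

test_that("pod OKS is 1 at zero error and follows the closed form", {
  expect_equal(oks_pod(gt3, gt3, s = 40), 1)

  # n = 1: one seed displaced so d^2 = 2 lambda_1 s^2 k^2 gives exp(-1)
  par <- oks_params()
  s <- 30
  d <- sqrt(2 * par$lambda[1] * s^2 * par$k^2)
  gt1 <- tibble::tibble(pod_id = 1L, n_seeds = 1L, seed_index = 1L,
                        x = 0, y = 0)
  pr1 <- tibble::tibble(seed_index = 1L, x = d, y = 0)
  expect_equal(oks_pod(pr1, gt1, s = s, par), exp(-1), tolerance = 1e-5)
})

test_that("pod OKS is invariant to joint rescaling of coordinates and s", {
  pred <- dplyr::mutate(gt3, x = .data$x + 3, y = .data$y - 2)
  v1 <- oks_pod(pred, gt3, s = 40)
  for (c in c(0.5, 2, 7.3)) {
    v2 <- oks_pod(dplyr::mutate(pred, x = x * c, y = y * c),
                  dplyr::mutate(gt3, x = x * c, y = y * c), s = 40 * c)
    expect_equal(v2, v1, tolerance = 1e-10)
  }
})

test_that("equal lambdas make pod OKS independent of seed count", {
  par <- oks_params(lambda = rep(1, 5))
  s <- 40
  for (n in c(1L, 2L, 4L, 5L)) {
    gt <- tibble::tibble(pod_id = 1L, n_seeds = n, seed_index = seq_len(n),
                         x = (seq_len(n) - 1) * 25, y = 0)
    pred <- dplyr::mutate(gt, y = y + 5) # equal per-seed distance
    expect_equal(oks_pod(pred, gt, s, par),
                 exp(-25 / (2 * s^2 * par$k^2)), tolerance = 1e-9)
  }
})

test_that("pod OKS decreases in every seed's distance", {
  s <- 40
  base <- dplyr::mutate(gt3, y = y + 2)
  v0 <- oks_pod(base, gt3, s)
  for (i in 1:3) {
    worse <- base
    worse$y[i] <- worse$y[i] + 4
    expect_lt(oks_pod(worse, gt3, s), v0)
  }
  # a missing seed contributes zero
  expect_equal(oks_pod(gt3[1:2, ], gt3, s), 2 / 3, tolerance = 1e-9)
})

test_that("original OKS honours visibility flags", {
  expect_equal(oks_original(gt3, gt3, s = 40), 1)
  s <- 30; k <- 0.1
  pr <- tibble::tibble(seed_index = 1L, x = sqrt(2 * s^2 * k^2), y = 0)
  gt1 <- tibble::tibble(pod_id = 1L, n_seeds = 1L, seed_index = 1L,
                        x = 0, y = 0)
  expect_equal(oks_original(pr, gt1, s, k_per_seed = k), exp(-1),
               tolerance = 1e-5)

  # perturbing invisible seeds changes nothing
  pred <- dplyr::mutate(gt3, x = x + 1)
  v <- oks_original(pred, gt3, 40, visibility = c(1, 0, 1))
  pred2 <- pred
  pred2$x[2] <- 999
  expect_equal(oks_original(pred2, gt3, 40, visibility = c(1, 0, 1)), v)
  expect_error(oks_original(pred, gt3, 40, visibility = c(0, 0, 0)),
               "no visible")
})

test_that("sigma estimation recovers known relabelling noise", {
  orig <- tibble::tibble(x = rep(0, 4), y = rep(0, 4))
  expect_equal(estimate_sigma(orig, orig, s = 10)$sigma, 0)

  # constant ratio d = c * s gives sigma = c exactly
  ref <- tibble::tibble(x = c(3, 6), y = 0)
  base <- tibble::tibble(x = c(0, 0), y = 0)
  est <- estimate_sigma(ref, base, s = c(10, 20))
  expect_equal(est$sigma, 0.3)
  expect_equal(est$k, 0.6)

  # Monte-Carlo: per-axis sd s*sigma/sqrt(2) makes E[d^2/s^2] = sigma^2
  set.seed(11)
  n <- 1000
  sig <- 0.07
  s <- 50
  ref <- tibble::tibble(x = rnorm(n, 0, s * sig / sqrt(2)),
                        y = rnorm(n, 0, s * sig / sqrt(2)))
  got <- estimate_sigma(ref, tibble::tibble(x = rep(0, n), y = rep(0, n)),
                        s = s)$sigma
  expect_lt(abs(got - sig), 3 * sig / sqrt(2 * n))
  expect_error(estimate_sigma(ref[0, ], ref[0, ], 1), "non-empty")
})

test_that("lambda estimation recovers area-proportional coefficients", {
  # pods built so the padded bounding-box area is exactly 144 n:
  # n seeds on a horizontal line spanning 12 (n - 1) px, pad 6
  mk_ann <- function(id) {
    rows <- dplyr::bind_rows(lapply(1:5, function(n) {
      tibble::tibble(pod_id = n, n_seeds = n, seed_index = seq_len(n),
                     x = 20 + (seq_len(n) - 1) * 12, y = 30 * n)
    }))
    pod_annotation(rows, image_id = paste0("img", id),
                   width = 200, height = 200)
  }
  est <- estimate_lambda(lapply(1:3, mk_ann), pad = 6)
  expect_equal(est$lambda, c(3, 1.5, 1, 0.75, 0.6), tolerance = 1e-9)
  expect_equal(est$lambda[3], 1)

  # entries with no qualifying image keep the default, with a message
  part <- pod_annotation(line_pod(1L, 3, 20, 20, spacing = 12),
                         image_id = "only3", width = 200, height = 200)
  expect_message(est2 <- estimate_lambda(list(part)), "default")
  expect_equal(est2$lambda[c(1, 2, 4, 5)],
               c(4.752, 1.353, 0.782, 0.673))
  expect_false(any(est2$estimated[c(1, 2, 4, 5)]))
})

test_that("greedy matching takes the best available truth per score", {
  ann <- pod_annotation(dplyr::bind_rows(line_pod(1L, 2, 20, 20),
                                         line_pod(2L, 2, 20, 120)),
                        image_id = "gm", width = 200, height = 200)
  dets <- annotation_to_detections(ann)
  mt <- greedy_match(dets, ann)
  expect_true(all(mt$detections$oks == 1))
  expect_true(all(mt$gts$matched))

  # one detection near gt 1, far from gt 2: matches the higher OKS
  one <- as_detections(tibble::tibble(pod_id = 1L, seed_index = 1:2,
                                      x = c(22, 47), y = 21,
                                      seed_score = 0.9, pod_score = 0.9))
  mt1 <- greedy_match(one, ann, oks_threshold = 0.05)
  expect_equal(mt1$detections$gt_id, 1L)
})

test_that("greedy matching equals a brute-force oracle on small cases", {
  # independent oracle working directly on an OKS matrix
  oracle <- function(oks, scores, thr) {
    assigned <- rep(NA_integer_, length(scores))
    taken <- rep(FALSE, ncol(oks))
    for (i in order(scores, decreasing = TRUE)) {
      best <- 0
      pick <- NA_integer_
      for (j in seq_len(ncol(oks))) {
        if (!taken[j] && oks[i, j] >= thr && oks[i, j] > best) {
          best <- oks[i, j]
          pick <- j
        }
      }
      if (!is.na(pick)) {
        assigned[i] <- pick
        taken[pick] <- TRUE
      }
    }
    assigned
  }
  set.seed(21)
  for (trial in 1:200) {
    nd <- sample(0:4, 1)
    ng <- sample(1:4, 1)
    om <- list(
      oks = matrix(round(runif(nd * ng), 3), nd, ng),
      det = tibble::tibble(pod_id = seq_len(nd),
                           pod_score = runif(nd), n_seeds = 2L),
      gt = tibble::tibble(pod_id = seq_len(ng), n_seeds = 2L,
                          n_present = 2L, truncated = FALSE)
    )
    got <- podkit:::match_from_oks(om, 0.5)
    want <- oracle(om$oks, om$det$pod_score, 0.5)
    expect_equal(got$detections$gt_id, as.integer(want))
  }
})

test_that("average precision handles perfect and mixed detections", {
  anns <- lapply(1:3, function(s) {
    crop_scene(500 + s, width = 250, height = 250, pods = 4)$annotation
  })
  perfect <- dplyr::bind_rows(lapply(anns, annotation_to_detections))
  rep <- average_precision(perfect, anns)
  expect_equal(rep$ap, 1)
  expect_equal(rep$ap50, 1)
  expect_true(all(stats::na.omit(rep$per_type$ap) == 1))

  # one true positive then one false positive among 2 gts -> AP 0.5
  ann <- pod_annotation(dplyr::bind_rows(line_pod(1L, 2, 20, 20),
                                         line_pod(2L, 2, 20, 120)),
                        image_id = "ap", width = 220, height = 220)
  tp <- annotation_to_detections(ann)
  tp <- tp[tp$pod_id == 1, ]
  tp$pod_score <- 0.9
  fp <- tibble::tibble(image_id = "ap", pod_id = 99L, n_seeds = 2L,
                       seed_index = 1:2, x = c(180, 205), y = 200,
                       seed_score = 0.8, pod_score = 0.8)
  rep2 <- average_precision(dplyr::bind_rows(tp, fp), list(ann))
  expect_equal(rep2$ap50, 0.5)
  expect_equal(rep2$ap, 0.5)

  # removing a low-score false positive never decreases AP
  rep3 <- average_precision(tp, list(ann))
  expect_gte(rep3$ap50, rep2$ap50)
})

test_that("per-type AP is restricted to pods of that seed count", {
  ann <- pod_annotation(dplyr::bind_rows(line_pod(1L, 2, 20, 20),
                                         line_pod(2L, 3, 20, 120)),
                        image_id = "pt", width = 220, height = 220)
  dets <- annotation_to_detections(ann)
  dets <- dets[dets$pod_id == 1, ] # only the 2-seeded pod is found
  rep <- average_precision(dets, list(ann))
  expect_equal(rep$per_type$ap[rep$per_type$n == 2], 1)
  expect_equal(rep$per_type$ap[rep$per_type$n == 3], 0)
  expect_true(is.na(rep$per_type$ap[rep$per_type$n == 4]))
})

test_that("count metrics match hand arithmetic", {
  same <- count_metrics(c(4, 7, 2), c(4, 7, 2))
  expect_equal(same$mae, 0)
  expect_equal(same$pcc, 1)
  expect_equal(count_metrics(c(1, 2, 3), c(2, 2, 5))$mae, 1)
  shift <- count_metrics(c(1, 2, 3) + 4, c(1, 2, 3))
  expect_equal(shift$mae, 4)
  expect_equal(shift$pcc, 1)
  expect_warning(z <- count_metrics(c(2, 2), c(1, 3)), "undefined")
  expect_true(is.na(z$pcc))
})

test_that("dataset statistics count pods, seeds and types", {
  expect_equal(dataset_statistics(list())$n_images, 0)
  anns <- list(
    pod_annotation(dplyr::bind_rows(line_pod(1L, 2, 20, 20),
                                    line_pod(2L, 3, 20, 80)),
                   image_id = "a", width = 220, height = 220),
    pod_annotation(line_pod(1L, 5, 20, 50, spacing = 20),
                   image_id = "b", width = 220, height = 220)
  )
  st <- dataset_statistics(anns)
  expect_equal(st$n_images, 2)
  expect_equal(st$total_pods, 3)
  expect_equal(st$total_seeds, 10)
  expect_equal(st$avg_pods, 1.5)
  expect_equal(st$avg_seeds, 5)
  expect_equal(c(st$pods_2, st$pods_3, st$pods_5), c(1, 1, 1))
})

test_that("split averages round half-up to two decimals", {
  expect_equal(split_averages(3, 8, 10)$avg_pods, 2.67)
  expect_equal(split_averages(8, 1, 1)$avg_pods, 0.13) # 0.125 rounds up
  expect_equal(split_averages(0, 0, 0)$avg_pods, 0)
})
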