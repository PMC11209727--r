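two_window_dets <- function(ann, at) {
  sp <- split_scene_across_windows(ann, at = at, axis = "x")
  list(dets = dplyr::bind_rows(sp$left, sp$right), windows = sp$windows)
}

test_that("dedup keeps the best-scoring copy of duplicated pods", {
  base <- line_pod(1L, 3, 50, 50)
  a <- tibble::tibble(image_id = "d", window = "w001", pod_id = 1L,
                      n_seeds = 3L, seed_index = 1:3, x = base$x,
                      y = base$y, seed_score = 0.9, pod_score = 0.9)
  b <- dplyr::mutate(a, window = "w002", x = x + 1, pod_score = 0.7,
                     seed_score = 0.7)
  kept <- dedupe_seeds(dplyr::bind_rows(a, b), dist_thresh = 10)
  expect_equal(dplyr::n_distinct(paste(kept$window, kept$pod_id)), 1)
  expect_equal(kept$pod_score[1], 0.9)

  far <- dplyr::mutate(b, x = x + 100)
  both <- dedupe_seeds(dplyr::bind_rows(a, far), dist_thresh = 10)
  expect_equal(dplyr::n_distinct(paste(both$window, both$pod_id)), 2)
})

test_that("dedup groups duplicates transitively like union-find", {
  base <- line_pod(1L, 2, 50, 50)
  mk <- function(w, dx, score) {
    tibble::tibble(image_id = "t", window = w, pod_id = 1L, n_seeds = 2L,
                   seed_index = 1:2, x = base$x + dx, y = base$y,
                   seed_score = score, pod_score = score)
  }
  # chain: a~b and b~c within threshold, a-c slightly beyond
  dets <- dplyr::bind_rows(mk("w1", 0, 0.5), mk("w2", 6, 0.9),
                           mk("w3", 12, 0.6))
  kept <- dedupe_seeds(dets, dist_thresh = 8)
  expect_equal(dplyr::n_distinct(paste(kept$window, kept$pod_id)), 1)
  expect_equal(kept$pod_score[1], 0.9)

  # oracle: brute-force transitive closure over the duplicate relation
  dup <- function(p, q) all(sqrt((p$x - q$x)^2 + (p$y - q$y)^2) < 8)
  pods_l <- list(mk("w1", 0, 0.5), mk("w2", 6, 0.9), mk("w3", 12, 0.6))
  adj <- outer(seq_along(pods_l), seq_along(pods_l),
               Vectorize(function(i, j) dup(pods_l[[i]], pods_l[[j]])))
  reach <- adj
  for (k in seq_along(pods_l)) reach <- reach | (reach %*% reach) > 0
  expect_true(all(reach)) # single component expected
})

test_that("border candidates pair pods flanking a shared edge", {
  ann <- pod_annotation(dplyr::bind_rows(
    line_pod(1L, 3, 360, 50),   # straddles x = 400
    line_pod(2L, 2, 100, 100),  # interior to the left window
    line_pod(3L, 2, 600, 300)   # interior to the right window
  ), image_id = "bc", width = 700, height = 400)
  wins <- tile_image(700, 400, 400, 300)
  dets <- tiled_perfect_detections(ann, wins)
  cand <- border_candidates(dets, wins, border_margin = 100)
  expect_gt(nrow(cand), 0)
  pods_in_cand <- unique(c(
    paste(cand$window_a, cand$pod_a), paste(cand$window_b, cand$pod_b)))
  # interior pods appear in no pair
  expect_false(any(grepl(" 2$", pods_in_cand) & grepl("^w001", pods_in_cand)))

  # windows with no shared edge produce no pairs
  wins2 <- tibble::tibble(window = c("wA", "wB"),
                          x_min = c(0, 2000), y_min = 0,
                          x_max = c(400, 2400), y_max = 400)
  d2 <- dets
  d2$window <- ifelse(d2$window == "w001", "wA", "wB")
  expect_equal(nrow(border_candidates(d2, wins2, 50)), 0)
})

test_that("DTW matches hand-enumerated alignments", {
  A <- rbind(c(0, 0), c(0, 10))
  same <- dtw_shape_distance(A, A)
  expect_equal(same$distance, 0)
  expect_equal(same$path, cbind(1:2, 1:2))

  # two points against one: both align to it, cost (0 + 10) / 2
  res <- dtw_shape_distance(A, rbind(c(0, 0)))
  expect_equal(res$distance, 5)
  expect_equal(res$path, cbind(1:2, c(1, 1)))

  # symmetry
  set.seed(31)
  for (i in 1:20) {
    P <- matrix(runif(2 * sample(1:3, 1), 0, 50), ncol = 2)
    Q <- matrix(runif(2 * sample(1:3, 1), 0, 50), ncol = 2)
    expect_equal(dtw_shape_distance(P, Q)$distance,
                 dtw_shape_distance(Q, P)$distance, tolerance = 1e-10)
  }
})

test_that("DTW equals brute-force path enumeration up to length 3", {
  # DTW minimises the total path cost; the reported distance divides by
  # that optimal path's length (unique a.s. for continuous random costs)
  brute <- function(cost) {
    la <- nrow(cost); lb <- ncol(cost)
    best_cost <- Inf
    best_len <- NA
    walk <- function(i, j, acc, len) {
      acc <- acc + cost[i, j]
      if (i == la && j == lb) {
        if (acc < best_cost) {
          best_cost <<- acc
          best_len <<- len + 1
        }
        return()
      }
      if (i < la) walk(i + 1, j, acc, len + 1)
      if (j < lb) walk(i, j + 1, acc, len + 1)
      if (i < la && j < lb) walk(i + 1, j + 1, acc, len + 1)
    }
    walk(1, 1, 0, 0)
    best_cost / best_len
  }
  set.seed(32)
  for (i in 1:50) {
    P <- matrix(runif(2 * sample(1:3, 1), 0, 40), ncol = 2)
    Q <- matrix(runif(2 * sample(1:3, 1), 0, 40), ncol = 2)
    cost <- as.matrix(dist(rbind(P, Q)))[seq_len(nrow(P)),
                                         nrow(P) + seq_len(nrow(Q)),
                                         drop = FALSE]
    expect_equal(dtw_shape_distance(P, Q)$distance, brute(cost),
                 tolerance = 1e-10)
  }
})

test_that("path monotonicity and endpoints hold for random sequences", {
  set.seed(33)
  for (i in 1:20) {
    P <- matrix(runif(2 * sample(1:5, 1), 0, 60), ncol = 2)
    Q <- matrix(runif(2 * sample(1:5, 1), 0, 60), ncol = 2)
    path <- dtw_shape_distance(P, Q)$path
    expect_equal(path[1, ], c(1, 1))
    expect_equal(path[nrow(path), ], c(nrow(P), nrow(Q)))
    expect_true(all(diff(path[, 1]) >= 0))
    expect_true(all(diff(path[, 2]) >= 0))
  }
})

test_that("merging a pod with itself is the identity", {
  p <- dplyr::mutate(line_pod(1L, 3, 10, 10), seed_score = 0.8,
                     pod_score = 0.8)
  m <- merge_pair(p, p)
  expect_equal(nrow(m), 3)
  expect_equal(m$x, p$x)
  expect_equal(m$seed_index, 1:3)
})

test_that("disjoint parts concatenate into the full chain", {
  # 2-seed left part + 1-seed right part of one straight pod
  a <- dplyr::mutate(line_pod(1L, 2, 0, 0), seed_score = 0.9,
                     pod_score = 0.9)
  b <- tibble::tibble(pod_id = 2L, n_seeds = 1L, seed_index = 1L,
                      x = 50, y = 0, seed_score = 0.6, pod_score = 0.6)
  m <- merge_pair(a, b)
  expect_equal(nrow(m), 3)
  expect_equal(m$x, c(0, 25, 50)) # base kept at the higher-scoring part
  expect_equal(m$seed_index, 1:3)
})

test_that("overhanging merges cap the chain at five seeds", {
  # 4-seed and 3-seed observations sharing 2 seeds -> 5 after the cap
  a <- dplyr::mutate(line_pod(1L, 4, 0, 0), seed_score = 0.9,
                     pod_score = 0.9)
  b <- tibble::tibble(pod_id = 2L, n_seeds = 3L, seed_index = 1:3,
                      x = c(50, 75, 100), y = 0,
                      seed_score = 0.5, pod_score = 0.5)
  m <- merge_pair(a, b)
  expect_equal(nrow(m), 5)
  expect_equal(m$x, c(0, 25, 50, 75, 100))

  # 5 + 2 with one shared seed would exceed the cap
  a5 <- dplyr::mutate(line_pod(1L, 5, 0, 0), seed_score = 0.9,
                      pod_score = 0.9)
  b2 <- tibble::tibble(pod_id = 2L, n_seeds = 2L, seed_index = 1:2,
                       x = c(100, 125), y = 0,
                       seed_score = 0.4, pod_score = 0.4)
  expect_warning(m2 <- merge_pair(a5, b2), "capping")
  expect_equal(nrow(m2), 5)
})

test_that("a single window reduces merge_full to dedup", {
  sc <- crop_scene(91, width = 300, height = 300, pods = 4)
  wins <- tibble::tibble(window = "w001", x_min = 0, y_min = 0,
                         x_max = 300, y_max = 300)
  dets <- tiled_perfect_detections(sc$annotation, wins)
  merged <- merge_full(dets, wins)
  expect_equal(dplyr::n_distinct(merged$pod_id),
               nrow(pods(sc$annotation)))
  expect_equal(nrow(merged), nrow(dets))
})

test_that("tiled perfect detections merge back to the original pods", {
  for (s in c(4, 10, 17)) { # includes formerly tricky partial overlaps
    sc <- generate_scene(scene_config(width = 700, height = 400,
                                      pods_per_image = 10, rng_seed = s))
    wins <- tile_image(700, 400, 400, 300)
    dets <- tiled_perfect_detections(sc$annotation, wins)
    merged <- merge_full(dets, wins)
    expect_equal(dplyr::n_distinct(merged$pod_id),
                 nrow(pods(sc$annotation)))
    expect_equal(nrow(merged), nrow(sc$annotation$seeds))
    # idempotence: re-merging changes nothing
    again <- merge_full(merged, wins)
    expect_equal(nrow(again), nrow(merged))
    expect_equal(dplyr::n_distinct(again$pod_id),
                 dplyr::n_distinct(merged$pod_id))
  }
})

test_that("genuinely distinct pods with close seeds are not merged", {
  # a horizontal and a vertical pod meeting near one end: one seed pair
  # is close but the DTW shapes diverge
  h <- tibble::tibble(image_id = "x", window = "w001", pod_id = 1L,
                      n_seeds = 3L, seed_index = 1:3,
                      x = c(395, 370, 345), y = 200,
                      seed_score = 0.9, pod_score = 0.9)
  v <- tibble::tibble(image_id = "x", window = "w002", pod_id = 1L,
                      n_seeds = 3L, seed_index = 1:3,
                      x = 402, y = c(203, 228, 253),
                      seed_score = 0.8, pod_score = 0.8)
  wins <- tile_image(700, 400, 400, 300)
  merged <- merge_full(dplyr::bind_rows(h, v), wins)
  expect_equal(dplyr::n_distinct(merged$pod_id), 2)
  expect_equal(nrow(merged), 6)
})

test_that("merging never increases the seed count", {
  for (s in 101:105) {
    sc <- generate_scene(scene_config(width = 700, height = 400,
                                      pods_per_image = 8, rng_seed = s))
    wins <- tile_image(700, 400, 400, 300)
    dets <- tiled_perfect_detections(sc$annotation, wins)
    merged <- merge_full(dets, wins)
    expect_lte(nrow(merged), nrow(dets))
  }
})
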