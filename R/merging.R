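# Combining per-crop detections into whole-plant results. Overlapping
# crop windows see boundary pods twice (often partially), so merging
# proceeds in three moves: Euclidean dedup of identical pods, border-
# band candidate pairing, and DTW shape matching that decides whether
# two partial detections are the same pod and which seeds coincide.

#' Merge configuration
#'
#' @param dist_thresh Seed-pair proximity gate, px. Pods whose seeds
#'   fall closer than this are duplicate candidates; matched DTW path
#'   pairs closer than this are averaged during a merge.
#' @param shape_thresh DTW distance gate, px (path-normalised), above
#'   which two pods are considered genuinely distinct. The default is
#'   calibrated on the synthetic benchmark (seed spacing ~25 px with
#'   jitter): a partial detection overhanging its counterpart by two
#'   seeds costs up to ~23 px under full-path DTW at the spacing tail,
#'   while crossing or diverging pods cost upwards of ~40 px, so 25 px
#'   separates the two regimes.
#' @param border_margin Width of the boundary bands in which cross-
#'   window candidates are sought, px; `NULL` means the window overlap
#'   width (crop size minus stride) computed from the supplied windows.
#' @return List of class `merge_config`.
#' @export
merge_config <- function(dist_thresh = 10, shape_thresh = 25,
                         border_margin = NULL) {
  stopifnot(dist_thresh > 0, shape_thresh > 0,
            is.null(border_margin) || border_margin > 0)
  structure(list(dist_thresh = dist_thresh, shape_thresh = shape_thresh,
                 border_margin = border_margin), class = "merge_config")
}

#' Remove duplicated pods by Euclidean seed distance
#'
#' Two pods are duplicates when they have the same detected seed count
#' and every ordinal-wise seed distance is below `dist_thresh`;
#' duplicate groups are closed transitively (union-find) and only the
#' highest-scoring pod of each group is kept.
#'
#' @param dets Detections tibble in one coordinate frame.
#' @param dist_thresh Proximity gate, px.
#' @return Detections tibble.
#' @export
dedupe_seeds <- function(dets, dist_thresh = 10) {
  dets <- as_detections(dets)
  if (nrow(dets) == 0) return(dets)
  key <- paste(dets$image_id, dets$window %||% "", dets$pod_id, sep = "\r")
  pods_list <- split(dets, factor(key, levels = unique(key)))
  n <- length(pods_list)
  if (n <= 1) return(dets)
  parent <- uf_new(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- pods_list[[i]]; b <- pods_list[[j]]
      if (nrow(a) != nrow(b)) next
      d <- paired_dist(cbind(a$x, a$y), cbind(b$x, b$y))
      if (all(d < dist_thresh)) parent <- uf_union(parent, i, j)
    }
  }
  groups <- uf_groups(parent)
  keep <- vapply(split(seq_len(n), groups), function(idx) {
    scores <- vapply(pods_list[idx], function(p) p$pod_score[1], numeric(1))
    idx[which.max(scores)]
  }, integer(1))
  dplyr::bind_rows(pods_list[sort(keep)])
}

#' Cross-window candidate pod pairs in border bands
#'
#' For every pair of windows whose rectangles, each expanded by the
#' border margin, intersect, the band is that intersection; a pod pair
#' (one pod per window) is a candidate when both pods have at least one
#' seed inside the band.
#'
#' @param dets Detections tibble in the full-image frame with a
#'   `window` column.
#' @param windows Window tibble as from [tile_image()].
#' @param border_margin Band half-width, px.
#' @return Tibble of candidate pairs with columns `window_a`, `pod_a`,
#'   `window_b`, `pod_b`.
#' @export
border_candidates <- function(dets, windows, border_margin = 100) {
  dets <- as_detections(dets)
  out <- tibble(window_a = character(), pod_a = integer(),
                window_b = character(), pod_b = integer())
  if (nrow(dets) == 0 || nrow(windows) < 2) return(out)
  if (!"window" %in% names(dets)) {
    abort("`dets` needs a `window` column for border pairing.")
  }
  rows <- list()
  for (i in seq_len(nrow(windows) - 1)) {
    for (j in (i + 1):nrow(windows)) {
      wa <- windows[i, ]; wb <- windows[j, ]
      x_lo <- max(wa$x_min, wb$x_min) - border_margin
      x_hi <- min(wa$x_max, wb$x_max) + border_margin
      y_lo <- max(wa$y_min, wb$y_min) - border_margin
      y_hi <- min(wa$y_max, wb$y_max) + border_margin
      if (x_lo >= x_hi || y_lo >= y_hi) next
      in_band <- function(d) {
        d[d$x >= x_lo & d$x < x_hi & d$y >= y_lo & d$y < y_hi, ,
          drop = FALSE]
      }
      da <- in_band(dets[dets$window == wa$window, , drop = FALSE])
      db <- in_band(dets[dets$window == wb$window, , drop = FALSE])
      if (nrow(da) == 0 || nrow(db) == 0) next
      rows[[length(rows) + 1]] <- tidyr::expand_grid(
        window_a = wa$window, pod_a = unique(da$pod_id),
        window_b = wb$window, pod_b = unique(db$pod_id)
      )
    }
  }
  if (length(rows) == 0) return(out)
  dplyr::bind_rows(rows)
}

#' Dynamic-time-warping distance between two seed chains
#'
#' Classical DTW with Euclidean local cost and steps (1,0), (0,1),
#' (1,1); the reported distance is the optimal path cost divided by the
#' path length, so thresholds are comparable across pod lengths. The
#' step pattern is symmetric, hence so is the distance.
#'
#' @param seq_a,seq_b Matrices (or tibbles with `x`, `y`) of ordered
#'   seed coordinates; both non-empty.
#' @return List of class `dtw_result`: `distance` (scalar) and `path`
#'   (m x 2 integer matrix of aligned index pairs from (1,1) to
#'   (len A, len B), monotone nondecreasing).
#' @export
dtw_shape_distance <- function(seq_a, seq_b) {
  A <- as_xy_matrix(seq_a)
  B <- as_xy_matrix(seq_b)
  la <- nrow(A); lb <- nrow(B)
  if (la == 0 || lb == 0) abort("Both sequences must be non-empty.")
  cost <- cross_dist(A, B)
  D <- matrix(Inf, la + 1, lb + 1)
  D[1, 1] <- 0
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      D[i + 1, j + 1] <- cost[i, j] +
        min(D[i, j], D[i, j + 1], D[i + 1, j])
    }
  }
  # backtrack
  path <- matrix(0L, nrow = la + lb, ncol = 2)
  i <- la; j <- lb; m <- 0L
  while (i >= 1 && j >= 1) {
    m <- m + 1L
    path[m, ] <- c(i, j)
    if (i == 1 && j == 1) break
    choices <- c(if (i > 1 && j > 1) D[i, j] else Inf,
                 if (i > 1) D[i, j + 1] else Inf,
                 if (j > 1) D[i + 1, j] else Inf)
    step <- which.min(choices)
    if (step == 1) { i <- i - 1; j <- j - 1 }
    else if (step == 2) i <- i - 1
    else j <- j - 1
  }
  path <- path[m:1, , drop = FALSE]
  structure(list(distance = D[la + 1, lb + 1] / nrow(path), path = path),
            class = "dtw_result")
}

as_xy_matrix <- function(s) {
  if (is.matrix(s)) return(matrix(as.numeric(s), ncol = 2))
  s <- as_tibble(s)
  cbind(s$x, s$y)
}

#' Merge two pod detections along a DTW path
#'
#' Path pairs whose seed distance is below `dist_thresh` are treated as
#' duplicate observations and averaged with score weighting (each seed
#' consumed at most once); all remaining seeds are kept and the two
#' sub-chains concatenated in the orientation with the smallest junction
#' gap. Ordinals are renumbered 1..n from the base end - the end
#' belonging to the part whose ordinal-1 seed had the higher confidence
#' - and n is capped at 5, dropping the lowest-confidence extras with a
#' warning. The pod score is the mean merged seed confidence.
#'
#' @param pod_a,pod_b Seed tibbles of the two pods (ordered by
#'   `seed_index`).
#' @param path DTW alignment path (from [dtw_shape_distance()]); if
#'   `NULL` it is computed.
#' @param dist_thresh Duplicate-averaging gate, px.
#' @return Seed tibble of the merged pod (columns as in
#'   [as_detections()], without ids).
#' @export
merge_pair <- function(pod_a, pod_b, path = NULL, dist_thresh = 10) {
  a <- dplyr::arrange(as_tibble(pod_a), .data$seed_index)
  b <- dplyr::arrange(as_tibble(pod_b), .data$seed_index)
  if (is.null(path)) path <- dtw_shape_distance(a, b)$path
  if (inherits(path, "dtw_result")) path <- path$path

  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  merged_of_a <- vector("list", nrow(a))
  for (r in seq_len(nrow(path))) {
    i <- path[r, 1]; j <- path[r, 2]
    if (used_a[i] || used_b[j]) next
    d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2)
    if (d < dist_thresh) {
      wa <- a$seed_score[i]; wb <- b$seed_score[j]
      wsum <- max(wa + wb, 1e-12)
      merged_of_a[[i]] <- tibble(
        x = (wa * a$x[i] + wb * b$x[j]) / wsum,
        y = (wa * a$y[i] + wb * b$y[j]) / wsum,
        seed_score = max(wa, wb)
      )
      used_a[i] <- TRUE
      used_b[j] <- TRUE
    }
  }
  chain_a <- purrr::map(seq_len(nrow(a)), function(i) {
    if (used_a[i]) merged_of_a[[i]] else
      tibble(x = a$x[i], y = a$y[i], seed_score = a$seed_score[i])
  }) |> dplyr::bind_rows()
  rest_b <- b[!used_b, c("x", "y", "seed_score"), drop = FALSE]

  if (nrow(rest_b) == 0) {
    chain <- chain_a
    base_first <- TRUE # chain starts at A's base
    base_is_a <- TRUE
  } else {
    junction <- function(p, q) {
      sqrt((p$x[nrow(p)] - q$x[1])^2 + (p$y[nrow(p)] - q$y[1])^2)
    }
    rev_rows <- function(p) p[rev(seq_len(nrow(p))), , drop = FALSE]
    layouts <- list(
      ab = list(chain = dplyr::bind_rows(chain_a, rest_b),
                gap = junction(chain_a, rest_b), a_head = TRUE),
      abr = list(chain = dplyr::bind_rows(chain_a, rev_rows(rest_b)),
                 gap = junction(chain_a, rev_rows(rest_b)), a_head = TRUE),
      ba = list(chain = dplyr::bind_rows(rest_b, chain_a),
                gap = junction(rest_b, chain_a), a_head = FALSE),
      bra = list(chain = dplyr::bind_rows(rev_rows(rest_b), chain_a),
                 gap = junction(rev_rows(rest_b), chain_a), a_head = FALSE)
    )
    gaps <- vapply(layouts, function(l) l$gap, numeric(1))
    pick <- layouts[[which.min(gaps)]]
    chain <- pick$chain
    base_is_a <- a$seed_score[1] >= b$seed_score[1]
    # orient so the base part's first seed sits at the head of the chain
    base_first <- if (base_is_a) pick$a_head else !pick$a_head
  }
  if (!base_first) chain <- chain[rev(seq_len(nrow(chain))), , drop = FALSE]

  if (nrow(chain) > 5) {
    warn(sprintf("Merged pod has %d seeds; capping at 5.", nrow(chain)))
    drop <- order(chain$seed_score)[seq_len(nrow(chain) - 5)]
    chain <- chain[-drop, , drop = FALSE]
  }
  chain$seed_index <- seq_len(nrow(chain))
  chain$n_seeds <- nrow(chain)
  chain$pod_score <- mean(chain$seed_score)
  chain
}

#' Merge per-window detections into a full-image detection set
#'
#' The full merging pass: detections (already remapped to the full
#' frame, with their source window recorded) are first deduplicated
#' ([dedupe_seeds()]); then, iterating to a fixed point, cross-window
#' candidate pairs from the border bands ([border_candidates()]) whose
#' closest seed pair lies within `dist_thresh` are merged - directly
#' when either pod has a single seed, otherwise only when the DTW shape
#' distance falls below `shape_thresh`, using the DTW path as the
#' merged combination ([merge_pair()]). Pairs are processed in
#' ascending seed-pair distance for determinism.
#'
#' @param dets Detections tibble in the full-image frame with a
#'   `window` column.
#' @param windows Window tibble as from [tile_image()].
#' @param config A [merge_config()].
#' @return Detections tibble with consecutive `pod_id`s and a `window`
#'   column naming the contributing window(s).
#' @export
merge_full <- function(dets, windows, config = merge_config()) {
  stopifnot(inherits(config, "merge_config"))
  dets <- as_detections(dets)
  if (nrow(dets) == 0) return(dets)
  if (!"window" %in% names(dets)) dets$window <- "w001"
  margin <- config$border_margin
  if (is.null(margin)) {
    size <- min(windows$x_max - windows$x_min)
    stride <- if (nrow(windows) > 1) {
      xs <- sort(unique(windows$x_min))
      ys <- sort(unique(windows$y_min))
      steps <- c(diff(xs), diff(ys))
      if (length(steps) > 0 && any(steps > 0)) min(steps[steps > 0]) else size
    } else size
    margin <- max(1, size - stride)
  }

  dets <- dedupe_seeds(dets, config$dist_thresh)

  image_id <- dets$image_id[1]
  key <- paste(dets$window, dets$pod_id, sep = "\r")
  pods_list <- split(dets, factor(key, levels = unique(key)))
  pods_list <- purrr::map(pods_list, function(p) {
    tibble(window = p$window[1],
           seed_index = p$seed_index, x = p$x, y = p$y,
           seed_score = p$seed_score, pod_score = p$pod_score[1])
  })

  windows_of <- function(p) strsplit(p$window[1], "+", fixed = TRUE)[[1]]

  for (iter in seq_len(20)) {
    # flat view for candidate pairing: a merged pod appears once per
    # component window so it can still pair with third windows
    flat <- dplyr::bind_rows(purrr::imap(pods_list, function(p, nm) {
      i <- match(nm, names(pods_list))
      dplyr::bind_rows(purrr::map(windows_of(p), function(w) {
        dplyr::mutate(p, window = w, image_id = image_id, pod_id = i)
      }))
    }))
    cand <- border_candidates(as_detections(flat), windows,
                              border_margin = margin)
    if (nrow(cand) == 0) break
    cand$ia <- cand$pod_a
    cand$ib <- cand$pod_b
    cand <- cand[cand$ia != cand$ib, , drop = FALSE]
    keep <- vapply(seq_len(nrow(cand)), function(r) {
      pa <- pods_list[[cand$ia[r]]]
      pb <- pods_list[[cand$ib[r]]]
      length(intersect(windows_of(pa), windows_of(pb))) == 0
    }, logical(1))
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0) break
    cand$min_d <- vapply(seq_len(nrow(cand)), function(r) {
      pa <- pods_list[[cand$ia[r]]]
      pb <- pods_list[[cand$ib[r]]]
      min(cross_dist(cbind(pa$x, pa$y), cbind(pb$x, pb$y)))
    }, numeric(1))
    cand <- cand[cand$min_d < config$dist_thresh, , drop = FALSE]
    if (nrow(cand) == 0) break
    cand <- cand[order(cand$min_d), , drop = FALSE]

    alive <- rep(TRUE, length(pods_list))
    merged_any <- FALSE
    for (r in seq_len(nrow(cand))) {
      ia <- cand$ia[r]; ib <- cand$ib[r]
      if (!alive[ia] || !alive[ib]) next
      pa <- pods_list[[ia]]; pb <- pods_list[[ib]]
      do_merge <- FALSE
      path <- NULL
      if (nrow(pa) == 1 || nrow(pb) == 1) {
        do_merge <- TRUE
      } else {
        dtw <- dtw_shape_distance(pa, pb)
        if (dtw$distance < config$shape_thresh) {
          do_merge <- TRUE
          path <- dtw$path
        }
      }
      if (!do_merge) next
      m <- merge_pair(pa, pb, path = path,
                      dist_thresh = config$dist_thresh)
      m$window <- paste(unique(c(windows_of(pa), windows_of(pb))),
                        collapse = "+")
      m$n_seeds <- NULL
      pods_list[[ia]] <- m[c("window", "seed_index", "x", "y",
                             "seed_score", "pod_score")]
      alive[ib] <- FALSE
      merged_any <- TRUE
    }
    pods_list <- pods_list[alive]
    if (!merged_any) break
  }

  out <- dplyr::bind_rows(purrr::imap(pods_list, function(p, nm) {
    tibble(image_id = image_id, window = p$window[1],
           pod_id = 0L, seed_index = p$seed_index, x = p$x, y = p$y,
           seed_score = p$seed_score, pod_score = p$pod_score[1],
           .key = nm)
  }))
  out$pod_id <- match(out$.key, unique(out$.key))
  out$.key <- NULL
  as_detections(out)
}
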