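# Synthetic pod scenes. Pods are rendered as near-collinear chains of
# 1-5 Gaussian-profile blobs; the generator controls geometry, class
# frequencies, overlap and noise, and every draw is a pure function of
# its rng seed. Blob size and peak intensity taper slightly from base to
# tip so that seed ordinals carry a local appearance cue, as they do in
# real pods (basal seeds sit in the widest part of the pod).

#' Scene generator configuration
#'
#' Defaults emulate mature-plant crops: pod-type frequencies are
#' proportional to a large field census of 1..5-seeded pods (about
#' 19.7, 29.8, 40.5, 10.0 and 0.02 percent), seeds sit ~25 px apart,
#' and blobs have a ~6 px radius on a 400 px crop.
#'
#' @param width,height Image size in pixels.
#' @param pods_per_image Number of pods to place.
#' @param pod_type_probs Probabilities for 1..5-seeded pods; normalised
#'   internally.
#' @param seed_spacing Mean seed-to-seed distance along the pod axis, px.
#' @param spacing_jitter SD of the along-axis spacing jitter, px.
#' @param seed_radius Nominal blob radius of the basal seed, px.
#' @param radius_taper Fractional radius shrink per ordinal toward tip.
#' @param intensity_taper Fractional peak-intensity drop per ordinal.
#' @param curvature_jitter SD of perpendicular displacement, px (pod
#'   chains are near-collinear, not exactly straight).
#' @param overlap_fraction Fraction of pods deliberately placed within
#'   one `seed_spacing` of an already-placed pod.
#' @param background_noise_sd SD of additive pixel noise (intensities
#'   live in `[0, 1]`).
#' @param rng_seed Integer seed; generation is a pure function of it.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(width = 400, height = 400, pods_per_image = 8,
                         pod_type_probs = c(6462, 9778, 13266, 3266, 8),
                         seed_spacing = 25, spacing_jitter = 3,
                         seed_radius = 6, radius_taper = 0.16,
                         intensity_taper = 0.12,
                         curvature_jitter = 2, overlap_fraction = 0,
                         background_noise_sd = 0.02, rng_seed = 1L) {
  stopifnot(length(pod_type_probs) == 5, all(pod_type_probs >= 0),
            sum(pod_type_probs) > 0, seed_spacing > 0, seed_radius > 0,
            width > 0, height > 0, pods_per_image >= 0,
            overlap_fraction >= 0, overlap_fraction <= 1)
  structure(list(
    width = width, height = height, pods_per_image = pods_per_image,
    pod_type_probs = pod_type_probs / sum(pod_type_probs),
    seed_spacing = seed_spacing, spacing_jitter = spacing_jitter,
    seed_radius = seed_radius, radius_taper = radius_taper,
    intensity_taper = intensity_taper,
    curvature_jitter = curvature_jitter,
    overlap_fraction = overlap_fraction,
    background_noise_sd = background_noise_sd,
    rng_seed = as.integer(rng_seed)
  ), class = "scene_config")
}

#' Generate a synthetic pod scene
#'
#' Places `pods_per_image` pods (types drawn from `pod_type_probs`) as
#' jittered straight chains at uniform random orientations, renders each
#' seed as a Gaussian blob, and returns both the raster and the exact
#' ground-truth annotation (blob centres, ordered base to tip).
#'
#' @param config A [scene_config()].
#' @param image_id Identifier stored in the annotation.
#' @return List with elements `image` (height x width matrix in
#'   `[0, 1]`) and `annotation` (a [pod_annotation()]).
#' @export
generate_scene <- function(config = scene_config(), image_id = "scene") {
  stopifnot(inherits(config, "scene_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$rng_seed)

  margin <- config$seed_radius + 2
  placed <- list()
  all_xy <- matrix(numeric(0), ncol = 2)
  min_sep <- 2 * config$seed_radius + 4

  n_overlap <- round(config$overlap_fraction * config$pods_per_image)
  for (p in seq_len(config$pods_per_image)) {
    n <- sample.int(5, 1, prob = config$pod_type_probs)
    want_overlap <- p > 1 && (config$pods_per_image - p) < n_overlap &&
      nrow(all_xy) > 0
    pod <- NULL
    for (try in seq_len(400)) {
      theta <- runif(1, 0, 2 * pi)
      dir <- c(cos(theta), sin(theta))
      perp <- c(-dir[2], dir[1])
      steps <- cumsum(c(0, pmax(
        config$seed_spacing / 2,
        rnorm(max(0, n - 1), config$seed_spacing, config$spacing_jitter)
      )))
      if (want_overlap) {
        anchor <- all_xy[sample.int(nrow(all_xy), 1), ]
        base <- anchor + runif(2, -config$seed_spacing, config$seed_spacing)
      } else {
        base <- c(runif(1, margin, config$width - margin),
                  runif(1, margin, config$height - margin))
      }
      xy <- cbind(base[1] + steps * dir[1], base[2] + steps * dir[2])
      xy <- xy + outer(rnorm(n, 0, config$curvature_jitter), perp)
      inside <- all(xy[, 1] >= margin & xy[, 1] < config$width - margin &
                      xy[, 2] >= margin & xy[, 2] < config$height - margin)
      if (!inside) next
      if (!want_overlap && nrow(all_xy) > 0) {
        if (min(cross_dist(xy, all_xy)) < min_sep) next
      }
      pod <- xy
      break
    }
    if (is.null(pod)) {
      abort(sprintf(
        "Could not place pod %d of %d in a %g x %g image; the scene is too crowded.",
        p, config$pods_per_image, config$width, config$height
      ))
    }
    placed[[p]] <- tibble(
      pod_id = p, n_seeds = n, seed_index = seq_len(n),
      x = pod[, 1], y = pod[, 2]
    )
    all_xy <- rbind(all_xy, pod)
  }

  seeds <- if (length(placed) > 0) dplyr::bind_rows(placed) else
    tibble(pod_id = integer(), n_seeds = integer(), seed_index = integer(),
           x = numeric(), y = numeric())
  ann <- pod_annotation(seeds, image_id = image_id,
                        width = config$width, height = config$height)

  img <- matrix(0, nrow = config$height, ncol = config$width)
  for (i in seq_len(nrow(seeds))) {
    k <- seeds$seed_index[i]
    r <- config$seed_radius * max(0.3, 1 - config$radius_taper * (k - 1))
    peak <- 0.85 * max(0.3, 1 - config$intensity_taper * (k - 1))
    img <- splat_blob(img, seeds$x[i], seeds$y[i], sd = r / 1.5, peak = peak)
  }
  if (config$background_noise_sd > 0) {
    img <- img + matrix(rnorm(length(img), 0, config$background_noise_sd),
                        nrow = nrow(img))
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  list(image = img, annotation = ann)
}

# max-combine a Gaussian blob onto the raster (pixel centres at i + 0.5)
splat_blob <- function(img, x, y, sd, peak) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(3 * sd)
  cx <- floor(x); cy <- floor(y)
  cols <- max(1, cx - r + 1):min(w, cx + r + 1)
  rows <- max(1, cy - r + 1):min(h, cy + r + 1)
  px <- cols - 0.5; py <- rows - 0.5
  g <- peak * exp(-(outer((py - y)^2, (px - x)^2, "+")) / (2 * sd^2))
  img[rows, cols] <- pmax(img[rows, cols], g)
  img
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Detection perturbation configuration
#'
#' Controls the noise model used to turn a ground-truth annotation into
#' a synthetic detection set: isotropic coordinate jitter, seed/pod
#' dropout, spurious pods, and a logistic-normal score model in which
#' true pods score high and spurious pods low.
#'
#' @param loc_sd SD of per-axis coordinate jitter, px (displacements are
#'   then Rayleigh with mean `loc_sd * sqrt(pi / 2)`).
#' @param p_drop_seed,p_drop_pod,p_spurious_pod Probabilities in `[0, 1]`.
#' @param score_true,score_spurious Mean/SD of the logit-scale score
#'   draws for true and spurious pods.
#' @param rng_seed Integer seed.
#' @return A list of class `perturb_config`.
#' @export
perturb_config <- function(loc_sd = 0, p_drop_seed = 0, p_drop_pod = 0,
                           p_spurious_pod = 0,
                           score_true = c(mean = 2.2, sd = 0.6),
                           score_spurious = c(mean = -1, sd = 0.6),
                           rng_seed = 1L) {
  stopifnot(loc_sd >= 0,
            all(c(p_drop_seed, p_drop_pod, p_spurious_pod) >= 0),
            all(c(p_drop_seed, p_drop_pod, p_spurious_pod) <= 1))
  structure(list(loc_sd = loc_sd, p_drop_seed = p_drop_seed,
                 p_drop_pod = p_drop_pod, p_spurious_pod = p_spurious_pod,
                 score_true = score_true, score_spurious = score_spurious,
                 rng_seed = as.integer(rng_seed)),
            class = "perturb_config")
}

#' Perturb a ground-truth annotation into a synthetic detection set
#'
#' @param ann A [pod_annotation()].
#' @param config A [perturb_config()].
#' @return Detections tibble (see [as_detections()]). With all noise
#'   parameters zero the output equals the ground truth with unit
#'   scores.
#' @export
perturb_annotation <- function(ann, config = perturb_config()) {
  stopifnot(inherits(ann, "pod_annotation"), inherits(config, "perturb_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$rng_seed)

  seeds <- ann$seeds
  identity_noise <- config$loc_sd == 0 && config$p_drop_seed == 0 &&
    config$p_drop_pod == 0 && config$p_spurious_pod == 0
  empty <- as_detections(tibble(image_id = character(), pod_id = integer(),
                                n_seeds = integer(), seed_index = integer(),
                                x = numeric(), y = numeric(),
                                seed_score = numeric(), pod_score = numeric()))
  if (nrow(seeds) == 0) return(empty)

  pod_ids <- unique(seeds$pod_id)
  keep_pod <- runif(length(pod_ids)) >= config$p_drop_pod
  seeds <- seeds[seeds$pod_id %in% pod_ids[keep_pod], , drop = FALSE]
  if (nrow(seeds) > 0 && config$p_drop_seed > 0) {
    seeds <- seeds[runif(nrow(seeds)) >= config$p_drop_seed, , drop = FALSE]
  }

  out <- NULL
  if (nrow(seeds) > 0) {
    if (identity_noise) {
      scores <- setNames(rep(1, length(unique(seeds$pod_id))),
                         unique(seeds$pod_id))
    } else {
      ids <- unique(seeds$pod_id)
      scores <- setNames(
        stats::plogis(rnorm(length(ids), config$score_true["mean"],
                            config$score_true["sd"])), ids)
    }
    out <- tibble(
      image_id = ann$image_id,
      pod_id = seeds$pod_id,
      seed_index = seeds$seed_index,
      x = seeds$x + rnorm(nrow(seeds), 0, config$loc_sd),
      y = seeds$y + rnorm(nrow(seeds), 0, config$loc_sd),
      pod_score = unname(scores[as.character(seeds$pod_id)])
    )
    out$seed_score <- out$pod_score
    out <- dplyr::mutate(out, n_seeds = dplyr::n(), .by = "pod_id")
  }

  n_spur <- rbinom(1, length(pod_ids), config$p_spurious_pod)
  if (n_spur > 0) {
    next_id <- max(c(0L, pod_ids)) + seq_len(n_spur)
    spur <- purrr::map(seq_len(n_spur), function(i) {
      n <- sample.int(4, 1)
      theta <- runif(1, 0, 2 * pi)
      base <- c(runif(1, 10, ann$width - 10), runif(1, 10, ann$height - 10))
      sc <- stats::plogis(rnorm(1, config$score_spurious["mean"],
                                config$score_spurious["sd"]))
      tibble(image_id = ann$image_id, pod_id = next_id[i], n_seeds = n,
             seed_index = seq_len(n),
             x = base[1] + (seq_len(n) - 1) * 25 * cos(theta),
             y = base[2] + (seq_len(n) - 1) * 25 * sin(theta),
             seed_score = sc, pod_score = sc)
    })
    out <- dplyr::bind_rows(out, dplyr::bind_rows(spur))
  }
  if (is.null(out) || nrow(out) == 0) return(empty)
  as_detections(out)
}

#' Synthesise a feature map with controlled pod-level cosine structure
#'
#' Builds an `H x W x C` feature grid whose channel vectors at seed
#' locations have expected pairwise cosine similarity `within_sim` for
#' seeds of the same pod and `between_sim` for seeds of different pods;
#' all other cells hold small-amplitude noise. Vectors are mixtures of a
#' shared direction, a per-pod identity direction and per-seed noise,
#' with mixing weights chosen in closed form to hit the targets. When
#' the number of pods + 1 does not exceed `channels`, the shared and
#' identity directions are exactly orthonormal (via QR) and the targets
#' are hit exactly in the noise-free limits; with more pods than
#' channels, random unit identities are used and similarities hold only
#' in expectation.
#'
#' @param ann A [pod_annotation()] giving the seed layout.
#' @param channels Number of channels C (>= 8).
#' @param within_sim,between_sim Target cosines,
#'   `0 <= between_sim <= within_sim <= 1`.
#' @param stride Image pixels per feature cell.
#' @param noise_sd SD of background cell noise.
#' @param rng_seed Integer seed.
#' @return A [feature_map()].
#' @export
synthesize_features <- function(ann, channels = 16, within_sim = 0.8,
                                between_sim = 0.2, stride = 1,
                                noise_sd = 0.01, rng_seed = 1L) {
  stopifnot(inherits(ann, "pod_annotation"), channels >= 8)
  if (!(between_sim >= 0 && between_sim <= within_sim && within_sim <= 1)) {
    abort("Infeasible similarity targets: need 0 <= between_sim <= within_sim <= 1.")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(rng_seed)

  H <- ceiling(ann$height / stride)
  W <- ceiling(ann$width / stride)
  C <- as.integer(channels)
  vals <- array(rnorm(H * W * C, 0, noise_sd), dim = c(H, W, C))

  seeds <- ann$seeds
  if (nrow(seeds) > 0) {
    pid <- match(seeds$pod_id, unique(seeds$pod_id))
    P <- max(pid)
    if (P + 1 <= C) {
      basis <- qr.Q(qr(matrix(rnorm(C * (P + 1)), nrow = C)))
      shared <- basis[, 1]
      ident <- basis[, -1, drop = FALSE]
    } else {
      shared <- rnorm(C); shared <- shared / sqrt(sum(shared^2))
      ident <- matrix(rnorm(C * P), nrow = C)
      ident <- sweep(ident, 2, sqrt(colSums(ident^2)), "/")
    }
    a <- sqrt(between_sim)
    b <- sqrt(within_sim - between_sim)
    e <- sqrt(1 - within_sim)
    for (i in seq_len(nrow(seeds))) {
      noise <- rnorm(C)
      # orthogonalise the per-seed component against the structured parts
      noise <- noise - sum(noise * shared) * shared
      hp <- ident[, pid[i]]
      noise <- noise - sum(noise * hp) * hp
      noise <- noise / sqrt(sum(noise^2))
      v <- a * shared + b * hp + e * noise
      r <- min(H, floor(seeds$y[i] / stride) + 1)
      cc <- min(W, floor(seeds$x[i] / stride) + 1)
      vals[r, cc, ] <- v
    }
  }
  feature_map(vals, stride = stride)
}

#' Split a scene's ground truth across a window boundary
#'
#' Emulates independent per-crop detection of a scene cut by a vertical
#' (`axis = "x"`) or horizontal (`axis = "y"`) line: every pod crossing
#' the boundary is split into two partial detections whose ordinals are
#' renumbered consecutively from each side's own first seed; pods
#' entirely on one side appear unsplit on that side only.
#'
#' @param ann A [pod_annotation()].
#' @param at Boundary coordinate, must lie inside the image.
#' @param axis `"x"` (vertical boundary) or `"y"`.
#' @return List with detection tibbles `left` and `right` (their
#'   `window` columns set to `"A"`/`"B"`) and a `windows` tibble giving
#'   the two half-image crop rectangles.
#' @export
split_scene_across_windows <- function(ann, at, axis = c("x", "y")) {
  stopifnot(inherits(ann, "pod_annotation"))
  axis <- match.arg(axis)
  lim <- if (axis == "x") ann$width else ann$height
  if (!(at > 0 && at < lim)) {
    abort(sprintf("Boundary at %g does not intersect the image (0..%g).",
                  at, lim))
  }
  seeds <- ann$seeds
  side <- if (axis == "x") seeds$x < at else seeds$y < at

  part <- function(rows, tag) {
    s <- seeds[rows, , drop = FALSE]
    if (nrow(s) == 0) {
      return(tibble(image_id = character(), window = character(),
                    pod_id = integer(), n_seeds = integer(),
                    seed_index = integer(), x = numeric(), y = numeric(),
                    seed_score = numeric(), pod_score = numeric()))
    }
    s |>
      dplyr::arrange(.data$pod_id, .data$seed_index) |>
      dplyr::mutate(seed_index = dplyr::row_number(),
                    n_seeds = dplyr::n(), .by = "pod_id") |>
      dplyr::transmute(image_id = ann$image_id, window = tag,
                       pod_id = .data$pod_id, n_seeds = .data$n_seeds,
                       seed_index = .data$seed_index,
                       x = .data$x, y = .data$y,
                       seed_score = 1, pod_score = 1)
  }
  windows <- if (axis == "x") {
    tibble(window = c("A", "B"),
           x_min = c(0, at), y_min = c(0, 0),
           x_max = c(at, ann$width), y_max = c(ann$height, ann$height))
  } else {
    tibble(window = c("A", "B"),
           x_min = c(0, 0), y_min = c(0, at),
           x_max = c(ann$width, ann$width), y_max = c(at, ann$height))
  }
  list(left = part(side, "A"), right = part(!side, "B"), windows = windows)
}
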