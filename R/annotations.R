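#' Parse seed-to-pod point labels
#'
#' Every annotated seed carries a text label of the form `"n-k(id)"`:
#' `n` is the declared number of seeds in the pod (1--5), `k` the 1-based
#' ordinal of this seed counted from the pod base, and `id` an integer
#' identifier unique to the pod within its image. `"3-2(58)"` therefore
#' reads "seed 2 of a 3-seeded pod with id 58". Whitespace around tokens
#' is tolerated; no other dialect is accepted.
#'
#' @param text Character vector of labels.
#' @return A tibble with one row per label and columns `n_seeds`,
#'   `seed_index`, `pod_id` (all integer).
#' @examples
#' parse_seed_label("3-2(58)")
#' parse_seed_label(c("1-1(0)", "5-5(123)"))
#' @export
parse_seed_label <- function(text) {
  if (!is.character(text)) {
    abort("`text` must be a character vector of seed labels.")
  }
  rx <- "^\\s*([0-9]+)\\s*-\\s*([0-9]+)\\s*\\(\\s*([0-9]+)\\s*\\)\\s*$"
  ok <- grepl(rx, text)
  if (any(!ok)) {
    bad <- text[!ok][1]
    abort(sprintf(
      "Malformed seed label %s: expected the form \"n-k(id)\".",
      encodeString(bad, quote = "\"")
    ))
  }
  n <- as.integer(sub(rx, "\\1", text))
  k <- as.integer(sub(rx, "\\2", text))
  id <- as.integer(sub(rx, "\\3", text))
  if (any(n < 1L | n > 5L)) {
    i <- which(n < 1L | n > 5L)[1]
    abort(sprintf(
      "Inconsistent seed label \"%s\": seed count n = %d outside 1..5.",
      text[i], n[i]
    ))
  }
  if (any(k < 1L | k > n)) {
    i <- which(k < 1L | k > n)[1]
    abort(sprintf(
      "Inconsistent seed label \"%s\": seed index %d outside 1..%d.",
      text[i], k[i], n[i]
    ))
  }
  tibble(n_seeds = n, seed_index = k, pod_id = id)
}

#' Format seed labels from their components
#'
#' Inverse of [parse_seed_label()].
#'
#' @param n_seeds,seed_index,pod_id Integer vectors (recycled).
#' @return Character vector of `"n-k(id)"` labels.
#' @export
seed_label <- function(n_seeds, seed_index, pod_id) {
  sprintf("%d-%d(%d)", as.integer(n_seeds), as.integer(seed_index),
          as.integer(pod_id))
}

#' Construct an image annotation
#'
#' An image annotation bundles the image identity and size with the seed
#' table. Seeds are stored one row per seed with columns `pod_id`,
#' `n_seeds`, `seed_index`, `x`, `y` and a pod-level `truncated` flag
#' (TRUE when some ordinals of the pod are missing, as happens when a
#' crop cuts through a pod).
#'
#' @param seeds Tibble of seed rows; passed through [assemble_pods()]
#'   for validation and ordering.
#' @param image_id Character scalar.
#' @param width,height Image size in pixels.
#' @return An object of class `pod_annotation`.
#' @export
pod_annotation <- function(seeds, image_id = "image", width, height) {
  seeds <- assemble_pods(seeds)
  if (nrow(seeds) > 0) {
    out <- seeds$x < 0 | seeds$x >= width | seeds$y < 0 | seeds$y >= height
    if (any(out)) {
      abort(sprintf(
        "%d seed(s) fall outside the %g x %g image bounds.",
        sum(out), width, height
      ))
    }
  }
  structure(
    list(image_id = as.character(image_id), width = as.numeric(width),
         height = as.numeric(height), seeds = seeds),
    class = "pod_annotation"
  )
}

#' @export
print.pod_annotation <- function(x, ...) {
  cat(sprintf("<pod_annotation> %s (%g x %g px): %d pod(s), %d seed(s)\n",
              x$image_id, x$width, x$height,
              dplyr::n_distinct(x$seeds$pod_id), nrow(x$seeds)))
  invisible(x)
}

#' Assemble labelled seed points into pods
#'
#' Groups seed rows by `pod_id`, orders seeds by ordinal within each pod,
#' and validates the grouping: duplicate `(pod_id, seed_index)` pairs and
#' disagreement on the declared seed count within a pod are errors. Pods
#' with missing ordinals (e.g. ordinals 1 and 3 present but not 2) are
#' retained and flagged `truncated` rather than rejected, because crop
#' windows legitimately cut pods.
#'
#' @param points Tibble (or data frame) with columns `pod_id`, `n_seeds`,
#'   `seed_index`, `x`, `y`. Extra columns are carried through.
#' @return A tibble ordered by `pod_id`, `seed_index`, with a logical
#'   `truncated` column.
#' @export
assemble_pods <- function(points) {
  points <- as_tibble(points)
  need <- c("pod_id", "n_seeds", "seed_index", "x", "y")
  miss <- setdiff(need, names(points))
  if (length(miss) > 0) {
    abort(paste0("`points` lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(points) == 0) {
    points$truncated <- logical(0)
    return(points)
  }
  bad_n <- points$n_seeds < 1 | points$n_seeds > 5 |
    points$seed_index < 1 | points$seed_index > points$n_seeds
  if (any(bad_n)) {
    abort("Seed rows violate 1 <= seed_index <= n_seeds <= 5.")
  }
  dup <- duplicated(points[c("pod_id", "seed_index")])
  if (any(dup)) {
    d <- points[dup, ][1, ]
    abort(sprintf("Duplicate seed ordinal %d in pod %d.",
                  d$seed_index, d$pod_id))
  }
  disagree <- points |>
    dplyr::summarise(k = dplyr::n_distinct(.data$n_seeds),
                     .by = "pod_id") |>
    dplyr::filter(.data$k > 1)
  if (nrow(disagree) > 0) {
    abort(sprintf("Pod %d members disagree on the declared seed count.",
                  disagree$pod_id[1]))
  }
  points |>
    dplyr::mutate(
      truncated = dplyr::n() < .data$n_seeds[1] ||
        !identical(sort(.data$seed_index), seq_len(dplyr::n())),
      .by = "pod_id"
    ) |>
    dplyr::relocate("pod_id", "n_seeds", "seed_index", "x", "y") |>
    dplyr::arrange(.data$pod_id, .data$seed_index)
}

#' Per-pod summary of an annotation
#'
#' @param x A `pod_annotation` or a seeds tibble.
#' @return Tibble with one row per pod: `pod_id`, `n_seeds` (declared),
#'   `n_present` (seeds actually present), `truncated`.
#' @export
pods <- function(x) {
  seeds <- if (inherits(x, "pod_annotation")) x$seeds else as_tibble(x)
  if (nrow(seeds) == 0) {
    return(tibble(pod_id = integer(), n_seeds = integer(),
                  n_present = integer(), truncated = logical()))
  }
  if (!"truncated" %in% names(seeds)) seeds$truncated <- FALSE
  seeds |>
    dplyr::summarise(
      n_seeds = .data$n_seeds[1],
      n_present = dplyr::n(),
      truncated = any(.data$truncated),
      .by = "pod_id"
    )
}

#' Axis-aligned bounding boxes of pods
#'
#' Returns the minimal axis-aligned rectangle containing each pod's
#' seeds, expanded by `pad` pixels on every side and, when image
#' dimensions are supplied, clamped to the image.
#'
#' @param seeds Seeds tibble or `pod_annotation` (all pods are boxed).
#' @param pad Padding in pixels added on each side.
#' @param width,height Optional image bounds used for clamping.
#' @return Tibble with columns `pod_id`, `x_min`, `y_min`, `x_max`,
#'   `y_max`, `area`.
#' @export
pod_bounding_box <- function(seeds, pad = 0, width = NULL, height = NULL) {
  if (inherits(seeds, "pod_annotation")) {
    if (is.null(width)) width <- seeds$width
    if (is.null(height)) height <- seeds$height
    seeds <- seeds$seeds
  }
  seeds <- as_tibble(seeds)
  if (nrow(seeds) == 0) {
    abort("Cannot compute a bounding box for a pod with zero seeds.")
  }
  box <- seeds |>
    dplyr::summarise(
      x_min = min(.data$x) - pad, y_min = min(.data$y) - pad,
      x_max = max(.data$x) + pad, y_max = max(.data$y) + pad,
      .by = "pod_id"
    )
  if (!is.null(width)) {
    box$x_min <- pmax(box$x_min, 0)
    box$x_max <- pmin(box$x_max, width)
  }
  if (!is.null(height)) {
    box$y_min <- pmax(box$y_min, 0)
    box$y_max <- pmin(box$y_max, height)
  }
  box$area <- (box$x_max - box$x_min) * (box$y_max - box$y_min)
  box
}
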