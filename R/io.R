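#' Read a Labelme-style point annotation document
#'
#' Reads the JSON dialect produced by the Labelme annotation tool: a
#' `shapes` array of point shapes, each with a `label` string in the
#' seed-to-pod grammar (see [parse_seed_label()]) and a single `[x, y]`
#' coordinate, plus `imageWidth`/`imageHeight`. Non-point shapes are
#' skipped with a warning; an unparsable label is an error naming the
#' shape index.
#'
#' @param path Path to the JSON file.
#' @return A [pod_annotation()].
#' @export
read_labelme <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  labelme_to_annotation(doc, image_id = doc$imagePath %||%
                          tools::file_path_sans_ext(basename(path)))
}

labelme_to_annotation <- function(doc, image_id = "image") {
  shapes <- doc$shapes %||% list()
  keep <- vapply(shapes, function(s) identical(s$shape_type, "point"),
                 logical(1))
  if (any(!keep)) {
    warn(sprintf("Skipping %d non-point shape(s).", sum(!keep)))
  }
  shapes <- shapes[keep]
  rows <- purrr::imap(shapes, function(s, i) {
    lab <- tryCatch(parse_seed_label(s$label),
                    error = function(e) {
                      abort(sprintf("Shape %d: %s", i, conditionMessage(e)))
                    })
    pt <- s$points[[1]]
    dplyr::mutate(lab, x = as.numeric(pt[[1]]), y = as.numeric(pt[[2]]))
  })
  seeds <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    tibble(pod_id = integer(), n_seeds = integer(), seed_index = integer(),
           x = numeric(), y = numeric())
  pod_annotation(seeds, image_id = image_id,
                 width = as.numeric(doc$imageWidth),
                 height = as.numeric(doc$imageHeight))
}

#' Write a Labelme-style point annotation document
#'
#' Emits the same dialect [read_labelme()] consumes, so that
#' write-then-read reproduces the annotation exactly.
#'
#' @param ann A [pod_annotation()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_labelme <- function(ann, path) {
  stopifnot(inherits(ann, "pod_annotation"))
  shapes <- purrr::pmap(
    ann$seeds[c("n_seeds", "seed_index", "pod_id", "x", "y")],
    function(n_seeds, seed_index, pod_id, x, y) {
      list(
        label = seed_label(n_seeds, seed_index, pod_id),
        points = list(c(x, y)),
        group_id = NULL,
        shape_type = "point",
        flags = setNames(list(), character(0))
      )
    }
  )
  doc <- list(
    version = "5.0.1",
    flags = setNames(list(), character(0)),
    shapes = shapes,
    imagePath = ann$image_id,
    imageData = NULL,
    imageHeight = ann$height,
    imageWidth = ann$width
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# ---- detections ------------------------------------------------------------

#' Construct or validate a detections table
#'
#' Detections are the common currency of decoding, merging and
#' evaluation: a tibble with one row per detected seed and columns
#' `image_id`, `pod_id` (detection-local identifier), `n_seeds`
#' (detected seed count of the pod), `seed_index` (1-based ordinal from
#' the base), `x`, `y`, `seed_score`, `pod_score`, and optionally
#' `window` (source crop window id, used by merging).
#'
#' @param x Data frame to validate/coerce.
#' @return The validated tibble.
#' @export
as_detections <- function(x) {
  x <- as_tibble(x)
  need <- c("pod_id", "seed_index", "x", "y")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("Detections lack column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"image_id" %in% names(x)) x$image_id <- "image"
  if (!"seed_score" %in% names(x)) x$seed_score <- 1
  if (!"n_seeds" %in% names(x)) {
    x <- dplyr::mutate(x, n_seeds = dplyr::n(), .by = c("image_id", "pod_id"))
  }
  if (!"pod_score" %in% names(x)) {
    x <- dplyr::mutate(x, pod_score = mean(.data$seed_score),
                       .by = c("image_id", "pod_id"))
  }
  dplyr::arrange(x, .data$image_id, .data$pod_id, .data$seed_index)
}

#' Convert a ground-truth annotation to a detections table
#'
#' Useful for identity fixtures: every seed becomes a detection with
#' unit score.
#'
#' @param ann A [pod_annotation()].
#' @return Detections tibble (see [as_detections()]).
#' @export
annotation_to_detections <- function(ann) {
  stopifnot(inherits(ann, "pod_annotation"))
  seeds <- ann$seeds
  if (nrow(seeds) == 0) {
    return(as_detections(tibble(image_id = character(), pod_id = integer(),
                                seed_index = integer(), x = numeric(),
                                y = numeric())))
  }
  as_detections(tibble(
    image_id = ann$image_id,
    pod_id = seeds$pod_id,
    n_seeds = seeds$n_seeds,
    seed_index = seeds$seed_index,
    x = seeds$x, y = seeds$y,
    seed_score = 1, pod_score = 1
  ))
}

#' Write detections as COCO-keypoints-style JSON
#'
#' One record per pod with a 5-slot `keypoints` array in the COCO
#' `(x, y, v)` layout: present seeds get their coordinates with
#' visibility 2, absent slots are zero-filled with visibility 0.
#' Seed-level scores ride along in a `seed_scores` array; the declared
#' seed count in `n_seeds`.
#'
#' @param dets Detections tibble.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_coco_detections <- function(dets, path) {
  dets <- as_detections(dets)
  recs <- dets |>
    tidyr::nest(.by = c("image_id", "pod_id", "n_seeds", "pod_score")) |>
    purrr::pmap(function(image_id, pod_id, n_seeds, pod_score, data) {
      kp <- rep(0, 15)
      sc <- rep(0, 5)
      for (i in seq_len(nrow(data))) {
        k <- data$seed_index[i]
        kp[3 * k - 2] <- data$x[i]
        kp[3 * k - 1] <- data$y[i]
        kp[3 * k] <- 2
        sc[k] <- data$seed_score[i]
      }
      list(image_id = image_id, id = pod_id, category_id = 1,
           keypoints = kp, seed_scores = sc,
           num_keypoints = nrow(data), n_seeds = n_seeds,
           score = pod_score)
    })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read COCO-keypoints-style detections
#'
#' Inverse of [write_coco_detections()].
#'
#' @param path JSON path.
#' @return Detections tibble.
#' @export
read_coco_detections <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- purrr::map(recs, function(r) {
    kp <- unlist(r$keypoints)
    sc <- unlist(r$seed_scores %||% rep(1, 5))
    k <- which(kp[seq(3, 15, by = 3)] > 0)
    if (length(k) == 0) return(NULL)
    tibble(
      image_id = as.character(r$image_id), pod_id = as.integer(r$id),
      n_seeds = as.integer(r$n_seeds %||% length(k)),
      seed_index = as.integer(k),
      x = kp[3 * k - 2], y = kp[3 * k - 1],
      seed_score = sc[k], pod_score = as.numeric(r$score %||% 1)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(as_detections(tibble(image_id = character(), pod_id = integer(),
                                seed_index = integer(), x = numeric(),
                                y = numeric())))
  }
  as_detections(out)
}
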