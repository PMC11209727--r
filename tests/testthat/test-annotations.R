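test_that("seed labels parse per the n-k(id) grammar", {
  expect_equal(parse_seed_label("3-2(58)"),
               tibble::tibble(n_seeds = 3L, seed_index = 2L, pod_id = 58L))
  expect_equal(parse_seed_label("1-1(0)"),
               tibble::tibble(n_seeds = 1L, seed_index = 1L, pod_id = 0L))
  expect_equal(parse_seed_label("5-5(123)"),
               tibble::tibble(n_seeds = 5L, seed_index = 5L, pod_id = 123L))
  # whitespace is tolerated around tokens, nothing else is
  expect_equal(parse_seed_label(" 3 - 2 ( 58 ) ")$pod_id, 58L)
  # vectorised
  got <- parse_seed_label(c("2-1(9)", "2-2(9)"))
  expect_equal(got$seed_index, c(1L, 2L))
})

test_that("malformed or inconsistent labels are rejected with context", {
  expect_error(parse_seed_label("pod3"), "Malformed.*pod3")
  expect_error(parse_seed_label("3-2"), "Malformed")
  expect_error(parse_seed_label("3.5-2(1)"), "Malformed")
  expect_error(parse_seed_label("2-3(4)"), "Inconsistent.*index")
  expect_error(parse_seed_label("6-1(2)"), "outside 1..5")
  expect_error(parse_seed_label("0-0(1)"), "outside 1..5")
})

test_that("seed_label is the inverse of parse_seed_label", {
  labs <- c("1-1(0)", "3-2(58)", "5-5(123)", "4-1(7)")
  p <- parse_seed_label(labs)
  expect_equal(seed_label(p$n_seeds, p$seed_index, p$pod_id), labs)
})

test_that("assemble_pods groups, orders and flags truncation", {
  pts <- dplyr::bind_rows(
    tibble::tibble(pod_id = 7L, n_seeds = 3L, seed_index = 3:1,
                   x = c(30, 20, 10), y = 5),
    tibble::tibble(pod_id = 4L, n_seeds = 1L, seed_index = 1L, x = 1, y = 1)
  )
  got <- assemble_pods(pts)
  expect_equal(got$pod_id, c(4L, 7L, 7L, 7L))
  expect_equal(got$x[got$pod_id == 7], c(10, 20, 30))
  expect_false(any(got$truncated))

  # permutation invariance of the input order
  perm <- assemble_pods(pts[sample(nrow(pts)), ])
  expect_equal(perm, got)

  # missing interior ordinal -> truncated, not an error
  tr <- assemble_pods(tibble::tibble(pod_id = 1L, n_seeds = 3L,
                                     seed_index = c(1L, 3L),
                                     x = c(0, 2), y = 0))
  expect_true(all(tr$truncated))

  # when nothing is truncated, declared seeds add up to the point count
  expect_equal(sum(pods(got)$n_seeds), nrow(pts))
})

test_that("assemble_pods rejects duplicate ordinals and n disagreement", {
  expect_error(assemble_pods(
    tibble::tibble(pod_id = 9L, n_seeds = 2L, seed_index = c(1L, 1L),
                   x = c(0, 5), y = 0)), "Duplicate")
  expect_error(assemble_pods(
    tibble::tibble(pod_id = 9L, n_seeds = c(2L, 3L), seed_index = c(1L, 2L),
                   x = c(0, 5), y = 0)), "disagree")
})

test_that("pod bounding boxes follow min/max arithmetic with pad and clamp", {
  degen <- pod_bounding_box(tibble::tibble(pod_id = 1, x = c(10, 10),
                                           y = c(10, 30)))
  expect_equal(unlist(degen[c("x_min", "y_min", "x_max", "y_max")]),
               c(x_min = 10, y_min = 10, x_max = 10, y_max = 30))

  padded <- pod_bounding_box(tibble::tibble(pod_id = 1, x = c(0, 4),
                                            y = c(0, 3)), pad = 2)
  expect_equal(unlist(padded[c("x_min", "y_min", "x_max", "y_max")]),
               c(x_min = -2, y_min = -2, x_max = 6, y_max = 5))

  single <- pod_bounding_box(tibble::tibble(pod_id = 1, x = 5, y = 5),
                             pad = 1)
  expect_equal(single$area, 4)

  clamped <- pod_bounding_box(tibble::tibble(pod_id = 1, x = 1, y = 1),
                              pad = 5, width = 10, height = 10)
  expect_equal(unlist(clamped[c("x_min", "y_min")]),
               c(x_min = 0, y_min = 0))

  expect_error(pod_bounding_box(tibble::tibble(pod_id = integer(),
                                               x = numeric(), y = numeric())),
               "zero seeds")
})

test_that("labelme documents round-trip bit-identically", {
  sc <- crop_scene(31, width = 200, height = 200, pods = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_labelme(sc$annotation, path)
  back <- read_labelme(path)
  expect_equal(back$seeds, sc$annotation$seeds)
  expect_equal(back$width, sc$annotation$width)
  expect_equal(back$height, sc$annotation$height)

  # write(load(doc)) reproduces the document's shapes exactly
  path2 <- withr::local_tempfile(fileext = ".json")
  write_labelme(back, path2)
  expect_equal(jsonlite::read_json(path)$shapes,
               jsonlite::read_json(path2)$shapes)
})

test_that("labelme reader skips non-point shapes and names bad labels", {
  doc <- list(
    shapes = list(
      list(label = "2-1(3)", points = list(c(10, 10)),
           shape_type = "point"),
      list(label = "whatever", points = list(c(0, 0), c(5, 5)),
           shape_type = "rectangle"),
      list(label = "2-2(3)", points = list(c(20, 12)),
           shape_type = "point")
    ),
    imageWidth = 100, imageHeight = 100
  )
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_warning(ann <- read_labelme(path), "non-point")
  expect_equal(nrow(ann$seeds), 2)

  doc$shapes[[2]] <- list(label = "oops", points = list(c(1, 1)),
                          shape_type = "point")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_error(suppressWarnings(read_labelme(path)), "Shape 2")
})

test_that("empty documents load as empty annotations", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(shapes = list(), imageWidth = 50,
                            imageHeight = 40),
                       path, auto_unbox = TRUE)
  ann <- read_labelme(path)
  expect_equal(nrow(ann$seeds), 0)
  expect_equal(nrow(pods(ann)), 0)
})

test_that("COCO-style detections round-trip, zero-filling absent slots", {
  sc <- crop_scene(32, width = 200, height = 200, pods = 3)
  dets <- annotation_to_detections(sc$annotation)
  path <- withr::local_tempfile(fileext = ".json")
  write_coco_detections(dets, path)
  back <- read_coco_detections(path)
  expect_equal(back$x, dets$x)
  expect_equal(back$y, dets$y)
  expect_equal(back$seed_index, dets$seed_index)
  expect_equal(back$n_seeds, dets$n_seeds)

  raw <- jsonlite::read_json(path)
  kp <- unlist(raw[[1]]$keypoints)
  expect_length(kp, 15)
  n1 <- sum(unlist(lapply(seq(3, 15, 3), function(i) kp[i] > 0)))
  expect_equal(n1, raw[[1]]$num_keypoints)
})
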