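# Shared fixtures: everything is generated in code at test time.

# a small crop-sized scene, deterministic in `seed`
crop_scene <- function(seed, width = 128, height = 128, pods = 2) {
  generate_scene(
    scene_config(width = width, height = height, pods_per_image = pods,
                 rng_seed = seed),
    image_id = sprintf("crop%04d", seed)
  )
}

# build an annotation straight from seed rows
ann_of <- function(..., width = 200, height = 200, image_id = "fix") {
  pod_annotation(tibble::tribble(...), image_id = image_id,
                 width = width, height = height)
}

# one straight horizontal pod with n seeds starting at (x0, y0)
line_pod <- function(pod_id, n, x0, y0, spacing = 25) {
  tibble::tibble(pod_id = pod_id, n_seeds = n, seed_index = seq_len(n),
                 x = x0 + (seq_len(n) - 1) * spacing, y = y0)
}

# perfect per-crop detections for a tiled scene, remapped to full frame
tiled_perfect_detections <- function(ann, windows) {
  out <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    ca <- crop_annotation(ann, w)
    if (nrow(ca$seeds) == 0) return(NULL)
    remap_to_full(annotation_to_detections(ca), w)
  })
  dplyr::bind_rows(out)
}
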