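# A compact pure-R convolutional detector used to exercise the full
# training objective (heatmaps + offsets + structural prior) at desk
# scale. Convolutions are evaluated as matrix products via im2col (BLAS
# does the heavy lifting); gradients are hand-derived. The trunk is a
# plain encoder, not a high-resolution backbone: the quantities under
# study here are the losses, the decoding and the evaluation metrics,
# not backbone capacity.
#
# Architecture (input H x W x 1, output stride 4):
#   conv1 5x5/2         ->  8 ch, ReLU
#   conv2 3x3/2         -> 16 ch, ReLU
#   conv3 3x3/1, dil 2  -> 16 ch, ReLU
#   conv4 3x3/1, dil 4  -> 16 ch, ReLU
#   conv5 3x3/1, dil 8  -> 16 ch, ReLU   <- structural-prior feature tap
#   heads 5x5/1         -> 16 ch: 6 sigmoid heatmaps + 10 linear offsets
# The heatmap and offset branches are one shared convolution over the
# trunk tap, sliced into the two outputs (equivalent to two parallel
# head convolutions, evaluated with a single gather).
# The dilations grow the receptive field to ~137 input px, enough to
# regress every seed of a 4-5-seeded pod (~75-100 px) from a candidate
# cell at either end of the chain.

# ---- im2col ----------------------------------------------------------------

.pk_idx_cache <- new.env(parent = emptyenv())

im2col_index <- function(H, W, Cin, k, stride, pad, dilation = 1) {
  key <- paste(H, W, Cin, k, stride, pad, dilation, sep = "_")
  hit <- .pk_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  keff <- (k - 1) * dilation + 1 # effective kernel span
  Hp <- H + 2 * pad; Wp <- W + 2 * pad
  Ho <- (Hp - keff) %/% stride + 1
  Wo <- (Wp - keff) %/% stride + 1
  r0 <- (seq_len(Ho) - 1) * stride # top-left row offset (0-based, padded)
  c0 <- (seq_len(Wo) - 1) * stride
  # output cells in column-major order over (Ho, Wo)
  cell_r <- rep(r0, times = Wo)
  cell_c <- rep(c0, each = Ho)
  # patch entries in column-major order over (kr, kc, ci)
  taps <- (seq_len(k) - 1) * dilation + 1
  kr <- rep(taps, times = k * Cin)
  kc <- rep(rep(taps, each = k), times = Cin)
  ci <- rep(seq_len(Cin), each = k * k)
  rows_in <- outer(cell_r, kr, "+")                  # (HoWo) x (k2Cin)
  cols_in <- outer(cell_c, kc, "+")
  lin <- rows_in + (cols_in - 1) * Hp +
    matrix((ci - 1) * Hp * Wp, nrow = Ho * Wo, ncol = k * k * Cin,
           byrow = TRUE)
  storage.mode(lin) <- "integer" # integer gather is much faster
  out <- list(idx = lin, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp,
              k = k, Cin = Cin, pad = pad, stride = stride,
              dilation = dilation, kr = kr, kc = kc, ci = ci)
  .pk_idx_cache[[key]] <- out
  out
}

pad_input <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  xp <- array(0, dim = c(d[1] + 2 * pad, d[2] + 2 * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  xp
}

conv_forward <- function(x, layer, stride, pad, dilation = 1) {
  d <- dim(x)
  ix <- im2col_index(d[1], d[2], d[3], layer$k, stride, pad, dilation)
  xp <- pad_input(x, pad)
  xcol <- xp[ix$idx]
  dim(xcol) <- dim(ix$idx)
  y <- xcol %*% layer$W
  for (j in seq_along(layer$b)) y[, j] <- y[, j] + layer$b[j]
  dim(y) <- c(ix$Ho, ix$Wo, ncol(layer$W))
  list(out = y, xcol = xcol, ix = ix, in_dim = d)
}

conv_backward <- function(dy, cache, layer, need_dx = TRUE) {
  dy_mat <- dy
  dim(dy_mat) <- c(nrow(cache$xcol), length(dy) / nrow(cache$xcol))
  dW <- crossprod(cache$xcol, dy_mat)
  db <- colSums(dy_mat)
  dx <- NULL
  if (need_dx) {
    ix <- cache$ix
    d <- cache$in_dim
    if (ix$stride == 1 && ix$pad == (ix$k - 1) * ix$dilation / 2) {
      # same-padding stride-1 conv: dX is a correlation of dY with the
      # spatially flipped, channel-transposed kernel
      k <- ix$k
      cout <- ncol(layer$W)
      Wa <- array(layer$W, dim = c(k, k, ix$Cin, cout))
      Wf <- matrix(aperm(Wa[k:1, k:1, , , drop = FALSE], c(1, 2, 4, 3)),
                   nrow = k * k * cout, ncol = ix$Cin)
      dy_arr <- dy_mat
      dim(dy_arr) <- c(ix$Ho, ix$Wo, cout)
      dx <- conv_forward(dy_arr, list(W = Wf, b = rep(0, ix$Cin), k = k),
                         stride = 1, pad = ix$pad,
                         dilation = ix$dilation)$out
    } else {
      dxcol <- tcrossprod(dy_mat, layer$W) # (HoWo) x (k2Cin)
      dxp <- array(0, dim = c(ix$Hp, ix$Wp, ix$Cin))
      # scatter-add one patch column at a time (strided blocks)
      for (q in seq_len(ncol(dxcol))) {
        rr <- ix$kr[q] + (seq_len(ix$Ho) - 1L) * ix$stride
        cc <- ix$kc[q] + (seq_len(ix$Wo) - 1L) * ix$stride
        ch <- ix$ci[q]
        dxp[rr, cc, ch] <- dxp[rr, cc, ch] +
          matrix(dxcol[, q], ix$Ho, ix$Wo)
      }
      p <- ix$pad
      dx <- dxp[p + seq_len(d[1]), p + seq_len(d[2]), , drop = FALSE]
    }
  }
  list(dW = dW, db = db, dx = dx)
}

new_conv <- function(k, cin, cout, gain = 2) {
  fan_in <- k * k * cin
  list(W = matrix(rnorm(fan_in * cout, 0, sqrt(gain / fan_in)),
                  nrow = fan_in, ncol = cout),
       b = rep(0, cout), k = k)
}

# ---- model -----------------------------------------------------------------

pod_net_init <- function(channels = 16, rng_seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(rng_seed)
  list(
    conv1 = new_conv(5, 1, 8),
    conv2 = new_conv(3, 8, channels),
    conv3 = new_conv(3, channels, channels),
    conv4 = new_conv(3, channels, channels),
    conv5 = new_conv(3, channels, channels),
    heads = new_conv(5, channels, 16, gain = 1)
  )
}

pod_net_forward <- function(params, image, keep_cache = FALSE,
                            off_gain = 8) {
  x <- array(image, dim = c(nrow(image), ncol(image), 1))
  c1 <- conv_forward(x, params$conv1, stride = 2, pad = 2)
  a1 <- pmax(c1$out, 0)
  c2 <- conv_forward(a1, params$conv2, stride = 2, pad = 1)
  a2 <- pmax(c2$out, 0)
  c3 <- conv_forward(a2, params$conv3, stride = 1, pad = 2, dilation = 2)
  a3 <- pmax(c3$out, 0)
  c4 <- conv_forward(a3, params$conv4, stride = 1, pad = 4, dilation = 4)
  a4 <- pmax(c4$out, 0)
  c5 <- conv_forward(a4, params$conv5, stride = 1, pad = 8, dilation = 8)
  feat <- pmax(c5$out, 0)
  hd <- conv_forward(feat, params$heads, stride = 1, pad = 2)
  heat <- 1 / (1 + exp(-hd$out[, , 1:6, drop = FALSE]))
  # the offset head works in O(1) units; a fixed gain maps them to cells
  out <- list(heatmaps = heat,
              offsets = hd$out[, , 7:16, drop = FALSE] * off_gain,
              features = feat)
  if (keep_cache) {
    out$cache <- list(c1 = c1, a1 = a1, c2 = c2, a2 = a2, c3 = c3,
                      a3 = a3, c4 = c4, a4 = a4, c5 = c5, feat = feat,
                      hd = hd)
  }
  out
}

pod_net_backward <- function(params, fwd, dheat, doff, dfeat_extra = NULL,
                             off_gain = 8) {
  cache <- fwd$cache
  # through sigmoid for the heat slice; linear (with gain) for offsets
  dz_heat <- dheat * fwd$heatmaps * (1 - fwd$heatmaps)
  dz <- array(0, dim = dim(cache$hd$out))
  dz[, , 1:6] <- dz_heat
  dz[, , 7:16] <- doff * off_gain
  ghd <- conv_backward(dz, cache$hd, params$heads)
  dfeat <- ghd$dx
  if (!is.null(dfeat_extra)) dfeat <- dfeat + dfeat_extra
  dfeat <- dfeat * (cache$c5$out > 0)
  g5 <- conv_backward(dfeat, cache$c5, params$conv5)
  da4 <- g5$dx * (cache$c4$out > 0)
  g4 <- conv_backward(da4, cache$c4, params$conv4)
  da3 <- g4$dx * (cache$c3$out > 0)
  g3 <- conv_backward(da3, cache$c3, params$conv3)
  da2 <- g3$dx * (cache$c2$out > 0)
  g2 <- conv_backward(da2, cache$c2, params$conv2)
  da1 <- g2$dx * (cache$c1$out > 0)
  g1 <- conv_backward(da1, cache$c1, params$conv1, need_dx = FALSE)
  list(conv1 = g1, conv2 = g2, conv3 = g3, conv4 = g4, conv5 = g5,
       heads = ghd)
}

# ---- losses and their gradients -------------------------------------------

sl1_grad <- function(x, beta = 1) {
  pmin(pmax(x / beta, -1), 1)
}

# returns loss components plus gradients wrt heatmaps (post-sigmoid),
# offsets and the feature tap
toy_loss_grads <- function(fwd, targets, seeds, rho, gamma, beta = 1,
                           stride = 4, offset_loss_scale = 30) {
  hp <- fwd$heatmaps; ht <- targets$heatmaps
  w <- targets$heat_weights / sum(targets$heat_weights)
  l_heat <- sum(w * (hp - ht)^2)
  dheat <- 2 * w * (hp - ht)

  op <- fwd$offsets; ot <- targets$offsets
  m <- targets$offset_mask
  active <- sum(m > 0)
  if (active > 0) {
    # the per-entry normalisations leave the heat and offset terms on
    # very different scales; a fixed rescale restores balance at the
    # reference gamma
    z <- (op - ot) * m
    l_p <- offset_loss_scale * sum(smooth_l1(z, beta)) / active
    doff <- offset_loss_scale * sl1_grad(z, beta) * m / active
  } else {
    l_p <- 0
    doff <- array(0, dim = dim(op))
  }

  l_sprior <- 0
  dfeat <- NULL
  if (rho > 0 && nrow(seeds) >= 2) {
    Hp <- dim(fwd$features)[1]; Wp <- dim(fwd$features)[2]
    C <- dim(fwd$features)[3]
    rr <- pmin(pmax(floor(seeds$y / stride) + 1, 1), Hp)
    cc <- pmin(pmax(floor(seeds$x / stride) + 1, 1), Wp)
    N <- nrow(seeds)
    V <- matrix(0, N, C)
    for (i in seq_len(N)) V[i, ] <- fwd$features[rr[i], cc[i], ]
    nrm <- pmax(sqrt(rowSums(V^2)), 1e-8)
    A <- (V %*% t(V)) / outer(nrm, nrm)
    diag(A) <- 1
    Tm <- sprior_target(seeds$pod_id)
    l_sprior <- sum((A - Tm)^2) / N^2
    E <- 4 * (A - Tm) / N^2
    diag(E) <- 0
    dV <- (E / outer(nrm, nrm)) %*% V -
      (rowSums(E * A) / nrm^2) * V
    dfeat <- array(0, dim = dim(fwd$features))
    for (i in seq_len(N)) {
      dfeat[rr[i], cc[i], ] <- dfeat[rr[i], cc[i], ] + rho * dV[i, ]
    }
  }

  list(l_heatmaps = l_heat, l_p = l_p, l_sprior = l_sprior,
       total = l_heat + gamma * l_p + rho * l_sprior,
       dheat = dheat, doff = doff, dfeat = dfeat)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  purrr::map(params, function(l) {
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    s <- state[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    mhW <- s$mW / (1 - beta1^t); vhW <- s$vW / (1 - beta2^t)
    mhb <- s$mb / (1 - beta1^t); vhb <- s$vb / (1 - beta2^t)
    params[[nm]]$W <- params[[nm]]$W - lr * mhW / (sqrt(vhW) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * mhb / (sqrt(vhb) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

# ---- training harness ------------------------------------------------------

#' Training configuration for the toy detector
#'
#' @param rho Structural-prior weight (default 0.2; 0 disables the
#'   prior branch).
#' @param gamma Offset-loss trade-off weight (default 0.03).
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param batch_size Samples per gradient step.
#' @param channels Trunk feature channels (the prior taps these).
#' @param stride Output stride of the network (fixed at 4 by the
#'   architecture).
#' @param gaussian_sd,offset_radius,heat_pos_weight Target rendering
#'   parameters, see [render_targets()].
#' @param sl1_beta Smooth-L1 knee for the offset loss.
#' @param off_gain Fixed output gain of the offset head (the head's raw
#'   outputs are O(1); the gain maps them to output-grid cells).
#' @param offset_loss_scale Fixed rescale of the normalised offset loss
#'   inside the combined objective; the heatmap term is normalised by
#'   total weight and the offset term per active entry, which leaves
#'   them on different scales at the reference `gamma`.
#' @param flip_augment Use random horizontal flips (the only
#'   augmentation: pods must stay intact, and seed ordinals are
#'   positional along the chain, not lateral, so flipping never swaps
#'   them).
#' @param rng_seed Integer seed controlling initialisation, batch
#'   order and augmentation.
#' @return List of class `toy_train_config`.
#' @export
toy_train_config <- function(rho = 0.2, gamma = 0.03, epochs = 40,
                             lr = 4e-3, batch_size = 4, channels = 16,
                             off_gain = 8, offset_loss_scale = 30,
                             stride = 4, gaussian_sd = 2,
                             offset_radius = 4, heat_pos_weight = 25,
                             sl1_beta = 1, flip_augment = TRUE,
                             rng_seed = 1L) {
  stopifnot(rho >= 0, gamma >= 0, epochs >= 1, lr > 0, batch_size >= 1,
            stride == 4)
  structure(as.list(environment()), class = "toy_train_config")
}

flip_sample <- function(image, ann) {
  W <- ncol(image)
  img <- image[, rev(seq_len(W)), drop = FALSE]
  s <- ann$seeds
  s$x <- pmin(W - s$x, W - 1e-9)
  list(image = img,
       annotation = pod_annotation(s, image_id = ann$image_id,
                                   width = ann$width, height = ann$height))
}

#' Train the toy pod detector
#'
#' Trains the compact multi-branch network on a list of crops with the
#' combined objective: weighted heatmap regression, masked smooth-L1
#' offset regression (weight `gamma`), and the structural-prior
#' cosine-affinity loss (weight `rho`, normalised variant) read from
#' the trunk feature tap at the ground-truth seed cells. Optimisation
#' is Adam; training is deterministic given `rng_seed`.
#'
#' @param dataset Non-empty list of samples, each a list with `image`
#'   (matrix in `[0, 1]`) and `annotation` (a [pod_annotation()]), e.g.
#'   from [generate_scene()].
#' @param config A [toy_train_config()].
#' @param quiet Suppress per-epoch progress messages.
#' @return A `pod_model`: list with `params`, `config`, `loss_log`
#'   (tibble: epoch, l_heatmaps, l_p, l_sprior, total), `stride`.
#' @export
train_toy <- function(dataset, config = toy_train_config(), quiet = FALSE) {
  stopifnot(inherits(config, "toy_train_config"))
  if (length(dataset) == 0) abort("`dataset` must be non-empty.")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$rng_seed)

  prep <- function(image, ann) {
    list(image = image,
         targets = render_targets(ann, stride = config$stride,
                                  gaussian_sd = config$gaussian_sd,
                                  offset_radius = config$offset_radius,
                                  heat_pos_weight = config$heat_pos_weight),
         seeds = ann$seeds)
  }
  samples <- purrr::map(dataset, function(s) {
    orig <- prep(s$image, s$annotation)
    if (!config$flip_augment) return(list(orig))
    fl <- flip_sample(s$image, s$annotation)
    list(orig, prep(fl$image, fl$annotation))
  })

  params <- pod_net_init(config$channels, rng_seed = config$rng_seed)
  state <- adam_init(params)
  t_step <- 0
  log_rows <- list()

  for (epoch in seq_len(config$epochs)) {
    idx <- sample(length(samples))
    sums <- c(l_heatmaps = 0, l_p = 0, l_sprior = 0, total = 0)
    nb <- 0
    # step decay: halve the rate at 1/2 and 3/4 of the schedule
    lr_now <- config$lr *
      0.5^((epoch > config$epochs / 2) + (epoch > 3 * config$epochs / 4))
    for (start in seq(1, length(idx), by = config$batch_size)) {
      batch <- idx[start:min(start + config$batch_size - 1, length(idx))]
      grads <- NULL
      for (si in batch) {
        variants <- samples[[si]]
        sm <- variants[[sample.int(length(variants), 1)]]
        fwd <- pod_net_forward(params, sm$image, keep_cache = TRUE,
                               off_gain = config$off_gain)
        lg <- toy_loss_grads(fwd, sm$targets, sm$seeds,
                             rho = config$rho, gamma = config$gamma,
                             beta = config$sl1_beta,
                             stride = config$stride,
                             offset_loss_scale = config$offset_loss_scale)
        if (!is.finite(lg$total)) {
          abort(sprintf(
            "Training diverged at epoch %d (non-finite loss %g/%g/%g).",
            epoch, lg$l_heatmaps, lg$l_p, lg$l_sprior))
        }
        g <- pod_net_backward(params, fwd, lg$dheat,
                              gamma_scale(lg$doff, config$gamma),
                              lg$dfeat, off_gain = config$off_gain)
        grads <- if (is.null(grads)) g else add_grads(grads, g)
        sums <- sums + c(lg$l_heatmaps, lg$l_p, lg$l_sprior, lg$total)
      }
      grads <- scale_grads(grads, 1 / length(batch))
      t_step <- t_step + 1
      upd <- adam_step(params, grads, state, lr = lr_now, t = t_step)
      params <- upd$params
      state <- upd$state
      nb <- nb + length(batch)
    }
    means <- sums / nb
    log_rows[[epoch]] <- tibble(epoch = epoch,
                                l_heatmaps = means[["l_heatmaps"]],
                                l_p = means[["l_p"]],
                                l_sprior = means[["l_sprior"]],
                                total = means[["total"]])
    if (!quiet) {
      inform(sprintf(
        "epoch %d/%d  heat %.4f  offset %.4f  sprior %.4f  total %.4f",
        epoch, config$epochs, means[["l_heatmaps"]], means[["l_p"]],
        means[["l_sprior"]], means[["total"]]))
    }
  }

  structure(list(params = params, config = config,
                 loss_log = dplyr::bind_rows(log_rows),
                 stride = config$stride),
            class = "pod_model")
}

gamma_scale <- function(doff, gamma) doff * gamma

add_grads <- function(a, b) {
  purrr::map2(a, b, function(x, y) {
    list(dW = x$dW + y$dW, db = x$db + y$db)
  })
}

scale_grads <- function(g, f) {
  purrr::map(g, function(x) list(dW = x$dW * f, db = x$db * f))
}

#' @export
print.pod_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, function(l) length(l$W) + length(l$b),
                      numeric(1)))
  cat(sprintf(
    "<pod_model> %d parameters, stride %d, trained %d epoch(s), final loss %.4f\n",
    n_par, x$stride, nrow(x$loss_log), tail(x$loss_log$total, 1)))
  invisible(x)
}

#' Run the toy detector on an image
#'
#' Forward pass plus decoding; optionally refines each surviving seed
#' to the intensity-weighted centroid of its type channel around the
#' regressed location, which recovers sub-cell accuracy from the
#' heatmap peak shape.
#'
#' @param model A `pod_model` from [train_toy()].
#' @param image Matrix in `[0, 1]`.
#' @param heatmap_thresh,nms_thresh,nms_radius Decoding thresholds,
#'   see [decode()].
#' @param refine_seeds Apply heatmap-centroid refinement (default TRUE).
#' @param image_id Identifier stamped on the detections.
#' @return Detections tibble.
#' @export
predict_pods <- function(model, image, heatmap_thresh = 0.3,
                         nms_thresh = 0.05, nms_radius = 10,
                         refine_seeds = TRUE, image_id = "image") {
  stopifnot(inherits(model, "pod_model"))
  fwd <- pod_net_forward(model$params, image,
                         off_gain = model$config$off_gain %||% 8)
  pred <- prediction_tensors(fwd$heatmaps, fwd$offsets,
                             stride = model$stride)
  dets <- decode(pred, heatmap_thresh = heatmap_thresh,
                 nms_thresh = nms_thresh, nms_radius = nms_radius,
                 image_id = image_id)
  if (refine_seeds && nrow(dets) > 0) {
    dets <- refine_to_heatmap(dets, fwd$heatmaps, model$stride)
    # refinement can pull duplicate chains onto the same blobs; a second
    # pose-NMS pass on the refined coordinates removes them
    dets <- pose_nms(dets, radius = nms_radius)
  }
  dets
}

# suppress lower-scoring pods whose mean per-ordinal seed distance to a
# kept pod is below `radius`
pose_nms <- function(dets, radius) {
  split_pods <- split(dets, dets$pod_id)
  ord <- order(vapply(split_pods, function(p) p$pod_score[1], numeric(1)),
               decreasing = TRUE)
  kept <- list()
  for (i in ord) {
    p <- split_pods[[i]]
    dup <- FALSE
    for (q in kept) {
      m <- min(nrow(p), nrow(q))
      d <- mean(sqrt((p$x[1:m] - q$x[1:m])^2 + (p$y[1:m] - q$y[1:m])^2))
      if (d < radius) { dup <- TRUE; break }
    }
    if (!dup) kept[[length(kept) + 1]] <- p
  }
  out <- dplyr::bind_rows(kept)
  out[order(out$pod_id, out$seed_index), , drop = FALSE]
}

# sub-cell refinement on the seed's type channel: snap to the local
# argmax within a small window, then a 1-D log-parabola fit per axis
# recovers the sub-cell peak of the Gaussian blob
refine_to_heatmap <- function(dets, heatmaps, stride, halfwin = 2) {
  Hp <- dim(heatmaps)[1]; Wp <- dim(heatmaps)[2]
  parab <- function(l, c0, r) {
    l <- log(pmax(c(l, c0, r), 1e-12))
    den <- l[1] - 2 * l[2] + l[3]
    if (den >= 0) return(0)
    min(max(0.5 * (l[1] - l[3]) / den, -0.5), 0.5)
  }
  for (i in seq_len(nrow(dets))) {
    k <- dets$seed_index[i]
    u <- dets$x[i] / stride
    v <- dets$y[i] / stride
    cc <- min(max(floor(u) + 1, 1), Wp)
    rr <- min(max(floor(v) + 1, 1), Hp)
    cols <- max(1, cc - halfwin):min(Wp, cc + halfwin)
    rows <- max(1, rr - halfwin):min(Hp, rr + halfwin)
    win <- heatmaps[rows, cols, k]
    pk <- which(win == max(win), arr.ind = TRUE)[1, ]
    pr <- rows[pk[1]]; pc <- cols[pk[2]]
    du <- if (pc > 1 && pc < Wp) {
      parab(heatmaps[pr, pc - 1, k], heatmaps[pr, pc, k],
            heatmaps[pr, pc + 1, k])
    } else 0
    dv <- if (pr > 1 && pr < Hp) {
      parab(heatmaps[pr - 1, pc, k], heatmaps[pr, pc, k],
            heatmaps[pr + 1, pc, k])
    } else 0
    dets$x[i] <- (pc - 0.5 + du) * stride
    dets$y[i] <- (pr - 0.5 + dv) * stride
  }
  dets
}

#' Prediction tensors for an image under a trained model
#'
#' @param model A `pod_model`.
#' @param image Matrix in `[0, 1]`.
#' @return A [prediction_tensors()].
#' @export
forward_tensors <- function(model, image) {
  fwd <- pod_net_forward(model$params, image,
                         off_gain = model$config$off_gain %||% 8)
  prediction_tensors(fwd$heatmaps, fwd$offsets, stride = model$stride)
}

#' Single-sample training loss of a model state
#'
#' Convenience for diagnostics: evaluates the combined objective on one
#' sample without updating parameters.
#'
#' @param model A `pod_model` (or bare parameter list with a config).
#' @param image,annotation One sample.
#' @return List of loss components as in [dekr_loss()] plus `l_sprior`
#'   and `total`.
#' @export
toy_loss <- function(model, image, annotation) {
  config <- model$config
  targets <- render_targets(annotation, stride = config$stride,
                            gaussian_sd = config$gaussian_sd,
                            offset_radius = config$offset_radius,
                            heat_pos_weight = config$heat_pos_weight)
  fwd <- pod_net_forward(model$params, image, keep_cache = FALSE,
                         off_gain = config$off_gain %||% 8)
  lg <- toy_loss_grads(fwd, targets, annotation$seeds, rho = config$rho,
                       gamma = config$gamma, beta = config$sl1_beta,
                       stride = config$stride,
                       offset_loss_scale = config$offset_loss_scale %||% 30)
  lg[c("l_heatmaps", "l_p", "l_sprior", "total")]
}
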