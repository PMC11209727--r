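# broom-style tidiers for the result objects.

#' Tidy an AP report
#'
#' @param x An `ap_report` from [average_precision()].
#' @param ... Unused.
#' @return Long tibble with columns `metric` and `value` (AP, AP50 and
#'   the per-seed-count APs).
#' @method tidy ap_report
#' @export
tidy.ap_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble(metric = "ap", value = x$ap),
    tibble(metric = "ap50", value = x$ap50),
    tibble(metric = sprintf("ap_%d_seeded", x$per_type$n),
           value = x$per_type$ap)
  )
}

#' @rdname tidy.ap_report
#' @method glance ap_report
#' @export
glance.ap_report <- function(x, ...) {
  wide <- setNames(as.list(x$per_type$ap),
                   sprintf("ap_%d_seeded", x$per_type$n))
  dplyr::bind_cols(tibble(ap = x$ap, ap50 = x$ap50), as_tibble(wide),
                   tibble(n_images = x$n_images))
}

#' Tidy a trained toy model
#'
#' @param x A `pod_model` from [train_toy()].
#' @param ... Unused.
#' @return The per-epoch loss log in long format (`epoch`, `loss`,
#'   `value`).
#' @method tidy pod_model
#' @export
tidy.pod_model <- function(x, ...) {
  tidyr::pivot_longer(x$loss_log, -"epoch", names_to = "loss",
                      values_to = "value")
}

#' @rdname tidy.pod_model
#' @method glance pod_model
#' @export
glance.pod_model <- function(x, ...) {
  last <- tail(x$loss_log, 1)
  tibble(
    epochs = nrow(x$loss_log),
    n_parameters = sum(vapply(x$params,
                              function(l) length(l$W) + length(l$b),
                              numeric(1))),
    rho = x$config$rho, gamma = x$config$gamma,
    l_heatmaps = last$l_heatmaps, l_p = last$l_p,
    l_sprior = last$l_sprior, total = last$total
  )
}

#' Tidy a match table
#'
#' @param x A `match_table` from [greedy_match()].
#' @param ... Unused.
#' @return The per-detection tibble with match outcomes.
#' @method tidy match_table
#' @export
tidy.match_table <- function(x, ...) x$detections

#' @rdname tidy.match_table
#' @method glance match_table
#' @export
glance.match_table <- function(x, ...) {
  tibble(
    n_detections = nrow(x$detections),
    n_gt = nrow(x$gts),
    n_matched = sum(!is.na(x$detections$gt_id)),
    mean_oks = mean(x$detections$oks, na.rm = TRUE)
  )
}
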