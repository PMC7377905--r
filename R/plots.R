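#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_col geom_tile
#'   geom_hline geom_vline geom_ribbon labs facet_wrap scale_fill_viridis_c
NULL

#' Plot a calibration fit
#'
#' Observed block accuracies with the fitted psychometric curve
#' \eqn{\Phi(k/\sigma)} overlaid for both calibration blocks.
#'
#' @param object A `calibration` from [calibrate_coherences()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.calibration <- function(object, ...) {
  obs <- dplyr::bind_rows(
    dplyr::mutate(as_tibble(object$block1), block = "block 1"),
    dplyr::mutate(as_tibble(object$block2), block = "block 2")
  )
  kk <- seq(0, max(obs$coherence) * 1.1, length.out = 200)
  curve <- dplyr::bind_rows(
    tibble(coherence = kk, accuracy = predict_accuracy(kk, object$sigma_block1),
           block = "block 1"),
    tibble(coherence = kk, accuracy = predict_accuracy(kk, object$sigma_block2),
           block = "block 2")
  )
  ggplot(obs, aes(x = .data$coherence, y = .data$accuracy)) +
    geom_line(data = curve, colour = "grey40") +
    geom_point() +
    facet_wrap(~block) +
    labs(x = "motion coherence", y = "proportion correct",
         title = "Stimulus calibration")
}

#' Plot a partner session's report distribution
#'
#' @param object A `partner_session`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.partner_session <- function(object, ...) {
  counts <- tibble(report = factor(1:6),
                   n = tabulate(object$trials$report, 6L))
  ggplot(counts, aes(x = .data$report, y = .data$n)) +
    geom_col(fill = "steelblue") +
    labs(x = "confidence report", y = "trials",
         title = sprintf("Partner '%s' (mean report %.2f)",
                         object$partner_id, mean(object$trials$report)))
}

#' Plot the group-accuracy strategy sweep
#'
#' Group accuracy as a function of the subject's mean confidence, with the
#' partner's mean confidence marked: the curve peaks where the subject
#' matches the partner.
#'
#' @param sweep Output of [sweep_group_accuracy()].
#' @return A ggplot object.
#' @export
plot_strategy_sweep <- function(sweep) {
  pm <- attr(sweep, "partner_mean")
  p <- ggplot(sweep, aes(x = .data$subject_mean, y = .data$group_accuracy)) +
    geom_line() + geom_point() +
    labs(x = "subject mean confidence", y = "group accuracy",
         title = "Reward-maximising strategy: match the partner's mean confidence")
  if (!is.null(pm)) p <- p + geom_vline(xintercept = pm, linetype = 2)
  p
}

#' Plot a split-data RDM
#'
#' @param object A `split_rdm` from [sdrdm()].
#' @param ... Unused.
#' @return A ggplot heatmap; the diagonal holds cross-run within-condition
#'   distances.
#' @export
autoplot.split_rdm <- function(object, ...) {
  m <- unclass(object)
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$dissimilarity <- m[cbind(df$row, df$col)]
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$dissimilarity)) +
    geom_tile() + scale_fill_viridis_c() +
    labs(x = "condition", y = "condition", title = "Split-data RDM",
         subtitle = sprintf("EDI = %.3f", edi(object)))
}

#' Plot group-level beta time courses
#'
#' Mean beta traces across subjects with per-timepoint significance
#' marking.
#'
#' @param group_traces Output of [group_timepoint_test()].
#' @return A ggplot object.
#' @export
plot_beta_traces <- function(group_traces) {
  ggplot(group_traces,
         aes(x = .data$time, y = .data$mean_beta, colour = .data$term)) +
    geom_hline(yintercept = 0, colour = "grey70") +
    geom_line() +
    geom_point(data = group_traces[group_traces$significant, ], size = 0.8) +
    labs(x = "time from event onset (s)", y = "beta (group mean)",
         colour = NULL, title = "Encoding time courses",
         subtitle = "dots: p < .05 per timepoint, uncorrected")
}
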