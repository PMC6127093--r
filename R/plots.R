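#' @importFrom ggplot2 ggplot aes geom_line geom_ribbon geom_raster
#'   geom_hline geom_segment labs scale_fill_gradient2 theme_minimal
#'   autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot a single-subject decoding time-course
#'
#' @param object A `decoding_timecourse`.
#' @param ... Unused.
#' @return A ggplot: AUC against time with the chance line.
#' @export
autoplot.decoding_timecourse <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$time_ms, y = .data$auc)) +
    geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    geom_line() +
    labs(x = "time (ms)", y = "AUC",
         title = paste("Decoding sensitivity -", object$participant)) +
    theme_minimal()
}

#' Plot a temporal generalization matrix
#'
#' @param object A `tg_matrix`.
#' @param ... Unused.
#' @return A ggplot raster of AUC over train x test time.
#' @export
autoplot.tg_matrix <- function(object, ...) {
  ggplot(tidy(object),
         aes(x = .data$test_ms, y = .data$train_ms, fill = .data$auc)) +
    geom_raster() +
    scale_fill_gradient2(midpoint = 0.5, low = "steelblue",
                         mid = "white", high = "firebrick") +
    labs(x = "testing time (ms)", y = "training time (ms)", fill = "AUC") +
    theme_minimal()
}

#' Plot a group decoding time-course with its clusters
#'
#' @param auc_matrix Subjects x timepoints AUC matrix.
#' @param times Time axis (ms).
#' @param clusters Optional `cluster_result` to mark significant intervals.
#' @param chance Chance level drawn as a reference line.
#' @return A ggplot: group mean AUC with a +/- SEM ribbon and cluster bars.
#' @export
plot_group_timecourse <- function(auc_matrix, times, clusters = NULL,
                                  chance = 0.5) {
  auc_matrix <- as.matrix(auc_matrix)
  df <- tibble(time_ms = times,
               mean_auc = colMeans(auc_matrix),
               sem = apply(auc_matrix, 2, sd) / sqrt(nrow(auc_matrix)))
  p <- ggplot(df, aes(x = .data$time_ms, y = .data$mean_auc)) +
    geom_hline(yintercept = chance, linetype = "dashed", colour = "grey50") +
    geom_ribbon(aes(ymin = .data$mean_auc - .data$sem,
                    ymax = .data$mean_auc + .data$sem), alpha = 0.25) +
    geom_line() +
    labs(x = "time (ms)", y = "mean AUC") +
    theme_minimal()
  if (!is.null(clusters) && nrow(clusters)) {
    sig <- clusters[clusters$significant, , drop = FALSE]
    if (nrow(sig)) {
      p <- p + geom_segment(
        data = tibble(x = times[sig$start], xend = times[sig$end]),
        aes(x = .data$x, xend = .data$xend), y = chance - 0.02,
        yend = chance - 0.02, linewidth = 2, colour = "grey30",
        inherit.aes = FALSE)
    }
  }
  p
}
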