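#' Aggregate per-subject metrics into group summaries
#'
#' Means and 95\% confidence intervals (mean +/- 1.96 SD / sqrt(n), sample
#' SD) of each metric per group — the error-bar summary used to compare
#' post-processing steps across lesion categories. Undefined Hausdorff
#' distances (one-empty-mask subjects) are excluded from the HD averages;
#' the excluded count is reported per group.
#'
#' @param records data frame of [metrics_record()] rows.
#' @param by character vector of grouping columns (e.g.
#'   \code{c("postproc_step", "category")}).
#' @param weight \code{"subject"} pools subjects across folds;
#'   \code{"fold"} first averages within each fold, then across folds
#'   (fold-mean-of-means).
#' @param include_all when grouping by \code{category}, add pooled rows
#'   with category \code{"all"} (the fourth, all-subjects column of the
#'   error-bar layout).
#' @return Data frame with columns \code{by}, \code{metric}, \code{n},
#'   \code{n_excluded}, \code{mean}, \code{sd}, \code{ci_low},
#'   \code{ci_high}.
#' @export
aggregate_metrics <- function(records, by = "postproc_step",
                              weight = c("subject", "fold"),
                              include_all = TRUE) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  weight <- match.arg(weight)
  metrics <- intersect(c("TPR", "TNR", "PPV", "ACC", "DSC", "MCC", "HD"),
                       names(records))
  if (include_all && "category" %in% by) {
    pooled <- records
    pooled$category <- "all"
    records <- rbind(records, pooled)
  }
  if (weight == "fold" && "fold_id" %in% names(records)) {
    # collapse to per-fold means first, then summarise across folds
    inner <- aggregate_metrics(records, by = unique(c(by, "fold_id")),
                               weight = "subject", include_all = FALSE)
    out <- do.call(rbind, lapply(split(inner, inner[c(by, "metric")], drop = TRUE),
      function(g) {
        s <- stats::sd(g$mean)
        n <- nrow(g)
        ci <- if (n > 1 && is.finite(s)) 1.96 * s / sqrt(n) else 0
        cbind(g[1, by, drop = FALSE],
              data.frame(metric = g$metric[1], n = n,
                         n_excluded = sum(g$n_excluded),
                         mean = mean(g$mean), sd = ifelse(is.na(s), 0, s),
                         ci_low = mean(g$mean) - ci,
                         ci_high = mean(g$mean) + ci))
      }))
    rownames(out) <- NULL
    return(out)
  }
  groups <- split(records, records[by], drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    do.call(rbind, lapply(metrics, function(m) {
      v <- g[[m]]
      n_exc <- sum(is.na(v))
      v <- v[!is.na(v)]
      n <- length(v)
      s <- if (n > 1) stats::sd(v) else 0
      mu <- if (n > 0) mean(v) else NA_real_
      ci <- if (n > 1) 1.96 * s / sqrt(n) else 0
      cbind(g[1, by, drop = FALSE],
            data.frame(metric = m, n = n, n_excluded = n_exc, mean = mu,
                       sd = s, ci_low = mu - ci, ci_high = mu + ci))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Bland-Altman volume agreement
#'
#' For every record, plots-ready pairs of x = (predicted + ground-truth
#' volume) / 2 and y = predicted - ground-truth volume (mm^3; positive y
#' means the pipeline overestimates the lesion), with per-group mean
#' difference and limits of agreement mean +/- 1.96 SD (sample SD).
#'
#' @param records data frame of [metrics_record()] rows (needs
#'   \code{gt_volume}, \code{pred_volume}).
#' @param by grouping columns; default \code{"postproc_step"}.
#' @return Object of class \code{bland_altman}: \code{points} (per-subject
#'   pairs with grouping keys) and \code{summary} (per-group
#'   \code{mean_diff}, \code{loa_low}, \code{loa_high}).
#' @export
bland_altman <- function(records, by = "postproc_step") {
  stopifnot(all(c("gt_volume", "pred_volume") %in% names(records)))
  points <- records[, intersect(c("subject_id", by), names(records)),
                    drop = FALSE]
  points$avg_volume <- (records$pred_volume + records$gt_volume) / 2
  points$diff_volume <- records$pred_volume - records$gt_volume
  groups <- split(points, points[by], drop = TRUE)
  summary <- do.call(rbind, lapply(groups, function(g) {
    mu <- mean(g$diff_volume)
    s <- if (nrow(g) > 1) stats::sd(g$diff_volume) else 0
    cbind(g[1, by, drop = FALSE],
          data.frame(n = nrow(g), mean_diff = mu,
                     loa_low = mu - 1.96 * s, loa_high = mu + 1.96 * s))
  }))
  rownames(summary) <- NULL
  structure(list(points = points, summary = summary, by = by),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("<bland_altman> volume agreement (mm^3)\n")
  print(x$summary)
  invisible(x)
}

#' @param x a \code{bland_altman} object.
#' @param group optional named list selecting one group to plot; default
#'   plots all points pooled with the first group's limits.
#' @param ... passed to [graphics::plot()].
#' @rdname bland_altman
#' @export
plot.bland_altman <- function(x, group = NULL, ...) {
  pts <- x$points
  smr <- x$summary
  if (!is.null(group)) {
    for (k in names(group)) {
      pts <- pts[pts[[k]] == group[[k]], , drop = FALSE]
      smr <- smr[smr[[k]] == group[[k]], , drop = FALSE]
    }
  }
  graphics::plot(pts$avg_volume, pts$diff_volume,
                 xlab = "average volume (mm^3)",
                 ylab = "prediction - ground truth (mm^3)",
                 main = "Bland-Altman volume agreement", ...)
  graphics::abline(h = smr$mean_diff[1], lty = 1)
  graphics::abline(h = c(smr$loa_low[1], smr$loa_high[1]), lty = 3)
  invisible(x)
}

#' Error-bar plot of a metric across groups
#'
#' @param summary output of [aggregate_metrics()].
#' @param metric metric to display, e.g. \code{"DSC"}.
#' @param by column of \code{summary} giving the x-axis groups.
#' @return Invisibly, the subset plotted.
#' @export
plot_metric_errorbars <- function(summary, metric = "DSC",
                                  by = "postproc_step") {
  s <- summary[summary$metric == metric, , drop = FALSE]
  xs <- seq_len(nrow(s))
  graphics::plot(xs, s$mean, ylim = range(s$ci_low, s$ci_high, na.rm = TRUE),
                 xaxt = "n", xlab = by, ylab = metric, pch = 19,
                 main = sprintf("%s (mean and 95%% CI)", metric))
  graphics::axis(1, at = xs, labels = s[[by]], las = 2, cex.axis = 0.8)
  graphics::arrows(xs, s$ci_low, xs, s$ci_high, angle = 90, code = 3,
                   length = 0.04)
  invisible(s)
}
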