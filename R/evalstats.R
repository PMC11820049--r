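#' Evaluation metrics and model-comparison statistics
#'
#' Per-series goodness-of-fit triple (R-squared, RMSE, NRMSE) and the
#' across-model comparison: one-way ANOVA on per-fold metric values
#' followed by Tukey HSD with significance stars at the conventional
#' 0.05 / 0.001 / 0.0001 bins.
#'
#' @name evalstats
NULL

#' Goodness-of-fit metrics for one predicted series
#'
#' `R2 = 1 - sum((yhat - y)^2) / sum((mean(y) - y)^2)` (total sum of
#' squares about the mean of the measured series; negative values are
#' reported, not clipped), `RMSE = sqrt(mean((yhat - y)^2))`,
#' `NRMSE = RMSE / (max(y) - min(y))` -- the range of the measured, not
#' the predicted, series.
#'
#' @param y measured series (degrees).
#' @param yhat predicted series, same length.
#' @return list of class `metrics_triple`: `r2`, `rmse`, `nrmse`, `n`.
#' @export
metrics <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  if (anyNA(y) || anyNA(yhat)) stop("metrics input contains NA")
  rng <- max(y) - min(y)
  if (rng == 0) {
    stop("measured series is constant: NRMSE (and R2) are undefined")
  }
  ss_res <- sum((yhat - y)^2)
  ss_tot <- sum((mean(y) - y)^2)
  rmse <- sqrt(mean((yhat - y)^2))
  structure(list(r2 = 1 - ss_res / ss_tot, rmse = rmse,
                 nrmse = rmse / rng, n = length(y)),
            class = "metrics_triple")
}

#' Aggregate per-fold metrics to per-model, per-joint mean and sd
#'
#' @param df tidy metric table (columns model, joint, r2, rmse, nrmse),
#'   e.g. from [run_comparison()].
#' @return data.frame with mean and sd per (model, joint) per metric.
#' @export
aggregate_metrics <- function(df) {
  stopifnot(all(c("model", "joint", "r2", "rmse", "nrmse") %in% names(df)))
  sp <- split(df, list(df$model, df$joint), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(g) {
    data.frame(model = g$model[1], joint = g$joint[1], n_folds = nrow(g),
               r2_mean = mean(g$r2), r2_sd = stats::sd(g$r2),
               rmse_mean = mean(g$rmse), rmse_sd = stats::sd(g$rmse),
               nrmse_mean = mean(g$nrmse), nrmse_sd = stats::sd(g$nrmse))
  }))
  rownames(out) <- NULL
  out[order(out$joint, out$model), ]
}

p_stars <- function(p) {
  ifelse(p < 1e-4, "***", ifelse(p <= 1e-3, "**", ifelse(p <= 0.05, "*", "ns")))
}

#' Compare models with one-way ANOVA and Tukey HSD
#'
#' For each joint (and metric), tests whether the per-fold metric values
#' differ across models, then runs all-pairs Tukey HSD at the 0.05 level.
#' Exact ties across all groups (zero residual variance) make F undefined;
#' this is reported explicitly rather than as a significant difference.
#'
#' @param df tidy metric table from [run_comparison()] (columns model,
#'   joint, fold, plus the metric columns).
#' @param metric which metric column to compare (default `"r2"`).
#' @return list of class `comparison_result`: `anova` (per-joint F, df,
#'   p), `tukey` (per-joint pairwise adjusted p, difference, stars),
#'   `metric`, `unit` (the unit of analysis: CV fold).
#' @export
compare_models <- function(df, metric = "r2") {
  stopifnot(metric %in% names(df), "model" %in% names(df))
  if (!"joint" %in% names(df)) df$joint <- "all"
  an_rows <- list(); tk_rows <- list()
  for (j in unique(df$joint)) {
    g <- df[df$joint == j, ]
    if (length(unique(g$model)) < 2) stop("need >= 2 models to compare")
    if (any(table(g$model) < 2)) stop("need >= 2 samples per model")
    vals <- g[[metric]]
    grp <- factor(g$model)
    if (stats::var(vals) == 0) {
      an_rows[[j]] <- data.frame(joint = j, F = NA_real_, df1 = NA, df2 = NA,
                                 p = NA_real_,
                                 note = "degenerate: all values tied, F undefined")
      next
    }
    fit <- stats::aov(vals ~ grp)
    s <- summary(fit)[[1]]
    if (s[2, "Mean Sq"] == 0 || !is.finite(s[1, "F value"])) {
      an_rows[[j]] <- data.frame(joint = j, F = NA_real_, df1 = NA, df2 = NA,
                                 p = NA_real_,
                                 note = "degenerate: zero within-group variance, F undefined")
      next
    }
    an_rows[[j]] <- data.frame(joint = j, F = s[1, "F value"],
                               df1 = s[1, "Df"], df2 = s[2, "Df"],
                               p = s[1, "Pr(>F)"], note = "")
    tk <- stats::TukeyHSD(fit, conf.level = 0.95)$grp
    tk_rows[[j]] <- data.frame(joint = j, pair = rownames(tk),
                               diff = tk[, "diff"], p_adj = tk[, "p adj"],
                               significant = tk[, "p adj"] < 0.05,
                               stars = p_stars(tk[, "p adj"]),
                               row.names = NULL)
  }
  structure(list(anova = do.call(rbind, c(an_rows, list(make.row.names = FALSE))),
                 tukey = if (length(tk_rows)) do.call(rbind, c(tk_rows, list(make.row.names = FALSE))) else NULL,
                 metric = metric, alpha = 0.05, unit = "cross-validation fold"),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("Model comparison on", x$metric, "(unit:", x$unit, ")\n\nANOVA:\n")
  print(x$anova, row.names = FALSE)
  if (!is.null(x$tukey)) {
    cat("\nTukey HSD (alpha = ", x$alpha, "):\n", sep = "")
    print(x$tukey, row.names = FALSE)
  }
  invisible(x)
}

#' @export
print.metrics_triple <- function(x, ...) {
  cat(sprintf("R2 = %.4f, RMSE = %.4f deg, NRMSE = %.5f (n = %d)\n",
              x$r2, x$rmse, x$nrmse, x$n))
  invisible(x)
}
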