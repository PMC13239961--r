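#' Pearson correlation with two-sided p-value
#'
#' Standard product-moment correlation; the p-value comes from the
#' t-transform with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors (n >= 3, nonconstant).
#' @return list of class `correlation_result` with `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) stop_rotqa("need at least 3 paired observations",
                                "rotqa_invalid_input")
  if (sd(x) == 0 || sd(y) == 0) {
    stop_rotqa("correlation undefined for constant input",
               "rotqa_undefined_correlation")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.3f, p = %.3g, n = %d\n",
              x$r, x$p, x$n))
  invisible(x)
}

#' Direction-stratified correlation and pass-proportion analysis
#'
#' Groups records by rotation direction (UP, RO, CW for single-direction
#' records; MULTI for 2-3 directions) and computes, per group, the Pearson
#' correlation of every dose metric against the total rotation angle,
#' plus the proportion of records whose 2%/2 mm gamma passing rate exceeds
#' the clinical threshold. The MULTI group additionally regresses each
#' metric on the direction count.
#'
#' @param metrics data.frame from [cohort_metrics()].
#' @param metric_cols metric columns to analyze; defaults to all SSIM /
#'   gamma / DD columns present.
#' @param pass_metric column holding the clinical gamma passing rate.
#' @param pass_threshold clinical acceptance threshold (percent).
#' @return list with `correlations` (group, metric, predictor, r, p, n)
#'   and `pass_proportions` (group, proportion, n).
#' @export
direction_analysis <- function(metrics, metric_cols = NULL,
                               pass_metric = "gamma_rd_2_2",
                               pass_threshold = 95) {
  if (is.null(metric_cols)) {
    metric_cols <- intersect(
      c(grep("^gamma_", names(metrics), value = TRUE),
        grep("^dd_", names(metrics), value = TRUE), "ssim"),
      names(metrics))
  }
  # UP/RO/CW: single-direction records; MULTI: 2-3 perturbed axes;
  # POOLED: both acquisition phases together, where the direction count
  # (1-3) serves as an additional independent variable
  groups <- list(UP = metrics$direction == "UP",
                 RO = metrics$direction == "RO",
                 CW = metrics$direction == "CW",
                 MULTI = metrics$n_directions >= 2,
                 POOLED = metrics$n_directions >= 1)
  cor_rows <- list()
  prop_rows <- list()
  for (g in names(groups)) {
    sub <- metrics[groups[[g]], , drop = FALSE]
    if (nrow(sub) < 3) {
      warning(sprintf("group %s has < 3 records; skipped", g))
      next
    }
    preds <- if (g %in% c("MULTI", "POOLED")) {
      c("angle_total_deg", "n_directions")
    } else {
      "angle_total_deg"
    }
    for (m in metric_cols) {
      for (pr in preds) {
        res <- tryCatch(pearson_cor(sub[[pr]], sub[[m]]),
                        rotqa_error = function(e) NULL)
        if (is.null(res)) next
        cor_rows[[length(cor_rows) + 1]] <- data.frame(
          group = g, metric = m, predictor = pr,
          r = res$r, p = res$p, n = res$n)
      }
    }
    if (pass_metric %in% names(sub)) {
      prop_rows[[length(prop_rows) + 1]] <- data.frame(
        group = g,
        proportion = 100 * mean(sub[[pass_metric]] > pass_threshold),
        n = nrow(sub))
    }
  }
  list(correlations = do.call(rbind, cor_rows),
       pass_proportions = do.call(rbind, prop_rows))
}
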