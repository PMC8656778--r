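#' Quartile-split Kaplan-Meier analysis of a phenotype score
#'
#' Splits samples on the 25th and 75th percentiles of a per-sample score
#' (linear-interpolation, type-7 quantiles) into a low group (score at or
#' below the 25th percentile) and a high group (score at or above the 75th
#' percentile), the interquartile middle being excluded; fits Kaplan-Meier
#' curves per group and compares them with the log-rank test. Significance
#' is declared at p < 0.05.
#'
#' @param records data.frame with columns sample_id, time (days, > 0),
#'   event (1/TRUE = death observed) and score.
#' @param min_group warn when a group ends up smaller than this (default
#'   10); an empty group is an error, as are degenerate quantiles (all
#'   scores identical).
#' @return object of class `"km_quartile"`: `fit` (a
#'   [survival::survfit] object), `logrank_chisq`, `p`, `cutpoints`,
#'   `records` (with a `group` column: low / high / excluded).
#' @export
km_quartile_analysis <- function(records, min_group = 10) {
  need <- c("sample_id", "time", "event", "score")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  if (any(records$time <= 0)) stop("survival times must be positive")
  qs <- stats::quantile(records$score, c(0.25, 0.75), type = 7,
                        names = FALSE)
  if (qs[1] == qs[2])
    stop("degenerate score quantiles: 25th and 75th percentiles coincide")
  group <- ifelse(records$score <= qs[1], "low",
                  ifelse(records$score >= qs[2], "high", "excluded"))
  n_low <- sum(group == "low"); n_high <- sum(group == "high")
  if (n_low == 0 || n_high == 0)
    stop("empty group after quartile split")
  if (n_low < min_group || n_high < min_group)
    warning("group sizes ", n_low, " (low) / ", n_high,
            " (high) below min_group = ", min_group)
  records$group <- group
  keep <- records[group != "excluded", , drop = FALSE]
  keep$group <- factor(keep$group, levels = c("low", "high"))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = keep)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = keep)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  structure(list(fit = fit, logrank_chisq = sd$chisq, p = p,
                 cutpoints = qs, records = records,
                 n = c(low = n_low, high = n_high)),
            class = "km_quartile")
}

#' @export
print.km_quartile <- function(x, ...) {
  cat(sprintf("Quartile-split survival analysis: %d low vs %d high samples\n",
              x$n["low"], x$n["high"]))
  cat(sprintf("  score cutpoints: <= %.4g (low), >= %.4g (high)\n",
              x$cutpoints[1], x$cutpoints[2]))
  cat(sprintf("  log-rank chi-square = %.3f, p = %.4g%s\n",
              x$logrank_chisq, x$p,
              if (x$p < 0.05) "  (significant)" else ""))
  invisible(x)
}

#' Kaplan-Meier table of a quartile-split analysis
#'
#' @param object a `"km_quartile"` fit.
#' @param ... ignored.
#' @return data.frame: group, time, n_risk, n_event, survival.
#' @export
summary.km_quartile <- function(object, ...) {
  s <- summary(object$fit)
  grp <- sub("^group=", "", as.character(s$strata))
  data.frame(group = grp, time = s$time, n_risk = s$n.risk,
             n_event = s$n.event, survival = s$surv,
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier curves for the low and high score groups
#'
#' @param x a `"km_quartile"` fit.
#' @param ... passed to [survival::plot.survfit].
#' @export
plot.km_quartile <- function(x, ...) {
  graphics::plot(x$fit, col = c("steelblue", "firebrick"), lwd = 2,
                 xlab = "Time (days)", ylab = "Survival probability", ...)
  graphics::legend("bottomleft", legend = c("low score", "high score"),
                   col = c("steelblue", "firebrick"), lwd = 2, bty = "n")
  graphics::mtext(sprintf("log-rank p = %.3g", x$p), side = 3, adj = 1,
                  cex = 0.8)
  invisible(x)
}
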