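#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up FDR adjustment: with order statistics `p_(1) <= ... <=
#' p_(m)`, the adjusted value for `p_(i)` is `min_{j >= i} m * p_(j) / j`,
#' capped at 1 and mapped back to input order.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
benjamini_hochberg <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    parameter_error("p-values must lie in [0, 1]")
  }
  m <- length(pvals)
  o <- order(pvals)
  adj_sorted <- pmin(1, rev(cummin(rev(pvals[o] * m / seq_len(m)))))
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# Guard around lmer: suppress boundary-fit chatter, keep real errors.
quiet_lmer <- function(formula, data) {
  withCallingHandlers(
    suppressMessages(lme4::lmer(formula, data = data, REML = TRUE)),
    warning = function(w) {
      if (grepl("boundary|singular", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

#' Within-session mixed-model contrasts against baseline
#'
#' Fits a linear mixed-effects model to one session's post/pre ratios with a
#' fixed effect per follow-up point and a random intercept per participant
#' (REML). On the default log scale the response is `log(ratio)`, so each
#' fixed-effect coefficient is the mean log ratio at that point and "no
#' change from baseline" is coefficient zero; `exp(estimate)` is the
#' model-based ratio. Each coefficient is tested against zero (Wald z by
#' default; Satterthwaite t if requested and `lmerTest` is installed), and
#' the per-session family of p-values is Benjamini-Hochberg adjusted.
#' Missing rows are handled natively by the likelihood.
#'
#' @param rt a `ratio_table`.
#' @param session `"control"` or `"fmv"`.
#' @param scale `"log"` (default) or `"raw"`; on the raw scale the model is
#'   `ratio ~ time + (1 | participant)` and coefficients are tested against 1.
#' @param df_method `"wald"` (default) or `"satterthwaite"`.
#' @return An `intragroup_result` data frame with one row per follow-up
#'   point: observed `mean_ratio`/`sd_ratio`/`n`, model `estimate` (contrast
#'   on the model scale), `ratio_estimate`, `se`, `statistic`, `p_raw`,
#'   `p_adj`.
#' @export
fit_intragroup <- function(rt, session = c("control", "fmv"),
                           scale = c("log", "raw"),
                           df_method = c("wald", "satterthwaite")) {
  session <- match.arg(session)
  scale <- match.arg(scale)
  df_method <- match.arg(df_method)
  d <- as.data.frame(rt)[as.data.frame(rt)$session == session, ]
  if (nrow(d) == 0L) fit_error(sprintf("no rows for session '%s'", session))
  if (length(unique(d$participant_id)) < 2L) {
    fit_error("need at least 2 participants to fit the mixed model")
  }
  if (scale == "log" && any(d$ratio <= 0)) {
    data_error("non-positive ratios: log-scale model undefined")
  }
  d$fup <- factor(d$follow_up_min, levels = sort(unique(d$follow_up_min)))
  d$y <- if (scale == "log") log(d$ratio) else d$ratio
  null_value <- if (scale == "log") 0 else 1

  obs <- do.call(rbind, lapply(split(d, d$fup), function(g) {
    data.frame(follow_up_min = g$follow_up_min[1], n = nrow(g),
               mean_ratio = mean(g$ratio), sd_ratio = stats::sd(g$ratio))
  }))

  if (stats::var(d$y) == 0) {
    # degenerate: identical responses; contrast against the null directly
    warning("all responses identical; mixed model degenerate", call. = FALSE)
    est <- rep(d$y[1], nlevels(d$fup))
    res <- data.frame(
      follow_up_min = as.integer(levels(d$fup)), estimate = est - null_value,
      se = 0, statistic = ifelse(est == null_value, 0, Inf),
      p_raw = ifelse(est == null_value, 1, 0))
  } else if (df_method == "satterthwaite") {
    if (!requireNamespace("lmerTest", quietly = TRUE)) {
      parameter_error("df_method = 'satterthwaite' requires the lmerTest package")
    }
    fit <- suppressMessages(lmerTest::lmer(y ~ 0 + fup + (1 | participant_id),
                                           data = d, REML = TRUE))
    cf <- stats::coef(summary(fit))
    tval <- (cf[, "Estimate"] - null_value) / cf[, "Std. Error"]
    res <- data.frame(
      follow_up_min = as.integer(levels(d$fup)),
      estimate = cf[, "Estimate"] - null_value, se = cf[, "Std. Error"],
      statistic = tval, p_raw = 2 * stats::pt(-abs(tval), df = cf[, "df"]))
  } else {
    fit <- quiet_lmer(y ~ 0 + fup + (1 | participant_id), d)
    cf <- stats::coef(summary(fit))
    z <- (cf[, "Estimate"] - null_value) / cf[, "Std. Error"]
    res <- data.frame(
      follow_up_min = as.integer(levels(d$fup)),
      estimate = cf[, "Estimate"] - null_value, se = cf[, "Std. Error"],
      statistic = z, p_raw = 2 * stats::pnorm(-abs(z)))
  }
  res$p_adj <- benjamini_hochberg(res$p_raw)
  res$ratio_estimate <- if (scale == "log") exp(res$estimate) else res$estimate + 1
  out <- merge(obs, res, by = "follow_up_min")
  out <- out[order(out$follow_up_min),
             c("follow_up_min", "n", "mean_ratio", "sd_ratio", "estimate",
               "ratio_estimate", "se", "statistic", "p_raw", "p_adj")]
  rownames(out) <- NULL
  attr(out, "session") <- session
  attr(out, "scale") <- scale
  class(out) <- c("intragroup_result", "data.frame")
  out
}

#' Between-session paired comparisons per follow-up point
#'
#' At each follow-up point, forms paired differences (`fmv - control`) of the
#' post/pre ratios over participants with both sessions, checks normality of
#' the differences with a Shapiro-Wilk test, and applies a paired t-test if
#' normality is not rejected at `alpha_normality`, otherwise a two-sided
#' Wilcoxon signed-rank test (zero differences dropped, as is conventional).
#' The family of raw p-values is Benjamini-Hochberg adjusted.
#'
#' @param rt a `ratio_table` containing both sessions.
#' @param alpha_normality significance level of the normality gate.
#' @return An `intergroup_result` data frame with one row per follow-up
#'   point: `n_pairs`, `mean_diff`, `shapiro_p`, `test_used`, `statistic`,
#'   `df` (paired t only), `p_raw`, `p_adj`.
#' @export
compare_groups <- function(rt, alpha_normality = 0.05) {
  d <- as.data.frame(rt)
  fups <- sort(unique(d$follow_up_min))
  rows <- lapply(fups, function(f) {
    g <- d[d$follow_up_min == f, ]
    wide <- merge(g[g$session == "fmv", c("participant_id", "ratio")],
                  g[g$session == "control", c("participant_id", "ratio")],
                  by = "participant_id", suffixes = c("_fmv", "_control"))
    if (nrow(wide) < 3L) {
      test_error(sprintf("fewer than 3 complete pairs at follow-up %d min", f))
    }
    diffs <- wide$ratio_fmv - wide$ratio_control
    if (all(diffs == 0)) {
      warning(sprintf("all paired differences zero at follow-up %d min", f),
              call. = FALSE)
      return(data.frame(follow_up_min = f, n_pairs = nrow(wide), mean_diff = 0,
                        shapiro_p = NA_real_, test_used = "degenerate",
                        statistic = NA_real_, df = NA_real_, p_raw = 1))
    }
    sw <- tryCatch(stats::shapiro.test(diffs)$p.value, error = function(e) NA_real_)
    normal <- !is.na(sw) && sw >= alpha_normality
    if (normal) {
      tt <- stats::t.test(diffs, mu = 0, paired = FALSE)
      data.frame(follow_up_min = f, n_pairs = nrow(wide), mean_diff = mean(diffs),
                 shapiro_p = sw, test_used = "paired_t",
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_raw = tt$p.value)
    } else {
      wt <- suppressWarnings(
        stats::wilcox.test(diffs[diffs != 0], mu = 0, exact = FALSE))
      data.frame(follow_up_min = f, n_pairs = nrow(wide), mean_diff = mean(diffs),
                 shapiro_p = sw, test_used = "wilcoxon",
                 statistic = unname(wt$statistic), df = NA_real_,
                 p_raw = wt$p.value)
    }
  })
  out <- do.call(rbind, rows)
  out$p_adj <- benjamini_hochberg(out$p_raw)
  rownames(out) <- NULL
  class(out) <- c("intergroup_result", "data.frame")
  out
}

#' Summary statistics of ratios per session and follow-up point
#'
#' @param rt a `ratio_table`.
#' @return Data frame with mean, SD and quartiles of the ratios, one row per
#'   session x follow-up point.
#' @export
summarize_ratios <- function(rt) {
  d <- as.data.frame(rt)
  parts <- split(d, list(d$session, d$follow_up_min), drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(g) {
    q <- stats::quantile(g$ratio, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(session = g$session[1], follow_up_min = g$follow_up_min[1],
               n = nrow(g), mean = mean(g$ratio), sd = stats::sd(g$ratio),
               q1 = q[1], median = q[2], q3 = q[3])
  }))
  out <- out[order(out$follow_up_min, out$session), ]
  rownames(out) <- NULL
  out
}

#' Assemble the full statistical report
#'
#' Runs both statistical families over a ratio table and bundles the results
#' with per-session summary statistics (the inputs for a ratio-evolution
#' boxplot figure).
#'
#' @param rt a `ratio_table` containing both sessions.
#' @param scale,df_method passed to [fit_intragroup()].
#' @param alpha_normality passed to [compare_groups()].
#' @return A `stats_report` list with elements `summary`, `intragroup`
#'   (named list per session), and `intergroup`.
#' @export
stats_report <- function(rt, scale = "log", df_method = "wald",
                         alpha_normality = 0.05) {
  intra <- lapply(stats::setNames(nm = intersect(sessions, unique(rt$session))),
                  function(s) fit_intragroup(rt, s, scale = scale,
                                             df_method = df_method))
  inter <- if (all(sessions %in% rt$session)) {
    compare_groups(rt, alpha_normality = alpha_normality)
  } else NULL
  structure(list(summary = summarize_ratios(rt), intragroup = intra,
                 intergroup = inter),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, digits = 3, ...) {
  cat("== RMS ratio vs. baseline, within session (mixed-model contrasts) ==\n")
  for (s in names(x$intragroup)) {
    d <- x$intragroup[[s]]
    cat(sprintf("-- session: %s --\n", s))
    for (i in seq_len(nrow(d))) {
      cat(sprintf("  post%-3s ratio %.2f +/- %.2f   adj. p = %s\n",
                  ifelse(d$follow_up_min[i] == 0, "", d$follow_up_min[i]),
                  d$mean_ratio[i], d$sd_ratio[i],
                  format.pval(d$p_adj[i], digits = digits)))
    }
  }
  if (!is.null(x$intergroup)) {
    cat("== FMV vs. control, per follow-up point (paired tests) ==\n")
    d <- x$intergroup
    for (i in seq_len(nrow(d))) {
      cat(sprintf("  post%-3s %s: diff %+.3f   adj. p = %s\n",
                  ifelse(d$follow_up_min[i] == 0, "", d$follow_up_min[i]),
                  d$test_used[i], d$mean_diff[i],
                  format.pval(d$p_adj[i], digits = digits)))
    }
  }
  invisible(x)
}

#' Boxplot of ratio evolution over the follow-up period
#'
#' Builds (but does not print or save) a ggplot of per-time-point ratio
#' distributions for both sessions, with group means connected across time.
#'
#' @param rt a `ratio_table`.
#' @return A `ggplot` object.
#' @export
plot_ratio_boxplot <- function(rt) {
  d <- as.data.frame(rt)
  d$fup <- factor(d$follow_up_min, levels = sort(unique(d$follow_up_min)),
                  labels = paste0("Post ", sort(unique(d$follow_up_min))))
  means <- stats::aggregate(ratio ~ fup + session, d, mean)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fup, y = .data$ratio,
                                  fill = .data$session)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(width = 0.75),
                          outlier.size = 0.6, alpha = 0.7) +
    ggplot2::geom_point(data = means,
                        ggplot2::aes(group = .data$session, colour = .data$session),
                        position = ggplot2::position_dodge(width = 0.75), size = 2) +
    ggplot2::geom_line(data = means,
                       ggplot2::aes(group = .data$session, colour = .data$session),
                       position = ggplot2::position_dodge(width = 0.75),
                       linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::scale_fill_manual(values = c(control = "#4daf4a", fmv = "#ff7f00")) +
    ggplot2::scale_colour_manual(values = c(control = "#2e7d32", fmv = "#e65100")) +
    ggplot2::labs(x = "Follow-up point (min)", y = "Triceps RMS ratio (post/pre)",
                  fill = "Session", colour = "Session") +
    ggplot2::theme_minimal()
}

#' Write a stats report to CSV files
#'
#' @param report a `stats_report`.
#' @param dir output directory (created as needed). Writes `summary.csv`,
#'   `intragroup_<session>.csv` and `intergroup.csv`.
#' @return `dir`, invisibly.
#' @export
write_stats_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(report$summary, file.path(dir, "summary.csv"))
  for (s in names(report$intragroup)) {
    data.table::fwrite(as.data.frame(report$intragroup[[s]]),
                       file.path(dir, sprintf("intragroup_%s.csv", s)))
  }
  if (!is.null(report$intergroup)) {
    data.table::fwrite(as.data.frame(report$intergroup),
                       file.path(dir, "intergroup.csv"))
  }
  invisible(dir)
}
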