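#' Standardized mean difference between two arms
#'
#' `smd = (mean1 - mean0) / pooled sd`, with the large-sample SMD variance
#' `var(d) = (n1 + n0)/(n1 n0) + d^2 / (2 (n1 + n0))` for the 95% CI, and a
#' two-sided Welch t-test p-value for the mean difference. |SMD| < 0.1 is
#' the conventional balance threshold.
#'
#' @param values_arm1,values_arm0 numeric vectors (each n >= 2).
#' @return list with `smd`, `ci_low`, `ci_high`, `p_value`, `n1`, `n0`.
#' @export
#' @examples
#' compute_smd(c(1, 2, 3), c(0, 1, 2))  # smd = 1
compute_smd <- function(values_arm1, values_arm0) {
  n1 <- length(values_arm1)
  n0 <- length(values_arm0)
  if (n1 < 2L || n0 < 2L) stop_data("each arm needs at least 2 observations")
  v1 <- stats::var(values_arm1)
  v0 <- stats::var(values_arm0)
  pooled <- sqrt(((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2))
  if (!is.finite(pooled) || pooled == 0) {
    stop_data("zero pooled variance; SMD undefined")
  }
  d <- (mean(values_arm1) - mean(values_arm0)) / pooled
  se <- sqrt((n1 + n0) / (n1 * n0) + d^2 / (2 * (n1 + n0)))
  p <- stats::t.test(values_arm1, values_arm0)$p.value
  list(smd = d,
       ci_low = d - stats::qnorm(0.975) * se,
       ci_high = d + stats::qnorm(0.975) * se,
       p_value = p, n1 = n1, n0 = n0)
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / n_tests`; with the default alpha and 20 PGS this is 2.5e-3, and
#' with 18 traits 2.8e-3 (two significant figures).
#'
#' @param n_tests number of tests (>= 1).
#' @param alpha family-wise error rate.
#' @return the per-test threshold.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (!is_count(n_tests)) stop_config("n_tests must be a positive integer")
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    stop_config("alpha must be in (0, 1]")
  }
  alpha / n_tests
}

#' PGS balance trajectory across emulation stages
#'
#' Computes, for every PGS and every stage, the between-arm SMD with CI and
#' Welch p-value, flags significance at the Bonferroni threshold (strict
#' inequality), and summarizes the stage-wise mean |SMD| together with a
#' monotone-decrease flag — the diagnostic that genetic imbalance shrinks as
#' confounder adjustment increases.
#'
#' @param staged a [staged_cohorts()] object, or any named list of stage
#'   frames (data.frames with `treated` and `pgs_*` columns).
#' @param pgs_names traits to report (default: all `pgs_*` columns).
#' @param stages stage names, in adjustment order. All must be present.
#' @param alpha family-wise alpha for the Bonferroni threshold.
#' @return data.frame of class `balance_report` with columns `trait`,
#'   `stage`, `smd`, `ci_low`, `ci_high`, `p_value`, `significant`;
#'   attributes `mean_abs_smd` (named by stage), `monotone_decrease`,
#'   `threshold`.
#' @export
balance_trajectory <- function(staged, pgs_names = NULL,
                               stages = c("plain", "eligible", "matched"),
                               alpha = 0.05) {
  frames <- if (inherits(staged, "staged_cohorts")) {
    staged[intersect(c("plain", "eligible", "matched"), names(staged))]
  } else staged
  missing_st <- setdiff(stages, names(frames))
  if (length(missing_st)) {
    stop_data("stage(s) missing from input: ", paste(missing_st, collapse = ", "))
  }
  frames <- frames[stages]
  if (is.null(pgs_names)) {
    pgs_names <- sub("^pgs_", "", grep("^pgs_", names(frames[[1]]), value = TRUE))
  }
  threshold <- bonferroni_threshold(length(pgs_names), alpha)
  rows <- list()
  for (st in stages) {
    fr <- frames[[st]]
    for (tr in pgs_names) {
      col <- paste0("pgs_", tr)
      if (!col %in% names(fr)) stop_data("trait absent from stage frame: ", tr)
      s <- compute_smd(fr[[col]][fr$treated == 1], fr[[col]][fr$treated == 0])
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr, stage = st, smd = s$smd, ci_low = s$ci_low,
        ci_high = s$ci_high, p_value = s$p_value,
        significant = s$p_value < threshold, stringsAsFactors = FALSE)
    }
  }
  rep <- do.call(rbind, rows)
  rep$stage <- factor(rep$stage, levels = stages)
  mean_abs <- tapply(abs(rep$smd), rep$stage, mean)
  attr(rep, "mean_abs_smd") <- mean_abs
  attr(rep, "monotone_decrease") <-
    length(mean_abs) < 2L || all(diff(mean_abs) < 0)
  attr(rep, "threshold") <- threshold
  class(rep) <- c("balance_report", "data.frame")
  rep
}

#' Write a balance report as TSV
#'
#' @param report a `balance_report`.
#' @param path output path.
#' @export
write_balance_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Forest-style plot of the PGS balance trajectory
#'
#' One panel per stage; points are SMDs with 95% CI whiskers; the dashed
#' lines mark the conventional |SMD| = 0.1 balance band.
#'
#' @param report a `balance_report`.
#' @return a ggplot object.
#' @export
plot_balance <- function(report) {
  df <- as.data.frame(report)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$smd, y = .data$trait)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::geom_vline(xintercept = c(-0.1, 0.1), linetype = "dashed",
                        colour = "grey70") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant)) +
    ggplot2::facet_wrap(~stage, nrow = 1) +
    ggplot2::labs(x = "Standardized mean difference (treated - control)",
                  y = NULL, colour = "Bonferroni-significant") +
    ggplot2::theme_bw()
}
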