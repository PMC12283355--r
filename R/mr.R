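#' Select and harmonize genetic instruments for two-sample MR
#'
#' Builds the instrument set in three steps, in this order: (1) keep
#' variants genome-wide significant for the exposure (`p < p_thresh`);
#' (2) greedy LD clumping by ascending exposure p-value — keep the most
#' significant variant, drop every variant within `window_kb` on the same
#' chromosome whose LD with a kept variant is `r^2 >= clump_r2`, iterate;
#' (3) exclude variants associated with the outcome
#' (`p < outcome_p_thresh`). Exposure and outcome records are harmonized by
#' variant id first: when the effect/other alleles are swapped between the
#' samples the outcome beta is sign-flipped; irreconcilable alleles are
#' excluded with a message.
#'
#' @param exposure,outcome summary-statistics data.frames (see
#'   [read_summary_stats()] for the schema).
#' @param ld LD information: `NULL` (all pairs treated as unlinked), a
#'   symmetric r^2 matrix with variant-id dimnames, or a list
#'   `list(blocks = <named vector: variant_id -> block>, r2 = <within-block
#'   r^2>)` as produced by block-structured genotype panels.
#' @param p_thresh exposure significance threshold (default 5e-8).
#' @param clump_r2 LD r^2 threshold above which variants are clumped
#'   (default 0.001).
#' @param window_kb clumping window in kilobases, center-to-center on the
#'   same chromosome (default 10000, i.e. 10 Mb).
#' @param outcome_p_thresh outcome-association exclusion threshold.
#' @return data.frame of class `instrument_set` with `variant_id`,
#'   `chromosome`, `position_bp`, `beta_exposure`, `se_exposure`,
#'   `p_exposure`, `beta_outcome`, `se_outcome`, `p_outcome`; attribute
#'   `"provenance"` records per input variant which filter it failed.
#' @export
select_instruments <- function(exposure, outcome, ld = NULL,
                               p_thresh = 5e-8, clump_r2 = 0.001,
                               window_kb = 10000, outcome_p_thresh = 5e-8) {
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  ex <- exposure[match(shared, exposure$variant_id), ]
  ou <- outcome[match(shared, outcome$variant_id), ]

  same <- ex$effect_allele == ou$effect_allele & ex$other_allele == ou$other_allele
  swapped <- ex$effect_allele == ou$other_allele & ex$other_allele == ou$effect_allele
  bad <- !(same | swapped)
  if (any(bad)) {
    message("excluding ", sum(bad), " variant(s) with irreconcilable alleles: ",
            paste(utils::head(shared[bad], 5), collapse = ", "),
            if (sum(bad) > 5) " ...")
  }
  beta_out <- ifelse(swapped, -ou$beta, ou$beta)

  tab <- data.frame(variant_id = shared,
                    chromosome = ex$chromosome,
                    position_bp = ex$position_bp,
                    beta_exposure = ex$beta, se_exposure = ex$se,
                    p_exposure = ex$p,
                    beta_outcome = beta_out, se_outcome = ou$se,
                    p_outcome = ou$p, stringsAsFactors = FALSE)[!bad, ]

  passed_p <- tab$p_exposure < p_thresh
  cand <- tab[passed_p, ]
  cand <- cand[order(cand$p_exposure, cand$variant_id), ]

  pair_r2 <- function(v1, v2) {
    if (is.null(ld)) return(0)
    if (is.matrix(ld)) {
      if (all(c(v1, v2) %in% rownames(ld))) return(ld[v1, v2]) else return(0)
    }
    b1 <- ld$blocks[v1]
    b2 <- ld$blocks[v2]
    if (!is.na(b1) && !is.na(b2) && b1 == b2) ld$r2 else 0
  }
  kept <- character()
  dropped_clump <- character()
  for (i in seq_len(nrow(cand))) {
    vid <- cand$variant_id[i]
    if (vid %in% dropped_clump) next
    kept <- c(kept, vid)
    near <- cand$variant_id[cand$chromosome == cand$chromosome[i] &
                              abs(cand$position_bp - cand$position_bp[i]) <=
                                window_kb * 1000 &
                              cand$variant_id != vid]
    near <- setdiff(near, c(kept, dropped_clump))
    linked <- near[vapply(near, function(v) pair_r2(vid, v) >= clump_r2,
                          logical(1))]
    dropped_clump <- c(dropped_clump, linked)
  }
  survived_clump <- tab$variant_id %in% kept
  not_outcome <- tab$p_outcome >= outcome_p_thresh
  retained <- passed_p & survived_clump & not_outcome

  prov <- data.frame(variant_id = tab$variant_id, passed_p = passed_p,
                     survived_clump = survived_clump,
                     not_outcome_associated = not_outcome,
                     retained = retained, stringsAsFactors = FALSE)
  out <- tab[retained, , drop = FALSE]
  if (!nrow(out)) stop_data("no valid instruments survive selection")
  rownames(out) <- NULL
  attr(out, "provenance") <- prov
  class(out) <- c("instrument_set", "data.frame")
  out
}

#' Inverse-variance-weighted MR estimate
#'
#' Fixed-effect IVW:
#' `beta_ivw = sum(bX bY / seY^2) / sum(bX^2 / seY^2)`,
#' `se = 1 / sqrt(sum(bX^2 / seY^2))` — weighted least squares of the
#' per-variant Wald ratios through the origin. With
#' `method = "random"` the standard error is inflated by the multiplicative
#' overdispersion factor `sqrt(max(1, Q / (k - 1)))`. A single instrument
#' degenerates to the Wald ratio with a delta-method standard error and is
#' flagged (`wald_ratio` attribute).
#'
#' @param iv an `instrument_set` (or data.frame with `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`).
#' @param method `"fixed"` (default) or `"random"`.
#' @param exposure_scale note carried into the result: `"per_1_sd"` for
#'   continuous exposures, `"presence_vs_absence"` for binary ones.
#' @return object of class `mr_result`: `beta_ivw`, `se_ivw`, `p`,
#'   `or_estimate`, `ci_low`, `ci_high` (OR scale), `n_instruments`,
#'   `exposure_scale`.
#' @export
ivw_estimate <- function(iv, method = c("fixed", "random"),
                         exposure_scale = "per_1_sd") {
  method <- match.arg(method)
  if (any(iv$se_outcome <= 0) || any(iv$se_exposure <= 0)) {
    stop_data("all standard errors must be > 0")
  }
  k <- nrow(iv)
  if (k < 1L) stop_data("no instruments")
  wald <- FALSE
  if (k == 1L) {
    wald <- TRUE
    beta <- iv$beta_outcome / iv$beta_exposure
    se <- sqrt(iv$se_outcome^2 / iv$beta_exposure^2 +
                 iv$beta_outcome^2 * iv$se_exposure^2 / iv$beta_exposure^4)
  } else {
    w <- iv$beta_exposure^2 / iv$se_outcome^2
    beta <- sum(iv$beta_exposure * iv$beta_outcome / iv$se_outcome^2) / sum(w)
    se <- 1 / sqrt(sum(w))
    if (method == "random") {
      ratio <- iv$beta_outcome / iv$beta_exposure
      q <- sum(w * (ratio - beta)^2)
      se <- se * sqrt(max(1, q / (k - 1)))
    }
  }
  z <- beta / se
  res <- structure(list(beta_ivw = beta, se_ivw = se,
                        p = 2 * stats::pnorm(-abs(z)),
                        or_estimate = exp(beta),
                        ci_low = exp(beta - stats::qnorm(0.975) * se),
                        ci_high = exp(beta + stats::qnorm(0.975) * se),
                        n_instruments = k, method = method,
                        exposure_scale = exposure_scale),
                   class = "mr_result")
  attr(res, "wald_ratio") <- wald
  res
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("IVW (%s): OR %.3f (95%% CI %.3f-%.3f), beta %.4f (se %.4f), p = %.3g, %d instruments [%s]\n",
              x$method, x$or_estimate, x$ci_low, x$ci_high, x$beta_ivw,
              x$se_ivw, x$p, x$n_instruments, x$exposure_scale))
  invisible(x)
}

#' Three-step MR confounder classification
#'
#' Step 1: MR of the candidate trait on treatment initiation. Step 2: MR of
#' the trait on the trial outcome. Step 3: if both are significant, the
#' trait is classified a putative confounder that should be adjusted for in
#' the emulation. Significance uses strict inequality and is evaluated at
#' both a nominal and a Bonferroni threshold; the verdict is taken at
#' `use`.
#'
#' @param mr_treatment,mr_outcome `mr_result`s from [ivw_estimate()].
#' @param trait optional trait label.
#' @param alpha_nominal nominal threshold (default 0.05).
#' @param alpha_bonferroni multiplicity-corrected threshold (default
#'   0.05/18, the correction for 18 testable traits).
#' @param use which threshold drives the verdict.
#' @return object of class `confounder_verdict`: `trait`,
#'   `significant_on_treatment`, `significant_on_outcome`, `verdict` in
#'   `{putative_confounder, exposure_only, outcome_only, neither}`,
#'   `thresholds`, and per-threshold significance flags.
#' @export
classify_confounder <- function(mr_treatment, mr_outcome, trait = NA_character_,
                                alpha_nominal = 0.05,
                                alpha_bonferroni = bonferroni_threshold(18),
                                use = c("nominal", "bonferroni")) {
  use <- match.arg(use)
  if (!inherits(mr_treatment, "mr_result") || !inherits(mr_outcome, "mr_result")) {
    stop_config("both MR results are required")
  }
  thr <- if (use == "nominal") alpha_nominal else alpha_bonferroni
  sig_t <- mr_treatment$p < thr
  sig_o <- mr_outcome$p < thr
  verdict <- if (sig_t && sig_o) "putative_confounder"
  else if (sig_t) "exposure_only"
  else if (sig_o) "outcome_only"
  else "neither"
  structure(list(trait = trait,
                 significant_on_treatment = sig_t,
                 significant_on_outcome = sig_o,
                 verdict = verdict,
                 thresholds = c(nominal = alpha_nominal,
                                bonferroni = alpha_bonferroni, used = thr),
                 significant_nominal = c(treatment = mr_treatment$p < alpha_nominal,
                                         outcome = mr_outcome$p < alpha_nominal),
                 significant_bonferroni = c(treatment = mr_treatment$p < alpha_bonferroni,
                                            outcome = mr_outcome$p < alpha_bonferroni),
                 p_treatment = mr_treatment$p, p_outcome = mr_outcome$p),
            class = "confounder_verdict")
}

#' Direct-effect (mediation) adjustment of a confounder-on-treatment effect
#'
#' A trait's total causal effect on treatment initiation may be partly
#' mediated through the outcome trait itself (the outcome influencing
#' prescription). The direct effect removes that path:
#' `direct = total_CX - effect_CY * effect_YX`, with a delta-method standard
#' error assuming the three estimates are independent. The trait is flagged
#' a putative confounder only if the direct effect remains significant.
#'
#' @param total_CX `mr_result` for the trait's total effect on treatment.
#' @param effect_CY `mr_result` for the trait's effect on the outcome.
#' @param effect_YX mediator-path estimate (outcome on treatment), a number.
#' @param effect_YX_se its standard error (0 if treated as fixed).
#' @param alpha significance level for the flag.
#' @return list with `beta_direct`, `se`, `p`, `significant`.
#' @export
direct_effect_adjustment <- function(total_CX, effect_CY, effect_YX,
                                     effect_YX_se = 0, alpha = 0.05) {
  if (!inherits(total_CX, "mr_result") || !inherits(effect_CY, "mr_result")) {
    stop_config("total_CX and effect_CY must be mr_result objects")
  }
  if (missing(effect_YX) || is.null(effect_YX) || !is.finite(effect_YX)) {
    stop_config("mediator-path estimate effect_YX is required")
  }
  direct <- total_CX$beta_ivw - effect_CY$beta_ivw * effect_YX
  se <- sqrt(total_CX$se_ivw^2 +
               effect_YX^2 * effect_CY$se_ivw^2 +
               effect_CY$beta_ivw^2 * effect_YX_se^2)
  p <- 2 * stats::pnorm(-abs(direct / se))
  list(beta_direct = direct, se = se, p = p, significant = p < alpha)
}
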