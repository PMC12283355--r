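#' Prognostic association of an outcome PGS within a matched trial cohort
#'
#' Cox model `h(t | T, PGS) = h0(t) exp(b1 T + b2 PGS)`: the PGS hazard
#' ratio per 1 sd, adjusted for the treatment arm, estimated on on-treatment
#' follow-up records of the matched cohort.
#'
#' @param records `survival_records` from [build_followup()].
#' @param pgs numeric PGS vector aligned with `records` rows.
#' @return a `cox_result` for the PGS term; the treatment term's result is
#'   attached as attribute `"treatment_result"`.
#' @export
prognostic_association <- function(records, pgs) {
  if (length(pgs) != nrow(records)) {
    stop_config("pgs must align with the follow-up records")
  }
  if (stats::sd(pgs) == 0) stop_data("constant PGS: association not identified")
  res <- fit_cox(records, include_pgs = pgs)
  out <- attr(res, "pgs_result")
  attr(out, "treatment_result") <- res
  out
}

#' Population-wide association of an outcome PGS
#'
#' Cox fit of the primary outcome on the PGS in the full cohort with age as
#' the timescale: survival time runs from birth to the earliest of the
#' outcome, death, or end of registry. By default everyone is analyzed from
#' birth; `left_truncate = TRUE` instead treats age at cohort entry as
#' delayed entry.
#'
#' @param cohort a full `cohort`.
#' @param trait trait name whose PGS is tested.
#' @param left_truncate use age at entry as delayed-entry time.
#' @return a `cox_result` for the PGS term.
#' @export
population_association <- function(cohort, trait, left_truncate = FALSE) {
  if (!trait %in% colnames(cohort$pgs)) stop_config("unknown trait: ", trait)
  ind <- cohort$individuals
  end_day <- pmax(pmin(ind$event_date, ind$death_date,
                       cohort$config$registry_end, na.rm = TRUE), 0.5)
  event <- !is.na(ind$event_date) & ind$event_date <= end_day
  age_end <- ind$age_years + end_day / 365.25
  dat <- data.frame(age_entry = ind$age_years, age_end = age_end,
                    event = event, pgs = cohort$pgs[, trait])
  if (stats::sd(dat$pgs) == 0) stop_data("constant PGS: association not identified")
  if (sum(dat$event) < 1L) stop_data("Cox fit requires at least one event")
  fml <- if (left_truncate) {
    survival::Surv(age_entry, age_end, event) ~ pgs
  } else {
    survival::Surv(age_end, event) ~ pgs
  }
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  cox_result(fit, "pgs", nrow(dat), sum(dat$event))
}

#' Event rates overall and in the top PGS quantile
#'
#' Events per person among all follow-up records and among records whose
#' PGS exceeds the `1 - q` quantile. By default the quantile cut is taken
#' from the full-population PGS distribution (a standardized PGS has the cut
#' at `qnorm(1 - q)` in expectation), matching a "top 25% genetic risk"
#' recruitment rule; `basis = "records"` uses the analyzed records' own
#' distribution.
#'
#' @param records `survival_records`.
#' @param pgs numeric PGS vector aligned with `records`.
#' @param q top-quantile fraction (default 0.25).
#' @param basis `"population"` (cut at `qnorm(1 - q)` of the standardized
#'   scale) or `"records"`.
#' @return list with `event_rate_all`, `event_rate_topq`, `cutoff`,
#'   `n_all`, `n_topq`.
#' @export
top_quantile_event_rates <- function(records, pgs, q = 0.25,
                                     basis = c("population", "records")) {
  basis <- match.arg(basis)
  if (q <= 0 || q >= 1) stop_config("q must lie in (0, 1)")
  if (length(pgs) != nrow(records)) stop_config("pgs must align with records")
  cutoff <- if (basis == "population") stats::qnorm(1 - q) else
    stats::quantile(pgs, 1 - q, names = FALSE)
  top <- pgs > cutoff
  if (!any(top)) stop_data("no individuals in the top PGS quantile")
  list(event_rate_all = mean(records$event),
       event_rate_topq = mean(records$event[top]),
       cutoff = cutoff, n_all = nrow(records), n_topq = sum(top))
}

#' Sample-size reduction from prognostic enrichment
#'
#' Operationalizes "same statistical power" as the same expected number of
#' events: recruiting only high-PGS individuals with event rate
#' `event_rate_topq` needs
#' `n_required = n_original * event_rate_all / event_rate_topq` participants
#' to accrue the original trial's expected events. With
#' `method = "schoenfeld"` the required events come from Schoenfeld's
#' log-rank formula `d = 4 (z_{1-alpha/2} + z_{power})^2 / log(hr)^2` and
#' are converted to sample sizes with each rate — the reduction percentage
#' is identical, but absolute sizes refer to the planned effect.
#'
#' @param event_rate_all event rate under unrestricted recruitment, in
#'   `(0, 1]`.
#' @param event_rate_topq event rate in the top PGS quantile, in `(0, 1]`
#'   (a warning is issued when it is below `event_rate_all`).
#' @param n_original planned sample size of the original design.
#' @param method `"events"` (default) or `"schoenfeld"`.
#' @param hr,alpha,power design parameters for the Schoenfeld variant.
#' @return list with `n_required`, `pct_reduction`
#'   (`100 (1 - n_required/n_original)`), `method` and, for Schoenfeld,
#'   `events_required`.
#' @export
enrichment_sample_size <- function(event_rate_all, event_rate_topq,
                                   n_original,
                                   method = c("events", "schoenfeld"),
                                   hr = 0.8, alpha = 0.05, power = 0.8) {
  method <- match.arg(method)
  if (!is.numeric(event_rate_all) || event_rate_all <= 0 || event_rate_all > 1 ||
      !is.numeric(event_rate_topq) || event_rate_topq > 1) {
    stop_config("event rates must lie in (0, 1]")
  }
  if (event_rate_topq <= 0) stop_data("zero event rate in the top quantile")
  if (event_rate_topq < event_rate_all) {
    warning("top-quantile event rate below the overall rate; enrichment increases the required size")
  }
  if (!is_count(n_original, 2)) stop_config("n_original must be an integer >= 2")
  out <- list(method = method)
  if (method == "events") {
    out$n_required <- n_original * event_rate_all / event_rate_topq
  } else {
    d <- 4 * (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2 / log(hr)^2
    out$events_required <- d
    out$n_required <- d / event_rate_topq
    n_original <- d / event_rate_all
    out$n_original_implied <- n_original
  }
  out$n_original <- n_original
  out$pct_reduction <- 100 * (1 - out$n_required / n_original)
  out
}

#' Predictive enrichment: PGS-by-treatment interaction
#'
#' Cox model with treatment, PGS and their product; returns the Wald
#' p-value of the interaction term — evidence that treatment benefit varies
#' with genetic risk.
#'
#' @param records `survival_records`.
#' @param pgs numeric PGS vector aligned with `records`.
#' @return list with `interaction_p`, `log_hr_interaction`, `se` and the
#'   fitted model.
#' @export
predictive_interaction <- function(records, pgs) {
  if (length(pgs) != nrow(records)) stop_config("pgs must align with records")
  if (stats::sd(pgs) == 0) stop_data("constant PGS: interaction not identified")
  if (sum(records$event) < 1L) stop_data("Cox fit requires at least one event")
  dat <- data.frame(time = records$time_days, event = records$event,
                    treated = records$treated, pgs = as.numeric(pgs))
  fit <- survival::coxph(survival::Surv(time, event) ~ treated * pgs,
                         data = dat, ties = "efron")
  co <- summary(fit)$coefficients
  if (anyNA(stats::coef(fit))) stop_numeric("interaction model has aliased terms")
  list(interaction_p = co["treated:pgs", "Pr(>|z|)"],
       log_hr_interaction = co["treated:pgs", "coef"],
       se = co["treated:pgs", "se(coef)"],
       model = fit)
}

#' Full PGS enrichment evaluation
#'
#' Bundles the prognostic association within the matched cohort, the
#' population-wide association, the top-quantile event rates with the
#' implied sample-size reduction, and the predictive interaction test.
#'
#' @param staged a [staged_cohorts()] object.
#' @param cohort the full `cohort` the stages came from.
#' @param trait outcome-PGS trait name.
#' @param q top-quantile fraction.
#' @param method sample-size method, see [enrichment_sample_size()].
#' @return list of class `enrichment_result`.
#' @export
evaluate_enrichment <- function(staged, cohort, trait, q = 0.25,
                                method = "events") {
  records <- build_followup(staged$matched_cohort)
  mc <- staged$matched_cohort
  pgs <- mc$pgs[match(records$individual_id, mc$individuals$individual_id), trait]
  rates <- top_quantile_event_rates(records, pgs, q = q)
  ss <- enrichment_sample_size(rates$event_rate_all, rates$event_rate_topq,
                               n_original = nrow(records), method = method)
  structure(list(hr_trial = prognostic_association(records, pgs),
                 hr_population = population_association(cohort, trait),
                 event_rate_all = rates$event_rate_all,
                 event_rate_topq = rates$event_rate_topq,
                 q = q,
                 n_original = ss$n_original,
                 n_required = ss$n_required,
                 pct_reduction = ss$pct_reduction,
                 interaction_p = predictive_interaction(records, pgs)$interaction_p,
                 trait = trait),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("PGS enrichment evaluation for", x$trait, "\n")
  cat(sprintf("  trial HR/sd      %.3f (%.3f-%.3f)\n", x$hr_trial$hr,
              x$hr_trial$ci_low, x$hr_trial$ci_high))
  cat(sprintf("  population HR/sd %.3f (%.3f-%.3f)\n", x$hr_population$hr,
              x$hr_population$ci_low, x$hr_population$ci_high))
  cat(sprintf("  event rate all/top%d%%: %.4f / %.4f\n", round(100 * x$q),
              x$event_rate_all, x$event_rate_topq))
  cat(sprintf("  sample size %d -> %.0f (%.1f%% reduction)\n",
              x$n_original, x$n_required, x$pct_reduction))
  cat(sprintf("  PGS x treatment interaction p = %.3g\n", x$interaction_p))
  invisible(x)
}
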