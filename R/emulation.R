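#' Declare a target-trial emulation protocol
#'
#' A declarative description of the emulation: eligibility rules with
#' look-back windows, the comparison design, the covariate set for the
#' propensity score (PS), the matching caliper, and the reference randomized
#' trial estimate against which agreement is judged.
#'
#' @param name protocol label.
#' @param design `"placebo_proxy"` (plain stage compares target-drug
#'   initiators vs everyone who did not initiate the target drug; an active
#'   comparator stands in for placebo from the eligible stage on) or
#'   `"active_comparator"` (target vs comparator initiators at every stage).
#' @param eligibility_rules list of rules, each a list with `covariate`
#'   (a trait/flag name), `require` (`TRUE`: the flag must be present before
#'   initiation; `FALSE`: it must be absent), and optional `window_days`
#'   (look-back window before initiation; `NULL` or `Inf` = any time
#'   before).
#' @param covariates_for_ps character vector of flag names entering the PS
#'   model, measured at (i.e. with onset on or before) initiation.
#' @param caliper `"auto"` (0.1 on the PS scale, tightened to 0.01 when the
#'   arm-wise PS density overlap coefficient exceeds 0.98) or a positive
#'   number.
#' @param outcome outcome label (the synthetic cohort has one primary
#'   outcome).
#' @param rct_reference length-3 numeric `c(hr, ci_low, ci_high)` from the
#'   reference trial, or `NULL`.
#' @return an object of class `trial_protocol`.
#' @export
trial_protocol <- function(name = "emulation",
                           design = c("placebo_proxy", "active_comparator"),
                           eligibility_rules = list(),
                           covariates_for_ps = character(),
                           caliper = "auto",
                           outcome = "primary",
                           rct_reference = NULL) {
  design <- match.arg(design)
  if (is.numeric(caliper) && caliper <= 0) stop_config("caliper must be > 0")
  if (!is.numeric(caliper) && !identical(caliper, "auto")) {
    stop_config("caliper must be a positive number or \"auto\"")
  }
  for (r in eligibility_rules) {
    if (is.null(r$covariate)) stop_config("every eligibility rule needs a covariate")
  }
  if (!is.null(rct_reference)) {
    if (length(rct_reference) != 3L || anyNA(rct_reference)) {
      stop_config("rct_reference must be c(hr, ci_low, ci_high)")
    }
    if (rct_reference[2] > rct_reference[3]) {
      stop_config("malformed RCT CI: lower bound exceeds upper bound")
    }
  }
  structure(list(name = name, design = design,
                 eligibility_rules = eligibility_rules,
                 covariates_for_ps = covariates_for_ps,
                 caliper = caliper, outcome = outcome,
                 rct_reference = rct_reference),
            class = "trial_protocol")
}

#' Read / write a trial protocol as YAML
#'
#' @param path YAML file path.
#' @return a `trial_protocol` (read) or `path` invisibly (write).
#' @export
read_trial_protocol <- function(path) {
  y <- yaml::read_yaml(path)
  y$rct_reference <- if (!is.null(y$rct_reference)) as.numeric(unlist(y$rct_reference))
  y$covariates_for_ps <- as.character(unlist(y$covariates_for_ps))
  do.call(trial_protocol, y)
}

#' @rdname read_trial_protocol
#' @param protocol a `trial_protocol`.
#' @export
write_trial_protocol <- function(protocol, path) {
  yaml::write_yaml(unclass(protocol), path)
  invisible(path)
}

# Flag status "measured at initiation": onset on or before the initiation
# date, optionally within a look-back window.
flag_at_initiation <- function(cohort, covariate, window_days = NULL) {
  if (!covariate %in% colnames(cohort$flags)) {
    stop_config("unknown covariate in rule: ", covariate)
  }
  onset <- cohort$flag_onset[, covariate]
  init <- cohort$individuals$initiation_date
  present <- cohort$flags[, covariate] == 1L & !is.na(onset) & !is.na(init) &
    onset <= init
  if (!is.null(window_days) && is.finite(window_days)) {
    present <- present & (init - onset) <= window_days
  }
  present
}

#' Apply eligibility criteria to a cohort
#'
#' Restricts to initiators of the target drug or comparator and then applies
#' each rule in order at the individual's initiation date. The attrition log
#' (attribute `"attrition"`) records the count removed per rule, mirroring a
#' cohort-formation flowchart.
#'
#' @param cohort a `cohort`.
#' @param protocol a [trial_protocol()].
#' @return the eligible `cohort`, with an `"attrition"` data.frame attribute
#'   (`step`, `n_before`, `n_removed`, `n_after`).
#' @export
apply_eligibility <- function(cohort, protocol) {
  for (r in protocol$eligibility_rules) {
    if (!r$covariate %in% colnames(cohort$flags)) {
      stop_config("eligibility rule references unknown covariate: ", r$covariate)
    }
  }
  keep <- cohort$individuals$arm %in% c("target_drug", "comparator")
  log <- data.frame(step = "initiator_of_target_or_comparator",
                    n_before = nrow(cohort$individuals),
                    n_removed = sum(!keep), n_after = sum(keep),
                    stringsAsFactors = FALSE)
  current <- subset_cohort(cohort, cohort$individuals$individual_id[keep])
  for (r in protocol$eligibility_rules) {
    present <- flag_at_initiation(current, r$covariate, r$window_days)
    ok <- if (isTRUE(r$require %||% TRUE)) present else !present
    lbl <- paste0(if (isTRUE(r$require %||% TRUE)) "require_" else "exclude_",
                  r$covariate,
                  if (!is.null(r$window_days) && is.finite(r$window_days)) {
                    paste0("_within_", r$window_days, "d")
                  } else "")
    log <- rbind(log, data.frame(step = lbl, n_before = nrow(current$individuals),
                                 n_removed = sum(!ok), n_after = sum(ok),
                                 stringsAsFactors = FALSE))
    current <- subset_cohort(current, current$individuals$individual_id[ok])
  }
  attr(current, "attrition") <- log
  current
}

#' Estimate the propensity score
#'
#' Main-effects logistic regression of the treated indicator (target drug vs
#' comparator) on the protocol covariates measured at initiation. Errors on
#' separation or a singular design, naming the offending covariates.
#'
#' @param eligible an eligible `cohort` (both arms nonempty).
#' @param covariates character vector of covariate names: a trait name uses
#'   its binary diagnosis flag at initiation; a name prefixed `conf_` uses
#'   the measured continuous trait value (e.g. a lab measurement).
#' @return numeric vector of fitted probabilities in (0,1), named by
#'   individual id; the fitted `glm` is attached as attribute `"model"`.
#' @export
estimate_propensity <- function(eligible, covariates) {
  arm <- eligible$individuals$arm
  treated <- as.integer(arm == "target_drug")
  if (length(unique(treated)) < 2L) stop_data("both arms must be nonempty")
  if (!length(covariates)) stop_config("covariate list is empty")
  x <- vapply(covariates, function(cv) {
    if (startsWith(cv, "conf_")) {
      tr <- sub("^conf_", "", cv)
      if (!tr %in% colnames(eligible$confounders)) {
        stop_config("unknown covariate in PS model: ", cv)
      }
      eligible$confounders[, tr]
    } else {
      as.numeric(flag_at_initiation(eligible, cv))
    }
  }, numeric(nrow(eligible$individuals)))
  colnames(x) <- make.names(covariates)
  dat <- data.frame(treated = treated, x)
  fit <- suppressWarnings(stats::glm(treated ~ ., data = dat,
                                     family = stats::binomial()))
  co <- stats::coef(fit)
  bad <- names(co)[is.na(co)]
  ps <- stats::fitted(fit)
  eps <- 1e-8
  if (length(bad)) {
    stop_numeric("singular propensity design; aliased covariates: ",
                 paste(bad, collapse = ", "))
  }
  if (!fit$converged || any(ps < eps | ps > 1 - eps)) {
    # identify covariates perfectly predicting the arm
    sep <- covariates[vapply(covariates, function(cv) {
      tab <- table(dat[[cv]], treated)
      any(rowSums(tab > 0) == 1L & rowSums(tab) > 0)
    }, logical(1))]
    stop_numeric("separation in propensity model",
                 if (length(sep)) paste0("; offending covariates: ",
                                         paste(sep, collapse = ", ")) else "")
  }
  names(ps) <- eligible$individuals$individual_id
  attr(ps, "model") <- fit
  ps
}

#' Overlap coefficient of arm-wise propensity densities
#'
#' Integral of the pointwise minimum of the two kernel density estimates;
#' 1 = identical distributions. Used by the automatic caliper rule.
#'
#' @param ps propensity vector.
#' @param treated logical/0-1 vector aligned with `ps`.
#' @return overlap coefficient in `[0, 1]`.
#' @export
overlap_coefficient <- function(ps, treated) {
  treated <- as.logical(treated)
  grid <- seq(min(ps), max(ps), length.out = 512)
  if (diff(range(ps)) == 0) return(1)
  d1 <- stats::density(ps[treated], from = grid[1], to = grid[512], n = 512)
  d0 <- stats::density(ps[!treated], from = grid[1], to = grid[512], n = 512)
  sum(pmin(d1$y, d0$y)) * diff(grid[1:2])
}

resolve_caliper <- function(caliper, ps, treated) {
  if (is.numeric(caliper)) return(caliper)
  if (overlap_coefficient(ps, treated) > 0.98) 0.01 else 0.1
}

#' 1:1 greedy nearest-neighbor propensity matching with a caliper
#'
#' Treated individuals are processed in a seeded random order; each is
#' matched without replacement to the comparator with the nearest PS within
#' the caliper (ties broken by lowest comparator id). Unmatched treated
#' individuals are dropped.
#'
#' @param ps named propensity vector (names = individual ids).
#' @param treated logical/0-1 vector aligned with `ps`.
#' @param caliper maximum allowed PS distance (> 0).
#' @param seed integer seed for the processing order.
#' @return list with `pairs` (data.frame `treated_id`, `control_id`,
#'   `distance`), `matched_ids`, `n_treated`, `n_control`, `n_matched`,
#'   `discard_fraction_treated` and the resolved `caliper`.
#' @export
match_nearest_neighbor <- function(ps, treated, caliper = 0.1, seed = 1L) {
  if (!is.numeric(caliper) || caliper <= 0) stop_config("caliper must be > 0")
  treated <- as.logical(treated)
  ids <- names(ps) %||% as.character(seq_along(ps))
  t_idx <- which(treated)
  c_idx <- which(!treated)
  if (!length(t_idx) || !length(c_idx)) stop_data("matching needs both arms nonempty")
  set.seed(split_seed(seed, 1L))
  order_t <- sample(t_idx)
  c_ids_num <- suppressWarnings(as.numeric(ids[c_idx]))
  if (anyNA(c_ids_num)) c_ids_num <- order(ids[c_idx])  # lexicographic fallback
  available <- rep(TRUE, length(c_idx))
  pairs <- vector("list", length(order_t))
  np <- 0L
  for (ti in order_t) {
    d <- abs(ps[c_idx] - ps[ti])
    d[!available] <- Inf
    best <- min(d)
    if (!is.finite(best) || best > caliper) next
    cand <- which(d == best)
    pick <- cand[which.min(c_ids_num[cand])]
    available[pick] <- FALSE
    np <- np + 1L
    pairs[[np]] <- data.frame(treated_id = ids[ti], control_id = ids[c_idx[pick]],
                              distance = best, stringsAsFactors = FALSE)
  }
  pairs <- if (np) do.call(rbind, pairs[seq_len(np)]) else
    data.frame(treated_id = character(), control_id = character(),
               distance = numeric(), stringsAsFactors = FALSE)
  list(pairs = pairs,
       matched_ids = c(pairs$treated_id, pairs$control_id),
       n_treated = length(t_idx), n_control = length(c_idx),
       n_matched = nrow(pairs),
       discard_fraction_treated = 1 - nrow(pairs) / length(t_idx),
       caliper = caliper)
}

stage_frame <- function(cohort, treated_logical) {
  pgs <- as.data.frame(cohort$pgs)
  names(pgs) <- paste0("pgs_", colnames(cohort$pgs))
  cbind(data.frame(individual_id = cohort$individuals$individual_id,
                   treated = as.integer(treated_logical)), pgs)
}

#' Build the three emulation stages of a cohort
#'
#' Stage 1 (`plain`): the plain observational contrast — target-drug
#' initiators vs all individuals who did not initiate the target drug
#' (placebo-proxy designs) or vs active-comparator initiators
#' (active-comparator designs). Stage 2 (`eligible`): target vs comparator
#' initiators after the eligibility criteria. Stage 3 (`matched`): after 1:1
#' PS nearest-neighbor matching. Stages are nested by individual id.
#'
#' @param cohort a `cohort`.
#' @param protocol a [trial_protocol()].
#' @param seed integer seed (matching order).
#' @return an object of class `staged_cohorts`: list with stage frames
#'   `plain`, `eligible`, `matched` (columns `individual_id`, `treated`,
#'   `pgs_*`), plus `eligible_cohort`, `matched_cohort`, `ps`, `match`,
#'   `attrition`, `caliper`.
#' @export
staged_cohorts <- function(cohort, protocol, seed = 1L) {
  arm <- cohort$individuals$arm
  if (protocol$design == "placebo_proxy") {
    plain <- stage_frame(cohort, arm == "target_drug")
  } else {
    sub <- subset_cohort(cohort,
                         cohort$individuals$individual_id[arm %in% c("target_drug", "comparator")])
    plain <- stage_frame(sub, sub$individuals$arm == "target_drug")
  }
  eligible_cohort <- apply_eligibility(cohort, protocol)
  eligible <- stage_frame(eligible_cohort,
                          eligible_cohort$individuals$arm == "target_drug")
  ps <- estimate_propensity(eligible_cohort, protocol$covariates_for_ps)
  treated <- eligible_cohort$individuals$arm == "target_drug"
  caliper <- resolve_caliper(protocol$caliper, ps, treated)
  match <- match_nearest_neighbor(ps, treated, caliper = caliper, seed = seed)
  matched_ids <- as.integer(match$matched_ids)
  matched_cohort <- subset_cohort(eligible_cohort, matched_ids)
  matched <- stage_frame(matched_cohort,
                         matched_cohort$individuals$arm == "target_drug")
  structure(list(plain = plain, eligible = eligible, matched = matched,
                 eligible_cohort = eligible_cohort,
                 matched_cohort = matched_cohort,
                 ps = ps, match = match,
                 attrition = attr(eligible_cohort, "attrition"),
                 caliper = caliper),
            class = "staged_cohorts")
}

#' Construct on-treatment follow-up survival records
#'
#' Follow-up starts at the first purchase and ends at the earliest of:
#' primary outcome event, death, therapy discontinuation (last purchase date
#' + total purchased packages x `package_days`; note this credits all
#' purchased supply from the last purchase onward), switch to the opposing
#' drug, or end of registry. The event flag is set only when the outcome is
#' the earliest terminator. Individuals without any purchase are excluded
#' with a warning.
#'
#' @param cohort a matched (or any initiator) `cohort`.
#' @param protocol a [trial_protocol()] (outcome label only; supply length
#'   comes from the cohort config).
#' @return data.frame of class `survival_records`: `individual_id`, `treated`
#'   (0/1), `time_days` (> 0), `event` (logical), `terminator`.
#' @export
build_followup <- function(cohort, protocol = NULL) {
  ind <- cohort$individuals
  ind <- ind[ind$arm %in% c("target_drug", "comparator"), , drop = FALSE]
  pd <- cohort$config$package_days
  reg_end <- cohort$config$registry_end
  has_purchase <- ind$individual_id %in% cohort$purchases$individual_id
  if (any(!has_purchase)) {
    warning(sum(!has_purchase), " initiator(s) without purchases excluded from follow-up")
    ind <- ind[has_purchase, , drop = FALSE]
  }
  if (!nrow(ind)) stop_data("no initiators with purchases to follow up")
  out <- lapply(seq_len(nrow(ind)), function(i) {
    id <- ind$individual_id[i]
    pp <- cohort$purchases[cohort$purchases$individual_id == id, , drop = FALSE]
    first <- min(pp$date)
    disc <- max(pp$date) + sum(pp$n_packages) * pd
    cand <- c(event = unname(ind$event_date[i]),
              death = unname(ind$death_date[i]),
              discontinuation = disc,
              switch = unname(ind$switch_date[i]),
              registry_end = reg_end)
    end <- min(cand, na.rm = TRUE)
    term <- names(cand)[which(cand == end)][1]  # event wins ties (listed first)
    data.frame(individual_id = id,
               treated = as.integer(ind$arm[i] == "target_drug"),
               time_days = max(end - first, 0.5),
               event = identical(term, "event"),
               terminator = term, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("survival_records", "data.frame")
  res
}

cox_result <- function(fit, term, n, n_events) {
  co <- summary(fit)$coefficients
  log_hr <- co[term, "coef"]
  se <- co[term, "se(coef)"]
  structure(list(hr = exp(log_hr),
                 ci_low = exp(log_hr - stats::qnorm(0.975) * se),
                 ci_high = exp(log_hr + stats::qnorm(0.975) * se),
                 log_hr = log_hr, se = se,
                 p = co[term, "Pr(>|z|)"],
                 n = n, n_events = n_events, term = term, model = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH [%s]: HR %.3f (95%% CI %.3f-%.3f), p = %.3g, n = %d, events = %d\n",
              x$term, x$hr, x$ci_low, x$ci_high, x$p, x$n, x$n_events))
  invisible(x)
}

#' Fit a Cox proportional-hazards model to follow-up records
#'
#' Partial-likelihood estimation with Efron's tie handling; the treatment
#' hazard ratio (and optionally a per-1-sd PGS term) with Wald 95% CI
#' `exp(log_hr +/- 1.96 se)`.
#'
#' @param records `survival_records` from [build_followup()].
#' @param include_pgs `FALSE`, or a numeric PGS vector aligned with
#'   `records` rows.
#' @return a `cox_result` for the treatment term; when a PGS is included the
#'   PGS term's `cox_result` is attached as attribute `"pgs_result"`.
#' @export
fit_cox <- function(records, include_pgs = FALSE) {
  if (!nrow(records) || sum(records$event) < 1L) {
    stop_data("Cox fit requires at least one event")
  }
  dat <- data.frame(time = records$time_days, event = records$event,
                    treated = records$treated)
  fml <- survival::Surv(time, event) ~ treated
  if (!isFALSE(include_pgs)) {
    dat$pgs <- as.numeric(include_pgs)
    fml <- survival::Surv(time, event) ~ treated + pgs
  }
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  if (any(is.na(stats::coef(fit)))) {
    stop_numeric("Cox model did not converge or has aliased terms")
  }
  res <- cox_result(fit, "treated", nrow(dat), sum(dat$event))
  if (!isFALSE(include_pgs)) {
    attr(res, "pgs_result") <- cox_result(fit, "pgs", nrow(dat), sum(dat$event))
  }
  res
}

#' Assess estimate agreement with the reference randomized trial
#'
#' TRUE iff the emulation's point hazard ratio lies inside the reference
#' trial's 95% confidence interval (closed interval: a point exactly on a
#' bound agrees).
#'
#' @param emulation a `cox_result` or a single HR.
#' @param rct_reference numeric `c(hr, ci_low, ci_high)`.
#' @return logical.
#' @export
estimate_agreement <- function(emulation, rct_reference) {
  hr <- if (inherits(emulation, "cox_result")) emulation$hr else as.numeric(emulation)
  if (length(rct_reference) != 3L || anyNA(rct_reference)) {
    stop_config("rct_reference must be c(hr, ci_low, ci_high)")
  }
  if (rct_reference[2] > rct_reference[3]) {
    stop_config("malformed RCT CI: lower bound exceeds upper bound")
  }
  rct_reference[2] <= hr && hr <= rct_reference[3]
}

#' Kaplan-Meier survival curves per arm
#'
#' Product-limit estimate with Greenwood variance (log-scale 95% CI), one
#' curve per arm, anchored at S(0) = 1.
#'
#' @param records `survival_records`.
#' @return data.frame with `arm`, `time`, `n_risk`, `n_event`, `surv`,
#'   `lower`, `upper`.
#' @export
kaplan_meier <- function(records) {
  if (!nrow(records)) stop_data("no records for Kaplan-Meier estimation")
  dat <- data.frame(time = records$time_days, event = records$event,
                    arm = ifelse(records$treated == 1, "target_drug", "comparator"))
  fit <- survival::survfit(survival::Surv(time, event) ~ arm, data = dat,
                           conf.type = "log")
  strata <- if (is.null(fit$strata)) {
    rep(unique(dat$arm), length(fit$time))
  } else {
    rep(sub("^arm=", "", names(fit$strata)), fit$strata)
  }
  out <- data.frame(arm = strata, time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv,
                    lower = fit$lower, upper = fit$upper,
                    stringsAsFactors = FALSE)
  anchor <- do.call(rbind, lapply(unique(out$arm), function(a) {
    data.frame(arm = a, time = 0, n_risk = sum(dat$arm == a), n_event = 0,
               surv = 1, lower = 1, upper = 1, stringsAsFactors = FALSE)
  }))
  out <- rbind(anchor, out)
  out[order(out$arm, out$time), ]
}
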