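test_that("eligibility rules filter at the initiation date and log attrition", {
  ch <- make_eligibility_cohort()
  proto0 <- trial_protocol(eligibility_rules = list())
  out0 <- apply_eligibility(ch, proto0)
  expect_equal(out0$individuals$individual_id, 1:10)  # identity (all initiators)

  proto1 <- trial_protocol(eligibility_rules = list(
    list(covariate = "trait01", require = TRUE)))
  out1 <- apply_eligibility(ch, proto1)
  expect_equal(out1$individuals$individual_id, 1:6)  # onset must precede initiation

  # look-back window: onset at day 500 is 500 days before initiation
  proto_w <- trial_protocol(eligibility_rules = list(
    list(covariate = "trait01", require = TRUE, window_days = 180)))
  expect_equal(nrow(apply_eligibility(ch, proto_w)$individuals), 0)

  # two overlapping rules: counts chain consistently with set intersection
  proto2 <- trial_protocol(eligibility_rules = list(
    list(covariate = "trait01", require = TRUE),
    list(covariate = "trait02", require = TRUE)))
  out2 <- apply_eligibility(ch, proto2)
  expect_equal(out2$individuals$individual_id, 1:3)
  att <- attr(out2, "attrition")
  expect_equal(att$n_after, c(10, 6, 3))
  expect_equal(att$n_before - att$n_removed, att$n_after)

  expect_error(apply_eligibility(ch, trial_protocol(eligibility_rules = list(
    list(covariate = "nope", require = TRUE)))), "unknown covariate")
})

test_that("propensity scores match an independently maximized likelihood", {
  env <- shared_confounded()
  elig <- apply_eligibility(subset_cohort(env$cohort, 1:4000), env$protocol)
  covs <- c("trait01", "trait02")
  ps <- estimate_propensity(elig, covs)
  expect_true(all(ps > 0 & ps < 1))

  # independent oracle: direct Newton-free optimization of the binomial
  # log-likelihood over (intercept, b1, b2)
  y <- as.integer(elig$individuals$arm == "target_drug")
  x <- cbind(1,
             vapply(covs, function(cv) {
               on <- elig$flag_onset[, cv]
               as.numeric(elig$flags[, cv] == 1 & !is.na(on) &
                            on <= elig$individuals$initiation_date)
             }, numeric(length(y))))
  nll <- function(b) {
    eta <- drop(x %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  opt <- optim(c(0, 0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 1000))
  ps_oracle <- plogis(drop(x %*% opt$par))
  expect_lt(max(abs(unname(ps) - ps_oracle)), 1e-6)

  # constant covariate -> singular design, named
  expect_error(estimate_propensity(elig, c("trait01", "conf_nope")),
               "unknown covariate")
})

test_that("separation in the propensity model raises a named error", {
  ch <- make_eligibility_cohort()
  # make trait02's flag-at-initiation coincide exactly with the arm
  treated <- ch$individuals$arm == "target_drug"
  ch$flags[, "trait02"] <- as.integer(treated)
  ch$flag_onset[, "trait02"] <- ifelse(treated, 500L, NA_integer_)
  expect_error(estimate_propensity(ch, "trait02"), "separation")
})

test_that("greedy caliper matching pairs nearest neighbors and honors the caliper", {
  # identical PS lists: every treated is matched, discard fraction 0
  ps <- c(a1 = 0.2, a2 = 0.4, a3 = 0.6, b1 = 0.2, b2 = 0.4, b3 = 0.6)
  m <- match_nearest_neighbor(ps, treated = c(1, 1, 1, 0, 0, 0), caliper = 0.1)
  expect_equal(m$n_matched, 3)
  expect_equal(m$discard_fraction_treated, 0)
  expect_equal(sort(m$pairs$distance), rep(0, 3))

  # caliper exclusion
  ps2 <- c(t = 0.9, c = 0.5)
  m2 <- match_nearest_neighbor(ps2, treated = c(1, 0), caliper = 0.1)
  expect_equal(m2$n_matched, 0)
  expect_equal(m2$discard_fraction_treated, 1)

  # 3 treated / 4 comparators with unambiguous nearest neighbors: the greedy
  # result is order-invariant, so it must equal the enumerated pairing
  ps3 <- c("1" = 0.30, "2" = 0.50, "3" = 0.70,
           "4" = 0.29, "5" = 0.52, "6" = 0.71, "7" = 0.90)
  for (s in 1:5) {
    m3 <- match_nearest_neighbor(ps3, treated = c(1, 1, 1, 0, 0, 0, 0),
                                 caliper = 0.1, seed = s)
    got <- m3$pairs[order(m3$pairs$treated_id), ]
    expect_equal(got$control_id, c("4", "5", "6"))
  }

  # exact distance tie (binary-exact values) broken by lowest comparator id
  ps4 <- c("1" = 0.50, "9" = 0.25, "2" = 0.75)
  m4 <- match_nearest_neighbor(ps4, treated = c(1, 0, 0), caliper = 0.5)
  expect_equal(m4$pairs$control_id, "2")

  expect_error(match_nearest_neighbor(ps4, treated = c(1, 0, 0), caliper = 0),
               "> 0")
  expect_error(match_nearest_neighbor(c(a = 0.5), treated = 1), "both arms")
})

test_that("follow-up terminates at the earliest of event, supply run-out, switch and registry end", {
  # event before the supply runs out
  r1 <- build_followup(make_followup_cohort(event_day = 50))
  expect_equal(r1$time_days, 50)
  expect_true(r1$event)

  # discontinuation first: 1 package of 100 days, event at day 150
  r2 <- build_followup(make_followup_cohort(event_day = 150))
  expect_equal(r2$time_days, 100)
  expect_false(r2$event)
  expect_equal(r2$terminator, "discontinuation")

  # administrative censoring
  r3 <- build_followup(make_followup_cohort(registry_end = 30L))
  expect_equal(r3$time_days, 30)
  expect_false(r3$event)

  # switch to the comparator ends follow-up
  r4 <- build_followup(make_followup_cohort(switch_day = 40, event_day = 60))
  expect_equal(r4$time_days, 40)
  expect_false(r4$event)

  # two purchases: supply counted from the last purchase date
  r5 <- build_followup(make_followup_cohort(purchase_days = c(0L, 100L),
                                            registry_end = 1000L))
  expect_equal(r5$time_days, 100 + 2 * 100)

  # initiator with no purchase row is excluded with a warning
  ch <- make_followup_cohort(event_day = 50)
  ch$purchases <- ch$purchases[0, ]
  expect_warning(expect_error(build_followup(ch)), "without purchases")
})

test_that("Cox fit matches a grid-search partial-likelihood oracle", {
  rec <- make_records(time = c(2, 5, 7, 11, 13, 17),
                      event = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
                      treated = c(1, 0, 1, 0, 1, 0))
  fit <- fit_cox(rec)
  expect_equal(exp(fit$log_hr), fit$hr, tolerance = 1e-9)
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)

  # untied event times: Efron = Breslow = the textbook partial likelihood
  pl <- function(beta) {
    ord <- order(rec$time_days)
    t_s <- rec$time_days[ord]; e_s <- rec$event[ord]; x_s <- rec$treated[ord]
    ll <- 0
    for (i in seq_along(t_s)) {
      if (!e_s[i]) next
      risk <- t_s >= t_s[i]
      ll <- ll + beta * x_s[i] - log(sum(exp(beta * x_s[risk])))
    }
    ll
  }
  grid <- seq(-3, 3, by = 1e-3)
  best <- max(vapply(grid, pl, numeric(1)))
  expect_equal(pl(fit$log_hr), best, tolerance = 1e-4)

  # null case: identical event-time distributions
  set.seed(42)
  recn <- make_records(time = rexp(4000, 0.01), event = rep(TRUE, 4000),
                       treated = rep(0:1, 2000))
  fitn <- fit_cox(recn)
  expect_lt(abs(fitn$log_hr), 3 * fitn$se)

  expect_error(fit_cox(make_records(c(5, 6), c(FALSE, FALSE), c(1, 0))),
               "at least one event")
})

test_that("estimate agreement uses the closed RCT interval and relabels symmetrically", {
  expect_true(estimate_agreement(0.88, c(0.79, 0.66, 0.96)))
  expect_true(estimate_agreement(0.96, c(0.79, 0.66, 0.96)))  # boundary
  expect_false(estimate_agreement(1.20, c(0.79, 0.66, 0.96)))
  expect_error(estimate_agreement(0.9, c(0.8, 0.96, 0.66)), "malformed")

  # relabeling arms: HR -> 1/HR with the CI reciprocal-swapped
  for (hr in c(0.7, 0.9, 1.05, 1.4)) {
    expect_equal(estimate_agreement(hr, c(0.79, 0.66, 0.96)),
                 estimate_agreement(1 / hr, c(1 / 0.79, 1 / 0.96, 1 / 0.66)))
  }
})

test_that("Kaplan-Meier matches hand-computed product-limit tables", {
  # textbook no-censoring case
  km <- kaplan_meier(make_records(c(1, 2, 3), rep(TRUE, 3)))
  expect_equal(km$surv[km$time > 0], c(2, 1, 0) / 3)
  expect_equal(km$surv[km$time == 0], 1)

  # mixed censoring: event(1), censored(2), event(3), event(4)
  km2 <- kaplan_meier(make_records(1:4, c(TRUE, FALSE, TRUE, TRUE)))
  ev <- km2[km2$n_event > 0, ]
  expect_equal(ev$surv, c(3 / 4, 3 / 4 * 1 / 2, 0))

  # no events: flat at 1
  km3 <- kaplan_meier(make_records(c(5, 6), c(FALSE, FALSE)))
  expect_true(all(km3$surv == 1))
  expect_error(kaplan_meier(make_records(numeric(), logical())), "no records")
})

test_that("staged cohorts nest, match equal arms, and matching shrinks covariate SMDs", {
  env <- shared_confounded()
  st <- env$staged
  expect_true(all(st$matched$individual_id %in% st$eligible$individual_id))
  expect_true(all(st$eligible$individual_id %in% st$plain$individual_id))
  expect_equal(sum(st$matched$treated == 1), sum(st$matched$treated == 0))

  # |SMD| of every PS-model covariate shrinks (within sampling noise 0.02)
  for (tr in c("trait01", "trait02", "trait03")) {
    smd_of <- function(ch) {
      tcol <- ch$individuals$arm == "target_drug"
      abs(compute_smd(ch$confounders[tcol, tr],
                      ch$confounders[!tcol, tr])$smd)
    }
    expect_lt(smd_of(st$matched_cohort), smd_of(st$eligible_cohort) + 0.02)
  }
})

test_that("without confounding, matched and unmatched hazard ratios agree", {
  cfg <- cohort_config(20000L, prescription_log_odds = 0,
                       confounder_log_hr = 0, seed = 31L)
  ch <- generate_cohort(cfg)
  proto <- trial_protocol(design = "active_comparator",
                          covariates_for_ps = c("trait01", "trait02"))
  st <- staged_cohorts(ch, proto, seed = 3L)
  fit_all <- fit_cox(build_followup(st$eligible_cohort))
  fit_m <- fit_cox(build_followup(st$matched_cohort))
  expect_lt(abs(fit_all$log_hr - fit_m$log_hr),
            2 * max(fit_all$se, fit_m$se))
})
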