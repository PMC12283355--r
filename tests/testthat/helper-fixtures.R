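# Shared fixtures, built in code at test time.

# Hand-assembled 10-person cohort for eligibility/attrition checks.
# trait01 flag: ids 1-6 onset day 500 (before initiation at day 1000),
# id 7 onset day 1500 (after initiation), ids 8-10 unflagged.
# trait02 flag: ids 1-3 onset day 900.
make_eligibility_cohort <- function() {
  n <- 10L
  tn <- c("trait01", "trait02")
  arm <- rep(c("target_drug", "comparator"), 5)
  init <- rep(1000L, n)
  flags <- cbind(trait01 = as.integer(seq_len(n) <= 7),
                 trait02 = as.integer(seq_len(n) <= 3))
  onset <- cbind(trait01 = c(rep(500L, 6), 1500L, rep(NA_integer_, 3)),
                 trait02 = c(rep(900L, 3), rep(NA_integer_, 7)))
  set.seed(99)
  pgs <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, tn))
  structure(list(
    individuals = data.frame(individual_id = seq_len(n), arm = arm,
                             initiation_date = init,
                             event_date = NA_integer_,
                             death_date = NA_integer_,
                             switch_date = NA_integer_,
                             age_years = 60, stringsAsFactors = FALSE),
    pgs = pgs, confounders = pgs, flags = flags, flag_onset = onset,
    purchases = data.frame(individual_id = seq_len(n), date = init,
                           n_packages = 1L),
    config = cohort_config(n, n_traits = 2L, seed = 1L)),
    class = "cohort")
}

# Single-individual cohort for follow-up timeline checks.
make_followup_cohort <- function(event_day = NA, death_day = NA,
                                 switch_day = NA, registry_end = 400L,
                                 package_days = 100L,
                                 purchase_days = 0L) {
  tn <- "trait01"
  m <- matrix(0, 1, 1, dimnames = list(NULL, tn))
  structure(list(
    individuals = data.frame(individual_id = 1L, arm = "target_drug",
                             initiation_date = min(purchase_days),
                             event_date = as.integer(event_day),
                             death_date = as.integer(death_day),
                             switch_date = as.integer(switch_day),
                             age_years = 60, stringsAsFactors = FALSE),
    pgs = m, confounders = m, flags = m, flag_onset = m,
    purchases = data.frame(individual_id = 1L,
                           date = as.integer(purchase_days), n_packages = 1L),
    config = cohort_config(2L, n_traits = 1L, registry_end = registry_end,
                           package_days = package_days, seed = 1L)),
    class = "cohort")
}

# One confounded cohort + staged emulation, built once and reused across
# test files (generation at n = 30,000 is the expensive part).
.fixture_env <- new.env(parent = emptyenv())
shared_confounded <- function() {
  if (is.null(.fixture_env$staged)) {
    cfg <- cohort_config(30000L, seed = 11L)
    cohort <- generate_cohort(cfg)
    protocol <- trial_protocol(
      design = "placebo_proxy",
      eligibility_rules = list(list(covariate = "trait04", require = FALSE)),
      covariates_for_ps = c("conf_trait01", "conf_trait02", "conf_trait03"),
      caliper = "auto",
      rct_reference = c(0.79, 0.66, 0.96))
    .fixture_env$config <- cfg
    .fixture_env$cohort <- cohort
    .fixture_env$protocol <- protocol
    .fixture_env$staged <- staged_cohorts(cohort, protocol, seed = 5L)
  }
  .fixture_env
}

# Survival records data.frame built directly (no cohort machinery).
make_records <- function(time, event, treated = rep(0L, length(time))) {
  data.frame(individual_id = seq_along(time), treated = treated,
             time_days = time, event = event,
             terminator = rep(NA_character_, length(time)))
}
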