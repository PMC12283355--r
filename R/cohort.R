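#' Configure a synthetic biobank cohort
#'
#' Defines the generative model for a registry-linked biobank-style cohort
#' with known ground truth. The structure mirrors what a nationwide biobank
#' interconnected with drug-purchase and diagnosis registries provides:
#' standardized polygenic scores (PGS), latent clinical traits the PGS
#' partially capture, dated diagnosis flags, drug initiation and purchase
#' records, and event/death/censoring dates. Confounding by indication is
#' built in: the probability of initiating therapy (and of being channelled
#' to the target drug rather than the comparator) depends on the latent
#' traits, which also drive the outcome hazard.
#'
#' Dates are integer days from an arbitrary epoch (day 0 = cohort entry);
#' `registry_end` is a hard administrative censoring date.
#'
#' @param n_individuals cohort size (>= 2).
#' @param n_traits number of traits with a PGS (default 20).
#' @param pgs_confounder_r2 fraction of each latent trait's variance
#'   explained by its PGS; scalar or length `n_traits`, values in `[0, 1]`.
#'   Default recycles the grid `{0.5, 0.3, 0.2, 0.1, 0.05, 0.01}`, spanning
#'   realistic PGS accuracies from strong to weak (the confounded traits
#'   come first so their PGS are informative proxies).
#' @param prescription_log_odds per-trait log-odds contribution of the
#'   latent trait to treatment initiation (and, scaled by `choice_scale`, to
#'   being channelled to the target drug). Default: the first three traits
#'   contribute 1.0, 0.8, 0.6; the rest 0.
#' @param true_treatment_log_hr true log hazard ratio of the target drug on
#'   the primary outcome (comparator is causally null). Default `log(0.8)`.
#' @param baseline_hazard baseline outcome rate, events per person-year.
#' @param confounder_log_hr per-trait log-hazard contribution of the latent
#'   trait to the outcome. Default 0.3 for the three prescription-driving
#'   traits, 0 otherwise.
#' @param registry_end administrative end of registry follow-up, in days
#'   (default 3652, ten years).
#' @param package_days days of drug supply per purchased package.
#' @param death_hazard background mortality, events per person-year.
#' @param init_intercept,choice_intercept,choice_scale logit intercepts for
#'   initiation and target-vs-comparator choice, and the factor by which the
#'   prescription log-odds enter the drug choice.
#' @param persistence per-refill probability of continuing therapy.
#' @param switch_prob probability that an initiator later switches to the
#'   opposing drug.
#' @param flag_intercept,flag_slope logit model linking each latent trait to
#'   its observable dated diagnosis flag.
#' @param age_range age at cohort entry, drawn uniformly (years).
#' @param seed integer seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_individuals,
                          n_traits = 20L,
                          pgs_confounder_r2 = NULL,
                          prescription_log_odds = NULL,
                          true_treatment_log_hr = log(0.8),
                          baseline_hazard = 0.05,
                          confounder_log_hr = NULL,
                          registry_end = 3652L,
                          package_days = 90L,
                          death_hazard = 0.01,
                          init_intercept = stats::qlogis(0.3),
                          choice_intercept = 0,
                          choice_scale = 0.6,
                          persistence = 0.9,
                          switch_prob = 0.05,
                          flag_intercept = -1,
                          flag_slope = 1.2,
                          age_range = c(40, 75),
                          seed = 1L) {
  if (!is_count(n_individuals, min = 2L)) stop_config("n_individuals must be >= 2")
  if (!is_count(n_traits)) stop_config("n_traits must be a positive integer")
  if (is.null(pgs_confounder_r2)) {
    pgs_confounder_r2 <- rep(c(0.5, 0.3, 0.2, 0.1, 0.05, 0.01),
                             length.out = n_traits)
  }
  pgs_confounder_r2 <- rep_len(pgs_confounder_r2, n_traits)
  if (!is_prob(pgs_confounder_r2)) {
    stop_config("pgs_confounder_r2 values must lie in [0, 1]")
  }
  if (is.null(prescription_log_odds)) {
    prescription_log_odds <- c(1.0, 0.8, 0.6, rep(0, max(0L, n_traits - 3L)))[seq_len(n_traits)]
  }
  prescription_log_odds <- rep_len(prescription_log_odds, n_traits)
  if (is.null(confounder_log_hr)) {
    confounder_log_hr <- ifelse(prescription_log_odds != 0, 0.3, 0)
  }
  confounder_log_hr <- rep_len(confounder_log_hr, n_traits)
  if (!is.numeric(baseline_hazard) || baseline_hazard <= 0) {
    stop_config("baseline_hazard must be > 0 (events per person-year)")
  }
  if (!is.numeric(package_days) || package_days <= 0) {
    stop_config("package_days must be > 0")
  }
  if (!is_prob(persistence) || !is_prob(switch_prob)) {
    stop_config("persistence and switch_prob must be probabilities")
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 n_traits = as.integer(n_traits),
                 pgs_confounder_r2 = pgs_confounder_r2,
                 prescription_log_odds = prescription_log_odds,
                 true_treatment_log_hr = true_treatment_log_hr,
                 baseline_hazard = baseline_hazard,
                 confounder_log_hr = confounder_log_hr,
                 registry_end = as.integer(registry_end),
                 package_days = as.numeric(package_days),
                 death_hazard = death_hazard,
                 init_intercept = init_intercept,
                 choice_intercept = choice_intercept,
                 choice_scale = choice_scale,
                 persistence = persistence,
                 switch_prob = switch_prob,
                 flag_intercept = flag_intercept,
                 flag_slope = flag_slope,
                 age_range = age_range,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

trait_names <- function(k) sprintf("trait%02d", seq_len(k))

#' Generate a synthetic biobank cohort
#'
#' Draws a cohort under the model in [cohort_config()]:
#' \itemize{
#'   \item PGS_k ~ N(0,1), explicitly standardized over the whole cohort;
#'   \item latent trait `C_k = sqrt(r2_k) PGS_k + sqrt(1 - r2_k) eps`, so
#'     `cor(PGS_k, C_k)^2 = r2_k`;
#'   \item dated diagnosis flags from a logit model on `C_k`;
#'   \item initiation and target-vs-comparator choice from logit models on
#'     the prescription linear predictor `sum_k w_k C_k` (confounding by
#'     indication);
#'   \item exponential proportional-hazards event times with hazard
#'     `baseline_hazard * exp(log_hr_T * treated + sum_k b_k C_k)`, clock
#'     starting at initiation (initiators) or entry (noninitiators);
#'   \item purchases every `package_days` days until discontinuation,
#'     switching, an event, death or registry end.
#' }
#'
#' @param config a [cohort_config()].
#' @return an object of class `cohort`: a list with `individuals`
#'   (data.frame), `pgs`, `confounders`, `flags`, `flag_onset` (matrices with
#'   one column per trait), `purchases` (data.frame `individual_id`, `date`,
#'   `n_packages`) and the `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop_config("config must be a cohort_config")
  set.seed(split_seed(config$seed, 0L))
  n <- config$n_individuals
  k <- config$n_traits
  tn <- trait_names(k)

  pgs <- matrix(stats::rnorm(n * k), n, k, dimnames = list(NULL, tn))
  pgs <- apply(pgs, 2, standardize)
  r2 <- config$pgs_confounder_r2
  conf <- sweep(pgs, 2, sqrt(r2), `*`) +
    sweep(matrix(stats::rnorm(n * k), n, k), 2, sqrt(1 - r2), `*`)
  colnames(conf) <- tn

  p_flag <- stats::plogis(config$flag_intercept + config$flag_slope * conf)
  flags <- matrix(stats::rbinom(n * k, 1L, p_flag), n, k, dimnames = list(NULL, tn))
  flag_onset <- matrix(NA_integer_, n, k, dimnames = list(NULL, tn))
  flag_onset[flags == 1L] <- as.integer(round(stats::runif(sum(flags), -1825,
                                                           config$registry_end)))

  lp <- drop(conf %*% config$prescription_log_odds)
  initiator <- stats::rbinom(n, 1L, stats::plogis(config$init_intercept + lp)) == 1L
  target <- initiator &
    stats::rbinom(n, 1L, stats::plogis(config$choice_intercept +
                                         config$choice_scale * lp)) == 1L
  arm <- ifelse(!initiator, "noninitiator",
                ifelse(target, "target_drug", "comparator"))

  initiation_date <- rep(NA_integer_, n)
  n_init <- sum(initiator)
  initiation_date[initiator] <-
    as.integer(round(stats::runif(n_init, 365, floor(config$registry_end * 0.6))))

  # event & death clocks start at initiation (initiators) or entry
  origin <- ifelse(initiator, initiation_date, 0L)
  rate_day <- config$baseline_hazard / 365.25 *
    exp(config$true_treatment_log_hr * (arm == "target_drug") +
          drop(conf %*% config$confounder_log_hr))
  t_event <- stats::rexp(n, rate_day)
  event_date <- as.integer(round(origin + t_event))
  event_date[event_date > config$registry_end] <- NA_integer_
  t_death <- stats::rexp(n, config$death_hazard / 365.25)
  death_date <- as.integer(round(origin + t_death))
  death_date[death_date > config$registry_end] <- NA_integer_

  switch_date <- rep(NA_integer_, n)
  sw <- initiator & stats::runif(n) < config$switch_prob
  switch_date[sw] <- as.integer(round(initiation_date[sw] +
    stats::runif(sum(sw)) * (config$registry_end - initiation_date[sw])))

  age_years <- stats::runif(n, config$age_range[1], config$age_range[2])

  purchases <- vector("list", n)
  init_idx <- which(initiator)
  for (i in init_idx) {
    stop_at <- min(event_date[i], death_date[i], switch_date[i],
                   config$registry_end, na.rm = TRUE)
    dates <- initiation_date[i]
    t <- initiation_date[i] + config$package_days
    while (t <= stop_at && stats::runif(1) < config$persistence) {
      dates <- c(dates, t)
      t <- t + config$package_days
    }
    purchases[[i]] <- data.frame(individual_id = i, date = as.integer(dates),
                                 n_packages = 1L)
  }
  purchases <- do.call(rbind, purchases[lengths(purchases) > 0])
  if (is.null(purchases)) {
    purchases <- data.frame(individual_id = integer(), date = integer(),
                            n_packages = integer())
  }

  individuals <- data.frame(individual_id = seq_len(n),
                            arm = arm,
                            initiation_date = initiation_date,
                            event_date = event_date,
                            death_date = death_date,
                            switch_date = switch_date,
                            age_years = age_years,
                            stringsAsFactors = FALSE)
  structure(list(individuals = individuals, pgs = pgs, confounders = conf,
                 flags = flags, flag_onset = flag_onset,
                 purchases = purchases, config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic biobank cohort:", nrow(x$individuals), "individuals,",
      ncol(x$pgs), "PGS/traits\n")
  print(table(x$individuals$arm))
  invisible(x)
}

#' Subset a cohort by individual ids
#'
#' @param cohort a `cohort`.
#' @param ids individual ids to keep.
#' @return the restricted `cohort` (purchases filtered accordingly).
#' @export
subset_cohort <- function(cohort, ids) {
  keep <- match(ids, cohort$individuals$individual_id)
  if (anyNA(keep)) stop_data("unknown individual ids in subset")
  out <- cohort
  out$individuals <- cohort$individuals[keep, , drop = FALSE]
  for (f in c("pgs", "confounders", "flags", "flag_onset")) {
    out[[f]] <- cohort[[f]][keep, , drop = FALSE]
  }
  out$purchases <- cohort$purchases[cohort$purchases$individual_id %in% ids, ,
                                    drop = FALSE]
  out
}

#' Write / read a cohort as tab-separated tables with a JSON schema sidecar
#'
#' Writes `<prefix>_individuals.tsv` (individual table with `pgs_*`,
#' `conf_*`, `flag_*`, `flagonset_*` columns), `<prefix>_purchases.tsv`, and
#' `<prefix>_schema.json` (trait names, config, column descriptions).
#'
#' @param cohort a `cohort`.
#' @param prefix file-path prefix.
#' @return `prefix`, invisibly (write) or the reconstructed `cohort` (read).
#' @export
write_cohort <- function(cohort, prefix) {
  tn <- colnames(cohort$pgs)
  wide <- cohort$individuals
  add <- function(m, p) {
    colnames(m) <- paste0(p, "_", tn)
    m
  }
  wide <- cbind(wide, add(cohort$pgs, "pgs"), add(cohort$confounders, "conf"),
                add(cohort$flags, "flag"), add(cohort$flag_onset, "flagonset"))
  utils::write.table(wide, paste0(prefix, "_individuals.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$purchases, paste0(prefix, "_purchases.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  schema <- list(traits = tn,
                 config = unclass(cohort$config),
                 columns = list(
                   pgs = "standardized polygenic score (mean 0, sd 1 in full cohort)",
                   conf = "latent clinical trait (confounder)",
                   flag = "binary diagnosis flag",
                   flagonset = "flag onset date, days from epoch (NA when flag absent)"))
  jsonlite::write_json(schema, paste0(prefix, "_schema.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(prefix) {
  wide <- utils::read.delim(paste0(prefix, "_individuals.tsv"),
                            stringsAsFactors = FALSE)
  purchases <- utils::read.delim(paste0(prefix, "_purchases.tsv"),
                                 stringsAsFactors = FALSE)
  schema <- jsonlite::read_json(paste0(prefix, "_schema.json"),
                                simplifyVector = TRUE)
  tn <- schema$traits
  pull <- function(p) {
    m <- as.matrix(wide[paste0(p, "_", tn)])
    colnames(m) <- tn
    m
  }
  cfg <- schema$config
  config <- do.call(cohort_config, cfg[setdiff(names(cfg), character())])
  base_cols <- c("individual_id", "arm", "initiation_date", "event_date",
                 "death_date", "switch_date", "age_years")
  structure(list(individuals = wide[base_cols],
                 pgs = pull("pgs"), confounders = pull("conf"),
                 flags = pull("flag"), flag_onset = pull("flagonset"),
                 purchases = purchases, config = config),
            class = "cohort")
}
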