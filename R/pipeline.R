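#' Read a pipeline run configuration from YAML
#'
#' The configuration has a `seed`, a `cohort` block (arguments of
#' [cohort_config()]), a `protocol` block (arguments of
#' [trial_protocol()]), and optional `balance`, `proxy_sim`, `mr` and
#' `enrichment` blocks; a stage whose block is absent is skipped (the
#' manifest records it). See `run_config_template()` for a complete
#' example.
#'
#' @param path YAML file.
#' @return a named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$cohort)) stop_config("run config needs a 'cohort' block")
  cfg
}

#' A complete example run configuration
#'
#' @param n_individuals cohort size for the demo.
#' @return a run-config list accepted by [run_pipeline()].
#' @export
run_config_template <- function(n_individuals = 20000L) {
  list(seed = 1L,
       cohort = list(n_individuals = n_individuals),
       protocol = list(
         name = "demo-emulation",
         design = "placebo_proxy",
         eligibility_rules = list(list(covariate = "trait04", require = FALSE)),
         covariates_for_ps = c("conf_trait01", "conf_trait02", "conf_trait03"),
         caliper = "auto",
         rct_reference = c(0.79, 0.66, 0.96)),
       balance = list(alpha = 0.05),
       proxy_sim = list(model = 1, iterations = 10L, n = 20000L,
                        r2_grid = c(0.1, 0.3, 0.5),
                        conf_frac_grid = c(0.1, 0.3)),
       mr = list(n_traits = 4L, n_instruments = 50L,
                 theta_treatment = c(0.3, 0, 0.25, 0),
                 theta_outcome = c(0.2, 0.15, 0, 0),
                 pleiotropy_sd = 0, n_sample = 200000L),
       enrichment = list(trait = "trait01", q = 0.25, method = "events"))
}

pipeline_stage_names <- c("simulate-cohort", "emulate", "balance",
                          "proxy-sim", "mr-scan", "enrich")

#' Run the genetics-augmented emulation pipeline
#'
#' Executes, in dependency order: cohort simulation, trial emulation
#' (eligibility, propensity matching, on-treatment Cox, estimate
#' agreement), the PGS balance trajectory, the confounder-proxy bias grid,
#' an MR confounder scan over synthetic per-trait GWAS summary statistics,
#' and the PGS enrichment evaluation. Every artifact is written under
#' `out_dir` as TSV/JSON and listed, with an MD5 checksum and record count,
#' in `manifest.json`. All randomness derives from the single `seed`
#' through [split_seed()], so a rerun with the same config is
#' byte-identical apart from the manifest's timestamp. A stage whose config
#' block is absent is skipped and noted in the manifest; `stages` restricts
#' which stage outputs are produced (prerequisites are still computed in
#' memory).
#'
#' @param config a run-config list or path to a YAML file
#'   ([read_run_config()]).
#' @param out_dir output directory; refuses a non-empty existing directory
#'   unless `overwrite = TRUE`.
#' @param seed optional override of `config$seed`.
#' @param overwrite allow writing into a non-empty directory.
#' @param stages subset of
#'   `c("simulate-cohort", "emulate", "balance", "proxy-sim", "mr-scan",
#'   "enrich")`.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, overwrite = FALSE,
                         stages = pipeline_stage_names) {
  if (is.character(config)) config <- read_run_config(config)
  stages <- match.arg(stages, pipeline_stage_names, several.ok = TRUE)
  seed <- as.integer(seed %||% config$seed %||% 1L)

  # validate every sub-config before any stage runs
  cohort_cfg <- do.call(cohort_config,
                        c(config$cohort, list(seed = split_seed(seed, 10L))))
  if (is.null(config$protocol)) stop_config("run config needs a 'protocol' block")
  proto_cfg <- config$protocol
  if (!is.null(proto_cfg$rct_reference)) {
    proto_cfg$rct_reference <- as.numeric(unlist(proto_cfg$rct_reference))
  }
  proto_cfg$covariates_for_ps <- as.character(unlist(proto_cfg$covariates_for_ps))
  protocol <- do.call(trial_protocol, proto_cfg)

  if (dir.exists(out_dir) && length(list.files(out_dir)) && !overwrite) {
    stop_config("output directory not empty: ", out_dir,
                " (use overwrite = TRUE)")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(package = "pgstrial",
                   version = as.character(utils::packageVersion("pgstrial")),
                   seed = seed,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   stages = list(), skipped = character())
  record <- function(name, files, n_records, elapsed) {
    message(sprintf("[pgstrial] stage %-15s %6.1fs  %s record(s)",
                    name, elapsed, format(n_records)))
    manifest$stages[[name]] <<- list(
      name = name,
      outputs = lapply(files, function(f) list(file = basename(f),
                                               md5 = unname(tools::md5sum(f)))),
      n_records = n_records, elapsed_s = round(elapsed, 3))
  }
  wrap_error <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(paste0("stage '", name, "' failed: ",
                                 conditionMessage(e)), class = class(e)))
    })
  }

  ## simulate-cohort (always computed: everything downstream needs it)
  t0 <- proc.time()[["elapsed"]]
  cohort <- wrap_error("simulate-cohort", generate_cohort(cohort_cfg))
  if ("simulate-cohort" %in% stages) {
    prefix <- file.path(out_dir, "cohort")
    write_cohort(cohort, prefix)
    record("simulate-cohort",
           paste0(prefix, c("_individuals.tsv", "_purchases.tsv", "_schema.json")),
           nrow(cohort$individuals), proc.time()[["elapsed"]] - t0)
  }

  ## emulate (prerequisite of balance and enrich)
  staged <- NULL
  if (any(c("emulate", "balance", "enrich") %in% stages)) {
    t0 <- proc.time()[["elapsed"]]
    staged <- wrap_error("emulate",
                         staged_cohorts(cohort, protocol,
                                        seed = split_seed(seed, 20L)))
    if ("emulate" %in% stages) {
      records <- wrap_error("emulate", build_followup(staged$matched_cohort))
      cox <- wrap_error("emulate", fit_cox(records))
      result <- list(protocol = protocol$name, caliper = staged$caliper,
                     n_plain = nrow(staged$plain),
                     n_eligible = nrow(staged$eligible),
                     n_matched = nrow(staged$matched),
                     discard_fraction_treated = staged$match$discard_fraction_treated,
                     hr = cox$hr, ci_low = cox$ci_low, ci_high = cox$ci_high,
                     log_hr = cox$log_hr, se = cox$se, p = cox$p,
                     n = cox$n, n_events = cox$n_events,
                     true_log_hr = cohort_cfg$true_treatment_log_hr,
                     estimate_agreement = if (!is.null(protocol$rct_reference)) {
                       estimate_agreement(cox, protocol$rct_reference)
                     })
      f_att <- file.path(out_dir, "attrition.tsv")
      utils::write.table(staged$attrition, f_att, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      f_cox <- file.path(out_dir, "emulation.json")
      jsonlite::write_json(result, f_cox, auto_unbox = TRUE, digits = NA,
                           null = "null")
      record("emulate", c(f_att, f_cox), nrow(records),
             proc.time()[["elapsed"]] - t0)
    }
  }

  ## balance
  if ("balance" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    alpha <- (config$balance %||% list())$alpha %||% 0.05
    rep <- wrap_error("balance", balance_trajectory(staged, alpha = alpha))
    f <- file.path(out_dir, "balance.tsv")
    write_balance_report(rep, f)
    record("balance", f, nrow(rep), proc.time()[["elapsed"]] - t0)
  }

  ## proxy-sim
  if ("proxy-sim" %in% stages) {
    if (is.null(config$proxy_sim)) {
      manifest$skipped <- c(manifest$skipped, "proxy-sim")
    } else {
      t0 <- proc.time()[["elapsed"]]
      ps <- config$proxy_sim
      grid <- wrap_error("proxy-sim", run_grid(
        model = ps$model %||% 1,
        r2_grid = unlist(ps$r2_grid) %||% c(0.01, 0.05, 0.1, 0.2, 0.3, 0.5),
        conf_frac_grid = unlist(ps$conf_frac_grid) %||% c(0.1, 0.2, 0.3, 0.5),
        b_gX_grid = unlist(ps$b_gX_grid) %||% c(0, -0.2, -0.4),
        iterations = ps$iterations %||% 100L,
        n = ps$n %||% 100000L,
        seed = split_seed(seed, 30L)))
      f <- file.path(out_dir, "proxy_bias.tsv")
      utils::write.table(as.data.frame(grid), f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      record("proxy-sim", f, nrow(grid), proc.time()[["elapsed"]] - t0)
    }
  }

  ## mr-scan
  if ("mr-scan" %in% stages) {
    if (is.null(config$mr)) {
      manifest$skipped <- c(manifest$skipped, "mr-scan")
    } else {
      t0 <- proc.time()[["elapsed"]]
      mr <- config$mr
      kt <- mr$n_traits %||% 4L
      tab <- wrap_error("mr-scan", do.call(rbind, lapply(seq_len(kt), function(t) {
        s_eff <- split_seed(seed, 40L + 3L * t)
        set.seed(s_eff)
        true_beta <- stats::rnorm(mr$n_instruments %||% 50L, 0, 0.05)
        gen <- function(theta, off) {
          generate_summary_stats(true_beta, theta = theta,
                                 pleiotropy_sd = mr$pleiotropy_sd %||% 0,
                                 n_exposure = mr$n_sample %||% 200000L,
                                 n_outcome = mr$n_sample %||% 200000L,
                                 seed = s_eff + off)
        }
        ss_t <- gen(unlist(mr$theta_treatment)[t], 1L)
        ss_o <- gen(unlist(mr$theta_outcome)[t], 2L)
        iv_t <- ivw_estimate(select_instruments(ss_t$exposure, ss_t$outcome))
        iv_o <- ivw_estimate(select_instruments(ss_o$exposure, ss_o$outcome))
        v <- classify_confounder(iv_t, iv_o, trait = sprintf("mr_trait%02d", t))
        data.frame(trait = v$trait,
                   beta_treatment = iv_t$beta_ivw, p_treatment = iv_t$p,
                   beta_outcome = iv_o$beta_ivw, p_outcome = iv_o$p,
                   n_instruments = iv_t$n_instruments,
                   verdict = v$verdict, stringsAsFactors = FALSE)
      })))
      f <- file.path(out_dir, "mr_scan.tsv")
      utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
      record("mr-scan", f, nrow(tab), proc.time()[["elapsed"]] - t0)
    }
  }

  ## enrich
  if ("enrich" %in% stages) {
    if (is.null(config$enrichment)) {
      manifest$skipped <- c(manifest$skipped, "enrich")
    } else {
      t0 <- proc.time()[["elapsed"]]
      en <- config$enrichment
      res <- wrap_error("enrich",
                        evaluate_enrichment(staged, cohort, trait = en$trait,
                                            q = en$q %||% 0.25,
                                            method = en$method %||% "events"))
      flat <- list(trait = res$trait,
                   hr_trial = res$hr_trial$hr,
                   hr_trial_ci = c(res$hr_trial$ci_low, res$hr_trial$ci_high),
                   hr_population = res$hr_population$hr,
                   hr_population_ci = c(res$hr_population$ci_low,
                                        res$hr_population$ci_high),
                   event_rate_all = res$event_rate_all,
                   event_rate_topq = res$event_rate_topq,
                   q = res$q, n_original = res$n_original,
                   n_required = res$n_required,
                   pct_reduction = res$pct_reduction,
                   interaction_p = res$interaction_p)
      f <- file.path(out_dir, "enrichment.json")
      jsonlite::write_json(flat, f, auto_unbox = TRUE, digits = NA)
      record("enrich", f, res$n_original, proc.time()[["elapsed"]] - t0)
    }
  }

  f_manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
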