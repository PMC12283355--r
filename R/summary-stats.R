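#' Generate two-sample GWAS summary statistics with known causal effect
#'
#' Produces exposure-sample and outcome-sample per-variant effect estimates
#' under the instrumental-variable data-generating model
#' `beta_Yj = theta * beta_Xj + alpha_j + noise`, where `alpha_j ~
#' N(0, pleiotropy_sd^2)` is horizontal pleiotropy (a path from variant to
#' outcome that bypasses the exposure). Standard errors follow the
#' `1/sqrt(n)` scaling of effect estimates for standardized genotypes and
#' traits; p-values come from the normal approximation, so they regenerate
#' exactly from `beta/se`.
#'
#' @param true_exposure_effects numeric vector of true per-variant effects on
#'   the exposure.
#' @param theta true causal effect of the exposure on the outcome.
#' @param pleiotropy_sd standard deviation of per-variant horizontal
#'   pleiotropy; 0 for none.
#' @param n_exposure,n_outcome GWAS sample sizes of the two (non-overlapping)
#'   samples.
#' @param seed integer seed.
#' @param map optional variant map (as produced by [generate_genotypes()]);
#'   when absent, variants are placed far apart so they are unlinked.
#' @return list with elements `exposure` and `outcome`, each a
#'   summary-statistics data.frame with columns `variant_id`, `chromosome`,
#'   `position_bp`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `p`, `n_sample`.
#' @export
generate_summary_stats <- function(true_exposure_effects, theta,
                                   pleiotropy_sd = 0,
                                   n_exposure = 200000L,
                                   n_outcome = 200000L,
                                   seed = 1L, map = NULL) {
  if (!is.numeric(pleiotropy_sd) || pleiotropy_sd < 0) {
    stop_config("pleiotropy_sd must be >= 0")
  }
  if (!is_count(n_exposure, 2) || !is_count(n_outcome, 2)) {
    stop_config("sample sizes must be integers >= 2")
  }
  m <- length(true_exposure_effects)
  set.seed(split_seed(seed, 0L))
  if (is.null(map)) {
    chrom <- rep(1:22, length.out = m)
    pos <- stats::ave(seq_len(m), chrom, FUN = seq_along) * 20000000L
    alleles <- c("A", "C", "G", "T")
    ea <- sample(alleles, m, replace = TRUE)
    oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1L), "")
    map <- data.frame(variant_id = sprintf("var%05d", seq_len(m)),
                      chromosome = chrom, position_bp = pos,
                      effect_allele = ea, other_allele = unname(oa),
                      stringsAsFactors = FALSE)
  }
  eaf <- stats::runif(m, 0.05, 0.95)
  alpha <- if (pleiotropy_sd > 0) stats::rnorm(m, 0, pleiotropy_sd) else numeric(m)
  se_x <- rep(1 / sqrt(n_exposure), m)
  se_y <- rep(1 / sqrt(n_outcome), m)
  beta_x <- true_exposure_effects + stats::rnorm(m, 0, se_x)
  beta_y <- theta * true_exposure_effects + alpha + stats::rnorm(m, 0, se_y)

  mk <- function(beta, se, n) {
    p <- 2 * stats::pnorm(-abs(beta / se))
    p[p == 0] <- .Machine$double.xmin  # keep p in (0, 1]
    data.frame(variant_id = map$variant_id, chromosome = map$chromosome,
               position_bp = map$position_bp,
               effect_allele = map$effect_allele,
               other_allele = map$other_allele,
               eaf = eaf, beta = beta, se = se, p = p,
               n_sample = as.integer(n), stringsAsFactors = FALSE)
  }
  list(exposure = mk(beta_x, se_x, n_exposure),
       outcome = mk(beta_y, se_y, n_outcome))
}

summary_stats_cols <- c("variant_id", "chromosome", "position_bp",
                        "effect_allele", "other_allele", "eaf",
                        "beta", "se", "p", "n_sample")

#' Read / write GWAS summary statistics
#'
#' Tab-delimited files with the canonical columns (`variant_id`,
#' `chromosome`, `position_bp`, `effect_allele`, `other_allele`, `eaf`,
#' `beta`, `se`, `p`, `n_sample`); gzip transparent.
#'
#' @param path file path (`.gz` accepted).
#' @return summary-statistics data.frame.
#' @export
read_summary_stats <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(summary_stats_cols, names(tab))
  if (length(miss)) {
    stop_data("summary-statistics file lacks columns: ",
              paste(miss, collapse = ", "))
  }
  if (any(tab$se <= 0)) stop_data("summary statistics contain se <= 0")
  tab[summary_stats_cols]
}

#' @rdname read_summary_stats
#' @param stats summary-statistics data.frame to write.
#' @export
write_summary_stats <- function(stats, path) {
  utils::write.table(stats[summary_stats_cols], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
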