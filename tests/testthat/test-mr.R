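iv_table <- function(bx, sx, by, sy, ids = NULL) {
  df <- data.frame(variant_id = ids %||% paste0("v", seq_along(bx)),
                   beta_exposure = bx, se_exposure = sx,
                   beta_outcome = by, se_outcome = sy,
                   stringsAsFactors = FALSE)
  class(df) <- c("instrument_set", "data.frame")
  df
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("IVW matches hand-computed weighted least squares through the origin", {
  # weights bX^2/seY^2 = (100, 100, 400); numerator = (50, 40, 160)
  iv <- iv_table(bx = c(0.1, 0.2, 0.3), sx = rep(0.01, 3),
                 by = c(0.05, 0.08, 0.12), sy = c(0.01, 0.02, 0.015))
  res <- ivw_estimate(iv)
  expect_equal(res$beta_ivw, 250 / 600, tolerance = 1e-12)
  expect_equal(res$se_ivw, 1 / sqrt(600), tolerance = 1e-12)
  expect_equal(res$or_estimate, exp(250 / 600))
  expect_equal(res$n_instruments, 3)
  expect_false(attr(res, "wald_ratio"))

  # exact proportionality: beta_ivw = theta whatever the weights
  set.seed(3)
  bx <- runif(20, 0.02, 0.2); sy <- runif(20, 0.005, 0.05)
  resp <- ivw_estimate(iv_table(bx, rep(0.01, 20), 0.37 * bx, sy))
  expect_equal(resp$beta_ivw, 0.37, tolerance = 1e-12)

  # single instrument degenerates to a flagged Wald ratio
  res1 <- ivw_estimate(iv_table(0.2, 0.01, 0.08, 0.02))
  expect_equal(res1$beta_ivw, 0.4)
  expect_true(attr(res1, "wald_ratio"))

  # random-effects variant never shrinks the standard error
  resr <- ivw_estimate(iv_table(bx, rep(0.01, 20),
                                0.37 * bx + rnorm(20, 0, 0.02), sy),
                       method = "random")
  resf <- ivw_estimate(iv_table(bx, rep(0.01, 20),
                                0.37 * bx + rnorm(20, 0, 0.02), sy))
  expect_gte(resr$se_ivw, resf$se_ivw * 0.999)

  expect_error(ivw_estimate(iv_table(0.1, 0, 0.1, 0.01)), "> 0")
})

test_that("instrument selection thresholds, clumps and excludes as specified", {
  # two perfectly linked variants: only the smaller exposure p survives
  mk_ss <- function(beta, se, chrom, pos, ea = "A", oa = "G", ids = NULL) {
    data.frame(variant_id = ids %||% paste0("v", seq_along(beta)),
               chromosome = chrom, position_bp = pos,
               effect_allele = ea, other_allele = oa,
               eaf = 0.3, beta = beta, se = se,
               p = 2 * pnorm(-abs(beta / se)), n_sample = 1e5,
               stringsAsFactors = FALSE)
  }
  expo <- mk_ss(c(0.10, 0.09), c(0.0155, 0.0148), chrom = 1,
                pos = c(1e6, 2e6))  # p ~ 1e-10 and 1e-9
  outc <- mk_ss(c(0.01, 0.01), c(0.01, 0.01), chrom = 1, pos = c(1e6, 2e6))
  ld <- list(blocks = c(v1 = 1, v2 = 1), r2 = 1)
  sel <- select_instruments(expo, outc, ld = ld)
  expect_equal(sel$variant_id, "v1")

  # nonsignificant exposure: explicit no-instruments error
  weak <- mk_ss(c(0.01, 0.01), c(0.01, 0.01), chrom = 1, pos = c(1e6, 2e6))
  expect_error(select_instruments(weak, outc), "no valid instruments")

  # outcome-associated instruments are excluded
  outc_sig <- mk_ss(c(0.2, 0.01), c(0.01, 0.01), chrom = 1, pos = c(1e6, 2e6))
  sel2 <- select_instruments(expo, outc_sig)
  expect_equal(sel2$variant_id, "v2")
  prov <- attr(sel2, "provenance")
  expect_false(prov$not_outcome_associated[prov$variant_id == "v1"])
})

test_that("greedy clumping equals a brute-force oracle and ignores row order", {
  set.seed(11)
  m <- 30
  blocks <- rep(1:6, each = 5)
  ids <- sprintf("v%02d", 1:m)
  beta <- runif(m, 0.06, 0.2) * sample(c(-1, 1), m, replace = TRUE)
  se <- rep(0.01, m)
  pos <- rep(seq(1e6, 5e6, length.out = 5), 6) + rep(0:5, each = 5) * 2e7
  chrom <- rep(c(1, 1, 1, 2, 2, 2), each = 5)
  expo <- data.frame(variant_id = ids, chromosome = chrom, position_bp = pos,
                     effect_allele = "A", other_allele = "G", eaf = 0.3,
                     beta = beta, se = se, p = 2 * pnorm(-abs(beta / se)),
                     n_sample = 1e5, stringsAsFactors = FALSE)
  outc <- expo
  outc$beta <- rnorm(m, 0, 0.01)
  outc$p <- 2 * pnorm(-abs(outc$beta / outc$se))
  ld <- list(blocks = setNames(blocks, ids), r2 = 0.9)

  sel <- select_instruments(expo, outc, ld = ld, window_kb = 10000,
                            outcome_p_thresh = 0)

  # oracle: independent greedy over explicitly sorted candidates
  ord <- ids[order(expo$p)]
  kept <- character(); dropped <- character()
  for (v in ord) {
    if (v %in% dropped) next
    kept <- c(kept, v)
    same_b <- ids[blocks == blocks[match(v, ids)]]
    near <- abs(pos - pos[match(v, ids)]) <= 1e7 & chrom == chrom[match(v, ids)]
    dropped <- union(dropped, setdiff(intersect(same_b, ids[near]), kept))
  }
  expect_setequal(sel$variant_id, kept)

  # row-order invariance
  shuf <- sample(m)
  sel_shuf <- select_instruments(expo[shuf, ], outc[shuf, ], ld = ld,
                                 window_kb = 10000, outcome_p_thresh = 0)
  expect_setequal(sel_shuf$variant_id, sel$variant_id)
})

test_that("allele harmonization leaves the IVW estimate unchanged", {
  set.seed(12)
  ss <- generate_summary_stats(runif(25, 0.03, 0.1), theta = 0.25,
                               n_exposure = 2e5, n_outcome = 2e5, seed = 2)
  base <- ivw_estimate(select_instruments(ss$exposure, ss$outcome,
                                          outcome_p_thresh = 0))
  flipped <- ss$outcome
  idx <- sample(25, 12)
  tmp <- flipped$effect_allele[idx]
  flipped$effect_allele[idx] <- flipped$other_allele[idx]
  flipped$other_allele[idx] <- tmp
  flipped$beta[idx] <- -flipped$beta[idx]
  after <- ivw_estimate(select_instruments(ss$exposure, flipped,
                                           outcome_p_thresh = 0))
  expect_equal(after$beta_ivw, base$beta_ivw, tolerance = 1e-12)

  # irreconcilable alleles are excluded with a message
  broken <- ss$outcome
  broken$effect_allele[1] <- "X"
  expect_message(select_instruments(ss$exposure, broken, outcome_p_thresh = 0),
                 "irreconcilable")
})

test_that("weak instruments attenuate the IVW estimate toward zero", {
  true_beta <- runif(40, 0.04, 0.1)
  mean_abs <- vapply(c(1e6, 2e3, 2e2), function(n_exp) {
    est <- vapply(1:30, function(i) {
      ss <- generate_summary_stats(true_beta, theta = 0.4,
                                   n_exposure = n_exp, n_outcome = 1e6,
                                   seed = 500 + i)
      iv <- iv_table(ss$exposure$beta, ss$exposure$se,
                     ss$outcome$beta, ss$outcome$se)
      ivw_estimate(iv)$beta_ivw
    }, numeric(1))
    mean(abs(est))
  }, numeric(1))
  expect_true(all(diff(mean_abs) < 0))
})

test_that("three-step confounder classification applies the conjunction rule", {
  sig <- function(p) {
    r <- ivw_estimate(iv_table(0.2, 0.01, 0.08, 0.02))
    r$p <- p
    r
  }
  v1 <- classify_confounder(sig(1e-20), sig(1e-20), trait = "bmi")
  expect_equal(v1$verdict, "putative_confounder")
  expect_true(v1$significant_on_treatment && v1$significant_on_outcome)

  expect_equal(classify_confounder(sig(0.5), sig(1e-5))$verdict, "outcome_only")
  expect_equal(classify_confounder(sig(1e-5), sig(0.5))$verdict, "exposure_only")
  expect_equal(classify_confounder(sig(0.5), sig(0.5))$verdict, "neither")

  # boundary: p exactly at the threshold is not significant
  vb <- classify_confounder(sig(0.05), sig(0.01))
  expect_false(vb$significant_on_treatment)
  expect_equal(vb$verdict, "outcome_only")

  # Bonferroni verdict can differ from the nominal one
  vn <- classify_confounder(sig(0.01), sig(0.01), use = "bonferroni")
  expect_equal(vn$verdict, "neither")

  expect_error(classify_confounder(sig(0.5), "not an mr result"), "required")
})

test_that("direct-effect adjustment removes the mediated path", {
  mk <- function(beta, se) {
    r <- ivw_estimate(iv_table(0.2, 0.01, 0.08, 0.02))
    r$beta_ivw <- beta
    r$se_ivw <- se
    r
  }
  # no mediation: direct equals total
  d0 <- direct_effect_adjustment(mk(0.9, 0.05), mk(0, 0.04), effect_YX = 1)
  expect_equal(d0$beta_direct, 0.9)
  # worked arithmetic
  d1 <- direct_effect_adjustment(mk(0.9, 0.05), mk(0.5, 0.04), effect_YX = 1)
  expect_equal(d1$beta_direct, 0.4)
  expect_equal(d1$se, sqrt(0.05^2 + 1 * 0.04^2), tolerance = 1e-12)
  expect_error(direct_effect_adjustment(mk(0.9, 0.05), mk(0.5, 0.04)),
               "mediator-path")

  # recovery of a known direct/indirect split from synthetic summary stats
  theta_cy <- 0.3; yx <- 0.5; theta_direct <- 0.25
  theta_total <- theta_direct + theta_cy * yx
  true_beta <- runif(30, 0.04, 0.1)
  hits <- vapply(1:100, function(i) {
    ss_x <- generate_summary_stats(true_beta, theta_total,
                                   n_exposure = 2e5, n_outcome = 2e5,
                                   seed = 900 + i)
    ss_y <- generate_summary_stats(true_beta, theta_cy,
                                   n_exposure = 2e5, n_outcome = 2e5,
                                   seed = 2900 + i)
    mr_x <- ivw_estimate(select_instruments(ss_x$exposure, ss_x$outcome,
                                            outcome_p_thresh = 0))
    mr_y <- ivw_estimate(select_instruments(ss_y$exposure, ss_y$outcome,
                                            outcome_p_thresh = 0))
    d <- direct_effect_adjustment(mr_x, mr_y, effect_YX = yx)
    abs(d$beta_direct - theta_direct) <= 2 * d$se
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
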