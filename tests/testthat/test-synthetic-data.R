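test_that("PGS standardization is exact, idempotent, and rejects zero variance", {
  set.seed(1)
  x <- rnorm(500, mean = 3, sd = 7)
  s1 <- standardize(x)
  expect_equal(mean(s1), 0, tolerance = 1e-12)
  expect_equal(sd(s1), 1, tolerance = 1e-12)
  expect_equal(standardize(s1), s1, tolerance = 1e-12)
  expect_error(standardize(rep(2, 10)), "zero-variance")
})

test_that("score_pgs matches hand-computed weighted sums and reconciles alleles", {
  dos <- rbind(c(2, 1, 0), c(0, 1, 2))
  colnames(dos) <- c("v1", "v2", "v3")
  map <- data.frame(variant_id = c("v1", "v2", "v3"),
                    effect_allele = c("A", "C", "G"),
                    other_allele = c("G", "T", "A"),
                    stringsAsFactors = FALSE)
  attr(dos, "map") <- map
  w <- data.frame(variant_id = c("v1", "v2", "v3"),
                  effect_allele = c("A", "C", "G"),
                  weight = c(0.2, -0.1, 0.5))
  expect_equal(score_pgs(dos, w, standardize = FALSE), c(0.3, 0.9))

  # flipping v1's effect allele to the panel's other allele counts 2 - d
  w_flip <- w
  w_flip$effect_allele[1] <- "G"
  expect_equal(score_pgs(dos, w_flip, standardize = FALSE),
               c(0.2 * 0 - 0.1 + 0, 0.2 * 2 - 0.1 + 1.0))

  # single variant, weight 1 -> standardized dosage
  w1 <- data.frame(variant_id = "v3", effect_allele = "G", weight = 1)
  expect_equal(score_pgs(dos, w1), standardize(dos[, "v3"]))

  # all-zero weights -> zero-variance standardization error
  w0 <- transform(w, weight = 0)
  expect_error(score_pgs(dos, w0), "zero-variance")

  # missing variant named in the error
  wm <- data.frame(variant_id = "v9", effect_allele = "A", weight = 1)
  expect_error(score_pgs(dos, wm), "v9")
})

test_that("genotype blocks reproduce the target LD and allele frequencies", {
  spec <- genotype_block_spec(30, 10, within_block_r = 0.6,
                              maf_range = c(0.15, 0.4))
  g <- generate_genotypes(20000, spec, seed = 2)
  map <- attr(g, "map")
  cc <- cor(g)
  same_block <- outer(map$block, map$block, "==")
  ut <- upper.tri(cc)
  expect_equal(mean(cc[same_block & ut]), 0.6, tolerance = 0.05)
  expect_lt(mean(abs(cc[!same_block & ut])), 0.03)
  expect_equal(unname(colMeans(g)), 2 * map$maf, tolerance = 0.05)

  # independence cases: r = 0 and single-variant blocks
  g0 <- generate_genotypes(5000, genotype_block_spec(12, 4, 0), seed = 3)
  expect_lt(mean(abs(cor(g0)[upper.tri(diag(12))])), 0.04)
  g1 <- generate_genotypes(5000, genotype_block_spec(12, 1, 0.9), seed = 4)
  expect_lt(mean(abs(cor(g1)[upper.tri(diag(12))])), 0.04)

  expect_error(genotype_block_spec(0, 5), "positive integer")
  expect_error(genotype_block_spec(10, 5, maf_range = c(0.5, 0.1)), "interval")
})

test_that("summary statistics are internally consistent and recover the causal slope", {
  ss <- generate_summary_stats(true_exposure_effects = runif(40, 0.02, 0.08),
                               theta = 0.4, pleiotropy_sd = 0,
                               n_exposure = 1e8, n_outcome = 1e8, seed = 5)
  for (tab in ss) {
    expect_true(all(tab$se > 0))
    expect_equal(tab$p, 2 * pnorm(-abs(tab$beta / tab$se)), tolerance = 1e-6)
    expect_equal(tab$se, rep(1e-4, 40))
  }
  # near the noiseless limit the per-variant Wald ratio is theta
  expect_equal(ss$outcome$beta / ss$exposure$beta, rep(0.4, 40),
               tolerance = 0.02)
  expect_error(generate_summary_stats(0.1, 0.4, pleiotropy_sd = -1), ">= 0")
})

test_that("cohort generator hits its design targets", {
  # PGS <-> confounder coupling at large n, few initiators to keep it light
  cfg <- cohort_config(100000L, init_intercept = qlogis(0.02), seed = 7L)
  ch <- generate_cohort(cfg)
  expect_equal(unname(colMeans(ch$pgs)), rep(0, 20), tolerance = 1e-6)
  expect_equal(unname(apply(ch$pgs, 2, sd)), rep(1, 20), tolerance = 1e-6)
  r2_hat <- vapply(seq_len(20),
                   function(k) cor(ch$pgs[, k], ch$confounders[, k])^2,
                   numeric(1))
  expect_equal(r2_hat, cfg$pgs_confounder_r2, tolerance = 0.02)

  # perfect-proxy edge case
  ch1 <- generate_cohort(cohort_config(2000L, n_traits = 1L,
                                       pgs_confounder_r2 = 1, seed = 8L))
  expect_equal(cor(ch1$pgs[, 1], ch1$confounders[, 1]), 1, tolerance = 1e-12)

  # registry semantics
  init_ids <- ch$individuals$individual_id[ch$individuals$arm != "noninitiator"]
  expect_true(all(init_ids %in% ch$purchases$individual_id))
  expect_true(all(ch$individuals$event_date <= cfg$registry_end, na.rm = TRUE))
  expect_error(cohort_config(1), ">= 2")
  expect_error(cohort_config(100, baseline_hazard = 0), "> 0")
  expect_error(cohort_config(100, pgs_confounder_r2 = 1.5), "\\[0, 1\\]")
})

test_that("arm assignment is exchangeable when prescription log-odds are zero", {
  cfg <- cohort_config(50000L, prescription_log_odds = 0, seed = 21L)
  ch <- generate_cohort(cfg)
  treated <- ch$individuals$arm == "target_drug"
  smds <- vapply(colnames(ch$pgs), function(tr) {
    compute_smd(ch$pgs[treated, tr], ch$pgs[!treated, tr])$smd
  }, numeric(1))
  expect_lt(max(abs(smds)), 0.05)
})

test_that("cohort round-trips through the TSV + JSON-schema serialization", {
  ch <- generate_cohort(cohort_config(300L, n_traits = 3L, seed = 13L))
  prefix <- file.path(withr::local_tempdir(), "cohort")
  write_cohort(ch, prefix)
  back <- read_cohort(prefix)
  expect_equal(back$individuals, ch$individuals, tolerance = 1e-12)
  expect_equal(back$pgs, ch$pgs, tolerance = 1e-12)
  expect_equal(back$flags, ch$flags)
  expect_equal(back$purchases$date, ch$purchases$date)
  expect_equal(back$config$package_days, ch$config$package_days)
})
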