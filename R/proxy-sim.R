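#' Confounding-coefficient parameterization by variance fractions
#'
#' The proxy simulations are naturally parameterized by the fraction of
#' variance the confounder C contributes: `conf_frac = Var(b_CX C)/Var(X) =
#' Var(b_CY C)/Var(Y)`. With `Var(X) = Var(C) = 1` this gives
#' `b_CX = sqrt(conf_frac)`; `b_CY` then solves the quadratic
#' `b_CY^2 (1 - f) - 2 f b_CX b_CY - f k = 0` (positive root), where
#' `k = 1 + b_gY^2 + 2 b_gY b_gX` accounts for an optional direct G' path
#' into Y (model 2; `k = 1` in model 1).
#'
#' @param conf_frac confounding variance fraction in `[0, 1)`.
#' @param b_gX,b_gY optional G' effects on X and Y (model 2), defaults 0.
#' @return list with `b_CX`, `b_CY`.
#' @export
confounding_coefs <- function(conf_frac, b_gX = 0, b_gY = 0) {
  if (!is.numeric(conf_frac) || conf_frac < 0 || conf_frac >= 1) {
    stop_config("conf_frac must lie in [0, 1)")
  }
  f <- conf_frac
  b_cx <- sqrt(f)
  k <- 1 + b_gY^2 + 2 * b_gY * b_gX
  b_cy <- (f * b_cx + sqrt(f^2 * b_cx^2 + f * (1 - f) * k)) / (1 - f)
  list(b_CX = b_cx, b_CY = b_cy)
}

#' Simulate the direct confounder-proxy model (model 1)
#'
#' The PGS is an imperfect proxy of a confounder C:
#' `PGS ~ N(0,1)`, `C = r PGS + sqrt(1 - r^2) eps_C`,
#' `X = b_CX C + sqrt(1 - b_CX^2) eps_X`, `Y = X + b_CY C`,
#' with `eps_C, eps_X ~ N(0,1)` independent. By construction PGS, C and X
#' all have variance 1 and the true effect of X on Y is 1.
#'
#' @param n sample size.
#' @param r correlation between C and PGS, in `[-1, 1]`.
#' @param b_CX effect of C on X, `|b_CX| <= 1`.
#' @param b_CY effect of C on Y.
#' @param seed integer seed.
#' @return data.frame with columns `PGS`, `C`, `X`, `Y`.
#' @export
simulate_model1 <- function(n, r, b_CX, b_CY, seed = 1L) {
  if (!is_count(n, 2)) stop_config("n must be an integer >= 2")
  if (abs(r) > 1) stop_config("|r| must be <= 1")
  if (abs(b_CX) > 1) stop_config("|b_CX| must be <= 1 so that Var(X) = 1")
  set.seed(split_seed(seed, 0L))
  pgs <- stats::rnorm(n)
  c_ <- r * pgs + sqrt(1 - r^2) * stats::rnorm(n)
  x <- b_CX * c_ + sqrt(1 - b_CX^2) * stats::rnorm(n)
  y <- x + b_CY * c_
  data.frame(PGS = pgs, C = c_, X = x, Y = y)
}

#' Simulate the shared-factor confounder-proxy model (model 2)
#'
#' PGS and C are correlated through a common causal factor G*, while an
#' extra component G' contributes only to the PGS (and possibly to X, Y) but
#' not to C:
#' `PGS = b_gp G* + sqrt(1 - b_gp^2) G'` with `b_gp^2 = b2_gstar_pgs`,
#' `C = b_gc G* + sqrt(1 - b_gc^2) eps_C` with `b_gc = r / b_gp`,
#' `X = b_gX G' + b_CX C + sqrt(1 - b_gX^2 - b_CX^2) eps_X`,
#' `Y = X + b_gY G' + b_CY C`.
#' G*, G', eps_C, eps_X are independent standard normals, so G*, G', PGS, C
#' and X all have variance 1, `cor(C, PGS) = r`, and the true effect of X on
#' Y is 1.
#'
#' @param n sample size.
#' @param b2_gstar_pgs fraction of Var(PGS) contributed by G*, in `(0, 1]`.
#' @param r2 squared C-PGS correlation; must satisfy `r2 <= b2_gstar_pgs`
#'   (else `b_gc` would exceed 1).
#' @param conf_frac confounding variance fraction (drives `b_CX`, `b_CY` via
#'   [confounding_coefs()]).
#' @param b_gX effect of G' on X (negative by convention here, so a larger
#'   |b_gX| inflates the bias); `b_gX^2 + b_CX^2` must be `<= 1`.
#' @param b_gY effect of G' on Y (0 in the reference configuration).
#' @param seed integer seed.
#' @return data.frame with columns `G_star`, `G_prime`, `PGS`, `C`, `X`,
#'   `Y`.
#' @export
simulate_model2 <- function(n, b2_gstar_pgs = 0.8, r2 = 0.3, conf_frac = 0.3,
                            b_gX = 0, b_gY = 0, seed = 1L) {
  if (!is_count(n, 2)) stop_config("n must be an integer >= 2")
  if (b2_gstar_pgs <= 0 || b2_gstar_pgs > 1) {
    stop_config("b2_gstar_pgs must lie in (0, 1]")
  }
  if (r2 < 0 || r2 > b2_gstar_pgs) {
    stop_config("r2 must lie in [0, b2_gstar_pgs]: b_{G*C} = r / b_{G*PGS} would exceed 1")
  }
  cf <- confounding_coefs(conf_frac, b_gX, b_gY)
  if (b_gX^2 + cf$b_CX^2 > 1) {
    stop_config("b_gX^2 + b_CX^2 must be <= 1 so that Var(X) = 1")
  }
  b_gp <- sqrt(b2_gstar_pgs)
  b_gc <- sqrt(r2) / b_gp
  set.seed(split_seed(seed, 0L))
  g_star <- stats::rnorm(n)
  g_prime <- stats::rnorm(n)
  pgs <- b_gp * g_star + sqrt(1 - b_gp^2) * g_prime
  c_ <- b_gc * g_star + sqrt(1 - b_gc^2) * stats::rnorm(n)
  x <- b_gX * g_prime + cf$b_CX * c_ +
    sqrt(1 - b_gX^2 - cf$b_CX^2) * stats::rnorm(n)
  y <- x + b_gY * g_prime + cf$b_CY * c_
  data.frame(G_star = g_star, G_prime = g_prime, PGS = pgs, C = c_,
             X = x, Y = y)
}

#' Estimate the PGS-conditioned bias in the X-on-Y effect
#'
#' Ordinary least squares of `Y ~ X + PGS` (with intercept); the bias is the
#' fitted X coefficient minus the true effect 1, reported as a percentage —
#' since the true effect is 1, percentage and absolute bias coincide.
#'
#' @param dataset data.frame with columns `X`, `PGS`, `Y` (output of
#'   [simulate_model1()] or [simulate_model2()]).
#' @return bias in percent, `100 * (beta_hat_X - 1)`.
#' @export
estimate_bias <- function(dataset) {
  if (!all(c("X", "PGS", "Y") %in% names(dataset))) {
    stop_config("dataset must have columns X, PGS, Y")
  }
  if (abs(stats::cor(dataset$X, dataset$PGS)) > 1 - 1e-10) {
    stop_numeric("X and PGS are collinear; the X coefficient is not identified")
  }
  fit <- stats::lm(Y ~ X + PGS, data = dataset)
  100 * (unname(stats::coef(fit)["X"]) - 1)
}

# Population OLS X-coefficient bias from the (X, PGS, Y) covariance
# structure: solve the 2x2 normal equations.
analytic_bias_from_covs <- function(c_xp, c_yx, c_yp) {
  det <- 1 - c_xp^2
  if (abs(det) < 1e-12) {
    stop_numeric("singular moment matrix: X and PGS are perfectly correlated")
  }
  beta_x <- (c_yx - c_xp * c_yp) / det
  100 * (beta_x - 1)
}

#' Closed-form expected bias under model 1
#'
#' Exact population-level counterpart of [estimate_bias()] on
#' [simulate_model1()] data, from the model-implied covariances:
#' `Cov(X, PGS) = b_CX r`, `Cov(Y, X) = 1 + b_CX b_CY`,
#' `Cov(Y, PGS) = r (b_CX + b_CY)`, all variances 1. Serves as the oracle
#' for the Monte-Carlo bias curves.
#'
#' @inheritParams simulate_model1
#' @return expected bias in percent.
#' @export
analytic_bias_model1 <- function(r, b_CX, b_CY) {
  if (abs(r) > 1 || abs(b_CX) > 1) stop_config("|r| and |b_CX| must be <= 1")
  analytic_bias_from_covs(c_xp = b_CX * r,
                          c_yx = 1 + b_CX * b_CY,
                          c_yp = r * (b_CX + b_CY))
}

#' Closed-form expected bias under model 2
#'
#' Model-implied covariances with `a = sqrt(b2_gstar_pgs)`:
#' `Cov(C, PGS) = r`, `Cov(X, PGS) = b_gX sqrt(1 - a^2) + b_CX r`,
#' `Cov(Y, X) = 1 + b_gY b_gX + b_CY b_CX`,
#' `Cov(Y, PGS) = Cov(X, PGS) + b_gY sqrt(1 - a^2) + b_CY r`.
#'
#' @inheritParams simulate_model2
#' @return expected bias in percent.
#' @export
analytic_bias_model2 <- function(b2_gstar_pgs = 0.8, r2 = 0.3,
                                 conf_frac = 0.3, b_gX = 0, b_gY = 0) {
  cf <- confounding_coefs(conf_frac, b_gX, b_gY)
  r <- sqrt(r2)
  gp <- sqrt(1 - b2_gstar_pgs)
  c_xp <- b_gX * gp + cf$b_CX * r
  analytic_bias_from_covs(c_xp = c_xp,
                          c_yx = 1 + b_gY * b_gX + cf$b_CY * cf$b_CX,
                          c_yp = c_xp + b_gY * gp + cf$b_CY * r)
}

#' Run a grid of proxy-bias simulation conditions
#'
#' For every condition, runs `iterations` independent replicates of size `n`
#' and summarizes the estimated bias as mean and 95% tolerance interval
#' (mean +/- 1.96 sd over iterations), next to the closed-form analytic
#' expectation. Deterministic given `seed`.
#'
#' @param model 1 or 2.
#' @param r2_grid squared C-PGS correlations (model 1 grid axis; fixed at
#'   `r2_fixed` for model 2).
#' @param conf_frac_grid confounding variance fractions.
#' @param b_gX_grid G'-on-X effects (model 2 grid axis; ignored for model 1).
#' @param b2_gstar_pgs,r2_fixed model-2 constants.
#' @param iterations replicates per condition.
#' @param n sample size per replicate.
#' @param seed integer seed.
#' @return data.frame of class `bias_grid`: condition columns, `mean_bias_pct`,
#'   `tolerance_low`, `tolerance_high`, `mc_se`, `analytic_bias_pct`.
#' @export
run_grid <- function(model = 1,
                     r2_grid = c(0.01, 0.05, 0.1, 0.2, 0.3, 0.5),
                     conf_frac_grid = c(0.1, 0.2, 0.3, 0.5),
                     b_gX_grid = c(0, -0.2, -0.4),
                     b2_gstar_pgs = 0.8, r2_fixed = 0.3,
                     iterations = 100L, n = 100000L, seed = 1L) {
  if (!model %in% c(1, 2)) stop_config("model must be 1 or 2")
  if (!is_count(iterations)) stop_config("iterations must be a positive integer")
  conditions <- if (model == 1) {
    expand.grid(r2 = r2_grid, conf_frac = conf_frac_grid)
  } else {
    expand.grid(b_gX = b_gX_grid, conf_frac = conf_frac_grid)
  }
  if (!nrow(conditions)) stop_config("empty condition grid")
  rows <- lapply(seq_len(nrow(conditions)), function(ci) {
    cond <- conditions[ci, , drop = FALSE]
    biases <- vapply(seq_len(iterations), function(it) {
      child <- split_seed(seed, (ci - 1L) * 100000L + it)
      if (model == 1) {
        cf <- confounding_coefs(cond$conf_frac)
        estimate_bias(simulate_model1(n, sqrt(cond$r2), cf$b_CX, cf$b_CY,
                                      seed = child))
      } else {
        estimate_bias(simulate_model2(n, b2_gstar_pgs, r2_fixed,
                                      cond$conf_frac, b_gX = cond$b_gX,
                                      seed = child))
      }
    }, numeric(1))
    m <- mean(biases)
    s <- if (iterations > 1L) stats::sd(biases) else 0
    analytic <- if (model == 1) {
      analytic_bias_model1(sqrt(cond$r2), confounding_coefs(cond$conf_frac)$b_CX,
                           confounding_coefs(cond$conf_frac)$b_CY)
    } else {
      analytic_bias_model2(b2_gstar_pgs, r2_fixed, cond$conf_frac,
                           b_gX = cond$b_gX)
    }
    cbind(cond, data.frame(mean_bias_pct = m,
                           tolerance_low = m - 1.96 * s,
                           tolerance_high = m + 1.96 * s,
                           mc_se = s / sqrt(iterations),
                           analytic_bias_pct = analytic))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "model") <- model
  attr(out, "iterations") <- iterations
  attr(out, "n") <- n
  class(out) <- c("bias_grid", "data.frame")
  out
}

#' Plot a bias grid
#'
#' Mean bias (with 95% tolerance ribbon) against the x-axis condition, one
#' line per confounding fraction; the analytic expectation is overlaid as a
#' dashed line.
#'
#' @param grid a `bias_grid` from [run_grid()].
#' @return a ggplot object.
#' @export
plot_bias_grid <- function(grid) {
  xvar <- if (attr(grid, "model") == 1) "r2" else "b_gX"
  df <- as.data.frame(grid)
  df$conf_frac <- factor(df$conf_frac)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[xvar]], y = .data$mean_bias_pct,
                                   colour = .data$conf_frac,
                                   fill = .data$conf_frac)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$tolerance_low,
                                      ymax = .data$tolerance_high),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$analytic_bias_pct),
                       linetype = "dashed") +
    ggplot2::labs(x = if (xvar == "r2") {
      expression(r^2 ~ "between confounder and PGS")
    } else "G' effect on X",
    y = "Bias in X-on-Y effect (%)",
    colour = "Confounding fraction", fill = "Confounding fraction") +
    ggplot2::theme_bw()
}
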