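test_that("binomial log-likelihood matches closed-form and oracle values", {
  one_arm <- arm_table(make_arm_df(100, 70, 35, brfs = 0.5))
  # k chosen so P = 0.5 with alpha = 0: symmetric case, 100*ln(0.5)
  p_half <- lq_params(log(log(2)), 0, 1)
  expect_equal(binomial_loglik(p_half, one_arm), 100 * log(0.5),
               tolerance = 1e-12)

  ten <- arm_table(make_arm_df(10, 70, 35, brfs = 0.8))
  p_09 <- lq_params(log(-log(0.9)), 0, 1)
  expect_equal(binomial_loglik(p_09, ten), 8 * log(0.9) + 2 * log(0.1),
               tolerance = 1e-12)

  # full fixture against the independent per-arm loop oracle
  conv <- load_fixture("conventional")
  expect_equal(binomial_loglik(lq_params(5.35, 0.043, 1.78), conv),
               oracle_loglik(5.35, 0.043, 1.78, conv),
               tolerance = 1e-9)

  # an arm with p_obs = 1 contributes only the success term
  full <- arm_table(make_arm_df(102, 40, 5, brfs = 1))
  p <- lq_params(1.67, 0.042, 4.24)
  P <- tcp_total_dose(p, 40, 5)
  expect_equal(binomial_loglik(p, full), 102 * log(P), tolerance = 1e-12)

  expect_error(binomial_loglik(p, data.frame()), "arm_table")
})

test_that("the MLE is refused for unidentifiable designs", {
  same_d <- arm_table(make_arm_df(c(100, 100, 100), c(70, 74, 78),
                                  c(35, 37, 39)))
  expect_error(fit_mle(same_d), "unidentifiable")
  two <- arm_table(make_arm_df(c(100, 100), c(70, 60), c(35, 20)))
  expect_error(fit_mle(two), "at least 3 arms")
})

test_that("the MLE recovers exact-model data and is locally optimal on fixtures", {
  truth <- lq_params(5, 0.05, 2)
  perfect <- make_perfect_table(truth)
  fit <- fit_mle(perfect)
  expect_equal(fit$params$k, truth$k, tolerance = 1e-4)
  expect_equal(fit$params$alpha, truth$alpha, tolerance = 1e-4)
  expect_equal(fit$params$alpha_beta, truth$alpha_beta, tolerance = 1e-3)
  expect_true(fit$converged)

  # perturbing any fitted parameter by +/-1% strictly decreases the
  # log-likelihood on each fixture
  for (g in c("conventional", "moderate_hypo", "sbrt")) {
    tab <- load_fixture(g)
    f <- fit_mle(tab)
    est <- c(f$params$k, f$params$alpha, f$params$alpha_beta)
    for (j in 1:3) for (s in c(0.99, 1.01)) {
      pert <- est; pert[j] <- pert[j] * s
      expect_lt(binomial_loglik(lq_params(pert[1], pert[2], pert[3]), tab),
                f$loglik)
    }
  }
})

test_that("the MLE beats a coarse brute-force grid on every fixture", {
  ks <- seq(-10, 15, length.out = 6)
  as <- seq(0, 0.2, length.out = 6)
  rs <- seq(0.2, 30, length.out = 8)
  for (g in c("conventional", "moderate_hypo", "sbrt")) {
    tab <- load_fixture(g)
    fit <- fit_mle(tab)
    grid_best <- max(vapply(ks, function(k)
      max(vapply(as, function(a)
        max(vapply(rs, function(r)
          binomial_loglik(lq_params(k, a, r), tab), numeric(1))),
        numeric(1))), numeric(1)))
    expect_gte(fit$loglik, grid_best)
  }
})

test_that("maximising over (k, alpha, beta) directly gives the same maximum", {
  conv <- load_fixture("conventional")
  dat <- list(D = conv$total_dose, C = conv$c, n = conv$n, p = conv$brfs_5y)
  nll_kab <- function(par) {
    P <- exp(-exp(par[1] - par[2] * dat$D - par[3] * dat$C))
    P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
    -sum(dat$n * dat$p * log(P) + dat$n * (1 - dat$p) * log(1 - P))
  }
  best <- Inf
  for (k0 in c(0, 5)) for (a0 in c(0.01, 0.1)) for (b0 in c(0.005, 0.05)) {
    o <- optim(c(k0, a0, b0), nll_kab, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 20000))
    best <- min(best, o$value)
  }
  fit <- fit_mle(conv)
  expect_equal(-best, fit$loglik, tolerance = 1e-6)
})

test_that("non-negativity bounds are honoured and reported", {
  # data generated from a pure-alpha model (beta = 0 via huge ratio);
  # the constrained fit must not go below zero
  truth <- lq_params(2, 0.06, 1e6)
  tab <- make_perfect_table(truth)
  fit <- fit_mle(tab, fit_options(nonnegative = TRUE))
  expect_gte(fit$params$alpha, 0)
  expect_gte(fit$params$alpha_beta, 0)
  # negative-ratio data: unconstrained fit goes negative, constrained stops
  # at the boundary and reports it
  neg <- lq_params(1, 0.05, -3)
  tabn <- arm_table(make_arm_df(rep(1000, 5), c(60, 64, 70, 74, 36),
                                c(30, 32, 35, 37, 5),
                                brfs = tcp_total_dose(neg, c(60, 64, 70, 74, 36),
                                                      c(30, 32, 35, 37, 5))))
  fit_free <- fit_mle(tabn)
  expect_lt(fit_free$params$alpha_beta, 0)
  fit_nn <- fit_mle(tabn, fit_options(nonnegative = TRUE))
  expect_gte(fit_nn$params$alpha_beta, 0)
  expect_lte(fit_nn$loglik, fit_free$loglik)
})

test_that("the profile over alpha/beta brackets the joint optimum", {
  conv <- load_fixture("conventional")
  fit <- fit_mle(conv)
  prof <- profile_alpha_beta(conv, c(1.0, 1.78, 3.0))
  expect_equal(which.max(prof$loglik), 2L)       # 1.78 beats 1.0 and 3.0
  expect_true(all(prof$loglik <= fit$loglik + 1e-8))

  fine <- profile_alpha_beta(conv, seq(1.5, 2.0, by = 0.01))
  expect_lt(abs(fine$alpha_beta[which.max(fine$loglik)] -
                  fit$params$alpha_beta), 0.02)

  # single grid value equals a 2-parameter fit at that ratio
  one <- profile_alpha_beta(conv, 1.78)
  expect_equal(nrow(one), 1L)
  expect_equal(one$loglik,
               binomial_loglik(lq_params(one$k, one$alpha, 1.78), conv),
               tolerance = 1e-9)
})

test_that("Wald machinery yields a symmetric positive-definite covariance", {
  fit <- fit_mle(load_fixture("conventional"))
  expect_equal(fit$covariance, t(fit$covariance))
  expect_true(all(eigen(fit$covariance, symmetric = TRUE)$values > 0))
  expect_true(all(fit$se > 0))
  expect_true(all(fit$wald_p >= 0 & fit$wald_p <= 1))
  expect_equal(unname(fit$se), unname(sqrt(diag(fit$covariance))),
               tolerance = 1e-12)
})
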