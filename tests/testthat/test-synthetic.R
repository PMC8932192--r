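test_that("the generator is deterministic and counter-stable", {
  des <- synthetic_design(data.frame(n = c(200, 300, 150),
                                     total_dose = c(70, 78, 36.25),
                                     n_fractions = c(35, 39, 5)),
                          truth = lq_params(5, 0.05, 2),
                          seed = 42, replicates = 3)
  a <- generate_table(des, 2)
  b <- generate_table(des, 2)
  expect_identical(a$brfs_5y, b$brfs_5y)
  expect_false(identical(a$brfs_5y, generate_table(des, 1)$brfs_5y))

  # adding an arm never perturbs existing draws (counter-based stream)
  des4 <- synthetic_design(rbind(des$arms,
                                 data.frame(n = 100, total_dose = 60,
                                            n_fractions = 20)),
                           truth = des$truth, seed = 42, replicates = 3)
  wider <- generate_table(des4, 2)
  expect_identical(wider$brfs_5y[1:3], a$brfs_5y[1:3])

  # the caller's RNG stream is left untouched
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(generate_table(des, 1)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("simulated proportions are exact rationals concentrated at the model TCP", {
  # alpha = beta = 0 and k = ln(ln 2): P = 0.5 in every arm
  des <- synthetic_design(data.frame(n = rep(1e6, 3),
                                     total_dose = c(60, 70, 36),
                                     n_fractions = c(30, 35, 5)),
                          truth = lq_params(log(log(2)), 0, 1),
                          seed = 7, replicates = 1)
  tab <- generate_table(des, 1)
  expect_true(all(tab$brfs_5y >= 0.497 & tab$brfs_5y <= 0.503))  # 6 sigma
  expect_true(all(abs(tab$brfs_5y * 1e6 - round(tab$brfs_5y * 1e6)) < 1e-6))

  # mean simulated brfs over replicates matches the model TCP within MC error
  des2 <- synthetic_design(data.frame(n = rep(400, 4),
                                      total_dose = c(66, 74, 78, 36.25),
                                      n_fractions = c(33, 37, 39, 5)),
                           truth = lq_params(5.35, 0.043, 1.78),
                           seed = 11, replicates = 300)
  P <- tcp_total_dose(des2$truth, des2$arms$total_dose, des2$arms$n_fractions)
  sims <- vapply(seq_len(300), function(r) generate_table(des2, r)$brfs_5y,
                 numeric(4))
  mc_se <- sqrt(P * (1 - P) / 400) / sqrt(300)
  expect_true(all(abs(rowMeans(sims) - P) < 3 * mc_se))
})

test_that("invalid designs are refused", {
  expect_error(synthetic_design(data.frame(n = 100, total_dose = 70,
                                           n_fractions = 35),
                                truth = lq_params(5, 0.05, 2), seed = 1),
               "unidentifiable")
  expect_error(synthetic_design(data.frame(n = c(10, 10, 10),
                                           total_dose = c(70, 70, 70),
                                           n_fractions = c(35, 35, 35)),
                                truth = lq_params(5, 0.05, 2), seed = 1),
               "unidentifiable")
  des <- conventional_design(replicates = 2)
  expect_error(generate_table(des, 3))
})

test_that("recovery harness reports bias, RMSE and respects constraints", {
  des <- conventional_design(truth = lq_params(5.35, 0.043, 1.78),
                             seed = 5, replicates = 12, n_scale = 100)
  rec <- recovery_experiment(des, intervals = FALSE)
  expect_s3_class(rec, "lq_recovery")
  expect_equal(nrow(rec$estimates), 12L)
  expect_true(all(rec$rmse >= abs(rec$bias)))
  # with n x100 the design is information-rich: estimates hug the truth
  expect_lt(abs(rec$median["alpha_beta"] - 1.78), 0.15)

  # truth on the boundary with the non-negativity option: no ratio below 0
  des_b <- synthetic_design(data.frame(n = rep(2000, 5),
                                       total_dose = c(60, 64, 70, 74, 36),
                                       n_fractions = c(30, 32, 35, 37, 5)),
                            truth = lq_params(2, 0.06, 1e6),
                            seed = 9, replicates = 8)
  rec_b <- recovery_experiment(des_b, fit_options(nonnegative = TRUE),
                               intervals = FALSE)
  expect_true(all(rec_b$estimates$alpha_beta >= 0))
})

test_that("RMSE shrinks like 1/sqrt(n) as per-arm cohorts grow", {
  reps <- 60
  base <- conventional_design(truth = lq_params(5.35, 0.043, 1.78),
                              seed = 17, replicates = reps, n_scale = 1)
  big <- conventional_design(truth = lq_params(5.35, 0.043, 1.78),
                             seed = 23, replicates = reps, n_scale = 100)
  r1 <- recovery_experiment(base, intervals = FALSE)
  r2 <- recovery_experiment(big, intervals = FALSE)
  ratio <- r1$rmse["alpha_beta"] / r2$rmse["alpha_beta"]
  expect_gt(ratio, 10 * 0.7)
  expect_lt(ratio, 10 * 1.4)
})
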