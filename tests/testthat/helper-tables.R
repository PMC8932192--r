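# Builders for small in-code fixtures.

# Minimal arm data.frame from schedule vectors; brfs defaults to 0.8.
make_arm_df <- function(n, D, N, brfs = rep(0.8, length(n)), d = NULL) {
  data.frame(study = seq_along(n), author = paste0("a", seq_along(n)),
             n = n, brfs_5y = brfs, total_dose = D,
             n_fractions = if (is.null(N)) NA_real_ else N,
             dose_per_fraction = if (is.null(d)) NA_real_ else d,
             c = NA_real_, definition = "Phoenix",
             risk_group = NA_character_, subset_of_pooled = FALSE)
}

# A table whose observed proportions equal the model TCP exactly, so the
# MLE reproduces `truth` and every leave-one-out refit is identical.
make_perfect_table <- function(truth = lq_params(5, 0.05, 2),
                               n = rep(500, 6),
                               D = c(60, 64, 70, 74, 78, 36),
                               N = c(30, 25, 35, 30, 39, 5)) {
  # fraction numbers chosen so every leave-one-out subtable still has at
  # least two distinct doses per fraction
  p <- tcp_total_dose(truth, D, N)
  arm_table(make_arm_df(n, D, N, brfs = p), group_label = "perfect")
}

# Independent per-arm oracle for the grouped binomial log-likelihood:
# a naive loop re-evaluating the TCP formula arm by arm.
oracle_loglik <- function(k, alpha, alpha_beta, table) {
  total <- 0
  for (i in seq_len(nrow(table))) {
    P <- exp(-exp(k - alpha * table$total_dose[i] -
                    (alpha / alpha_beta) * table$c[i]))
    P <- min(max(P, 1e-12), 1 - 1e-12)
    total <- total + table$n[i] * table$brfs_5y[i] * log(P) +
      table$n[i] * (1 - table$brfs_5y[i]) * log(1 - P)
  }
  total
}
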