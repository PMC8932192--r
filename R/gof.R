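#' Model-predicted bRFS per arm
#'
#' Evaluates the TCP model at given parameters for every arm of a table
#' (order-preserving), through each arm's quadratic dose so that schedules
#' specified by fraction number and by fraction size are handled
#' identically.
#'
#' @param params An [lq_params()] triple.
#' @param table An [arm_table()].
#' @return Numeric vector of probabilities, one per arm.
#' @export
predicted_brfs <- function(params, table) {
  stopifnot(inherits(params, "lq_params"), inherits(table, "arm_table"))
  exp(-exp(params$k - params$alpha * table$total_dose -
             params$beta * table$c))
}

#' Proportion-based chi-square verification of a fit
#'
#' Compares model-calculated control proportions with the proportions from
#' the original studies using
#' \deqn{X^2 = \sum_i (P^{model}_i - p^{obs}_i)^2 / p^{obs}_i,}
#' i.e. the observed study proportion plays the role of the expected
#' frequency in the denominator.  The p-value is the upper chi-square tail
#' at `m - 1` degrees of freedom by default (`df_rule = "m_minus_1"`); the
#' alternative rule `"m_minus_3"` subtracts the three fitted parameters.
#'
#' This statistic operates on proportions, not counts; see
#' [chi_square_counts()] for the statistically conventional count-based
#' Pearson test.
#'
#' @param p_obs Observed proportions (all > 0).
#' @param p_model Model proportions, same length.
#' @param df_rule Degrees-of-freedom rule.
#' @param labels Optional arm labels for the per-arm table.
#' @return An object of class `lq_gof`: `x2`, `df`, `p_value`, `per_arm`
#'   (arm label, observed, model, contribution).
#' @export
chi_square_gof <- function(p_obs, p_model,
                           df_rule = c("m_minus_1", "m_minus_3"),
                           labels = NULL) {
  df_rule <- match.arg(df_rule)
  if (length(p_obs) == 0L || length(p_obs) != length(p_model))
    stop("p_obs and p_model must have equal, non-zero length", call. = FALSE)
  if (any(p_obs == 0))
    stop("p_obs contains 0: the proportion-based statistic divides by the observed proportion",
         call. = FALSE)
  m <- length(p_obs)
  contribution <- (p_model - p_obs)^2 / p_obs
  x2 <- sum(contribution)
  df <- if (df_rule == "m_minus_1") m - 1L else m - 3L
  if (df < 1L) stop("too few arms for the chosen df rule", call. = FALSE)
  if (is.null(labels)) labels <- paste0("arm", seq_len(m))
  structure(list(x2 = x2, df = df,
                 p_value = pchisq(x2, df, lower.tail = FALSE),
                 df_rule = df_rule,
                 per_arm = data.frame(arm = labels, p_obs = p_obs,
                                      p_model = p_model,
                                      contribution = contribution,
                                      stringsAsFactors = FALSE)),
            class = "lq_gof")
}

#' @export
print.lq_gof <- function(x, ...) {
  cat(sprintf("Proportion-based chi-square: X^2 = %.4f, df = %d (%s), p = %.4g\n",
              x$x2, x$df, x$df_rule, x$p_value))
  invisible(x)
}

#' Count-based Pearson chi-square (conventional alternative)
#'
#' The statistically conventional goodness-of-fit test on patient counts:
#' per arm, observed successes/failures `n*p_obs` and `n*(1 - p_obs)`
#' against expected `n*p_model` and `n*(1 - p_model)`.  Provided as a
#' clearly-labelled alternative; it is not the proportion-based statistic of
#' [chi_square_gof()] and generally gives a very different value.
#'
#' @param p_obs Observed proportions.
#' @param p_model Model proportions in (0, 1).
#' @param n Patient counts per arm.
#' @param df_rule Degrees-of-freedom rule, as in [chi_square_gof()].
#' @return An `lq_gof` object.
#' @export
chi_square_counts <- function(p_obs, p_model, n,
                              df_rule = c("m_minus_1", "m_minus_3")) {
  df_rule <- match.arg(df_rule)
  stopifnot(length(p_obs) == length(p_model), length(p_obs) == length(n))
  if (any(p_model <= 0 | p_model >= 1))
    stop("p_model must lie strictly in (0, 1) for expected counts", call. = FALSE)
  m <- length(p_obs)
  contribution <- (n * p_obs - n * p_model)^2 / (n * p_model) +
    (n * (1 - p_obs) - n * (1 - p_model))^2 / (n * (1 - p_model))
  x2 <- sum(contribution)
  df <- if (df_rule == "m_minus_1") m - 1L else m - 3L
  if (df < 1L) stop("too few arms for the chosen df rule", call. = FALSE)
  structure(list(x2 = x2, df = df,
                 p_value = pchisq(x2, df, lower.tail = FALSE),
                 df_rule = df_rule,
                 per_arm = data.frame(arm = paste0("arm", seq_len(m)),
                                      p_obs = p_obs, p_model = p_model,
                                      contribution = contribution,
                                      stringsAsFactors = FALSE)),
            class = "lq_gof")
}
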