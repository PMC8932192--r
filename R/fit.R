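#' @importFrom stats nlminb optim pchisq pnorm qnorm quantile rbinom sd setNames
NULL

# Probabilities are clamped to this range inside likelihood evaluation only,
# to guard the logs; model math elsewhere is exact.
.p_eps <- 1e-12

#' Fitting options
#'
#' @param nonnegative Constrain `alpha >= 0` and `alpha_beta >= 0` during
#'   optimisation (bound-constrained, so an estimate exactly at 0 is
#'   representable).
#' @param init_grid Matrix or data.frame of starting triples with columns
#'   `k`, `alpha`, `alpha_beta`.  The default is a 4 x 3 x 6 grid spanning
#'   the plausible range; every start is run and the best final
#'   log-likelihood wins.
#' @param max_iter Iteration cap per start.
#' @param tol_loglik Convergence tolerance on the log-likelihood.
#' @param tol_param Convergence tolerance on the parameters.
#' @param drop_pooled_subsets Drop arms flagged `subset_of_pooled` before
#'   fitting.
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(nonnegative = FALSE,
                        init_grid = default_init_grid(),
                        max_iter = 2000L,
                        tol_loglik = 1e-10,
                        tol_param = 1e-8,
                        drop_pooled_subsets = FALSE) {
  init_grid <- as.data.frame(init_grid)
  stopifnot(nrow(init_grid) >= 1L,
            all(c("k", "alpha", "alpha_beta") %in% names(init_grid)),
            tol_loglik > 0, tol_param > 0)
  structure(list(nonnegative = isTRUE(nonnegative),
                 init_grid = init_grid[c("k", "alpha", "alpha_beta")],
                 max_iter = as.integer(max_iter),
                 tol_loglik = tol_loglik,
                 tol_param = tol_param,
                 drop_pooled_subsets = isTRUE(drop_pooled_subsets)),
            class = "fit_options")
}

#' Default multi-start grid for the MLE
#'
#' @return A data.frame of 72 starting triples
#'   (`k` in \{-5, 0, 5, 10\}, `alpha` in \{0.01, 0.05, 0.1\},
#'   `alpha_beta` in \{0.5, 1.5, 3, 5, 10, 20\}).
#' @export
default_init_grid <- function() {
  expand.grid(k = c(-5, 0, 5, 10), alpha = c(0.01, 0.05, 0.1),
              alpha_beta = c(0.5, 1.5, 3, 5, 10, 20),
              KEEP.OUT.ATTRS = FALSE)
}

# Extract the fitting vectors from an arm table.
.fit_data <- function(table) {
  stopifnot(inherits(table, "arm_table"))
  list(D = table$total_dose, C = table$c, n = table$n, p = table$brfs_5y)
}

# Log-likelihood in the canonical (k, alpha, r = alpha/beta) parameterisation.
# beta = alpha / r; the exponent is k - alpha*D - (alpha/r)*C.
.ll_kar <- function(par, dat) {
  P <- exp(-exp(par[1] - par[2] * dat$D - (par[2] / par[3]) * dat$C))
  P <- pmin(pmax(P, .p_eps), 1 - .p_eps)
  sum(dat$n * dat$p * log(P) + dat$n * (1 - dat$p) * log1p(-P))
}

.grad_kar <- function(par, dat) {
  k <- par[1]; a <- par[2]; r <- par[3]
  E <- exp(k - a * dat$D - (a / r) * dat$C)
  P <- exp(-E)
  P <- pmin(pmax(P, .p_eps), 1 - .p_eps)
  dll_dE <- -P * (dat$n * dat$p / P - dat$n * (1 - dat$p) / (1 - P))
  c(sum(dll_dE * E),
    sum(dll_dE * E * (-(dat$D + dat$C / r))),
    sum(dll_dE * E * (a * dat$C / r^2)))
}

#' Grouped binomial log-likelihood of an arm table
#'
#' \deqn{\ell = \sum_i n_i p_i \log P_i + n_i (1 - p_i) \log(1 - P_i)}
#' where \eqn{P_i} is the model TCP of arm i evaluated through its quadratic
#' dose (so schedules given by fraction number and by fraction size are
#' handled identically), \eqn{p_i} the observed bRFS proportion and
#' \eqn{n_i} the patient count.  Fractional successes \eqn{n_i p_i} are used
#' exactly as given, without rounding to integer counts.  Model
#' probabilities are clamped to `[1e-12, 1 - 1e-12]` before taking logs; an
#' arm with \eqn{p_i = 1} contributes only the first term.
#'
#' @param params An [lq_params()] triple.
#' @param table An [arm_table()].
#' @return The log-likelihood (a single finite number).
#' @export
binomial_loglik <- function(params, table) {
  stopifnot(inherits(params, "lq_params"))
  if (!inherits(table, "arm_table") || nrow(table) == 0L)
    stop("table must be a non-empty arm_table", call. = FALSE)
  dat <- .fit_data(table)
  P <- exp(-exp(params$k - params$alpha * dat$D - params$beta * dat$C))
  P <- pmin(pmax(P, .p_eps), 1 - .p_eps)
  sum(dat$n * dat$p * log(P) + dat$n * (1 - dat$p) * log1p(-P))
}

.check_identifiable <- function(table) {
  if (nrow(table) < 3L)
    stop("need at least 3 arms to fit (k, alpha, alpha/beta)", call. = FALSE)
  d <- table$dose_per_fraction
  d[is.na(d)] <- table$total_dose[is.na(d)] / table$n_fractions[is.na(d)]
  if (length(unique(round(d, 6))) < 2L)
    stop("alpha/beta is unidentifiable: all arms share one dose per fraction",
         call. = FALSE)
  invisible(TRUE)
}

# Numerical Hessian of the log-likelihood by central differences of the
# analytic gradient.
.hessian_kar <- function(par, dat, h = 1e-5) {
  H <- matrix(0, 3L, 3L)
  for (j in 1:3) {
    hj <- h * max(1, abs(par[j]))
    e <- numeric(3); e[j] <- hj
    H[, j] <- (.grad_kar(par + e, dat) - .grad_kar(par - e, dat)) / (2 * hj)
  }
  (H + t(H)) / 2
}

#' Maximum-likelihood fit of the LQ/TCP model
#'
#' Maximises [binomial_loglik()] over \eqn{(k, \alpha, \alpha/\beta)} with a
#' derivative-based quasi-Newton optimiser run from every start in
#' `options$init_grid`; the best final log-likelihood wins and ties (within
#' 1e-8) are broken by the smallest absolute ratio.  The selected optimum is
#' polished with a derivative-free simplex pass.  With
#' `options$nonnegative`, optimisation is bound-constrained at
#' \eqn{\alpha \ge 0}, \eqn{\alpha/\beta \ge 0}, and active bounds are
#' reported.
#'
#' Requires at least 3 arms with at least 2 distinct doses per fraction,
#' otherwise \eqn{\alpha/\beta} is unidentifiable and the fit is refused.
#'
#' @param table An [arm_table()].
#' @param options A [fit_options()] object.
#' @return An object of class `lq_fit`: elements `params` ([lq_params()]),
#'   `loglik`, `converged`, `n_arms`, `n_patients`, `se`, `wald_p`,
#'   `covariance` (3 x 3, from the inverse observed information at the
#'   optimum), `active_bounds`, `group_label`, `options_used`.
#' @examples
#' fit <- fit_mle(load_fixture("conventional"))
#' fit$params
#' @export
fit_mle <- function(table, options = fit_options()) {
  stopifnot(inherits(options, "fit_options"))
  if (options$drop_pooled_subsets) table <- table[!table$subset_of_pooled, ]
  .check_identifiable(table)
  .lqtcp_env$n_fits <- .lqtcp_env$n_fits + 1L
  dat <- .fit_data(table)

  lower <- if (options$nonnegative) c(-Inf, 0, 1e-8) else rep(-Inf, 3)
  obj <- function(par) -.ll_kar(par, dat)
  gr  <- function(par) -.grad_kar(par, dat)

  runs <- lapply(seq_len(nrow(options$init_grid)), function(i) {
    start <- as.numeric(options$init_grid[i, ])
    if (options$nonnegative) start <- pmax(start, lower)
    o <- tryCatch(
      nlminb(start, obj, gradient = gr, lower = lower,
             control = list(iter.max = options$max_iter,
                            eval.max = 4L * options$max_iter,
                            rel.tol = 1e-14, x.tol = options$tol_param)),
      error = function(e) NULL)
    if (is.null(o) || !is.finite(o$objective)) return(NULL)
    o
  })
  runs <- Filter(Negate(is.null), runs)
  if (!length(runs))
    stop("all optimisation starts failed; no candidate optimum", call. = FALSE)

  values <- -vapply(runs, `[[`, numeric(1), "objective")
  best_ll <- max(values)
  tied <- which(values >= best_ll - 1e-8)
  best <- runs[[tied[which.min(vapply(tied, function(i) abs(runs[[i]]$par[3]),
                                      numeric(1)))]]]

  # simplex polish, then a final gradient pass from the polished point
  if (!options$nonnegative) {
    pol <- optim(best$par, obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-15, maxit = 20000L))
    if (pol$value < best$objective) best <- list(par = pol$par, objective = pol$value)
  }
  fin <- nlminb(best$par, obj, gradient = gr, lower = lower,
                control = list(iter.max = options$max_iter,
                               rel.tol = 1e-15, x.tol = 1e-12))
  if (fin$objective <= best$objective) best <- fin

  par <- best$par
  ll <- -best$objective
  g <- .grad_kar(par, dat)
  at_bound <- options$nonnegative & c(FALSE, par[2] <= 1e-10, par[3] <= 1e-8 + 1e-12)
  active_bounds <- c("k", "alpha", "alpha_beta")[at_bound]
  # gradient components along active bounds need not vanish
  converged <- max(abs(g[!at_bound])) < 1e-2

  H <- .hessian_kar(par, dat)
  cov <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, 3L, 3L))
  if (!anyNA(cov) && any(diag(cov) < 0)) cov[] <- NA_real_
  se <- sqrt(diag(cov))
  names(se) <- c("k", "alpha", "alpha_beta")
  dimnames(cov) <- list(names(se), names(se))
  wald_p <- 2 * pnorm(-abs(par / se))
  names(wald_p) <- names(se)

  structure(list(params = lq_params(par[1], par[2], par[3]),
                 loglik = ll,
                 converged = converged,
                 n_arms = nrow(table),
                 n_patients = sum(table$n),
                 se = se,
                 wald_p = wald_p,
                 covariance = cov,
                 active_bounds = active_bounds,
                 group_label = attr(table, "group_label"),
                 options_used = options),
            class = "lq_fit")
}

#' @export
print.lq_fit <- function(x, digits = 4, ...) {
  cat(sprintf("LQ/TCP maximum-likelihood fit: '%s' (%d arms, %d patients)\n",
              x$group_label, x$n_arms, x$n_patients))
  est <- c(x$params$k, x$params$alpha, x$params$alpha_beta)
  tab <- data.frame(estimate = signif(est, digits),
                    se = signif(x$se, digits),
                    wald_p = signif(x$wald_p, 3),
                    row.names = c("k", "alpha (Gy^-1)", "alpha/beta (Gy)"))
  print(tab)
  cat(sprintf("log-likelihood %.4f; converged: %s%s\n", x$loglik, x$converged,
              if (length(x$active_bounds))
                paste0("; active bounds: ", paste(x$active_bounds, collapse = ", "))
              else ""))
  invisible(x)
}

#' Profile the log-likelihood over alpha/beta
#'
#' For each ratio in `r_grid`, maximises the log-likelihood over
#' \eqn{(k, \alpha)} only.  A diagnostic for the optimiser and for interval
#' sanity: the grid maximum brackets the [fit_mle()] optimum.
#'
#' @param table An [arm_table()].
#' @param r_grid Numeric vector of alpha/beta values (all non-zero).
#' @param options A [fit_options()] object.
#' @return A `data.frame` with columns `alpha_beta`, `loglik`, `k`, `alpha`.
#' @export
profile_alpha_beta <- function(table, r_grid, options = fit_options()) {
  stopifnot(length(r_grid) >= 1L, all(r_grid != 0))
  if (options$drop_pooled_subsets) table <- table[!table$subset_of_pooled, ]
  if (nrow(table) < 2L) stop("need at least 2 arms to profile", call. = FALSE)
  dat <- .fit_data(table)
  starts <- unique(options$init_grid[c("k", "alpha")])
  lower2 <- if (options$nonnegative) c(-Inf, 0) else rep(-Inf, 2)
  prev <- NULL
  rows <- lapply(r_grid, function(r) {
    obj2 <- function(p) -.ll_kar(c(p, r), dat)
    gr2 <- function(p) -.grad_kar(c(p, r), dat)[1:2]
    ss <- starts
    if (!is.null(prev)) ss <- rbind(prev, ss)
    cand <- lapply(seq_len(nrow(ss)), function(i) {
      tryCatch(nlminb(pmax(as.numeric(ss[i, ]), lower2), obj2, gradient = gr2,
                      lower = lower2, control = list(rel.tol = 1e-14)),
               error = function(e) NULL)
    })
    cand <- Filter(function(o) !is.null(o) && is.finite(o$objective), cand)
    b <- cand[[which.min(vapply(cand, `[[`, numeric(1), "objective"))]]
    prev <<- data.frame(k = b$par[1], alpha = b$par[2])
    data.frame(alpha_beta = r, loglik = -b$objective, k = b$par[1],
               alpha = b$par[2])
  })
  do.call(rbind, rows)
}
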