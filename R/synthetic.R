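#' Synthetic multi-arm cohort design
#'
#' Describes a simulated meta-analytic cohort with the exact statistical
#' structure the likelihood assumes: each arm's relapse-free count is a
#' binomial draw with success probability given by the TCP model at stated
#' true parameters.
#'
#' @param arms `data.frame` with columns `n` (patients), `total_dose` (Gy)
#'   and `n_fractions` (positive, not necessarily integer).
#' @param truth An [lq_params()] triple: the generating parameters.
#' @param seed Integer master seed.
#' @param replicates Number of replicate tables the design describes.
#' @return An object of class `synthetic_design`.
#' @seealso [generate_table()], [recovery_experiment()],
#'   [conventional_design()]
#' @export
synthetic_design <- function(arms, truth, seed, replicates = 1L) {
  arms <- as.data.frame(arms)
  stopifnot(all(c("n", "total_dose", "n_fractions") %in% names(arms)),
            nrow(arms) >= 1L, inherits(truth, "lq_params"),
            replicates >= 1L)
  if (any(arms$n < 1) || any(arms$total_dose <= 0) || any(arms$n_fractions <= 0))
    stop("invalid arm in design", call. = FALSE)
  d <- arms$total_dose / arms$n_fractions
  if (nrow(arms) < 3L || length(unique(round(d, 6))) < 2L)
    stop("design is unidentifiable: need >= 3 arms and >= 2 distinct doses per fraction",
         call. = FALSE)
  structure(list(arms = arms[c("n", "total_dose", "n_fractions")],
                 truth = truth, seed = as.integer(seed),
                 replicates = as.integer(replicates)),
            class = "synthetic_design")
}

#' Design copying the conventional-fractionation fixture
#'
#' Convenience constructor: the (n, D, N) triples of the packaged
#' conventional-fractionation table (fraction numbers recovered as `D^2/c`
#' where only the fraction size is published), with configurable truth.
#'
#' @param truth Generating parameters; defaults to the conventional-group
#'   estimates `(k = 5.35, alpha = 0.043, alpha/beta = 1.78)`.
#' @param seed Integer master seed.
#' @param replicates Number of replicate tables.
#' @param n_scale Multiplier applied to every arm's patient count.
#' @return A [synthetic_design()].
#' @export
conventional_design <- function(truth = lq_params(5.35, 0.043, 1.78),
                                seed = 1L, replicates = 200L, n_scale = 1) {
  tab <- load_fixture("conventional")
  synthetic_design(
    data.frame(n = as.integer(round(tab$n * n_scale)),
               total_dose = tab$total_dose,
               n_fractions = tab$total_dose^2 / tab$c),
    truth = truth, seed = seed, replicates = replicates)
}

# Counter-based stream: the sub-seed depends only on (seed, replicate, arm),
# so adding arms or replicates never perturbs existing draws.  Kept below
# 2^31 - 1.
.arm_seed <- function(seed, replicate_index, arm_index) {
  as.integer((as.double(seed) + 1000003 * replicate_index +
                7919 * arm_index) %% 2147483629)
}

.with_preserved_rng <- function(code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

#' Generate one synthetic arm table
#'
#' For each design arm, the model TCP is evaluated at the design truth and
#' the relapse-free count drawn as Binomial(n, P) from a deterministic
#' stream derived from (seed, replicate, arm).  The observed proportion is
#' the exact rational successes/n; all derived columns are filled
#' consistently (c = D^2/N).  The caller's RNG state is left untouched.
#'
#' @param design A [synthetic_design()].
#' @param replicate_index Which replicate to generate (1-based).
#' @return An [arm_table()].
#' @export
generate_table <- function(design, replicate_index = 1L) {
  stopifnot(inherits(design, "synthetic_design"),
            replicate_index >= 1L, replicate_index <= design$replicates)
  arms <- design$arms
  P <- tcp_total_dose(design$truth, arms$total_dose, arms$n_fractions)
  successes <- .with_preserved_rng({
    vapply(seq_len(nrow(arms)), function(i) {
      set.seed(.arm_seed(design$seed, replicate_index, i))
      rbinom(1L, arms$n[i], P[i])
    }, numeric(1))
  })
  arm_table(
    data.frame(study = seq_len(nrow(arms)),
               author = sprintf("sim%02d", seq_len(nrow(arms))),
               n = arms$n,
               brfs_5y = successes / arms$n,
               total_dose = arms$total_dose,
               n_fractions = arms$n_fractions,
               dose_per_fraction = NA_real_,
               c = arms$total_dose^2 / arms$n_fractions,
               definition = "Phoenix",
               risk_group = NA_character_,
               subset_of_pooled = FALSE),
    group_label = sprintf("synthetic replicate %d", replicate_index))
}

#' Parameter-recovery experiment
#'
#' For each replicate of the design: generate a table, fit the MLE, and
#' (optionally) compute jackknife-normal intervals.  Reports per-parameter
#' bias, RMSE and empirical interval coverage against the design truth.
#' Replicate fit failures are recorded with their indices, not raised;
#' more than 10% failures aborts the harness.
#'
#' @param design A [synthetic_design()].
#' @param options A [fit_options()] object used for every fit.
#' @param level Interval coverage level.
#' @param intervals Compute jackknife-normal intervals per replicate (m
#'   extra refits each) and report empirical coverage.
#' @return An object of class `lq_recovery`: `estimates` (one row per
#'   successful replicate), `bias`, `rmse`, `median`, `coverage` (or `NA`),
#'   `failures` (replicate indices), `truth`, `design`.
#' @export
recovery_experiment <- function(design, options = fit_options(),
                                level = 0.95, intervals = TRUE) {
  stopifnot(inherits(design, "synthetic_design"))
  truth <- .params_vec(design$truth)
  rows <- vector("list", design$replicates)
  covered <- matrix(NA, design$replicates, 3L,
                    dimnames = list(NULL, names(truth)))
  failures <- integer(0)
  for (r in seq_len(design$replicates)) {
    tab <- generate_table(design, r)
    fit <- tryCatch(fit_mle(tab, options), error = function(e) NULL)
    if (is.null(fit)) { failures <- c(failures, r); next }
    est <- .params_vec(fit$params)
    rows[[r]] <- data.frame(replicate = r, k = est[1], alpha = est[2],
                            alpha_beta = est[3], loglik = fit$loglik,
                            converged = fit$converged)
    if (intervals) {
      jk <- tryCatch(jackknife(tab, options, point = fit),
                     error = function(e) NULL)
      if (!is.null(jk)) {
        ci <- jackknife_interval(jk, level = level, flavor = "normal")
        covered[r, ] <- ci$lower <= truth & truth <= ci$upper
      }
    }
  }
  if (length(failures) > 0.1 * design$replicates)
    stop(sprintf("recovery harness: %d of %d replicate fits failed",
                 length(failures), design$replicates), call. = FALSE)
  est <- do.call(rbind, rows)
  mat <- as.matrix(est[c("k", "alpha", "alpha_beta")])
  bias <- colMeans(mat) - truth
  rmse <- sqrt(colMeans(sweep(mat, 2L, truth)^2))
  coverage <- if (intervals) colMeans(covered, na.rm = TRUE)
              else setNames(rep(NA_real_, 3L), names(truth))
  structure(list(estimates = est, bias = bias, rmse = rmse,
                 median = apply(mat, 2L, stats::median),
                 coverage = coverage, level = level,
                 failures = failures, truth = truth, design = design),
            class = "lq_recovery")
}

#' @export
print.lq_recovery <- function(x, ...) {
  cat(sprintf("Parameter recovery: %d replicates (%d failed), truth (k, alpha, a/b) = (%g, %g, %g)\n",
              x$design$replicates, length(x$failures),
              x$truth[1], x$truth[2], x$truth[3]))
  print(data.frame(truth = x$truth, bias = signif(x$bias, 4),
                   rmse = signif(x$rmse, 4), median = signif(x$median, 4),
                   coverage = x$coverage))
  invisible(x)
}
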