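# Reduced warm-started grid used for resampling refits: the full-sample
# optimum plus a coarse cage of corners.  Replicate surfaces differ from the
# full-sample surface by one arm, so the cage guards against a replicate
# optimum escaping the neighbourhood of the warm start.
.warm_grid <- function(point) {
  rbind(data.frame(k = point[1], alpha = point[2], alpha_beta = point[3]),
        expand.grid(k = c(0, 5), alpha = c(0.01, 0.1),
                    alpha_beta = c(1.5, 10), KEEP.OUT.ATTRS = FALSE))
}

.params_vec <- function(p) c(k = p$k, alpha = p$alpha, alpha_beta = p$alpha_beta)

#' Leave-one-arm-out jackknife of the MLE
#'
#' Removes one study arm at a time and refits; with m arms this performs
#' exactly m refits, and replicate i never sees arm i.  The jackknife
#' standard error per parameter is
#' \deqn{\widehat{se} = \sqrt{\frac{m-1}{m} \sum_i (\theta_i - \bar\theta)^2}.}
#'
#' Replicate refits are warm-started from the full-sample optimum (plus a
#' coarse safety grid); results are deterministic given `options`.
#'
#' @param table An [arm_table()] with at least 4 arms (each leave-one-out
#'   subtable must itself be fittable).
#' @param options A [fit_options()] object.
#' @param point Optional precomputed full-sample [fit_mle()] result; fitted
#'   here when `NULL`.
#' @return An object of class `lq_jackknife`: `replicates` (m x 3 matrix),
#'   `jack_mean`, `jack_se`, `m`, `point` (the full-sample `lq_fit`).
#' @export
jackknife <- function(table, options = fit_options(), point = NULL) {
  if (options$drop_pooled_subsets) {
    table <- table[!table$subset_of_pooled, ]
    options$drop_pooled_subsets <- FALSE  # already applied; keep indices stable
  }
  m <- nrow(table)
  if (m < 4L) stop("jackknife needs at least 4 arms", call. = FALSE)
  if (is.null(point)) point <- fit_mle(table, options)
  stopifnot(inherits(point, "lq_fit"))

  rep_options <- options
  rep_options$init_grid <- .warm_grid(.params_vec(point$params))

  replicates <- matrix(NA_real_, m, 3L,
                       dimnames = list(NULL, c("k", "alpha", "alpha_beta")))
  for (i in seq_len(m)) {
    fit_i <- tryCatch(fit_mle(table[-i, ], rep_options), error = function(e) e)
    if (inherits(fit_i, "error")) {
      stop(sprintf("jackknife replicate failed with arm %d (%s) left out: %s",
                   i, table$author[i], conditionMessage(fit_i)), call. = FALSE)
    }
    replicates[i, ] <- .params_vec(fit_i$params)
  }
  jack_mean <- colMeans(replicates)
  jack_se <- sqrt((m - 1) / m *
                    colSums(sweep(replicates, 2L, jack_mean)^2))
  structure(list(replicates = replicates, jack_mean = jack_mean,
                 jack_se = jack_se, m = m, point = point,
                 options_used = options),
            class = "lq_jackknife")
}

#' @export
print.lq_jackknife <- function(x, ...) {
  cat(sprintf("Leave-one-out jackknife over %d arms\n", x$m))
  print(data.frame(point = signif(.params_vec(x$point$params), 5),
                   jack_mean = signif(x$jack_mean, 5),
                   jack_se = signif(x$jack_se, 5)))
  invisible(x)
}

#' Jackknife confidence intervals
#'
#' Symmetric intervals centred on the full-sample MLE (the default) using
#' the jackknife standard error: `point +/- z * se` (normal flavour) or
#' `point +/- t[m-1] * se` (t flavour).  The jackknife mean is reported
#' alongside.
#'
#' @param summary An [jackknife()] result.
#' @param level Coverage level in (0, 1).
#' @param flavor `"normal"` (z multiplier) or `"t"` (Student t, m - 1 df).
#' @param center `"point"` (full-sample MLE, default) or `"jack_mean"`.
#' @return A `data.frame` with one row per parameter: `parameter`, `point`,
#'   `lower`, `upper`, `level`, `method`, `jack_mean`, `jack_se`.
#' @export
jackknife_interval <- function(summary, level = 0.95,
                               flavor = c("normal", "t"),
                               center = c("point", "jack_mean")) {
  stopifnot(inherits(summary, "lq_jackknife"), level > 0, level < 1)
  flavor <- match.arg(flavor)
  center <- match.arg(center)
  est <- .params_vec(summary$point$params)
  ctr <- if (center == "point") est else summary$jack_mean
  mult <- if (flavor == "normal") qnorm((1 + level) / 2)
          else stats::qt((1 + level) / 2, df = summary$m - 1L)
  data.frame(parameter = names(est),
             point = unname(est),
             lower = unname(ctr - mult * summary$jack_se),
             upper = unname(ctr + mult * summary$jack_se),
             level = level,
             method = paste0("jackknife_", flavor),
             jack_mean = unname(summary$jack_mean),
             jack_se = unname(summary$jack_se),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Draw one bootstrap index set that yields a fittable table (>= 2 distinct
# doses per fraction).  Uses the current RNG stream; invalid draws are
# redrawn so the stream stays deterministic under a fixed seed.
.boot_indices <- function(table, m, max_tries = 1000L) {
  d <- table$dose_per_fraction
  for (try in seq_len(max_tries)) {
    idx <- sample.int(m, m, replace = TRUE)
    if (length(unique(round(d[idx], 6))) >= 2L) return(idx)
  }
  stop("could not draw an identifiable bootstrap resample", call. = FALSE)
}

#' BCa bootstrap confidence intervals
#'
#' Nonparametric bootstrap over study arms (arms resampled with replacement;
#' patients are never resampled individually), with Efron's bias-corrected
#' and accelerated adjustment: the bias correction z0 comes from the
#' fraction of bootstrap replicates below the full-sample estimate and the
#' acceleration a from jackknife influence values.  Reproducible under a
#' fixed seed.
#'
#' If the bootstrap distribution of a parameter is degenerate (all
#' replicates equal) the interval falls back to the percentile interval with
#' a warning.
#'
#' @param table An [arm_table()].
#' @param options A [fit_options()] object.
#' @param n_boot Number of bootstrap resamples (>= 1000 recommended).
#' @param seed Integer seed; mandatory.
#' @param level Coverage level in (0, 1).
#' @param force_z0,force_accel Override the estimated bias-correction and
#'   acceleration (testing hooks: with both forced to 0 the BCa interval
#'   reduces to the bootstrap percentile interval).
#' @return A `data.frame` as in [jackknife_interval()] with
#'   `method = "bca"`, plus columns `z0` and `accel`; the bootstrap
#'   replicate matrix is attached as attribute `"replicates"`.
#' @export
bca_interval <- function(table, options = fit_options(), n_boot = 2000L,
                         seed, level = 0.95,
                         force_z0 = NULL, force_accel = NULL) {
  if (missing(seed)) stop("seed is mandatory for bca_interval", call. = FALSE)
  stopifnot(n_boot >= 1L, level > 0, level < 1)
  if (options$drop_pooled_subsets) {
    table <- table[!table$subset_of_pooled, ]
    options$drop_pooled_subsets <- FALSE
  }
  m <- nrow(table)
  point <- fit_mle(table, options)
  jk <- jackknife(table, options, point = point)
  est <- .params_vec(point$params)

  rep_options <- options
  rep_options$init_grid <- .warm_grid(est)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  boot <- matrix(NA_real_, n_boot, 3L,
                 dimnames = list(NULL, names(est)))
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- .boot_indices(table, m)
      fit_b <- tryCatch(fit_mle(table[idx, ], rep_options),
                        error = function(e) NULL)
      if (!is.null(fit_b)) break
    }
    boot[b, ] <- .params_vec(fit_b$params)
  }

  z_lo <- qnorm((1 - level) / 2)
  z_hi <- qnorm((1 + level) / 2)
  rows <- lapply(seq_along(est), function(j) {
    th <- boot[, j]
    if (diff(range(th)) == 0) {
      warning(sprintf(
        "degenerate bootstrap distribution for %s; percentile fallback",
        names(est)[j]))
      lo <- hi <- th[1]
      z0 <- a <- 0
    } else {
      frac <- mean(th < est[j])
      frac <- min(max(frac, 1 / (n_boot + 1)), n_boot / (n_boot + 1))
      z0 <- qnorm(frac)
      infl <- jk$jack_mean[j] - jk$replicates[, j]
      denom <- sum(infl^2)^1.5
      a <- if (denom > 0) sum(infl^3) / (6 * denom) else 0
      if (!is.null(force_z0)) z0 <- force_z0
      if (!is.null(force_accel)) a <- force_accel
      p_lo <- pnorm(z0 + (z0 + z_lo) / (1 - a * (z0 + z_lo)))
      p_hi <- pnorm(z0 + (z0 + z_hi) / (1 - a * (z0 + z_hi)))
      qs <- quantile(th, c(p_lo, p_hi), names = FALSE, type = 7)
      lo <- qs[1]; hi <- qs[2]
    }
    data.frame(parameter = names(est)[j], point = unname(est[j]),
               lower = lo, upper = hi, level = level, method = "bca",
               z0 = z0, accel = a, row.names = NULL,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "replicates") <- boot
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- as.integer(seed)
  out
}
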