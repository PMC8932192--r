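#' LQ/TCP parameter triple
#'
#' Canonical parameterisation of the tumour control probability model:
#' `k` (natural logarithm of the effective clonogenic target cell number),
#' `alpha` (one-track lethal damage coefficient, Gy^-1) and the ratio
#' `alpha_beta` (Gy).  `beta` (Gy^-2) is always derived as
#' `alpha / alpha_beta`, never stored independently, so
#' `beta * alpha_beta == alpha` holds by construction.
#'
#' @param k Dimensionless log effective target cell number.
#' @param alpha One-track coefficient in Gy^-1.
#' @param alpha_beta Ratio alpha/beta in Gy; must be non-zero.
#' @return An object of class `lq_params` with elements `k`, `alpha`,
#'   `alpha_beta`, `beta`.
#' @examples
#' p <- lq_params(k = 5.35, alpha = 0.043, alpha_beta = 1.78)
#' tcp_total_dose(p, total_dose = 78, n_fractions = 39)
#' @export
lq_params <- function(k, alpha, alpha_beta) {
  stopifnot(is.numeric(k), is.numeric(alpha), is.numeric(alpha_beta),
            length(k) == 1L, length(alpha) == 1L, length(alpha_beta) == 1L,
            is.finite(k), is.finite(alpha), is.finite(alpha_beta))
  if (alpha_beta == 0) stop("alpha_beta must be non-zero", call. = FALSE)
  structure(list(k = k, alpha = alpha, alpha_beta = alpha_beta,
                 beta = alpha / alpha_beta),
            class = "lq_params")
}

#' @export
print.lq_params <- function(x, digits = 4, ...) {
  cat(sprintf("LQ/TCP parameters: k = %s, alpha = %s Gy^-1, alpha/beta = %s Gy (beta = %s Gy^-2)\n",
              format(x$k, digits = digits), format(x$alpha, digits = digits),
              format(x$alpha_beta, digits = digits),
              format(x$beta, digits = digits)))
  invisible(x)
}

#' Tumour control probability from total dose and fraction number
#'
#' Evaluates \eqn{P = \exp(-\exp(k - \alpha D - \beta D^2/N))}, the
#' Poisson-type TCP for a schedule delivering total dose `D` in `N` equal
#' fractions.  `n_fractions` need not be an integer (it enters only through
#' `D^2/N`).  No clamping is applied here; probabilities are guarded only
#' inside likelihood evaluation.
#'
#' @param params An [lq_params()] triple.
#' @param total_dose Total dose D in Gy (>= 0); vectorised.
#' @param n_fractions Number of fractions N (> 0); vectorised.
#' @return Probabilities in (0, 1).
#' @export
tcp_total_dose <- function(params, total_dose, n_fractions) {
  stopifnot(inherits(params, "lq_params"))
  if (any(total_dose < 0)) stop("total_dose must be >= 0", call. = FALSE)
  if (any(n_fractions <= 0)) stop("n_fractions must be > 0", call. = FALSE)
  exp(-exp(params$k - params$alpha * total_dose -
             params$beta * total_dose^2 / n_fractions))
}

#' Tumour control probability from total dose and dose per fraction
#'
#' Evaluates \eqn{P = \exp(-\exp(k - \alpha D - \beta D d))}; algebraically
#' identical to [tcp_total_dose()] whenever `d = D/N`.
#'
#' @param params An [lq_params()] triple.
#' @param total_dose Total dose D in Gy (>= 0); vectorised.
#' @param dose_per_fraction Dose per fraction d in Gy (> 0); vectorised.
#' @return Probabilities in (0, 1).
#' @export
tcp_fraction_dose <- function(params, total_dose, dose_per_fraction) {
  stopifnot(inherits(params, "lq_params"))
  if (any(total_dose < 0)) stop("total_dose must be >= 0", call. = FALSE)
  if (any(dose_per_fraction <= 0)) stop("dose_per_fraction must be > 0", call. = FALSE)
  exp(-exp(params$k - params$alpha * total_dose -
             params$beta * total_dose * dose_per_fraction))
}

#' Biologically effective dose
#'
#' \eqn{BED = D (1 + d / (\alpha/\beta))}.  Strictly increasing in the dose
#' per fraction at fixed total dose and ratio; tends to `D` as the ratio
#' grows.  A non-positive `alpha_beta` is refused: a restriction-free fit can
#' produce negative ratios, for which the BED is undefined.
#'
#' @param total_dose Total dose D in Gy (> 0).
#' @param dose_per_fraction Dose per fraction d in Gy (> 0).
#' @param alpha_beta Ratio alpha/beta in Gy (> 0).
#' @return BED in Gy; vectorised over all arguments.
#' @examples
#' bed(70, 2.5, 1.5)    # 186.7 Gy
#' bed(70, 2.5, 3.46)   # 120.6 Gy
#' @export
bed <- function(total_dose, dose_per_fraction, alpha_beta) {
  if (any(total_dose <= 0) || any(dose_per_fraction <= 0))
    stop("doses must be positive", call. = FALSE)
  if (any(alpha_beta <= 0))
    stop("alpha_beta must be positive; BED is undefined for non-positive ratios",
         call. = FALSE)
  total_dose * (1 + dose_per_fraction / alpha_beta)
}
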