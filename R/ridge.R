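# Ridge closed forms for the continuous-response case, used analytically:
# ridge with a common penalty on raw covariates is the rescaled solution of
# ridge on standardized covariates with per-covariate penalties
# lambda / s_j^2, so covariates with larger variance are effectively
# penalized less.

#' Closed-form ridge regression estimate
#'
#' Returns \eqn{(X'X + \Lambda)^{-1} X'y} for centered covariates and a
#' continuous response, where \eqn{\Lambda} is diagonal with the given
#' (scalar or per-covariate) penalties.
#'
#' @param x centered covariate matrix (samples x covariates).
#' @param y continuous response.
#' @param penalty scalar or per-covariate non-negative penalty.
#' @return Coefficient vector.
#' @export
ridge_closed_form <- function(x, y, penalty) {
  x <- as.matrix(x)
  penalty <- rep_len(penalty, ncol(x))
  xtx <- crossprod(x) + diag(penalty, ncol(x))
  out <- tryCatch(solve(xtx, crossprod(x, y)),
                  error = function(e)
                    stop_invalid("rank error: X'X + penalty is singular (p > n with zero penalty?)"))
  as.numeric(out)
}

#' Ridge on standardized covariates, with the rescaling map
#'
#' Standardizes each covariate to unit SD (denominator \eqn{n-1}),
#' solves the ridge problem there, and also returns the solution mapped
#' back to the raw covariate scale (\eqn{D^{-1}} rescaling).
#'
#' @inheritParams ridge_closed_form
#' @return List with \code{coef_standardized}, \code{coef_rescaled}
#'   (raw-scale coefficients) and \code{sd} (the per-covariate SDs).
#' @export
ridge_standardized <- function(x, y, penalty) {
  x <- as.matrix(x)
  sdv <- apply(x, 2, stats::sd)
  if (any(sdv <= 0)) stop_invalid("constant covariate cannot be standardized")
  z <- sweep(x, 2, sdv, "/")
  bz <- ridge_closed_form(z, y, penalty)
  list(coef_standardized = bz, coef_rescaled = bz / sdv, sd = sdv)
}
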