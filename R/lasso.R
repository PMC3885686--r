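# Lasso-penalized Cox regression with mandatory unpenalized covariates.
# The convex problem is solved by glmnet (penalty.factor = 0 on the
# mandatory block, no internal standardization — covariate scaling is the
# object of study here); correctness of returned solutions is pinned by an
# explicit Karush-Kuhn-Tucker check on the partial-likelihood gradient.

# gradient of the Breslow partial log-likelihood at beta
cox_pll_grad <- function(x, time, event, beta) {
  co <- cox_order(time, event)
  x <- as.matrix(x)[co$ord, , drop = FALSE]
  w <- exp(as.numeric(x %*% beta))
  rs0 <- rev(cumsum(rev(w)))[co$first]
  S1 <- revcumsum_mat(w * x)[co$first, , drop = FALSE]
  colSums(x[co$evi, , drop = FALSE] -
            S1[co$evi, , drop = FALSE] / rs0[co$evi])
}

#' Lasso Cox path with mandatory unpenalized covariates
#'
#' @param x covariate matrix (samples x covariates).
#' @param time,event survival outcome (event: 1 = observed).
#' @param mandatory integer column indices left unpenalized.
#' @param lambda optional decreasing penalty grid; glmnet's data-derived
#'   grid when NULL.
#' @param lambda.min.ratio smallest penalty as a fraction of the critical
#'   one when the grid is data-derived (0.05: the far tail of the path is
#'   badly conditioned for p >> events and is never selected by CV).
#' @param ... passed to \code{glmnet::glmnet}.
#' @return Object of class \code{countsig_lasso}: the glmnet fit plus
#'   \code{lambda}, \code{mandatory}, and accessors via
#'   \code{\link{lasso_coef}} / \code{\link{lasso_kkt_violation}}.
#' @export
lasso_cox_fit <- function(x, time, event, mandatory = integer(0),
                          lambda = NULL, lambda.min.ratio = 0.05, ...) {
  if (sum(event) < 1) stop_invalid("cox lasso needs at least one event")
  if (!is.null(lambda) && is.unsorted(rev(lambda)))
    stop_invalid("lambda grid must be decreasing")
  pf <- rep(1, ncol(x))
  pf[mandatory] <- 0
  fit <- if (is.null(lambda))
    glmnet::glmnet(as.matrix(x), survival::Surv(time, event),
                   family = "cox", penalty.factor = pf,
                   standardize = FALSE,
                   lambda.min.ratio = lambda.min.ratio,
                   thresh = 1e-12, ...)
  else
    glmnet::glmnet(as.matrix(x), survival::Surv(time, event),
                   family = "cox", penalty.factor = pf,
                   standardize = FALSE, lambda = lambda,
                   thresh = 1e-12, ...)
  structure(list(glmnet = fit, lambda = fit$lambda, mandatory = mandatory,
                 time = time, event = event),
            class = "countsig_lasso")
}

#' Coefficients of a lasso Cox fit at a penalty value
#'
#' @param fit a \code{countsig_lasso}.
#' @param lambda penalty value (matched exactly or interpolated by glmnet).
#' @return Named coefficient vector.
#' @export
lasso_coef <- function(fit, lambda = min(fit$lambda)) {
  as.numeric(glmnet::coef.glmnet(fit$glmnet, s = lambda))
}

#' Maximum KKT violation of a lasso Cox solution
#'
#' For the objective \eqn{-(1/n)\,pll(\beta) + \lambda \sum_j pf_j
#' |\beta_j|} (the scaling glmnet uses) the stationarity conditions are
#' \eqn{|(1/n) U_j| \le \lambda pf_j} for zero coefficients and
#' \eqn{(1/n) U_j = \lambda pf_j\, sign(\beta_j)} for active ones, with
#' \eqn{U} the partial-likelihood gradient.  Returns the largest
#' violation across coordinates.
#'
#' @param fit a \code{countsig_lasso}.
#' @param x the covariate matrix the fit was computed on.
#' @param lambda penalty value at which to check.
#' @return Non-negative scalar; 0 means the conditions hold exactly.
#' @export
lasso_kkt_violation <- function(fit, x, lambda = min(fit$lambda)) {
  beta <- lasso_coef(fit, lambda)
  n <- nrow(x)
  g <- cox_pll_grad(x, fit$time, fit$event, beta) / n
  pf <- rep(1, ncol(x)); pf[fit$mandatory] <- 0
  pf <- pf * length(pf) / sum(pf)   # glmnet rescales factors to sum to nvars
  active <- beta != 0 & pf > 0
  viol <- numeric(ncol(x))
  zero <- !active & pf > 0
  viol[zero] <- pmax(0, abs(g[zero]) - lambda * pf[zero])
  viol[active] <- abs(g[active] - lambda * pf[active] * sign(beta[active]))
  viol[pf == 0] <- abs(g[pf == 0])
  max(viol)
}
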