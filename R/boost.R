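# Componentwise likelihood-based boosting for logistic, Cox and the
# continuous-response (stagewise) special case, with mandatory unpenalized
# covariates.  At every step each penalized covariate is scored by the
# penalized score statistic U^2 / (I + lambda) at the current fit; the best
# one receives a one-dimensional penalized Newton update U / (I + lambda);
# the intercept and mandatory covariates are then refreshed by one
# unpenalized Newton step.

# per-column suffix sums: out[i, j] = sum(m[i:n, j]).  Written via the
# whole-matrix running sum; the cross-column offsets cancel in the
# difference, so no per-column correction is needed.
revcumsum_mat <- function(m) {
  n <- nrow(m); p <- ncol(m)
  cs <- matrix(cumsum(m), n, p)
  rep(cs[n, ], each = n) - cs + m
}

# suffix sums evaluated only at the requested rows
revcumsum_rows <- function(m, rows) {
  n <- nrow(m); p <- ncol(m)
  cs <- matrix(cumsum(m), n, p)
  rep(cs[n, ], each = length(rows)) - cs[rows, , drop = FALSE] +
    m[rows, , drop = FALSE]
}

cox_order <- function(time, event) {
  ord <- order(time)
  tt <- time[ord]
  list(ord = ord, time = tt, event = event[ord],
       first = match(tt, tt), evi = which(event[ord] == 1))
}

# Breslow partial log-likelihood for eta already in cox_order's ordering
cox_pll <- function(co, eta) {
  w <- exp(eta)
  rs0 <- rev(cumsum(rev(w)))[co$first]
  sum(eta[co$evi] - log(rs0[co$evi]))
}

logistic_loglik <- function(y, eta) {
  p <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Componentwise likelihood-based boosting
#'
#' Fits a sparse regularized model by iteratively updating one penalized
#' coefficient per step, the one maximizing the penalized score statistic
#' \eqn{U_j^2 / (I_j + \lambda)} (score ties broken toward the lowest
#' column index).  Mandatory covariates (and the intercept, for
#' non-Cox families) are unpenalized: they are fitted at initialization
#' and refreshed by one unpenalized Newton step after every boosting
#' update.  Because the penalty is shared, covariates with larger
#' variance receive relatively less shrinkage and are preferentially
#' selected — the behavior whose consequences this package studies.
#'
#' @param x numeric matrix, samples in rows, covariates in columns.
#' @param y response: 0/1 vector (logistic), numeric vector (gaussian), or
#'   a \code{survival::Surv} object (cox).
#' @param family \code{"logistic"}, \code{"cox"} or \code{"gaussian"}
#'   (the continuous-response special case in which boosting is stagewise
#'   regression).
#' @param mandatory integer column indices of unpenalized covariates.
#' @param steps number of boosting steps.
#' @param nu shrinkage factor in (0, 1]; the penalty is derived as
#'   \eqn{\lambda = (1/\nu - 1) \times} (sum of working weights at the
#'   null fit), so a standardized covariate's update is shrunk by about
#'   \eqn{\nu}.  Ignored when \code{penalty} is given.
#' @param penalty optional explicit non-negative penalty \eqn{\lambda}.
#' @return Object of class \code{countsig_boost} with elements
#'   \code{beta} (final coefficients), \code{intercept}, \code{selected}
#'   (per-step updated column), \code{delta} (per-step update values),
#'   \code{mand_path} (per-step intercept/mandatory coefficients),
#'   \code{loglik} (per-step (partial) log-likelihood) and \code{penalty}.
#' @export
boost_fit <- function(x, y, family = c("logistic", "cox", "gaussian"),
                      mandatory = integer(0), steps = 100, nu = 0.1,
                      penalty = NULL) {
  family <- match.arg(family)
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (anyNA(x)) stop_invalid("x contains missing values")
  if (steps < 0) stop_invalid("steps must be >= 0")
  pen_idx <- setdiff(seq_len(p), mandatory)
  q <- length(mandatory)

  if (family == "cox") {
    if (inherits(y, "Surv")) { time <- y[, 1]; event <- y[, 2] }
    else stop_invalid("cox family needs a survival::Surv response")
    if (sum(event) < 1) stop_invalid("cox family needs at least one event")
    co <- cox_order(time, event)
    x <- x[co$ord, , drop = FALSE]
  } else {
    y <- as.numeric(y)
  }

  Zp <- x[, pen_idx, drop = FALSE]
  Zp2 <- Zp^2
  Xm <- if (family == "cox") x[, mandatory, drop = FALSE]
        else cbind(`(Intercept)` = 1, x[, mandatory, drop = FALSE])
  beta <- numeric(p)
  mand_coef <- numeric(ncol(Xm))
  eta <- rep(0, n)

  # one unpenalized Newton step for the intercept/mandatory block
  newton_block <- function(eta) {
    if (ncol(Xm) == 0) return(NULL)
    if (family == "logistic") {
      pr <- plogis(eta)
      w <- pmax(pr * (1 - pr), 1e-10)
      U <- crossprod(Xm, y - pr)
      H <- crossprod(Xm * w, Xm)
    } else if (family == "gaussian") {
      U <- crossprod(Xm, y - eta)
      H <- crossprod(Xm)
    } else {
      w <- exp(eta)
      rs0 <- rev(cumsum(rev(w)))[co$first]
      S1 <- revcumsum_rows(w * Xm, co$first[co$evi])
      mbar <- S1 / rs0[co$evi]
      U <- colSums(Xm[co$evi, , drop = FALSE] - mbar)
      H <- matrix(0, q, q)
      for (a in seq_len(q)) for (b in a:q) {
        s2 <- rev(cumsum(rev(w * Xm[, a] * Xm[, b])))[co$first]
        h <- sum(s2[co$evi] / rs0[co$evi] - mbar[, a] * mbar[, b])
        H[a, b] <- H[b, a] <- h
      }
    }
    solve(H + diag(1e-8, ncol(Xm)), U)
  }

  refresh <- function(iter_max = 1) {
    if (ncol(Xm) == 0) return(invisible())
    for (it in seq_len(iter_max)) {
      d <- newton_block(eta)
      mand_coef <<- mand_coef + as.numeric(d)
      eta <<- eta + as.numeric(Xm %*% d)
      if (max(abs(d)) < 1e-10) break
    }
  }
  refresh(iter_max = 25)  # initial (null + mandatory) fit

  loglik_now <- function() switch(family,
    logistic = logistic_loglik(y, eta),
    gaussian = -sum((y - eta)^2) / 2,
    cox = cox_pll(co, eta))

  if (is.null(penalty)) {
    wsum <- switch(family,
      logistic = { pr <- plogis(eta); sum(pr * (1 - pr)) },
      gaussian = n,
      cox = length(co$evi))
    penalty <- (1 / nu - 1) * wsum
  }

  if (family == "cox" && length(pen_idx) > 0)
    zp_ev_sum <- .colSums(Zp[co$evi, , drop = FALSE], length(co$evi),
                          ncol(Zp))
  selected <- integer(steps)
  delta <- numeric(steps)
  mand_path <- matrix(0, steps + 1, ncol(Xm))
  mand_path[1, ] <- mand_coef
  loglik <- numeric(steps + 1)
  loglik[1] <- loglik_now()

  for (m in seq_len(steps)) {
    if (length(pen_idx) == 0) {   # nothing penalized: keep refreshing block
      refresh()
      mand_path[m + 1, ] <- mand_coef
      loglik[m + 1] <- loglik_now()
      next
    }
    if (family == "logistic") {
      pr <- plogis(eta)
      w <- pmax(pr * (1 - pr), 1e-10)
      U <- as.numeric(crossprod(Zp, y - pr))
      I <- as.numeric(crossprod(Zp2, w))
    } else if (family == "gaussian") {
      U <- as.numeric(crossprod(Zp, y - eta))
      I <- colSums(Zp2)
    } else {
      w <- exp(eta)
      rs0 <- rev(cumsum(rev(w)))[co$first]
      rse <- rs0[co$evi]
      rows <- co$first[co$evi]
      S1 <- revcumsum_rows(w * Zp, rows)
      S2 <- revcumsum_rows(w * Zp2, rows)
      mb <- S1 / rse
      U <- zp_ev_sum - .colSums(mb, nrow(mb), ncol(mb))
      I <- .colSums(S2 / rse - mb^2, nrow(mb), ncol(mb))
    }
    stat <- U^2 / (I + penalty)
    j <- which.max(stat)            # ties -> lowest index
    d <- U[j] / (I[j] + penalty)
    beta[pen_idx[j]] <- beta[pen_idx[j]] + d
    eta <- eta + d * Zp[, j]
    selected[m] <- pen_idx[j]
    delta[m] <- d
    refresh()
    mand_path[m + 1, ] <- mand_coef
    loglik[m + 1] <- loglik_now()
    if (!is.finite(loglik[m + 1]))
      stop_invalid("boosting diverged at step %d (non-finite likelihood)", m)
  }

  has_int <- family != "cox"
  beta[mandatory] <- mand_coef[if (has_int) -1 else seq_len(q)]
  structure(list(
    beta = beta,
    intercept = if (has_int) mand_coef[1] else 0,
    selected = selected, delta = delta,
    mandatory = mandatory, mand_path = mand_path,
    loglik = loglik, penalty = penalty, nu = nu,
    steps = steps, family = family,
    covariate_names = colnames(x)),
    class = "countsig_boost")
}

#' @export
#' @method print countsig_boost
print.countsig_boost <- function(x, ...) {
  cat(sprintf("componentwise boosting (%s): %d steps, penalty %.3g\n",
              x$family, x$steps, x$penalty))
  cat(sprintf("  selected %d penalized covariates; %d mandatory\n",
              length(selected_set(x)), length(x$mandatory)))
  invisible(x)
}

#' Penalized support of a boosting fit
#'
#' @param fit a \code{countsig_boost}.
#' @param step optional step at which to evaluate (default: final).
#' @return Integer column indices with non-zero penalized coefficients,
#'   in order of first selection.
#' @export
selected_set <- function(fit, step = fit$steps) {
  sel <- fit$selected[seq_len(step)]
  unique(sel[sel > 0])
}

#' Coefficients of a boosting fit at an intermediate step
#'
#' @param fit a \code{countsig_boost}.
#' @param step boosting step (0 = initial fit).
#' @return Full coefficient vector (mandatory entries included) with the
#'   intercept as attribute \code{"intercept"}.
#' @export
boost_coef <- function(fit, step = fit$steps) {
  beta <- numeric(length(fit$beta))
  if (step > 0) {
    sel <- fit$selected[seq_len(step)]
    for (k in seq_along(sel)) beta[sel[k]] <- beta[sel[k]] + fit$delta[k]
  }
  has_int <- fit$family != "cox"
  mc <- fit$mand_path[step + 1, ]
  beta[fit$mandatory] <- mc[if (has_int) -1 else seq_along(fit$mandatory)]
  attr(beta, "intercept") <- if (has_int) mc[1] else 0
  beta
}

#' Linear-predictor path on new data
#'
#' @param fit a \code{countsig_boost}.
#' @param newx matrix with the same columns as the training matrix.
#' @return Matrix \code{nrow(newx) x (steps + 1)}; column \code{m + 1} is
#'   the linear predictor after step \code{m}.
#' @export
boost_eta_path <- function(fit, newx) {
  newx <- as.matrix(newx)
  has_int <- fit$family != "cox"
  Xm <- if (has_int) cbind(1, newx[, fit$mandatory, drop = FALSE])
        else newx[, fit$mandatory, drop = FALSE]
  eta <- matrix(0, nrow(newx), fit$steps + 1)
  cur <- if (ncol(Xm) > 0) as.numeric(Xm %*% fit$mand_path[1, ]) else rep(0, nrow(newx))
  eta[, 1] <- cur
  for (m in seq_len(fit$steps)) {
    if (fit$selected[m] > 0)
      cur <- cur + fit$delta[m] * newx[, fit$selected[m]]
    if (ncol(Xm) > 0)
      cur <- cur + as.numeric(Xm %*% (fit$mand_path[m + 1, ] - fit$mand_path[m, ]))
    eta[, m + 1] <- cur
  }
  eta
}

#' @export
predict.countsig_boost <- function(object, newx,
                                   type = c("link", "response"),
                                   step = object$steps, ...) {
  type <- match.arg(type)
  newx <- as.matrix(newx)
  beta <- boost_coef(object, step)
  eta <- as.numeric(newx %*% beta) + attr(beta, "intercept")
  if (type == "response" && object$family == "logistic") plogis(eta)
  else if (type == "response" && object$family == "cox") exp(eta)
  else eta
}
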