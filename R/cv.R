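# Cross-validation tuning: the number of boosting steps or the lasso
# penalty.  Folds are seeded and stratified (by the outcome for logistic,
# by the event indicator for Cox).  The Cox out-of-fold criterion is the
# full-minus-reduced partial log-likelihood (Verweij-van Houwelingen),
# which is also what cv.glmnet's grouped Cox CV computes.

#' Seeded stratified fold assignment
#'
#' @param strata vector defining strata (0/1 outcome or event indicator).
#' @param folds number of folds.
#' @param seed integer seed.
#' @return Integer fold id per sample.
#' @export
make_folds <- function(strata, folds, seed) {
  n <- length(strata)
  if (folds < 2 || folds > n) stop_invalid("need 2 <= folds <= n")
  with_seed(seed, {
    id <- integer(n)
    counter <- 0L
    for (s in unique(strata)) {
      idx <- sample(which(strata == s))
      id[idx] <- (counter + seq_along(idx) - 1L) %% folds + 1L
      counter <- counter + length(idx)
    }
    id
  })
}

#' Cross-validated tuning of boosting steps or lasso penalty
#'
#' For boosting, fits the full path on each fold's training part and
#' scores every step by the out-of-fold log-likelihood (logistic) or the
#' full-minus-reduced partial log-likelihood (cox); the step maximizing
#' the summed criterion is chosen, ties toward the smaller model.  For
#' the lasso (cox only), delegates to \code{glmnet::cv.glmnet} with the
#' same stratified fold ids and grouped partial-likelihood criterion,
#' returning \code{lambda.min}.  Cox folds whose training part has no
#' events are redrawn (up to 10 attempts).
#'
#' @param x covariate matrix (samples x covariates).
#' @param y 0/1 vector (logistic) or \code{survival::Surv} (cox).
#' @param family \code{"logistic"} or \code{"cox"}.
#' @param method \code{"boost"} or \code{"lasso"}.
#' @param folds number of CV folds.
#' @param seed integer seed for the fold assignment.
#' @param mandatory unpenalized column indices.
#' @param steps maximum boosting steps scored.
#' @param nu,penalty boosting penalty specification (see
#'   \code{\link{boost_fit}}).
#' @return For boosting: list with \code{best} (chosen step count) and
#'   \code{criterion} (summed out-of-fold criterion per step, index 1 =
#'   step 0).  For lasso: list with \code{best} (lambda) and the
#'   \code{cv.glmnet} object as \code{cvfit}.
#' @export
cv_tune <- function(x, y, family = c("logistic", "cox"),
                    method = c("boost", "lasso"), folds = 10, seed = 1L,
                    mandatory = integer(0), steps = 100, nu = 0.1,
                    penalty = NULL) {
  family <- match.arg(family)
  method <- match.arg(method)
  x <- as.matrix(x)
  strata <- if (family == "logistic") as.numeric(y) else y[, 2]

  fold_id <- make_folds(strata, folds, seed)
  if (family == "cox") {
    for (attempt in seq_len(10)) {
      ok <- vapply(seq_len(folds), function(k)
        sum(strata[fold_id != k]) >= 1, logical(1))
      if (all(ok)) break
      warning("fold without events in its training part; redrawing folds")
      fold_id <- make_folds(strata, folds, child_seed(seed, attempt))
    }
  }

  if (method == "lasso") {
    if (family != "cox")
      stop_invalid("the lasso path is provided for the cox family only")
    pf <- rep(1, ncol(x)); pf[mandatory] <- 0
    cvfit <- glmnet::cv.glmnet(x, y, family = "cox", penalty.factor = pf,
                               standardize = FALSE, foldid = fold_id,
                               lambda.min.ratio = 0.05, grouped = TRUE)
    return(list(best = cvfit$lambda.min, cvfit = cvfit, fold_id = fold_id))
  }

  crit <- matrix(0, folds, steps + 1)
  for (k in seq_len(folds)) {
    tr <- fold_id != k
    fit <- boost_fit(x[tr, , drop = FALSE],
                     if (family == "cox") y[tr] else y[tr],
                     family = family, mandatory = mandatory,
                     steps = steps, nu = nu, penalty = penalty)
    if (family == "logistic") {
      eta_oof <- boost_eta_path(fit, x[!tr, , drop = FALSE])
      yk <- as.numeric(y)[!tr]
      crit[k, ] <- apply(eta_oof, 2, function(e) logistic_loglik(yk, e))
    } else {
      eta_full <- boost_eta_path(fit, x)
      co_full <- cox_order(y[, 1], y[, 2])
      co_tr <- cox_order(y[tr, 1], y[tr, 2])
      for (m in seq_len(steps + 1)) {
        e <- eta_full[, m]
        crit[k, m] <- cox_pll(co_full, e[co_full$ord]) -
          cox_pll(co_tr, e[tr][co_tr$ord])
      }
    }
  }
  total <- colSums(crit)
  best <- which.max(total) - 1L   # which.max takes the first (smallest) tie
  list(best = best, criterion = total, fold_id = fold_id)
}
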