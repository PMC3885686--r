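# Evaluation statistics: selection ROC-like curves with partial area up to
# ten false positives, selection-overlap accounting, censoring-weighted
# Brier prediction-error curves with the 0.632+ estimator, integrated
# prediction error (IPEC), and added value over a clinical-only model.

#' Selection curve and partial area up to ten false positives
#'
#' Walks a boosting path in step order; whenever the penalized support
#' grows, records the (false positive, true positive) counts of the
#' current support.  \eqn{TP^*(f)} is the largest TP count reached while
#' at most \eqn{f} false positives were selected; the partial area is the
#' mean of \eqn{TP^*(f)} over \eqn{f = 0, \ldots, fp\_max} and can be read
#' as the mean number of truly informative genes found within ten or
#' fewer false positives.
#'
#' @param selection_order covariate identifiers in order of first
#'   selection along the path (see \code{\link{selected_set}}), or a
#'   \code{countsig_boost} fit (ids taken from its covariate names).
#' @param truth non-empty set of truly informative identifiers.
#' @param fp_max largest false-positive count included (10).
#' @return List of class \code{selection_curve} with \code{points}
#'   (data.frame fp/tp after each support increment), \code{tp_star}
#'   (vector over fp = 0..fp_max) and \code{pauc}.
#' @export
selection_curve <- function(selection_order, truth, fp_max = 10) {
  if (length(truth) == 0) stop_invalid("truth set must be non-empty")
  if (inherits(selection_order, "countsig_boost")) {
    fit <- selection_order
    sel <- selected_set(fit)
    selection_order <- if (!is.null(fit$covariate_names))
      fit$covariate_names[sel] else sel
  }
  is_tp <- selection_order %in% truth
  tp <- cumsum(is_tp)
  fp <- cumsum(!is_tp)
  tp_star <- vapply(0:fp_max, function(f) {
    ok <- fp <= f
    if (any(ok)) max(tp[ok]) else 0L
  }, numeric(1))
  structure(list(points = data.frame(fp = fp, tp = tp),
                 tp_star = tp_star, pauc = mean(tp_star),
                 fp_max = fp_max, n_informative = length(truth)),
            class = "selection_curve")
}

#' @export
#' @method print selection_curve
print.selection_curve <- function(x, ...) {
  cat(sprintf("selection curve: pAUC(0..%d FP) = %.3f of %d informative\n",
              x$fp_max, x$pauc, x$n_informative))
  invisible(x)
}

#' Selection-overlap table across transformations
#'
#' Given, per transformation tag, a list of selected gene-id sets over
#' replicates, computes the mean (SD) set size on the diagonal, the mean
#' (SD) pairwise intersection size off the diagonal, and — when a block
#' structure is supplied — the mean (SD) size of the replicate-wise
#' intersection across all tags of a block, and across the union of two
#' blocks for block pairs.
#'
#' @param selected_sets named list: tag -> list over replicates of
#'   character vectors.
#' @param blocks optional named list of tag groups, e.g.
#'   \code{list(non_standardized = c("naive", ...), ...)}.
#' @return List with matrices \code{mean} and \code{sd} (tags x tags) and,
#'   when blocks are given, \code{block_mean} / \code{block_sd}.
#' @export
overlap_table <- function(selected_sets, blocks = NULL) {
  tags <- names(selected_sets)
  reps <- lengths(selected_sets)
  if (length(unique(reps)) != 1)
    stop_invalid("all tags need the same replicate count")
  r <- reps[1]
  pair_sizes <- function(a, b)
    vapply(seq_len(r), function(k)
      length(intersect(selected_sets[[a]][[k]], selected_sets[[b]][[k]])),
      numeric(1))
  mn <- sd <- matrix(NA_real_, length(tags), length(tags),
                     dimnames = list(tags, tags))
  for (a in seq_along(tags)) for (b in seq_len(a)) {
    sizes <- if (a == b) lengths(selected_sets[[a]])
             else pair_sizes(tags[a], tags[b])
    mn[a, b] <- mn[b, a] <- mean(sizes)
    sd[a, b] <- sd[b, a] <- stats::sd(sizes)
  }
  out <- list(mean = mn, sd = sd, n_replicates = r)
  if (!is.null(blocks)) {
    inter_all <- function(tag_group)
      vapply(seq_len(r), function(k)
        length(Reduce(intersect,
                      lapply(selected_sets[tag_group], `[[`, k))),
        numeric(1))
    bn <- names(blocks)
    bm <- bs <- matrix(NA_real_, length(bn), length(bn),
                       dimnames = list(bn, bn))
    for (a in seq_along(bn)) for (b in seq_len(a)) {
      sizes <- inter_all(unique(c(blocks[[a]], blocks[[b]])))
      bm[a, b] <- bm[b, a] <- mean(sizes)
      bs[a, b] <- bs[b, a] <- stats::sd(sizes)
    }
    out$block_mean <- bm
    out$block_sd <- bs
  }
  out
}

#' Breslow baseline cumulative hazard
#'
#' @param time,event training survival outcome.
#' @param lp training linear predictors.
#' @return Function \code{H0(t)} (step function, 0 before the first event).
#' @export
breslow_basehaz <- function(time, event, lp) {
  co <- cox_order(time, event)
  w <- exp(lp[co$ord])
  rs0 <- rev(cumsum(rev(w)))[co$first]
  et <- unique(co$time[co$evi])
  dH <- vapply(et, function(t) {
    i <- which(co$time == t & co$event == 1)
    length(i) / rs0[i[1]]
  }, numeric(1))
  H <- cumsum(dH)
  function(t) {
    i <- findInterval(t, et)
    ifelse(i == 0, 0, H[pmax(i, 1)])
  }
}

#' Predicted survival probabilities from a Cox linear predictor
#'
#' @param lp linear predictors of the subjects to predict for.
#' @param H0 baseline cumulative hazard function from
#'   \code{\link{breslow_basehaz}}.
#' @param times evaluation time grid.
#' @return Matrix \code{length(lp) x length(times)} of \eqn{S(t | x)}.
#' @export
cox_survival_prob <- function(lp, H0, times) {
  outer(exp(lp), H0(times), function(r, h) exp(-h * r))
}

# Kaplan-Meier censoring distribution fitted on training data; returns
# evaluators for G(t) (right-continuous) and G(t-) (left limit), floored.
censoring_km <- function(time, event, floor = 1e-3) {
  sf <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  tt <- sf$time; ss <- sf$surv
  G <- function(t) {
    i <- findInterval(t, tt)
    pmax(ifelse(i == 0, 1, ss[pmax(i, 1)]), floor)
  }
  Gminus <- function(t) {
    i <- findInterval(t, tt, left.open = TRUE)
    pmax(ifelse(i == 0, 1, ss[pmax(i, 1)]), floor)
  }
  list(G = G, Gminus = Gminus)
}

#' Censoring-weighted Brier curve
#'
#' Inverse-probability-of-censoring-weighted Brier score at each grid
#' time: subjects with an observed event by \eqn{t} contribute
#' \eqn{\hat S(t|x)^2 / \hat G(T^-)}, subjects still at risk contribute
#' \eqn{(1 - \hat S(t|x))^2 / \hat G(t)}, censored-before-\eqn{t}
#' subjects contribute zero.
#'
#' @param surv_prob matrix (subjects x grid) of predicted survival
#'   probabilities.
#' @param time,event the subjects' outcome.
#' @param cens censoring-distribution evaluators from the training data
#'   (internal list with \code{G}, \code{Gminus}).
#' @param times evaluation grid.
#' @return Numeric vector of Brier scores along the grid.
#' @export
brier_curve <- function(surv_prob, time, event, cens, times) {
  n <- length(time)
  vapply(seq_along(times), function(k) {
    t <- times[k]
    s <- surv_prob[, k]
    dead <- time <= t & event == 1
    alive <- time > t
    contrib <- numeric(n)
    contrib[dead] <- s[dead]^2 / cens$Gminus(time[dead])
    contrib[alive] <- (1 - s[alive])^2 / cens$G(t)
    mean(contrib)
  }, numeric(1))
}

# no-information Brier curve: every prediction paired with every outcome
noinf_curve <- function(surv_prob, time, event, cens, times) {
  vapply(seq_along(times), function(k) {
    t <- times[k]
    s <- surv_prob[, k]
    dead <- time <= t & event == 1
    alive <- time > t
    w_dead <- mean(ifelse(dead, 1 / cens$Gminus(time), 0))
    w_alive <- mean(ifelse(alive, 1 / cens$G(t), 0))
    mean(s^2) * w_dead + mean((1 - s)^2) * w_alive
  }, numeric(1))
}

#' The 0.632+ prediction-error combination
#'
#' Pointwise on a common grid: relative overfitting
#' \eqn{R = (oob - apparent) / (noinf - apparent)} clipped to [0, 1]
#' (set to 0 where \eqn{noinf \le apparent}), weight
#' \eqn{w = 0.632 / (1 - 0.368 R)}, estimate
#' \eqn{(1 - w) \cdot apparent + w \cdot \min(oob, noinf)}.
#'
#' @param apparent,oob,noinf curves on a common grid.
#' @return The 0.632+ curve.
#' @export
estimator_632plus <- function(apparent, oob, noinf) {
  R <- ifelse(noinf > apparent,
              pmin(pmax((oob - apparent) / (noinf - apparent), 0), 1), 0)
  w <- 0.632 / (1 - 0.368 * R)
  (1 - w) * apparent + w * pmin(oob, noinf)
}

#' Integrated prediction error (trapezoidal)
#'
#' @param times increasing grid.
#' @param curve prediction-error values on the grid.
#' @return Area under the curve over the grid span.
#' @export
ipec <- function(times, curve) {
  if (length(times) < 2) return(0)
  sum(diff(times) * (utils::head(curve, -1) + utils::tail(curve, -1)) / 2)
}

#' 0.632+ prediction-error curves and IPEC for one model and split
#'
#' Computes the apparent (train-on-train), out-of-sample (train-on-test)
#' and no-information Brier curves for a Cox model given by its linear
#' predictors, combines them with \code{\link{estimator_632plus}}, and
#' integrates.  The censoring distribution and the Breslow baseline are
#' estimated on the training data only.
#'
#' @param lp_train,lp_test linear predictors for training and test
#'   subjects.
#' @param time_train,event_train,time_test,event_test split outcomes.
#' @param times evaluation grid; default: training event times up to the
#'   0.95 quantile of all observed times.
#' @return List of class \code{pred_err_result} with \code{times},
#'   \code{apparent}, \code{oob}, \code{noinf}, \code{curve632plus} and
#'   \code{ipec}.
#' @export
pred_error_632plus <- function(lp_train, time_train, event_train,
                               lp_test, time_test, event_test,
                               times = NULL) {
  if (is.null(times)) {
    upper <- stats::quantile(c(time_train, time_test), 0.95, names = FALSE)
    times <- sort(unique(time_train[event_train == 1 & time_train <= upper]))
    if (length(times) < 2)
      stop_invalid("undefined curve: fewer than two training event times inside the grid span")
  }
  if (!any(time_test >= times[1]))
    stop_invalid("undefined curve: all test subjects end before the first grid point")
  cens <- censoring_km(time_train, event_train)
  H0 <- breslow_basehaz(time_train, event_train, lp_train)
  sp_train <- cox_survival_prob(lp_train, H0, times)
  sp_test <- cox_survival_prob(lp_test, H0, times)
  apparent <- brier_curve(sp_train, time_train, event_train, cens, times)
  oob <- brier_curve(sp_test, time_test, event_test, cens, times)
  noinf <- noinf_curve(sp_train, time_train, event_train, cens, times)
  curve <- estimator_632plus(apparent, oob, noinf)
  structure(list(times = times, apparent = apparent, oob = oob,
                 noinf = noinf, curve632plus = curve,
                 ipec = ipec(times, curve)),
            class = "pred_err_result")
}

#' @export
#' @method print pred_err_result
print.pred_err_result <- function(x, ...) {
  cat(sprintf("0.632+ prediction error: %d grid times in [%.3g, %.3g], IPEC = %.4g\n",
              length(x$times), min(x$times), max(x$times), x$ipec))
  invisible(x)
}

#' Added value of a combined model over the clinical model
#'
#' \eqn{\Delta_k = 1 - IPEC_{combined,k} / IPEC_{clinical,k}} per split:
#' zero when the combined model does not improve on the clinical one,
#' negative when it is worse, and (0, 1] when it eliminates part of the
#' clinical model's prediction error.
#'
#' @param ipec_clinical,ipec_combined per-split IPEC vectors.
#' @return List of class \code{added_value} with \code{delta} (per split)
#'   and \code{summary} (mean and quartiles).
#' @export
added_value <- function(ipec_clinical, ipec_combined) {
  if (any(ipec_clinical <= 0))
    stop_invalid("clinical IPEC must be positive")
  delta <- 1 - ipec_combined / ipec_clinical
  structure(list(delta = delta,
                 summary = c(mean = mean(delta),
                             stats::quantile(delta, c(0.25, 0.5, 0.75)))),
            class = "added_value")
}

#' @export
#' @method print added_value
print.added_value <- function(x, ...) {
  cat(sprintf("added value over %d splits: mean %.4f, median %.4f\n",
              length(x$delta), x$summary["mean"], x$summary["50%"]))
  invisible(x)
}
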