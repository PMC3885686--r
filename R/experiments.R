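# Study drivers: the identification (simulation) study comparing the
# transformations by selection performance of boosting on a simulated
# binary outcome, and the prediction (resampling) study comparing them by
# 0.632+ prediction error, IPEC and added value on survival data.

#' Seeded train/test resampling plan
#'
#' Draws, for each split, a training index set without replacement;
#' the remaining samples form the test set.
#'
#' @param n number of samples.
#' @param n_splits number of splits (50 in the full-scale study).
#' @param train_fraction fraction of samples drawn for training (default
#'   0.632, matching the subsampling rationale of the 0.632+ estimator).
#' @param seed integer seed.
#' @return List of integer training index vectors.
#' @export
resampling_plan <- function(n, n_splits, train_fraction = 0.632, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_invalid("train_fraction must lie in (0, 1)")
  n_train <- max(2L, round(train_fraction * n))
  with_seed(seed, lapply(seq_len(n_splits), function(k)
    sort(sample.int(n, n_train))))
}

#' Configuration for the identification study
#'
#' @param n_genes,n_samples generator dimensions.
#' @param n_informative number of informative genes (10 or 20).
#' @param snr_target target signal-to-noise ratio (2.5); 0 gives the
#'   pure-noise scenario with all effects zero.
#' @param effect_scale \code{"linear"} or \code{"logarithmic"} true
#'   effects.
#' @param tags transformation tags to compare.
#' @param replicates informative-set redraws (50 at full scale).
#' @param steps boosting steps per fit (500).
#' @param nu shrinkage factor (0.1).
#' @param fp_max partial-area limit (10 false positives).
#' @param seed master seed.
#' @param ... generator overrides passed to \code{\link{generate_counts}}.
#' @return List of class \code{sim_study_config}.
#' @export
sim_study_config <- function(n_genes = 2000, n_samples = 200,
                             n_informative = 10, snr_target = 2.5,
                             effect_scale = c("linear", "logarithmic"),
                             tags = transform_tags(), replicates = 10,
                             steps = 500, nu = 0.1, fp_max = 10,
                             seed = 1L, ...) {
  effect_scale <- match.arg(effect_scale)
  structure(c(as.list(environment()), list(generator = list(...))),
            class = "sim_study_config")
}

#' Run the identification (simulation) study
#'
#' Generates one synthetic count matrix, preprocesses it (low-count
#' filter, median-of-ratios normalization, truncation), fits every
#' transformation once on the full data, and then, per replicate, redraws
#' the informative gene set (one gene per gene-length bin), calibrates the
#' common effect size to the target SNR, simulates the binary outcome, and
#' fits componentwise boosting to the full step count on every transformed
#' matrix, scoring each path by the partial selection-curve area up to ten
#' false positives.
#'
#' @param config a \code{\link{sim_study_config}}.
#' @return List of class \code{countsig_sim_study} with \code{pauc}
#'   (data.frame replicate x tag), \code{summary} (per-tag mean/sd),
#'   and the preprocessed dimensions.
#' @export
run_simulation_study <- function(config) {
  stopifnot(inherits(config, "sim_study_config"))
  empty <- data.frame(replicate = integer(0), tag = character(0),
                      pauc = numeric(0), stringsAsFactors = FALSE)
  if (config$replicates < 1)
    return(structure(list(pauc = empty,
                          summary = data.frame(tag = character(0),
                                               mean = numeric(0),
                                               sd = numeric(0)),
                          config = config),
                     class = "countsig_sim_study"))
  counts <- do.call(generate_counts,
                    c(list(n_genes = config$n_genes,
                           n_samples = config$n_samples,
                           seed = child_seed(config$seed, 0)),
                      config$generator))
  prep <- preprocess_counts(counts)
  tx <- lapply(config$tags, function(tag)
    t(transform_fit(prep$x, tag,
                    seed = child_seed(config$seed, 17))$train))
  names(tx) <- config$tags

  rows <- vector("list", config$replicates * length(config$tags))
  ri <- 0L
  for (i in seq_len(config$replicates)) {
    inf <- choose_informative_genes(prep$genes, config$n_informative,
                                    child_seed(config$seed, i))
    x_eff <- prep$x[inf, , drop = FALSE]
    if (config$effect_scale == "logarithmic") x_eff <- log(x_eff + 1)
    # snr_target = 0 is the pure-noise scenario: no calibration, no effects
    b <- if (config$snr_target <= 0) 0
         else calibrate_effects(x_eff, config$snr_target)
    design <- simulation_design(inf, rep(as.numeric(b), length(inf)),
                                config$effect_scale, config$snr_target)
    out <- simulate_binary_outcome(prep$x, design,
                                   child_seed(config$seed, 1000 + i))
    for (tag in config$tags) {
      fit <- boost_fit(tx[[tag]], out$y, family = "logistic",
                       steps = config$steps, nu = config$nu)
      sc <- selection_curve(fit, inf, config$fp_max)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(replicate = i, tag = tag, pauc = sc$pauc,
                               stringsAsFactors = FALSE)
    }
  }
  pauc <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(pauc$pauc, pauc$tag)[config$tags],
                                function(v) data.frame(mean = mean(v),
                                                       sd = stats::sd(v))))
  summ <- data.frame(tag = config$tags, summ, row.names = NULL,
                     stringsAsFactors = FALSE)
  structure(list(pauc = pauc, summary = summ,
                 n_genes_kept = nrow(prep$x), config = config),
            class = "countsig_sim_study")
}

#' @export
#' @method print countsig_sim_study
print.countsig_sim_study <- function(x, ...) {
  cat(sprintf("identification study: %d replicates, %s effects\n",
              x$config$replicates, x$config$effect_scale))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Configuration for the prediction (resampling) study
#'
#' @param tags transformation tags to compare.
#' @param methods model builders: \code{"boost"} and/or \code{"lasso"}.
#' @param n_splits train/test splits (50 at full scale).
#' @param train_fraction training fraction per split.
#' @param folds CV folds for tuning.
#' @param max_steps boosting step ceiling for CV-stopped fits.
#' @param nu shrinkage factor.
#' @param fixed_steps optional fixed-step boosting run (200 in the
#'   selected-gene characterization) collecting selected sets; NULL to
#'   skip.
#' @param seed master seed.
#' @return List of class \code{resample_study_config}.
#' @export
resample_study_config <- function(tags = transform_tags(),
                                  methods = c("boost", "lasso"),
                                  n_splits = 20, train_fraction = 0.632,
                                  folds = 10, max_steps = 100, nu = 0.1,
                                  fixed_steps = NULL, seed = 1L) {
  structure(as.list(environment()), class = "resample_study_config")
}

#' Run the prediction (resampling) study
#'
#' For each split of the samples into training and test sets: fits each
#' transformation's parameters on the training samples only, fits a
#' clinical-only Cox model, fits combined (clinical + gene) models by
#' CV-tuned componentwise boosting and/or the lasso with the clinical
#' block mandatory and unpenalized, and evaluates 0.632+ Brier curves,
#' IPEC and the added value over the clinical model on that split.
#' Optionally also runs a fixed-step boosting fit per split collecting
#' the selected gene sets for overlap accounting.
#'
#' @param x normalized count matrix (genes x samples, rownames = ids).
#' @param clinical numeric matrix of clinical covariates (samples x q).
#' @param time,event survival outcome.
#' @param config a \code{\link{resample_study_config}}.
#' @return List of class \code{countsig_resample_study} with
#'   \code{results} (one row per split x tag x method), \code{added_value}
#'   (per tag x method), \code{selected_sets} (fixed-step run, per tag),
#'   \code{selected_variance} (median variance of selected genes per
#'   split x tag) and \code{fits} (per-split coefficient records for
#'   audit).
#' @export
run_resampling_study <- function(x, clinical, time, event, config) {
  stopifnot(inherits(config, "resample_study_config"))
  x <- as.matrix(x)
  clinical <- as.matrix(clinical)
  n <- ncol(x)
  q <- ncol(clinical)
  plan <- resampling_plan(n, config$n_splits, config$train_fraction,
                          child_seed(config$seed, 1))
  rows <- list()
  sel_sets <- stats::setNames(
    lapply(config$tags, function(t) vector("list", config$n_splits)),
    config$tags)
  sel_var <- list()
  fits <- vector("list", config$n_splits)

  for (k in seq_len(config$n_splits)) {
    tr <- plan[[k]]
    te <- setdiff(seq_len(n), tr)
    y_tr <- survival::Surv(time[tr], event[tr])
    cl_tr <- clinical[tr, , drop = FALSE]
    cl_te <- clinical[te, , drop = FALSE]

    cfit <- survival::coxph(y_tr ~ cl_tr)
    cb <- stats::coef(cfit)
    cb[is.na(cb)] <- 0
    lp_cl_tr <- as.numeric(cl_tr %*% cb)
    lp_cl_te <- as.numeric(cl_te %*% cb)
    pe_cl <- pred_error_632plus(lp_cl_tr, time[tr], event[tr],
                                lp_cl_te, time[te], event[te])
    fits[[k]] <- list()

    for (tag in config$tags) {
      tf <- transform_fit(x[, tr, drop = FALSE], tag,
                          seed = child_seed(config$seed, 100 + k))
      z_tr <- cbind(cl_tr, t(tf$train))
      z_te <- cbind(cl_te, t(transform_apply(tf, x[, te, drop = FALSE])))
      mand <- seq_len(q)

      if ("boost" %in% config$methods) {
        cv <- cv_tune(z_tr, y_tr, family = "cox", method = "boost",
                      folds = config$folds,
                      seed = child_seed(config$seed, 200 + k),
                      mandatory = mand, steps = config$max_steps,
                      nu = config$nu)
        bfit <- boost_fit(z_tr, y_tr, family = "cox", mandatory = mand,
                          steps = cv$best, nu = config$nu)
        pe <- pred_error_632plus(
          predict(bfit, z_tr), time[tr], event[tr],
          predict(bfit, z_te), time[te], event[te])
        sel <- setdiff(selected_set(bfit), mand)
        rows[[length(rows) + 1]] <- data.frame(
          split = k, tag = tag, method = "boost", tuning = cv$best,
          n_selected = length(sel), ipec_clinical = pe_cl$ipec,
          ipec_combined = pe$ipec,
          delta = 1 - pe$ipec / pe_cl$ipec, stringsAsFactors = FALSE)
        fits[[k]][[paste0(tag, ".boost")]] <-
          list(beta = bfit$beta, steps = cv$best)
      }
      if ("lasso" %in% config$methods) {
        cv <- cv_tune(z_tr, y_tr, family = "cox", method = "lasso",
                      folds = config$folds,
                      seed = child_seed(config$seed, 300 + k),
                      mandatory = mand)
        lfit <- lasso_cox_fit(z_tr, time[tr], event[tr], mandatory = mand)
        beta <- lasso_coef(lfit, cv$best)
        pe <- pred_error_632plus(
          as.numeric(z_tr %*% beta), time[tr], event[tr],
          as.numeric(z_te %*% beta), time[te], event[te])
        sel <- setdiff(which(beta != 0), mand)
        rows[[length(rows) + 1]] <- data.frame(
          split = k, tag = tag, method = "lasso", tuning = cv$best,
          n_selected = length(sel), ipec_clinical = pe_cl$ipec,
          ipec_combined = pe$ipec,
          delta = 1 - pe$ipec / pe_cl$ipec, stringsAsFactors = FALSE)
        fits[[k]][[paste0(tag, ".lasso")]] <-
          list(beta = beta, lambda = cv$best)
      }
      if (!is.null(config$fixed_steps)) {
        ffit <- boost_fit(z_tr, y_tr, family = "cox", mandatory = mand,
                          steps = config$fixed_steps, nu = config$nu)
        sel <- setdiff(selected_set(ffit), mand)
        ids <- rownames(x)[sel - q]
        sel_sets[[tag]][[k]] <- ids
        sel_var[[length(sel_var) + 1]] <- data.frame(
          split = k, tag = tag, n_selected = length(sel),
          median_variance = if (length(sel) > 0)
            stats::median(apply(z_tr[, sel, drop = FALSE], 2, stats::var))
          else NA_real_, stringsAsFactors = FALSE)
      }
    }
  }

  results <- do.call(rbind, rows)
  av <- NULL
  if (length(rows) > 0) {
    av <- do.call(rbind, lapply(
      split(results, list(results$tag, results$method), drop = TRUE),
      function(d) data.frame(tag = d$tag[1], method = d$method[1],
                             mean_delta = mean(d$delta),
                             sd_delta = stats::sd(d$delta),
                             stringsAsFactors = FALSE)))
    row.names(av) <- NULL
  }
  structure(list(results = results, added_value = av,
                 selected_sets = if (is.null(config$fixed_steps)) NULL
                                 else sel_sets,
                 selected_variance = if (length(sel_var) > 0)
                   do.call(rbind, sel_var) else NULL,
                 fits = fits, plan = plan, config = config),
            class = "countsig_resample_study")
}

#' @export
#' @method print countsig_resample_study
print.countsig_resample_study <- function(x, ...) {
  cat(sprintf("prediction study: %d splits\n", x$config$n_splits))
  if (!is.null(x$added_value)) print(x$added_value, digits = 3)
  invisible(x)
}

#' Write a study's tables and manifest to a directory
#'
#' Emits the per-replicate partial-area table (box-plot data) or the
#' per-split prediction results, summary tables, the overlap table when
#' selected sets were collected, and a JSON manifest of seeds, parameters
#' and numerical conventions.
#'
#' @param study a \code{countsig_sim_study} or
#'   \code{countsig_resample_study} (or a list of them).
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
make_report <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wt <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  studies <- if (inherits(study, c("countsig_sim_study",
                                   "countsig_resample_study")))
    list(study) else study
  for (i in seq_along(studies)) {
    s <- studies[[i]]
    pre <- if (length(studies) > 1) sprintf("study%02d_", i) else ""
    if (inherits(s, "countsig_sim_study")) {
      wt(s$pauc, paste0(pre, "pauc_by_replicate.tsv"))
      wt(s$summary, paste0(pre, "pauc_summary.tsv"))
    } else if (inherits(s, "countsig_resample_study")) {
      if (!is.null(s$results)) wt(s$results, paste0(pre, "prediction_results.tsv"))
      if (!is.null(s$added_value)) wt(s$added_value, paste0(pre, "added_value.tsv"))
      if (!is.null(s$selected_variance))
        wt(s$selected_variance, paste0(pre, "selected_gene_variance.tsv"))
      if (!is.null(s$selected_sets)) {
        ot <- overlap_table(s$selected_sets)
        wt(data.frame(tag = rownames(ot$mean), round(ot$mean, 2),
                      check.names = FALSE),
           paste0(pre, "overlap_mean.tsv"))
        wt(data.frame(tag = rownames(ot$sd), round(ot$sd, 2),
                      check.names = FALSE),
           paste0(pre, "overlap_sd.tsv"))
      }
    }
    cfg <- s$config
    cfg$generator <- NULL
    write_manifest(cfg[!vapply(cfg, is.function, logical(1))],
                   file.path(dir, paste0(pre, "manifest.json")))
    paths <- c(paths, file.path(dir, paste0(pre, "manifest.json")))
  }
  invisible(paths)
}
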