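# The ten covariate transformations, individually and behind a registry
# with train/test parameter discipline: every data-dependent parameter
# (per-gene means and SDs, Box-Cox lambdas, the VST dispersion) is fitted
# on training samples only and reused unchanged on held-out samples.

#' Transformation registry tags
#'
#' @return Character vector of the ten supported transformation tags.
#' @export
transform_tags <- function() {
  c("naive", "log", "vst", "boxcox",
    "standardize", "standardize_log", "standardize_vst",
    "standardize_boxcox", "ranks", "blom")
}

#' Shifted log transformation
#'
#' \code{log(x + 1)} (natural log); the shift by one keeps zero counts
#' finite while leaving the order of values within a gene unchanged.
#'
#' @param x non-negative numeric matrix (genes x samples).
#' @return Transformed matrix of the same shape.
#' @export
t_log <- function(x) {
  if (any(x < 0)) stop_invalid("log transform requires non-negative input")
  log(x + 1)
}

#' Fit the variance-stabilizing transformation
#'
#' Models the per-gene variance as \eqn{v(\mu) = \mu + \alpha \mu^2}
#' (the negative-binomial form), estimating the common dispersion
#' \eqn{\alpha} by least squares of \eqn{s_g^2 - m_g} on \eqn{m_g^2}
#' across genes (through the origin, clamped at zero).  The transform is
#' the closed-form integral of \eqn{1/\sqrt{v(\mu)}}:
#' \eqn{w(x) = (2/\sqrt{\alpha}) \, asinh(\sqrt{\alpha x})}, degrading to
#' \eqn{2\sqrt{x}} (the Poisson case) as \eqn{\alpha \to 0}.
#'
#' @param x non-negative matrix of normalized counts (>= 20 genes).
#' @return List with the fitted \code{alpha}.
#' @export
fit_vst <- function(x) {
  if (nrow(x) < 20)
    stop_invalid("VST needs at least 20 genes to estimate the mean-variance trend")
  m <- rowMeans(x)
  s2 <- apply(x, 1, stats::var)
  denom <- sum(m^4)
  if (!is.finite(denom) || denom <= 0)
    stop_invalid("VST failure: degenerate mean-variance trend")
  alpha <- max(0, sum(m^2 * (s2 - m)) / denom)
  list(alpha = alpha)
}

#' Apply the variance-stabilizing transformation
#'
#' @param x non-negative matrix.
#' @param params list with \code{alpha}, from \code{\link{fit_vst}}.
#' @return Transformed matrix.
#' @export
apply_vst <- function(x, params) {
  a <- params$alpha
  if (a <= 0) 2 * sqrt(x) else (2 / sqrt(a)) * asinh(sqrt(a * x))
}

boxcox_grid <- function() seq(-2, 2, by = 0.25)

boxcox1 <- function(x, lambda) {
  if (lambda == 0) log(x + 1) else ((x + 1)^lambda - 1) / lambda
}

#' Select a Box-Cox exponent for one gene
#'
#' Candidates \eqn{((x+1)^\lambda - 1)/\lambda} (with \eqn{log(x+1)} at
#' \eqn{\lambda = 0}) over the grid \eqn{-2, -1.75, \ldots, 2}; the
#' selected \eqn{\lambda} maximizes the Pearson correlation between the
#' sorted transformed values and standard-normal quantiles at Blom
#' plotting positions.  Candidates whose correlation comes within
#' \code{tie_tol} of the maximum are treated as tied — on near-affine
#' data (mean far above SD) the whole power family fits equally well to
#' within sampling noise — and ties are broken toward \eqn{\lambda}
#' closest to 1 (the identity), then toward 0 (the log).
#'
#' @param x_g one gene's non-negative values.
#' @param tie_tol correlation tolerance within which candidates count as
#'   tied.
#' @return The selected lambda; a constant gene returns 1 with attribute
#'   \code{"constant" = TRUE}.
#' @export
fit_boxcox_lambda <- function(x_g, tie_tol = 1e-3) {
  if (any(x_g < 0)) stop_invalid("Box-Cox requires non-negative input")
  if (length(unique(x_g)) < 2) {
    warning("constant gene: Box-Cox lambda set to 1")
    return(structure(1, constant = TRUE))
  }
  n <- length(x_g)
  q <- stats::qnorm((seq_len(n) - 0.375) / (n + 0.25))
  grid <- boxcox_grid()
  cors <- vapply(grid, function(l) {
    y <- sort(boxcox1(x_g, l))
    if (stats::sd(y) == 0) return(-Inf)
    stats::cor(y, q)
  }, numeric(1))
  best <- which(cors >= max(cors) - tie_tol)
  best <- best[order(abs(grid[best] - 1), abs(grid[best]))]
  grid[best[1]]
}

#' Apply per-gene Box-Cox transformations
#'
#' @param x non-negative matrix (genes x samples).
#' @param lambdas per-gene exponent vector (recycled).
#' @return Transformed matrix.
#' @export
apply_boxcox <- function(x, lambdas) {
  lambdas <- rep_len(lambdas, nrow(x))
  out <- x
  for (l in unique(lambdas)) {
    rows <- lambdas == l
    out[rows, ] <- boxcox1(x[rows, , drop = FALSE], l)
  }
  out
}

#' Gene-wise standardization
#'
#' Centers and scales each gene to empirical mean zero and variance one
#' (SD with denominator \eqn{n - 1}).
#'
#' @param x numeric matrix (genes x samples).
#' @return Standardized matrix; fitted means and SDs in attributes
#'   \code{"center"} / \code{"scale"}.
#' @export
t_standardize <- function(x) {
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  bad <- sdv <= 0
  if (any(bad))
    stop_invalid("constant gene(s) cannot be standardized: %s",
                 paste(utils::head(rownames(x)[bad], 5), collapse = ", "))
  out <- (x - mu) / sdv
  attr(out, "center") <- mu
  attr(out, "scale") <- sdv
  out
}

tie_noise_matrix <- function(x, tie_noise_sd, seed) {
  has_tie <- apply(x, 1, anyDuplicated) > 0
  if (!any(has_tie)) return(x)
  sdv <- if (is.null(tie_noise_sd)) {
    iqr <- apply(x[has_tie, , drop = FALSE], 1, stats::IQR)
    1e-4 * (iqr + 1)
  } else rep_len(tie_noise_sd, sum(has_tie))
  noise <- with_seed(seed, matrix(stats::rnorm(sum(has_tie) * ncol(x)),
                                  nrow = sum(has_tie)))
  x[has_tie, ] <- x[has_tie, , drop = FALSE] + noise * sdv
  x
}

#' Rank transformation
#'
#' Replaces each gene's values by their within-gene ranks, after adding a
#' small seeded Gaussian noise (SD \code{1e-4 * (gene IQR + 1)} by
#' default) to genes containing ties, so every gene's transformed values
#' are exactly the multiset \eqn{\{1, \ldots, n\}}.
#'
#' @param x numeric matrix (genes x samples).
#' @param tie_noise_sd noise SD; NULL for the IQR-based default.
#' @param seed seed for the tie-breaking noise.
#' @return Matrix of ranks.
#' @export
t_ranks <- function(x, tie_noise_sd = NULL, seed = 1L) {
  x <- tie_noise_matrix(x, tie_noise_sd, seed)
  t(apply(x, 1, rank, ties.method = "first"))
}

#' Blom transformation (rank-based normal scores)
#'
#' Maps each gene's ranks to standard-normal quantiles,
#' \eqn{\Phi^{-1}((r - c) / (n - 2c + 1))} with the Blom constant
#' \eqn{c = 3/8}; every gene gets the identical, normal-shaped multiset
#' of values and therefore identical means and variances.
#'
#' @inheritParams t_ranks
#' @param c plotting-position constant (3/8).
#' @return Matrix of normal scores.
#' @export
t_blom <- function(x, tie_noise_sd = NULL, seed = 1L, c = 3 / 8) {
  r <- t_ranks(x, tie_noise_sd, seed)
  n <- ncol(x)
  stats::qnorm((r - c) / (n - 2 * c + 1))
}

# midrank of each value of `new` against the training values `train`
midrank_against <- function(new, train) {
  ord <- sort(train)
  lt <- findInterval(new, ord, left.open = TRUE)        # train < v
  le <- findInterval(new, ord)                          # train <= v
  lt + (le - lt) / 2 + 0.5
}

#' Fit a transformation on training data
#'
#' Estimates everything the tag needs (per-gene means/SDs, Box-Cox
#' lambdas, the VST dispersion, the rank reference sample) on the given
#' matrix, so held-out samples can later be mapped through
#' \code{\link{transform_apply}} without touching the fit.
#'
#' @param x training matrix of normalized counts (genes x samples,
#'   rownames = gene ids).
#' @param tag one of \code{\link{transform_tags}}.
#' @param tie_noise_sd,seed tie handling for the rank-based tags.
#' @return An object of class \code{countsig_transform} carrying the tag,
#'   fitted parameters, and the transformed training matrix
#'   (\code{$train}).
#' @export
transform_fit <- function(x, tag, tie_noise_sd = NULL, seed = 1L) {
  tag <- match.arg(tag, transform_tags())
  x <- as.matrix(x)
  fit <- list(tag = tag, n_train = ncol(x))
  tx <- switch(tag,
    naive = x,
    log = t_log(x),
    vst = {
      fit$vst <- fit_vst(x)
      apply_vst(x, fit$vst)
    },
    boxcox = {
      fit$lambdas <- apply(x, 1, fit_boxcox_lambda)
      apply_boxcox(x, fit$lambdas)
    },
    standardize = x,
    standardize_log = t_log(x),
    standardize_vst = {
      fit$vst <- fit_vst(x)
      apply_vst(x, fit$vst)
    },
    standardize_boxcox = {
      fit$lambdas <- apply(x, 1, fit_boxcox_lambda)
      apply_boxcox(x, fit$lambdas)
    },
    ranks = ,
    blom = tie_noise_matrix(x, tie_noise_sd, seed))

  if (startsWith(tag, "standardize")) {
    tx <- t_standardize(tx)
    fit$center <- attr(tx, "center")
    fit$scale <- attr(tx, "scale")
    attr(tx, "center") <- attr(tx, "scale") <- NULL
  }
  if (tag %in% c("ranks", "blom")) {
    fit$reference <- tx              # noise-broken training values
    r <- t(apply(tx, 1, rank, ties.method = "first"))
    tx <- if (tag == "ranks") r
          else stats::qnorm((r - 0.375) / (ncol(x) - 0.75 + 1))
  }
  fit$train <- tx
  class(fit) <- "countsig_transform"
  fit
}

#' Apply a fitted transformation to new samples
#'
#' Maps a matrix of held-out samples through the parameters fitted by
#' \code{\link{transform_fit}}.  Rank-based tags place each new value at
#' its midrank among the training values, keeping new covariates on the
#' training rank scale.
#'
#' @param object a \code{countsig_transform}.
#' @param newx matrix with the same genes (rows) as the training matrix.
#' @return Transformed matrix.
#' @export
transform_apply <- function(object, newx) {
  stopifnot(inherits(object, "countsig_transform"))
  newx <- as.matrix(newx)
  tag <- object$tag
  tx <- switch(tag,
    naive = ,
    standardize = newx,
    log = ,
    standardize_log = t_log(newx),
    vst = ,
    standardize_vst = apply_vst(newx, object$vst),
    boxcox = ,
    standardize_boxcox = apply_boxcox(newx, object$lambdas),
    ranks = ,
    blom = {
      r <- newx
      for (g in seq_len(nrow(newx)))
        r[g, ] <- midrank_against(newx[g, ], object$reference[g, ])
      if (tag == "blom")
        r <- stats::qnorm((r - 0.375) / (object$n_train - 0.75 + 1))
      r
    })
  if (startsWith(tag, "standardize"))
    tx <- (tx - object$center) / object$scale
  tx
}

#' One-shot transformation dispatch
#'
#' Fits (or reuses) a transformation and returns the transformed matrix.
#'
#' @param x matrix to transform.
#' @param tag one of \code{\link{transform_tags}}.
#' @param fit optional \code{countsig_transform} fitted on training data;
#'   when supplied, \code{x} is treated as held-out data.
#' @param ... passed to \code{\link{transform_fit}}.
#' @return The transformed matrix.
#' @export
apply_transform <- function(x, tag, fit = NULL, ...) {
  if (is.null(fit)) transform_fit(x, tag, ...)$train
  else transform_apply(fit, x)
}

#' Per-gene moment diagnostics before/after transformation
#'
#' @param before,after matrices of the same shape (genes x samples).
#' @return data.frame with per-gene mean, variance and skewness of both
#'   matrices.
#' @export
transform_stats <- function(before, after) {
  skew <- function(m) {
    mu <- rowMeans(m)
    s <- apply(m, 1, stats::sd)
    rowMeans((m - mu)^3) / pmax(s, .Machine$double.eps)^3
  }
  data.frame(gene_id = rownames(before),
             mean_before = rowMeans(before),
             var_before = apply(before, 1, stats::var),
             skew_before = skew(before),
             mean_after = rowMeans(after),
             var_after = apply(after, 1, stats::var),
             skew_after = skew(after),
             stringsAsFactors = FALSE)
}
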