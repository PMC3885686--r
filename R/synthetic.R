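#' Construct a count matrix object
#'
#' Bundles a genes-by-samples matrix of non-negative integer counts with
#' per-gene metadata (id, length in bp, expected normalized count,
#' negative-binomial dispersion).
#'
#' @param counts integer matrix, genes in rows, samples in columns.
#' @param genes data.frame with columns \code{gene_id}, \code{length_bp},
#'   \code{base_mean}, \code{dispersion}.
#' @param sample_ids character vector of sample names.
#' @return An object of class \code{count_matrix}: a list with elements
#'   \code{counts} (matrix with dimnames) and \code{genes}.
#' @export
count_matrix <- function(counts, genes, sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop_invalid("count matrix must have at least one gene and one sample")
  if (any(counts < 0) || any(counts != round(counts)))
    stop_invalid("counts must be non-negative integers")
  if (anyDuplicated(genes$gene_id))
    stop_invalid("gene ids must be unique")
  if (nrow(genes) != nrow(counts))
    stop_invalid("gene metadata rows (%d) do not match count rows (%d)",
                 nrow(genes), nrow(counts))
  if (is.null(sample_ids))
    sample_ids <- sprintf("sample_%03d", seq_len(ncol(counts)))
  if (any(genes$length_bp < 1) || any(genes$base_mean <= 0) ||
      any(genes$dispersion < 0))
    stop_invalid("invalid gene metadata: need length_bp >= 1, base_mean > 0, dispersion >= 0")
  dimnames(counts) <- list(genes$gene_id, sample_ids)
  structure(list(counts = counts, genes = genes), class = "count_matrix")
}

#' @export
#' @method print count_matrix
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  total counts: %.3g; zero fraction: %.2f\n",
              sum(x$counts), mean(x$counts == 0)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Generate a synthetic RNA-Seq count matrix
#'
#' Draws negative-binomial counts whose variance follows
#' \eqn{v = \mu + \alpha \mu^2}, with heavy-tailed (log-normal) per-gene
#' base means, gene-gene correlation in blocks via a Gaussian copula,
#' per-sample library-size factors, and a small fraction of entries
#' multiplied by a large factor to mimic the extreme values seen in real
#' count data.
#'
#' @param n_genes,n_samples matrix dimensions (both at least 2).
#' @param seed integer seed; the same seed reproduces the matrix exactly.
#' @param base_mean optional vector (recycled) of expected normalized
#'   counts; default drawn from log-normal(meanlog = 3, sdlog = 1.5).
#' @param dispersion optional vector (recycled) of NB dispersions
#'   \eqn{\alpha}; default drawn from log-normal(log 0.2, 0.7).
#' @param correlation_block_size genes per correlated block (Gaussian
#'   copula with common within-block latent correlation).
#' @param block_rho latent within-block correlation in [0, 1).
#' @param extreme_value_rate fraction of entries (in [0, 0.05]) multiplied
#'   by a factor drawn uniformly from [10, 50].
#' @param size_factor_sdlog sdlog of the log-normal per-sample library-size
#'   factors; 0 gives equal factors.
#' @param length_meanlog,length_sdlog log-normal parameters for gene
#'   lengths (bp).
#' @return A \code{\link{count_matrix}}; the true per-sample size factors
#'   are attached as attribute \code{"size_factors"}.
#' @export
generate_counts <- function(n_genes, n_samples, seed,
                            base_mean = NULL, dispersion = NULL,
                            correlation_block_size = 50, block_rho = 0.5,
                            extreme_value_rate = 0.001,
                            size_factor_sdlog = 0.25,
                            length_meanlog = log(1500), length_sdlog = 0.7) {
  if (n_genes < 2 || n_samples < 2)
    stop_invalid("need n_genes >= 2 and n_samples >= 2")
  if (extreme_value_rate < 0 || extreme_value_rate > 0.05)
    stop_invalid("extreme_value_rate must lie in [0, 0.05]")
  with_seed(seed, {
    mu <- if (is.null(base_mean)) exp(rnorm(n_genes, 3, 1.5))
          else rep_len(base_mean, n_genes)
    alpha <- if (is.null(dispersion)) exp(rnorm(n_genes, log(0.2), 0.7))
             else rep_len(dispersion, n_genes)
    len <- pmax(100L, as.integer(round(exp(rnorm(n_genes, length_meanlog,
                                                 length_sdlog)))))
    sf <- if (size_factor_sdlog > 0) exp(rnorm(n_samples, 0, size_factor_sdlog))
          else rep(1, n_samples)
    sf <- sf / exp(mean(log(sf)))

    # latent Gaussian copula: shared block factor + idiosyncratic noise
    block <- rep(seq_len(ceiling(n_genes / correlation_block_size)),
                 each = correlation_block_size)[seq_len(n_genes)]
    z_block <- matrix(rnorm(max(block) * n_samples), max(block), n_samples)
    z <- sqrt(block_rho) * z_block[block, , drop = FALSE] +
      sqrt(1 - block_rho) * matrix(rnorm(n_genes * n_samples), n_genes)
    u <- pnorm(z)
    u <- pmin(pmax(u, 1e-12), 1 - 1e-12)

    mu_mat <- outer(mu, sf)
    counts <- matrix(0, n_genes, n_samples)
    pois <- alpha <= 0
    if (any(pois))
      counts[pois, ] <- qpois(u[pois, , drop = FALSE],
                              lambda = mu_mat[pois, , drop = FALSE])
    if (any(!pois))
      counts[!pois, ] <- qnbinom(u[!pois, , drop = FALSE],
                                 size = 1 / alpha[!pois],
                                 mu = mu_mat[!pois, , drop = FALSE])

    if (extreme_value_rate > 0) {
      n_ext <- rbinom(1, length(counts), extreme_value_rate)
      if (n_ext > 0) {
        idx <- sample.int(length(counts), n_ext)
        counts[idx] <- round(counts[idx] * runif(n_ext, 10, 50))
      }
    }

    genes <- data.frame(
      gene_id = sprintf("g%05d", seq_len(n_genes)),
      length_bp = len, base_mean = mu, dispersion = alpha,
      stringsAsFactors = FALSE)
    out <- count_matrix(counts, genes,
                        sprintf("s%04d", seq_len(n_samples)))
    attr(out, "size_factors") <- sf
    out
  })
}

#' Pick informative genes, one per gene-length bin
#'
#' Orders genes by length, splits them into \code{n_informative} contiguous
#' near-equal bins (any remainder spread over the first bins), and samples
#' one gene uniformly from each bin, so that informative genes cover the
#' whole range of gene lengths.
#'
#' @param genes data.frame with columns \code{gene_id} and \code{length_bp}.
#' @param n_informative number of informative genes (10 or 20 in the
#'   studies shipped here).
#' @param seed integer seed.
#' @return Character vector of \code{n_informative} gene ids.
#' @export
choose_informative_genes <- function(genes, n_informative, seed) {
  p <- nrow(genes)
  if (n_informative < 1 || n_informative > p)
    stop_invalid("need 1 <= n_informative (%d) <= n_genes (%d)",
                 n_informative, p)
  ord <- order(genes$length_bp, seq_len(p))  # stable in input order
  sizes <- rep(p %/% n_informative, n_informative)
  rem <- p %% n_informative
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  stops <- cumsum(sizes)
  starts <- c(1L, head(stops, -1L) + 1L)
  with_seed(seed, {
    picks <- vapply(seq_len(n_informative), function(b) {
      bin <- ord[starts[b]:stops[b]]
      bin[sample.int(length(bin), 1L)]
    }, integer(1))
    genes$gene_id[picks]
  })
}

# latent-scale SNR: linear-predictor variance over the logistic error
# variance pi^2/3 (the standard definition when simulating binary outcomes
# from a latent logistic model)
snr_latent <- function(b, x_sum) {
  eta <- b * (x_sum - mean(x_sum))
  stats::var(eta) / (pi^2 / 3)
}

# conditional-variance SNR: linear-predictor variance over the mean
# Bernoulli conditional variance at the implied probabilities
snr_bernoulli <- function(b, x_sum) {
  eta <- b * (x_sum - mean(x_sum))
  p <- plogis(eta)
  v <- mean(p * (1 - p))
  if (v <= 0) return(Inf)
  stats::var(eta) / v
}

snr_fun <- function(snr_def) {
  switch(snr_def, latent = snr_latent, bernoulli = snr_bernoulli,
         stop_invalid("unknown snr_def '%s'", snr_def))
}

#' Calibrate a common effect size to a target signal-to-noise ratio
#'
#' For a binary outcome generated through a logistic model with equal
#' effects \eqn{b} on a set of informative covariates, the default
#' signal-to-noise ratio is the latent-scale one,
#' \eqn{Var_i(\eta_i) / (\pi^2/3)} with
#' \eqn{\eta_i = b \sum_j x_{ij}} centered across patients — the
#' variance of the linear predictor over the variance of the logistic
#' latent error, the standard definition when simulating two-group
#' outcomes from a logistic model.  The alternative
#' \code{snr_def = "bernoulli"} divides by the mean Bernoulli
#' conditional variance \eqn{mean_i(\pi_i(1-\pi_i))} instead.  The
#' common effect size achieving the target is found by bisection after
#' verifying monotonicity of SNR(b) on the bracket.
#'
#' @param x_effective informative-covariate matrix, genes in rows and
#'   samples in columns (already on the scale that carries the effect,
#'   i.e. normalized counts or their logs).
#' @param snr_target positive target SNR (2.5 in the shipped studies).
#' @param snr_def \code{"latent"} (default) or \code{"bernoulli"}.
#' @param tol relative tolerance of the bisection.
#' @return The positive scalar effect size \code{b}, with the achieved SNR
#'   as attribute \code{"snr"} and the definition used as
#'   \code{"snr_def"}.
#' @export
calibrate_effects <- function(x_effective, snr_target,
                              snr_def = c("latent", "bernoulli"),
                              tol = 1e-6) {
  snr_def <- match.arg(snr_def)
  snr <- snr_fun(snr_def)
  if (snr_target <= 0) stop_invalid("snr_target must be positive")
  x_sum <- colSums(rbind(x_effective))
  if (stats::var(x_sum) <= 0)
    stop_invalid("calibration failure: informative covariate sum is constant")
  lo <- 0
  hi <- 1e-6
  while (snr(hi, x_sum) < snr_target && hi < 1e8) hi <- hi * 4
  if (snr(hi, x_sum) < snr_target)
    stop_invalid("calibration failure: SNR target %.3g unreachable on bracket",
                 snr_target)
  grid <- seq(lo, hi, length.out = 9)
  vals <- vapply(grid, snr, numeric(1), x_sum = x_sum)
  if (any(diff(vals) < -1e-8 * max(vals)))
    stop_invalid("calibration failure: SNR(b) not monotone on [0, %.3g]", hi)
  root <- stats::uniroot(function(b) snr(b, x_sum) - snr_target,
                         lower = lo, upper = hi, tol = tol * hi)$root
  structure(root, snr = snr(root, x_sum), snr_def = snr_def)
}

#' Describe a simulation design
#'
#' @param informative_ids gene ids carrying non-zero effects.
#' @param beta named effect vector (one entry per informative gene).
#' @param effect_scale \code{"linear"} (effects act on normalized counts)
#'   or \code{"logarithmic"} (effects act on \code{log(x + 1)}).
#' @param snr_target the SNR the effects were calibrated to (for the record).
#' @param snr_definition the SNR formula used (for the record).
#' @return A list of class \code{simulation_design}.
#' @export
simulation_design <- function(informative_ids, beta,
                              effect_scale = c("linear", "logarithmic"),
                              snr_target = NA_real_,
                              snr_definition = "var(eta) / (pi^2/3)") {
  effect_scale <- match.arg(effect_scale)
  if (length(beta) != length(informative_ids))
    stop_invalid("beta must have one entry per informative gene")
  names(beta) <- informative_ids
  structure(list(informative_ids = informative_ids, beta = beta,
                 effect_scale = effect_scale, snr_target = snr_target,
                 snr_definition = snr_definition),
            class = "simulation_design")
}

effect_covariates <- function(x, design) {
  miss <- setdiff(design$informative_ids, rownames(x))
  if (length(miss) > 0)
    stop_invalid("informative gene(s) not present in matrix: %s",
                 paste(miss, collapse = ", "))
  xs <- x[design$informative_ids, , drop = FALSE]
  if (design$effect_scale == "logarithmic") xs <- log(xs + 1) else xs
}

#' Simulate a binary outcome from informative genes
#'
#' Computes the linear predictor \eqn{\eta_i = \sum_{j \in S} \beta_j
#' x_{ij}} (with \eqn{x} the normalized counts or, under the logarithmic
#' effect scale, \eqn{log(x+1)}), centers it across patients (an
#' intercept keeping the two groups balanced — with all-positive
#' covariates and positive effects the outcome would otherwise be almost
#' constant), converts it to a case probability through the logistic
#' model, and draws Bernoulli outcomes.
#'
#' @param x numeric matrix of normalized counts, genes in rows (rownames =
#'   gene ids), samples in columns.
#' @param design a \code{\link{simulation_design}}.
#' @param seed integer seed.
#' @return List with \code{y} (0/1 vector), \code{pi} (generating
#'   probabilities) and \code{eta} (linear predictor).
#' @export
simulate_binary_outcome <- function(x, design, seed) {
  xs <- effect_covariates(x, design)
  eta <- as.numeric(crossprod(xs, design$beta[design$informative_ids]))
  eta <- eta - mean(eta)
  pi <- plogis(eta)
  y <- with_seed(seed, rbinom(length(pi), 1L, pi))
  list(y = y, pi = pi, eta = eta)
}

#' Simulate a right-censored survival outcome
#'
#' Event times are exponential with hazard \eqn{h_0 \exp(\eta_i)}, where
#' \eqn{\eta_i} combines informative-gene effects (per the design's effect
#' scale) and clinical-covariate effects.  Censoring times are uniform on
#' \eqn{[0, c_{max}]} with \eqn{c_{max}} tuned by bisection so that the
#' realized censoring fraction hits \code{censor_rate} within 0.05.
#'
#' @param x numeric matrix of normalized counts (genes x samples).
#' @param clinical numeric matrix or data.frame of clinical covariates
#'   (samples x q), or NULL.
#' @param design a \code{\link{simulation_design}}.
#' @param clinical_beta effect vector for the clinical covariates.
#' @param baseline_hazard constant baseline hazard \eqn{h_0}.
#' @param censor_rate target fraction censored, in [0, 0.95].
#' @param seed integer seed.
#' @return List with \code{time}, \code{event} (1 = observed), and
#'   \code{true_linpred}.
#' @export
simulate_survival_outcome <- function(x, clinical, design,
                                      clinical_beta = NULL,
                                      baseline_hazard = 0.1,
                                      censor_rate = 0.3, seed) {
  if (censor_rate < 0 || censor_rate > 0.95)
    stop_invalid("censor_rate must lie in [0, 0.95]")
  xs <- effect_covariates(x, design)
  eta <- as.numeric(crossprod(xs, design$beta[design$informative_ids]))
  if (!is.null(clinical) && !is.null(clinical_beta)) {
    cl <- as.matrix(clinical)
    if (ncol(cl) != length(clinical_beta))
      stop_invalid("clinical_beta length must match clinical covariates")
    eta <- eta + as.numeric(cl %*% clinical_beta)
  }
  eta <- eta - mean(eta)
  n <- length(eta)
  with_seed(seed, {
    t_event <- rexp(n, rate = baseline_hazard * exp(eta))
    if (censor_rate == 0)
      return(list(time = t_event, event = rep(1L, n), true_linpred = eta))
    u <- runif(n)
    frac_cens <- function(cmax) mean(cmax * u < t_event)
    # sample i is censored iff cmax < t_i / u_i, so the empirical rate is
    # hit exactly at a quantile of those per-sample thresholds
    cmax <- stats::quantile(t_event / u, 1 - censor_rate, names = FALSE,
                            type = 1)
    if (abs(frac_cens(cmax) - censor_rate) > 0.05)
      stop_invalid("calibration failure: cannot reach censor rate %.2f (achieved %.2f)",
                   censor_rate, frac_cens(cmax))
    t_cens <- cmax * u
    list(time = pmin(t_event, t_cens),
         event = as.integer(t_event <= t_cens),
         true_linpred = eta)
  })
}

#' Simulate a clinical covariate table
#'
#' A continuous age-like covariate (standardized) and a balanced binary
#' covariate, the minimal clinical table used by the resampling study.
#'
#' @param n_samples number of samples.
#' @param seed integer seed.
#' @return Numeric matrix \code{n_samples x 2} with columns \code{age}
#'   and \code{sex}.
#' @export
simulate_clinical <- function(n_samples, seed) {
  with_seed(seed, {
    cbind(age = as.numeric(scale(rnorm(n_samples, 60, 10))),
          sex = rbinom(n_samples, 1L, 0.5))
  })
}
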