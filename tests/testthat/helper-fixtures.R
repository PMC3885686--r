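# Fixture builders shared across the suite.  Everything is generated in
# code under fixed seeds; no data files.

# small positive expression-like matrix with gene rownames
make_expr <- function(p = 50, n = 30, seed = 1, meanlog = 3, sdlog = 1) {
  set.seed(seed)
  x <- matrix(exp(rnorm(p * n, meanlog, sdlog)), p, n)
  rownames(x) <- sprintf("g%03d", seq_len(p))
  colnames(x) <- sprintf("s%03d", seq_len(n))
  x
}

# gene metadata table with controllable lengths
make_genes <- function(lengths) {
  data.frame(gene_id = sprintf("g%03d", seq_along(lengths)),
             length_bp = lengths,
             base_mean = 10, dispersion = 0.1,
             stringsAsFactors = FALSE)
}

# censored survival data from a known Cox model
make_survival <- function(n = 100, beta = 0.8, seed = 1, cens_upper = 15,
                          base_rate = 0.1) {
  set.seed(seed)
  x <- matrix(rnorm(n * 3), n)
  t_event <- rexp(n, base_rate * exp(beta * x[, 1]))
  t_cens <- runif(n, 0, cens_upper)
  list(x = x, time = pmin(t_event, t_cens),
       event = as.integer(t_event <= t_cens))
}

pop_var <- function(v) mean((v - mean(v))^2)
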