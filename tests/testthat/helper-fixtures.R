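# Shared fixture builders; everything is generated in code.

# Tiny hand-written expression matrix (genes x samples).
tiny_expr <- function() {
  m <- matrix(c(5.2, 3.1, 2.0,
                3.1, 3.1, 4.5,
                1.0, 9.9, 2.0),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("GA", "GB", "GC"),
                              c("s1", "s2", "s3")))
  m
}

# Random valid expression matrix.
random_expr <- function(n_genes = 10, n_samples = 6, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * n_samples, 8, 2), n_genes,
                dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                                sprintf("s%03d", seq_len(n_samples))))
    m
  })
}

# Brute-force two-sided Fisher oracle: enumerate every table with the
# observed margins, each table's probability from first principles.
fisher_oracle <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; k <- a + c; N <- n1 + n2
  if (n1 == 0 || n2 == 0 || k == 0 || k == N) return(1)
  xs <- max(0, k - n2):min(k, n1)
  probs <- exp(lchoose(n1, xs) + lchoose(n2, k - xs) - lchoose(N, k))
  pobs <- exp(lchoose(n1, a) + lchoose(n2, k - a) - lchoose(N, k))
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# Brute-force hypergeometric upper tail by summing the mass function.
hyper_oracle <- function(overlap, list_size, set_size, universe_size) {
  xs <- overlap:min(list_size, set_size)
  sum(exp(lchoose(set_size, xs) +
            lchoose(universe_size - set_size, list_size - xs) -
            lchoose(universe_size, list_size)))
}

# A small strictly increasing transform bank for invariance properties.
monotone_bank <- list(
  function(x) exp(x / 4),
  function(x) x^3 + x,
  function(x) atan(x) + x / 10,
  function(x) 100 + 0.01 * x,
  function(x) x + 0.5 * sin(x)
)

# Features + labels with one strongly reversed pair and pure-noise pairs,
# built directly as +1/-1 draws (no expression detour).
planted_feature_set <- function(n_case = 100, n_ctrl = 100, n_null = 20,
                                rate_case = 0.95, rate_ctrl = 0.05,
                                seed = 1) {
  withr::with_seed(seed, {
    n <- n_case + n_ctrl
    ids <- sprintf("s%03d", seq_len(n))
    labels <- stats::setNames(c(rep(1L, n_case), rep(0L, n_ctrl)), ids)
    rate <- ifelse(labels == 1L, rate_case, rate_ctrl)
    planted <- ifelse(runif(n) < rate, 1L, -1L)
    nulls <- matrix(sample(c(1L, -1L), n_null * n, replace = TRUE),
                    nrow = n_null)
    values <- rbind(planted, nulls)
    gene_a <- sprintf("N%03da", 0:n_null)
    gene_b <- sprintf("N%03db", 0:n_null)
    pairs <- data.frame(gene_a = gene_a, gene_b = gene_b,
                        stringsAsFactors = FALSE)
    rownames(values) <- paste(gene_a, gene_b, sep = "|")
    colnames(values) <- ids
    list(features = pairdx:::new_pair_features(pairs, values),
         labels = labels, planted_id = rownames(values)[1])
  })
}

# Survival data driven by +/-1 features through an exponential
# proportional-hazards model.
survival_from_features <- function(values, betas, baseline_rate = 0.1,
                                   censor_max = 20, seed = 1) {
  withr::with_seed(seed, {
    lp <- as.numeric(betas %*% values[seq_along(betas), , drop = FALSE])
    t_ev <- rexp(ncol(values), rate = baseline_rate * exp(lp))
    t_cn <- if (is.finite(censor_max))
      runif(ncol(values), 0, censor_max) else rep(Inf, ncol(values))
    data.frame(sample_id = colnames(values),
               time = pmin(t_ev, t_cn),
               event = as.integer(t_ev <= t_cn),
               stringsAsFactors = FALSE)
  })
}
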