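# Small fixtures built in code, shared across test files.

# Items with a planted 4-block correlation structure (within-block r ~ 0.9,
# cross-block r ~ 0), via a block factor model.
planted_items <- function(n = 60, per_block = 5, within = 0.9, seed = 42) {
  set.seed(seed)
  blocks <- rep(seq_len(4), each = per_block)
  f <- matrix(rnorm(n * 4), n, 4)
  x <- sapply(seq_along(blocks), function(j) {
    sqrt(within) * f[, blocks[j]] + sqrt(1 - within) * rnorm(n)
  })
  colnames(x) <- paste0("v", seq_along(blocks))
  list(x = x, blocks = blocks)
}

# Perfectly separable two-class data.
separable_xy <- function(n_per_class = 10, p = 3, gap = 10, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p)
  y <- rep(c(0, 1), each = n_per_class)
  X[, 1] <- X[, 1] * 0.1 + gap * y
  colnames(X) <- paste0("v", seq_len(p))
  list(x = X, y = y)
}

# Config with all randomness switched off (degenerate noise).
degenerate_config <- function(n_donors = 4) {
  ph <- fearscore:::default_physio_moments()
  ph$fear_sd <- 0; ph$neutral_sd <- 0
  it <- fearscore:::default_item_moments()
  it$fear_sd <- 0; it$neutral_sd <- 0
  # integer item means so the 0-5 discretization is the identity
  it$fear_mean <- c(2, 3, 1, 1)
  it$neutral_mean <- c(1, 0, 1, 4)
  generator_config(n_donors = n_donors, seed = 1, physio = ph,
                   item_clusters = it, intensity_spread = 0,
                   rating_noise_sd = 0)
}

# Exact binomial upper tail by brute-force enumeration of outcomes.
binom_tail_bruteforce <- function(k, n, p) {
  if (k > n) return(0)
  sum(vapply(k:n, function(j) choose(n, j) * p^j * (1 - p)^(n - j),
             numeric(1)))
}
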