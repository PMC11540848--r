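# Independent oracles used across test files. Each is a deliberately naive
# implementation (normal equations, enumeration, direct simulation) kept
# separate from the package's code paths.

# closed-form simple-regression oracle via explicit normal equations
ols_oracle <- function(y, x) {
  n <- length(y)
  X <- cbind(1, x)
  XtX <- t(X) %*% X
  bh <- solve(XtX, t(X) %*% y)
  res <- y - X %*% bh
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 * solve(XtX)[2, 2])
  tt <- bh[2] / se
  list(beta = bh[2], se = se, p = 2 * pt(abs(tt), n - 2, lower.tail = FALSE))
}

# two-covariate OLS oracle (intercept + m + g), slope and p for g
ols2_oracle <- function(y, m, g) {
  n <- length(y)
  X <- cbind(1, m, g)
  XtX <- t(X) %*% X
  bh <- solve(XtX, t(X) %*% y)
  res <- y - X %*% bh
  s2 <- sum(res^2) / (n - 3)
  se <- sqrt(s2 * solve(XtX)[3, 3])
  tt <- bh[3] / se
  list(beta = bh[3], se = se, p = 2 * pt(abs(tt), n - 3, lower.tail = FALSE))
}

# brute-force five-hypothesis coloc by enumerating all single-causal
# configurations: (0|i) x (0|j) over variants
coloc_enum_oracle <- function(labf1, labf2, p1, p2, p12) {
  m <- length(labf1)
  w <- c(H0 = 0, H1 = -Inf, H2 = -Inf, H3 = -Inf, H4 = -Inf)
  acc <- list(H1 = c(), H2 = c(), H3 = c(), H4 = c())
  for (i in seq_len(m)) acc$H1 <- c(acc$H1, log(p1) + labf1[i])
  for (j in seq_len(m)) acc$H2 <- c(acc$H2, log(p2) + labf2[j])
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) {
      acc$H4 <- c(acc$H4, log(p12) + labf1[i] + labf2[j])
    } else {
      acc$H3 <- c(acc$H3, log(p1) + log(p2) + labf1[i] + labf2[j])
    }
  }
  lse <- function(x) { mx <- max(x); mx + log(sum(exp(x - mx))) }
  lw <- c(0, lse(acc$H1), lse(acc$H2), lse(acc$H3), lse(acc$H4))
  exp(lw - lse(lw))
}

# direct AR(1) haplotype simulator used as large-n oracle for dosage LD
haplotype_ld_oracle <- function(n_hap, freqs, rho) {
  m <- length(freqs)
  z <- matrix(rnorm(n_hap * m), n_hap, m)
  for (j in seq_len(m)[-1]) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
  al <- sweep(z, 2, qnorm(freqs), `<`) + 0
  al
}

# small simulated study shared by several files
tiny_study <- function(seed = 7, n = 200, n_genes = 6, beta = 0.5,
                       maf = c(0.2, 0.5), nf = 0, ...) {
  cfg <- sim_config(n_samples = n, n_variants = 120, n_blocks = 6,
                    n_genes = n_genes, maf_range = maf,
                    cis_effect_beta = beta, n_hidden_factors = nf,
                    seed = seed, ...)
  g <- simulate_genotypes(cfg)
  tr <- simulate_traits(g, cfg)
  list(cfg = cfg, geno = g, mrna = tr$mrna, protein = tr$protein,
       truth = tr$truth)
}

# single-trait view used by scenario tests
subset_traits_for_test <- function(traits, ids) {
  idx <- match(ids, traits$traits$trait_id)
  trait_matrix(traits$values[idx, , drop = FALSE],
               traits$traits[idx, , drop = FALSE])
}
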