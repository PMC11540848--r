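mk_assoc <- function(b, se, ids = sprintf("v%02d", seq_along(b))) {
  tibble::tibble(variant_id = ids, b = b, se = se, z = b / se)
}

test_that("log ABF follows the closed form and its limits", {
  # z = 0: log ABF = 0.5 log(V / (V + W)) < 0
  a <- mk_assoc(0, 0.1)
  got <- approximate_bayes_factors(a, W = 0.15^2)$labf
  expect_equal(got, 0.5 * log(0.01 / (0.01 + 0.0225)), tolerance = 1e-12)
  expect_lt(got, 0)
  # W -> 0: all log ABF -> 0
  set.seed(1)
  a2 <- mk_assoc(rnorm(20), runif(20, 0.05, 0.2))
  expect_lt(max(abs(approximate_bayes_factors(a2, W = 1e-12)$labf)), 1e-6)
  # literal transcription on random inputs
  set.seed(2)
  for (i in 1:50) {
    b <- rnorm(1); se <- runif(1, 0.01, 0.5); W <- runif(1, 0.001, 0.1)
    V <- se^2; z <- b / se
    expect_equal(approximate_bayes_factors(mk_assoc(b, se), W)$labf,
                 0.5 * (log(V / (V + W)) + z^2 * W / (V + W)),
                 tolerance = 1e-12)
  }
})

test_that("se is reconstructed from maf and n when absent", {
  a <- tibble::tibble(variant_id = "v1", b = 0.1, maf = 0.25, n = 400)
  got <- approximate_bayes_factors(a)
  expect_equal(got$se, 1 / sqrt(2 * 400 * 0.25 * 0.75), tolerance = 1e-12)
})

test_that("null signals give PP0 near 1; refusal below 2 shared variants", {
  set.seed(3)
  a1 <- mk_assoc(rnorm(100, 0, 0.02), rep(0.1, 100))
  a2 <- mk_assoc(rnorm(100, 0, 0.02), rep(0.1, 100))
  cc <- colocalize(a1, a2)
  expect_gt(cc$PP0, 0.9)
  expect_equal(cc$PP0 + cc$PP1 + cc$PP2 + cc$PP3 + cc$PP4, 1,
               tolerance = 1e-9)
  expect_error(colocalize(a1[1, ], a2[1, ]), "at least 2")
})

test_that("swapping the traits swaps PP1 and PP2 and fixes the rest", {
  set.seed(4)
  b1 <- rnorm(50, 0, 0.05); b1[25] <- 0.8
  a1 <- mk_assoc(b1, rep(0.08, 50))
  a2 <- mk_assoc(rnorm(50, 0, 0.05), rep(0.08, 50))
  cc12 <- colocalize(a1, a2)
  cc21 <- colocalize(a2, a1)
  expect_equal(cc12$PP1, cc21$PP2, tolerance = 1e-12)
  expect_equal(cc12$PP2, cc21$PP1, tolerance = 1e-12)
  expect_equal(cc12$PP0, cc21$PP0, tolerance = 1e-12)
  expect_equal(cc12$PP3, cc21$PP3, tolerance = 1e-12)
  expect_equal(cc12$PP4, cc21$PP4, tolerance = 1e-12)
})

test_that("posteriors equal brute-force configuration enumeration on toys", {
  set.seed(5)
  for (i in 1:10) {
    a1 <- mk_assoc(rnorm(3, 0, 0.4), runif(3, 0.05, 0.2))
    a2 <- mk_assoc(rnorm(3, 0, 0.4), runif(3, 0.05, 0.2))
    cc <- colocalize(a1, a2)
    l1 <- approximate_bayes_factors(a1)$labf
    l2 <- approximate_bayes_factors(a2)$labf
    oracle <- coloc_enum_oracle(l1, l2, 1e-4, 1e-4, 1e-5)
    expect_equal(unlist(cc[1, 1:5]), oracle, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("posteriors are invariant to a constant added to one trait's log ABFs", {
  set.seed(6)
  a1 <- mk_assoc(rnorm(20, 0, 0.3), runif(20, 0.05, 0.2))
  a2 <- mk_assoc(rnorm(20, 0, 0.3), runif(20, 0.05, 0.2))
  l1 <- approximate_bayes_factors(a1)$labf
  l2 <- approximate_bayes_factors(a2)$labf
  pp <- coloc_enum_oracle(l1, l2, 1e-4, 1e-4, 1e-5)
  pp_shift <- coloc_enum_oracle(l1 + 3.7, l2, 1e-4, 1e-4, 1e-5)
  # H0 trades off against the rest when one trait's evidence is rescaled;
  # the *relative* weights of H1/H3/H4 configurations involving trait 1
  # all scale together, so the conditional split is unchanged
  expect_equal(pp_shift[c(2, 4, 5)] / sum(pp_shift[c(2, 4, 5)]),
               pp[c(2, 4, 5)] / sum(pp[c(2, 4, 5)]), tolerance = 1e-9)
})

test_that("allele-swapped records are aligned before combination", {
  a1 <- mk_assoc(c(0.5, 0.1), c(0.1, 0.1))
  a1$A1 <- c("A", "C"); a1$A2 <- c("G", "T")
  a2 <- a1
  a2$b <- -a2$b
  a2$A1 <- a1$A2; a2$A2 <- a1$A1      # swapped orientation, flipped sign
  cc <- colocalize(a1, a2)
  a2_same <- a1
  cc_same <- colocalize(a1, a2_same)
  expect_equal(cc$PP4, cc_same$PP4, tolerance = 1e-12)
})

test_that("distinct strong causal variants drive PP3 toward 1", {
  b1 <- rep(0, 40); b1[10] <- 1
  b2 <- rep(0, 40); b2[30] <- 1
  a1 <- mk_assoc(b1, rep(0.05, 40))
  a2 <- mk_assoc(b2, rep(0.05, 40))
  expect_gt(colocalize(a1, a2)$PP3, 0.99)
})

test_that("a shared causal variant in simulation yields high PP4 with matched signs", {
  set.seed(7)
  hits <- replicate(25, {
    cfg <- sim_config(n_samples = 500, n_variants = 50, n_blocks = 1,
                      n_genes = 1, maf_range = c(0.2, 0.5),
                      cis_effect_beta = 0.5, mediation_fraction = 1,
                      mediation_slope = 1, n_hidden_factors = 0,
                      seed = sample.int(1e6, 1))
    g <- simulate_genotypes(cfg)
    tr <- simulate_traits(g, cfg)
    w <- window_config()
    a_p <- nominal_scan(tr$protein, g, w, "cis")
    a_e <- nominal_scan(tr$mrna, g, w, "cis")
    cc <- colocalize(a_p, a_e)
    top_p <- a_p$variant_id[which.min(a_p$p)]
    sign_match <- sign(a_p$beta[a_p$variant_id == top_p]) ==
      sign(a_e$beta[a_e$variant_id == top_p])
    c(cc$PP4, sign_match)
  })
  expect_gte(mean(hits[1, ] > 0.8), 0.8)
  expect_gt(mean(hits[2, ]), 0.95)
})

test_that("window restriction keeps only variants near the lead", {
  st <- tiny_study(seed = 31, n = 200, n_genes = 2)
  w <- window_config()
  a_p <- nominal_scan(st$protein, st$geno, w, "cis")
  a_e <- nominal_scan(st$mrna, st$geno, w, "cis")
  lead <- st$truth$causal_variant[1]
  cc <- colocalize_window(a_p, a_e, st$geno$variants, lead, window = 5e4)
  in_win <- sum(abs(st$geno$variants$pos -
                      st$geno$variants$pos[st$geno$variants$variant_id == lead]) <= 5e4 &
                  st$geno$variants$chrom == st$truth$chrom[1])
  expect_lte(cc$n_snps, in_win)
})
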