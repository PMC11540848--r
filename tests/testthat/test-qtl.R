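test_that("nominal scan slopes and p-values match the normal-equations oracle", {
  st <- tiny_study(seed = 21, n = 150, n_genes = 6)
  sc <- nominal_scan(st$mrna, st$geno, window_config(), "cis")
  set.seed(1)
  pick <- sample(nrow(sc), 100)
  for (i in pick) {
    y <- st$mrna$values[sc$trait_id[i], ]
    gref <- 2 - st$geno$dosages[, sc$variant_id[i]]
    o <- ols_oracle(y, gref)
    expect_equal(sc$beta[i], unname(o$beta), tolerance = 1e-10)
    expect_equal(sc$se[i], unname(o$se), tolerance = 1e-10)
    expect_equal(sc$p[i], unname(o$p), tolerance = 1e-10)
  }
})

test_that("positive beta means higher expression with the reference allele", {
  st <- tiny_study(seed = 22, n = 400, beta = 1)
  sc <- nominal_scan(st$mrna, st$geno, window_config(), "cis")
  top <- sc |>
    dplyr::filter(.data$trait_id == "G001") |>
    dplyr::slice_min(.data$p, n = 1)
  # generator effects are on reference dosage with positive slope
  expect_gt(top$beta, 0)
})

test_that("null p-values are uniform across a window scan", {
  st <- tiny_study(seed = 23, n = 2000, beta = 0, n_genes = 2)
  sc <- nominal_scan(st$mrna, st$geno, window_config(), "cis")
  expect_gt(stats::ks.test(sc$p, "punif")$p.value, 0.01)
})

test_that("a trait identical to a dosage column yields the extreme record finitely", {
  st <- tiny_study(seed = 24, n = 100, n_genes = 1)
  v <- st$truth$causal_variant[1]
  vals <- matrix(2 - st$geno$dosages[, v], 1,
                 dimnames = list("G001", rownames(st$geno$dosages)))
  tm <- trait_matrix(vals, st$mrna$traits[1, ])
  sc <- nominal_scan(tm, st$geno, window_config(), "cis")
  hit <- sc[sc$variant_id == v, ]
  expect_equal(hit$beta, 1, tolerance = 1e-12)
  expect_true(is.finite(hit$p) && hit$p >= 0)
  expect_lt(hit$p, 1e-200)
})

test_that("cis and trans windows partition variants correctly", {
  st <- tiny_study(seed = 25)
  w <- window_config(cis_window = 1e6, trans_min_distance = 5e6)
  cis <- nominal_scan(st$mrna, st$geno, w, "cis")
  expect_true(all(abs(cis$tss_distance) <= 1e6))
  trans <- nominal_scan(st$mrna, st$geno, w, "trans")
  tr_meta <- st$mrna$traits[match(trans$trait_id, st$mrna$traits$trait_id), ]
  same_chr <- trans$chrom == tr_meta$chrom
  expect_true(all(!same_chr |
                    trans$pos < tr_meta$gene_start - 5e6 |
                    trans$pos > tr_meta$gene_end + 5e6))
})

test_that("single-variant windows make adjusted, direct and nominal p agree", {
  st <- tiny_study(seed = 26, n = 200, n_genes = 1)
  keep <- which(st$geno$variants$variant_id == st$truth$causal_variant[1])
  g1 <- geno_matrix(st$geno$dosages[, keep, drop = FALSE],
                    st$geno$variants[keep, ])
  pp <- permutation_pass(st$mrna, g1,
                         window_config(n_permutations = 2000), seed = 3)
  expect_equal(pp$adjusted_p, pp$nominal_p, tolerance = 1e-12)
  expect_lt(abs(pp$direct_empirical_p - pp$nominal_p), 0.05)
})

test_that("beta-approximated and direct empirical p agree over a null scan", {
  st <- tiny_study(seed = 27, n = 150, beta = 0, n_genes = 24)
  pp <- permutation_pass(st$mrna, st$geno,
                         window_config(n_permutations = 2000), seed = 11)
  expect_gt(cor(pp$adjusted_p, pp$direct_empirical_p, method = "spearman"),
            0.99)
  expect_lt(max(abs(pp$adjusted_p - pp$direct_empirical_p)), 0.05)
  expect_true(all(pp$beta_shape1 > 0 & pp$beta_shape2 > 0, na.rm = TRUE))
})

test_that("adjusted p is monotone in the observed minimum nominal p", {
  # fixed null, moving observation: the Beta CDF is increasing
  shapes <- c(1.1, 18)
  obs <- sort(runif(20))
  expect_true(all(diff(pbeta(obs, shapes[1], shapes[2])) >= 0))
})

test_that("jointly permuting samples in genotypes and traits changes nothing", {
  st <- tiny_study(seed = 28, n = 120, n_genes = 3)
  w <- window_config(n_permutations = 200)
  base <- permutation_pass(st$mrna, st$geno, w, seed = 2)
  set.seed(9)
  perm <- sample(ncol(st$mrna$values))
  g2 <- geno_matrix(st$geno$dosages[perm, ], st$geno$variants)
  t2 <- trait_matrix(st$mrna$values[, perm], st$mrna$traits)
  shuffled <- permutation_pass(t2, g2, w, seed = 2)
  expect_equal(base$nominal_p, shuffled$nominal_p, tolerance = 1e-12)
  expect_equal(base$beta, shuffled$beta, tolerance = 1e-12)
})

test_that("Storey q-values with pi0 = 1 reproduce Benjamini-Hochberg exactly", {
  set.seed(10)
  p <- c(runif(300)^2, runif(200))
  q <- storey_qvalues(p, pi0 = 1)
  expect_equal(as.numeric(q), p.adjust(p, "BH"), tolerance = 1e-12)
})

test_that("Storey pi0 is near 1 for uniform p-values and q is monotone", {
  set.seed(11)
  p <- runif(10000)
  q <- storey_qvalues(p)
  expect_gte(attr(q, "pi0"), 0.9)
  expect_lte(attr(q, "pi0"), 1.0)
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-12))
  expect_true(all(storey_qvalues(rep(1, 200)) == 1))
})

test_that("few p-values fall back to BH with a warning", {
  p <- runif(50)
  expect_warning(q <- storey_qvalues(p), "fewer than 100")
  expect_equal(as.numeric(q), p.adjust(p, "BH"), tolerance = 1e-12)
})

test_that("trans Bonferroni threshold reproduces the genome-wide scale", {
  expect_equal(trans_threshold(8101465, 11608), 0.05 / (8101465 * 11608))
  expect_equal(signif(trans_threshold(8101465, 11608), 2), 5.3e-13)
  expect_equal(trans_threshold(1, 1), 0.05)
  expect_equal(trans_threshold(10, 10), 5e-4)
  expect_error(trans_threshold(0, 10))
})

test_that("annotation summary multiplies exonic and non-synonymous fractions", {
  # construct significant records whose annotation composition is known
  n <- 1000
  vid <- sprintf("v%04d", 1:n)
  anno <- rep("intergenic", n)
  anno[1:151] <- "exonic_nonsyn"; anno[152:200] <- "exonic_syn"
  recs <- tibble::tibble(
    trait_id = sprintf("T%04d", 1:n), variant_id = vid,
    qvalue = 0.01, tss_distance = rep(c(5000, 50000), c(563, 437))
  )
  variants <- tibble::tibble(variant_id = vid, anno_class = anno)
  s <- summarize_annotations(recs, variants)
  expect_equal(s$nonsynonymous$exonic_fraction, 0.2)
  expect_equal(s$nonsynonymous$nonsyn_within_exonic, 0.755)
  expect_equal(s$nonsynonymous$overall_nonsyn, 0.151)
  expect_equal(s$tss$fraction, 0.563)
  # the study arithmetic: 15.13% exonic x 75.63% nonsyn = 11.44% overall
  expect_equal(round(100 * 0.1513 * 0.7563, 2), 11.44)
  expect_equal(round(100 * 0.0543 * 0.3364, 2), 1.83)
  expect_equal(round(100 * 5605 / 9960, 2), 56.28)
})

test_that("per-trait permutation streams make results independent of trait subsetting", {
  st <- tiny_study(seed = 29, n = 100, n_genes = 4)
  w <- window_config(n_permutations = 150)
  all4 <- permutation_pass(st$mrna, st$geno, w, seed = 5)
  # nominal results identical regardless of which traits ride along
  solo <- permutation_pass(
    trait_matrix(st$mrna$values[2, , drop = FALSE], st$mrna$traits[2, ]),
    st$geno, w, seed = 5)
  expect_equal(solo$nominal_p, all4$nominal_p[2], tolerance = 1e-12)
})
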