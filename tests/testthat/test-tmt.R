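make_psm <- function(X, protein_id = "P1", batch_id = "B01") {
  k <- nrow(X)
  tibble::tibble(
    psm_id = sprintf("PSM%03d", seq_len(k)),
    protein_id = rep_len(protein_id, k),
    batch_id = batch_id, jscore = 50
  ) |>
    dplyr::bind_cols(tibble::as_tibble(setNames(
      as.data.frame(X), paste0("channel_", seq_len(ncol(X)))
    )))
}

test_that("identity impurity leaves intensities untouched; zero stays zero", {
  X <- matrix(runif(33, 1e3, 1e5), 3, 11)
  X[2, ] <- 0
  psm <- make_psm(X)
  out <- correct_impurity(psm, diag(11))
  expect_equal(as.matrix(out[, paste0("channel_", 1:11)]), X,
               ignore_attr = TRUE)
  expect_true(all(out[2, paste0("channel_", 1:11)] == 0))
})

test_that("impurity correction inverts a known 5% spillover exactly", {
  set.seed(4)
  M <- impurity_matrix(0.05)
  truth <- matrix(runif(55, 1e3, 1e6), 5, 11)
  observed <- t(M %*% t(truth))
  psm <- make_psm(observed)
  out <- correct_impurity(psm, M)
  rec <- as.matrix(out[, paste0("channel_", 1:11)])
  expect_lt(max(abs(rec - truth) / truth), 1e-8)
})

test_that("singular impurity matrices are refused by name", {
  M <- matrix(1 / 11, 11, 11)
  expect_error(validate_impurity(M), "dominant|singular")
})

test_that("intensity filters are boundary-inclusive", {
  X <- rbind(
    c(999, rep(6000, 10)),            # min fails
    c(1000, rep(5000, 10)),           # exactly at both boundaries
    c(1500, rep(4999, 10))            # median fails
  )
  psm <- make_psm(X)
  out <- filter_psms(psm)
  expect_equal(out$psm_id, "PSM002")
  expect_warning(filter_psms(make_psm(X[c(1, 3), , drop = FALSE])),
                 "no PSMs")
})

test_that("equal channels give unit factors; a doubled channel gets exactly 0.5", {
  v <- 2^seq(10, 18, length.out = 101)
  X <- matrix(v, 101, 11)
  psm <- make_psm(X)
  expect_true(all(abs(attr(normalize_channels(psm), "scale_factors")$B01 - 1) < 1e-12))
  X2 <- X
  X2[, 4] <- X2[, 4] * 2
  sf <- attr(normalize_channels(make_psm(X2)), "scale_factors")$B01
  expect_equal(unname(sf[4]), 0.5, tolerance = 1e-12)
  expect_true(all(abs(sf[-4] - 1) < 1e-12))
})

test_that("channel normalization recovers scale factors and equalizes medians", {
  set.seed(5)
  X <- matrix(2^rnorm(11 * 400, 14, 1), 400, 11)
  X[, 4] <- X[, 4] * 2
  psm <- make_psm(X)
  out <- normalize_channels(psm, trim_fraction = 0.1)
  sf <- attr(out, "scale_factors")$B01
  expect_equal(unname(sf[4] / mean(sf[-4])), 0.5, tolerance = 0.1)
  # post-normalization trimmed channel medians agree with a sort-based
  # oracle and are equal across channels
  Xn <- as.matrix(out[, paste0("channel_", 1:11)])
  keep <- order(rowMeans(X))[41:360]
  meds <- apply(Xn[keep, ], 2, function(v) sort(v)[c(160, 161)] |> mean())
  expect_lt(diff(range(meds)) / mean(meds), 1e-9)
})

test_that("flat one-PSM protein summarizes to its log2 mean", {
  X <- matrix(8000, 1, 11)
  pm <- summarize_proteins(make_psm(X))
  expect_equal(unname(pm["P1", ]), rep(log2(8000), 11))
})

test_that("top-3 rule degrades gracefully with two PSMs", {
  X <- rbind(rep(1000, 11) * 2, rep(3000, 11))
  pm <- summarize_proteins(make_psm(X))
  expect_equal(unname(pm["P1", ]), rep(log2(2500), 11))
})

test_that("bridging removes a global batch shift", {
  set.seed(6)
  b1 <- matrix(rnorm(33, 10), 3, 11,
               dimnames = list(paste0("P", 1:3), paste0("channel_", 1:11)))
  b2 <- b1 + 2                    # batch 2 shifted x4 on linear scale
  class(b1) <- class(b2) <- "protein_matrix"
  smap <- tibble::tibble(
    batch_id = rep(c("B01", "B02"), each = 11),
    channel = rep(1:11, 2),
    sample_id = c(sprintf("S%02d", 1:10), "IS1", sprintf("S%02d", 11:20), "IS2")
  )
  out <- bridge_batches(list(B01 = b1, B02 = b2), smap)
  expect_equal(out[, 1:10], out[, 11:20], ignore_attr = TRUE)
  expect_error(bridge_batches(list(B01 = b1[, 1:5]), smap), "internal-standard")
})

test_that("quantification is scale-equivariant", {
  sim <- simulate_psm_table(10, 2, low_fraction = 0, seed = 21)
  pm1 <- quantify_batches(sim$psm, sim$sample_map)
  psm_scaled <- sim$psm
  cc <- paste0("channel_", 1:11)
  psm_scaled[, cc] <- psm_scaled[, cc] * 7
  pm2 <- quantify_batches(psm_scaled, sim$sample_map)
  # IS-centred log ratios are invariant to a global intensity rescale
  expect_equal(pm1, pm2, tolerance = 1e-10)
})

test_that("zero-noise generator output round-trips exactly", {
  sim <- simulate_psm_table(12, 2, noise_sd = 1e-12, low_fraction = 0,
                            seed = 7)
  pm <- quantify_batches(sim$psm, sim$sample_map, normalize = FALSE)
  rel <- 2^sim$truth
  expected <- matrix(NA_real_, nrow(rel), ncol(rel), dimnames = dimnames(rel))
  for (b in 1:2) {
    idx <- (10 * (b - 1) + 1):(10 * b)
    expected[, idx] <- log2(rel[, idx] / rowMeans(rel[, idx]))
  }
  expect_equal(unclass(pm), expected[rownames(pm), colnames(pm)],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("normalization removes known channel loadings under flat biology", {
  loads <- 2^seq(-0.5, 0.5, length.out = 11)
  sim <- simulate_psm_table(50, 1, noise_sd = 1e-12, bio_sd = 0,
                            low_fraction = 0, channel_loadings = loads,
                            seed = 8)
  pm <- quantify_batches(sim$psm, sim$sample_map)
  expect_lt(max(abs(pm)), 1e-9)
})

test_that("impurity mixing plus the full chain still recovers profiles across 29 batches", {
  M <- impurity_matrix(0.05)
  sim <- simulate_psm_table(120, 29, impurity = M, seed = 9)
  pm <- quantify_batches(sim$psm, sim$sample_map, impurity = M)
  rel <- 2^sim$truth
  expected <- matrix(NA_real_, nrow(rel), ncol(rel), dimnames = dimnames(rel))
  for (b in 1:29) {
    idx <- (10 * (b - 1) + 1):(10 * b)
    expected[, idx] <- log2(rel[, idx] / rowMeans(rel[, idx]))
  }
  cors <- vapply(rownames(pm), function(p) {
    cor(pm[p, ], expected[p, colnames(pm)], use = "pairwise.complete.obs")
  }, 0)
  expect_gt(median(cors), 0.95)
})
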