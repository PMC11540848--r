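# Summary-based Mendelian randomization with the HEIDI heterogeneity test:
# does a molecular trait's top QTL effect propagate to a GWAS signal
# through one shared (causal or pleiotropic) variant, or do distinct
# variants in LD drive the two signals (linkage)?

#' SMR configuration
#'
#' @param top_qtl_p_max Maximum QTL p-value for instrument eligibility
#'   (default 5e-8).
#' @param heidi_r2_min,heidi_r2_max LD r-squared bounds with the instrument
#'   for HEIDI candidate SNPs (defaults 0.05 and 0.9).
#' @param heidi_max_snps Cap on HEIDI SNPs, kept by descending QTL
#'   significance (default 20).
#' @param heidi_qtl_p_max Relaxed QTL p-value bound for HEIDI candidates
#'   (default 1.57e-3, i.e. `|z| > 3.16`).
#' @param p_heidi_pass HEIDI pass threshold (default 0.05).
#' @param alpha Family-wise significance level for the SMR test (default
#'   0.05); the Bonferroni divisor is the number of tested traits.
#' @param correction `"bonferroni"` (default) or `"fdr"` for the SMR
#'   multiple-testing rule.
#' @return A list of class `smr_config`.
#' @export
smr_config <- function(top_qtl_p_max = 5e-8, heidi_r2_min = 0.05,
                       heidi_r2_max = 0.9, heidi_max_snps = 20L,
                       heidi_qtl_p_max = 1.57e-3, p_heidi_pass = 0.05,
                       alpha = 0.05, correction = c("bonferroni", "fdr")) {
  abort_if(!(heidi_r2_min > 0 && heidi_r2_min < heidi_r2_max && heidi_r2_max < 1),
           "need 0 < heidi_r2_min < heidi_r2_max < 1")
  structure(list(
    top_qtl_p_max = top_qtl_p_max, heidi_r2_min = heidi_r2_min,
    heidi_r2_max = heidi_r2_max, heidi_max_snps = as.integer(heidi_max_snps),
    heidi_qtl_p_max = heidi_qtl_p_max, p_heidi_pass = p_heidi_pass,
    alpha = alpha, correction = match.arg(correction)
  ), class = "smr_config")
}

#' SMR test at a single instrument variant
#'
#' `b_xy = b_gwas / b_qtl` estimates the effect of the molecular exposure
#' on the outcome; the test statistic is
#' `T = z_qtl^2 * z_gwas^2 / (z_qtl^2 + z_gwas^2)`, referred to
#' chi-square(1).
#'
#' @param b_qtl,se_qtl Instrument effect and SE on the molecular trait.
#' @param b_gwas,se_gwas Instrument effect and SE on the outcome (alleles
#'   aligned with the QTL's effect allele).
#' @return A one-row tibble: `b_xy`, `se_xy` (delta method), `T_smr`,
#'   `p_smr`.
#' @export
smr_test <- function(b_qtl, se_qtl, b_gwas, se_gwas) {
  abort_if(b_qtl == 0, "b_qtl = 0: instrument invalid")
  abort_if(se_qtl <= 0 || se_gwas <= 0, "standard errors must be positive")
  z1 <- b_qtl / se_qtl
  z2 <- b_gwas / se_gwas
  T_smr <- if (z2 == 0) 0 else z1^2 * z2^2 / (z1^2 + z2^2)
  b_xy <- b_gwas / b_qtl
  se_xy <- sqrt(b_xy^2 * (se_gwas^2 / b_gwas^2 + se_qtl^2 / b_qtl^2))
  if (b_gwas == 0) se_xy <- abs(se_gwas / b_qtl)
  tibble::tibble(
    b_xy = b_xy, se_xy = se_xy, T_smr = T_smr,
    p_smr = pchisq(T_smr, df = 1, lower.tail = FALSE)
  )
}

#' HEIDI heterogeneity test
#'
#' Tests whether the Wald ratio `b_xy` is homogeneous across SNPs in LD
#' with the instrument. Candidates must pass a relaxed QTL threshold and
#' have r-squared with the instrument inside the configured band, capped at
#' `heidi_max_snps` by QTL significance. For each candidate,
#' `d_i = b_xy(i) - b_xy(top)`; the covariance of `d` follows from the
#' delta method with LD-induced correlation of effect estimates, and the
#' statistic `sum(z_d^2)` is referred to a Satterthwaite-scaled chi-square
#' matching the first two moments of the implied weighted sum.
#'
#' @param qtl_window,gwas_window Summary tibbles (`variant_id`, `b`, `se`,
#'   `p` for the QTL side) over the same window, alleles aligned.
#' @param ld Correlation matrix (r, not r-squared) of the window's
#'   dosages, dimnames = variant ids.
#' @param instrument Variant id of the top QTL.
#' @param cfg An [smr_config()].
#' @return A one-row tibble: `p_heidi`, `n_heidi_snps`. With fewer than 3
#'   eligible candidates `p_heidi` is `NA`.
#' @export
heidi_test <- function(qtl_window, gwas_window, ld, instrument,
                       cfg = smr_config()) {
  qtl_window <- normalize_assoc(qtl_window)
  gwas_window <- normalize_assoc(gwas_window)
  shared <- intersect(qtl_window$variant_id, gwas_window$variant_id)
  shared <- intersect(shared, colnames(ld))
  abort_if(!(instrument %in% shared), "instrument missing from the window")
  q <- qtl_window[match(shared, qtl_window$variant_id), ]
  g <- gwas_window[match(shared, gwas_window$variant_id), ]
  r_top <- ld[instrument, shared]
  r2 <- r_top^2
  eligible <- shared != instrument &
    q$p <= cfg$heidi_qtl_p_max &
    r2 >= cfg$heidi_r2_min & r2 <= cfg$heidi_r2_max
  cand <- which(eligible)
  cand <- cand[order(q$p[cand])]
  cand <- head(cand, cfg$heidi_max_snps)
  if (length(cand) < 3) {
    return(tibble::tibble(p_heidi = NA_real_, n_heidi_snps = length(cand)))
  }
  top <- which(shared == instrument)
  sel <- c(top, cand)
  bq <- q$b[sel]; sq <- q$se[sel]
  bg <- g$b[sel]; sg <- g$se[sel]
  R <- ld[shared[sel], shared[sel]]
  bxy <- bg / bq
  k <- length(sel)
  # delta-method covariance of the Wald ratios; GWAS and QTL cohorts are
  # independent, so effect-estimate covariances are r * se_i * se_j within
  # each study
  cov_bxy <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    cov_bxy[i, j] <- R[i, j] * sg[i] * sg[j] / (bq[i] * bq[j]) +
      bg[i] * bg[j] * R[i, j] * sq[i] * sq[j] / (bq[i]^2 * bq[j]^2)
  }
  # d_i = bxy_i - bxy_top, i over candidates (top is index 1)
  idx <- 2:k
  d <- bxy[idx] - bxy[1]
  cov_d <- cov_bxy[idx, idx, drop = FALSE] -
    matrix(cov_bxy[idx, 1], k - 1, k - 1) -
    t(matrix(cov_bxy[idx, 1], k - 1, k - 1)) +
    cov_bxy[1, 1]
  vd <- diag(cov_d)
  ok <- vd > 0
  if (sum(ok) < 3) {
    return(tibble::tibble(p_heidi = NA_real_, n_heidi_snps = sum(ok)))
  }
  d <- d[ok]; cov_d <- cov_d[ok, ok, drop = FALSE]; vd <- vd[ok]
  zd <- d / sqrt(vd)
  stat <- sum(zd^2)
  # null: sum of correlated squared normals = weighted chi-square with
  # weights the eigenvalues of the correlation matrix of d; Satterthwaite
  # moment matching gives a scaled chi-square tail
  corr_d <- cov_d / sqrt(vd %o% vd)
  lam <- eigen(corr_d, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  a <- sum(lam^2) / sum(lam)
  g_df <- sum(lam)^2 / sum(lam^2)
  p <- pchisq(stat / a, df = g_df, lower.tail = FALSE)
  tibble::tibble(p_heidi = p, n_heidi_snps = length(d))
}

#' Bonferroni thresholds for SMR across trait sets
#'
#' @param n_traits Vector of tested-trait counts (e.g. number of pGenes
#'   and of eGenes).
#' @param alpha Family-wise level (default 0.05).
#' @return `alpha / n_traits`, named like the input.
#' @export
smr_thresholds <- function(n_traits, alpha = 0.05) {
  abort_if(any(n_traits <= 0), "trait counts must be positive")
  alpha / n_traits
}

#' SMR + HEIDI over a set of molecular traits
#'
#' For each trait with an eligible instrument (top QTL p below
#' `top_qtl_p_max`), runs the SMR test at the instrument and the HEIDI test
#' over the instrument's window, then assigns a verdict:
#' `"causal_or_pleiotropic"` when the SMR p passes the multiplicity rule
#' and HEIDI does not reject; `"linkage"` when HEIDI rejects (regardless of
#' SMR); otherwise `"not_significant"`. Traits with an undefined HEIDI p
#' get verdict `NA`.
#'
#' @param qtl_summaries Named list (by trait id) of per-variant QTL summary
#'   tibbles (`variant_id`, `b`, `se`, `p`).
#' @param gwas Per-variant GWAS summary tibble.
#' @param geno A [geno_matrix()] supplying the in-sample LD reference.
#' @param cfg An [smr_config()].
#' @return A tibble of class `smr_result`: per trait `instrument`,
#'   `b_xy`, `se_xy`, `T_smr`, `p_smr`, `p_heidi`, `n_heidi_snps`,
#'   `verdict`; the applied SMR threshold is attribute `smr_threshold`.
#' @export
run_smr <- function(qtl_summaries, gwas, geno, cfg = smr_config()) {
  rows <- purrr::imap(qtl_summaries, function(qs, tid) {
    qs <- normalize_assoc(qs)
    top <- qs[which.min(qs$p), ]
    if (top$p > cfg$top_qtl_p_max) return(NULL)
    gw <- gwas[match(top$variant_id, gwas$variant_id), ]
    if (is.na(gw$variant_id)) return(NULL)
    st <- smr_test(top$b, top$se, gw$b, gw$se)
    ids <- intersect(qs$variant_id, gwas$variant_id)
    ld <- cor(geno$dosages[, ids, drop = FALSE])
    ht <- heidi_test(qs[qs$variant_id %in% ids, ],
                     gwas[gwas$variant_id %in% ids, ],
                     ld, top$variant_id, cfg)
    dplyr::bind_cols(
      tibble::tibble(trait_id = tid, instrument = top$variant_id),
      st, ht
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(structure(out, class = c("smr_result", class(out))))
  thr <- if (cfg$correction == "bonferroni") {
    cfg$alpha / nrow(out)
  } else {
    # largest p_smr kept by BH at level alpha
    pa <- stats::p.adjust(out$p_smr, "BH")
    if (any(pa < cfg$alpha)) max(out$p_smr[pa < cfg$alpha]) else 0
  }
  out$verdict <- dplyr::case_when(
    is.na(out$p_heidi) ~ NA_character_,
    out$p_heidi < cfg$p_heidi_pass ~ "linkage",
    out$p_smr < thr ~ "causal_or_pleiotropic",
    TRUE ~ "not_significant"
  )
  structure(out, class = c("smr_result", class(out)), smr_threshold = thr)
}
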