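# Cis/trans QTL mapping with permutation-calibrated empirical p-values.
#
# Effect-sign convention throughout: slopes are reported in reference-allele
# orientation, i.e. a positive beta means higher expression in the presence
# of the reference allele (dosages store ALT counts, so the OLS slope on
# dosage is negated).

#' Window configuration for QTL mapping
#'
#' @param cis_window Distance from the TSS defining the cis window on each
#'   side (default 1 Mb).
#' @param trans_min_distance Minimum distance from the gene boundaries for
#'   a trans test (default 5 Mb); different chromosomes always qualify.
#' @param n_permutations Permutations for the empirical null
#'   (default 10,000).
#' @return A list of class `window_config`.
#' @export
window_config <- function(cis_window = 1e6, trans_min_distance = 5e6,
                          n_permutations = 10000L) {
  abort_if(cis_window <= 0, "cis_window must be positive")
  abort_if(trans_min_distance <= cis_window,
           "trans_min_distance must exceed cis_window")
  abort_if(!is_count(n_permutations), "n_permutations must be a count")
  structure(list(cis_window = cis_window,
                 trans_min_distance = trans_min_distance,
                 n_permutations = as.integer(n_permutations)),
            class = "window_config")
}

# indices of variants eligible for one trait
window_variants <- function(trait_row, variants, window, mode) {
  if (mode == "cis") {
    which(variants$chrom == trait_row$chrom &
            abs(variants$pos - trait_row$tss) <= window$cis_window)
  } else {
    other <- variants$chrom != trait_row$chrom
    dist_ok <- variants$pos < trait_row$gene_start - window$trans_min_distance |
      variants$pos > trait_row$gene_end + window$trans_min_distance
    which(other | (!other & dist_ok))
  }
}

#' Nominal association scan
#'
#' Per trait, regresses the (already covariate-corrected) trait on each
#' eligible variant's dosage and reports the slope in reference-allele
#' orientation, its standard error, t statistic and two-sided p-value on
#' `n - 2` degrees of freedom.
#'
#' @param traits A [trait_matrix()] (factor-corrected).
#' @param geno A [geno_matrix()] on the same samples.
#' @param window A [window_config()].
#' @param mode `"cis"` (TSS +/- `cis_window`) or `"trans"` (beyond
#'   `trans_min_distance` from the gene boundaries, or another chromosome).
#' @return A tibble: `trait_id`, `variant_id`, `chrom`, `pos`, `beta`,
#'   `se`, `tstat`, `p`, `maf`, `n`, `tss_distance` (signed, variant minus
#'   TSS). Traits with empty windows contribute no rows.
#' @export
nominal_scan <- function(traits, geno, window = window_config(), mode = c("cis", "trans")) {
  mode <- match.arg(mode)
  align_samples(traits, geno)
  Y <- traits$values
  ds <- geno$dosages
  n <- ncol(Y)
  res <- vector("list", nrow(Y))
  for (i in seq_len(nrow(Y))) {
    tr <- traits$traits[i, ]
    idx <- window_variants(tr, geno$variants, window, mode)
    if (length(idx) == 0) next
    marg <- marginal_scan(Y[i, ], 2 - ds[, idx, drop = FALSE])
    res[[i]] <- tibble::tibble(
      trait_id = tr$trait_id,
      variant_id = geno$variants$variant_id[idx],
      chrom = geno$variants$chrom[idx],
      pos = geno$variants$pos[idx],
      beta = marg$beta, se = marg$se, tstat = marg$t, p = marg$p,
      maf = geno$variants$maf[idx], n = n,
      tss_distance = geno$variants$pos[idx] - tr$tss
    )
  }
  dplyr::bind_rows(res)
}

align_samples <- function(traits, geno) {
  abort_if(ncol(traits$values) != nrow(geno$dosages) ||
             !identical(colnames(traits$values), rownames(geno$dosages)),
           "traits and genotypes must share the same sample order")
  invisible(TRUE)
}

# min nominal p over a window for R permutations, vectorized through BLAS:
# correlations of permuted traits with standardized dosages.
perm_min_pvalues <- function(y, G, R, seed) {
  n <- length(y)
  set.seed(seed)
  Yp <- matrix(0, n, R)
  for (r in seq_len(R)) Yp[, r] <- y[sample.int(n)]
  Yp <- sweep(Yp, 2, colMeans(Yp))
  Yp <- sweep(Yp, 2, sqrt(colSums(Yp^2)), `/`)
  Gc <- sweep(G, 2, colMeans(G))
  Gc <- sweep(Gc, 2, sqrt(colSums(Gc^2)), `/`)
  r2max <- apply(crossprod(Gc, Yp)^2, 2, max)
  tstat2 <- r2max * (n - 2) / (1 - r2max)
  2 * pt(sqrt(tstat2), n - 2, lower.tail = FALSE)
}

# Beta(a, b) maximum-likelihood fit with method-of-moments start
fit_beta_null <- function(x) {
  x <- pmin(pmax(x, 1e-300), 1 - 1e-16)
  m <- mean(x); v <- var(x)
  start <- if (is.finite(v) && v > 0 && v < m * (1 - m)) {
    k <- m * (1 - m) / v - 1
    list(shape1 = max(m * k, 1e-3), shape2 = max((1 - m) * k, 1e-3))
  } else {
    list(shape1 = 1, shape2 = 1)
  }
  fit <- tryCatch(
    suppressWarnings(fitdistrplus::fitdist(x, "beta", start = start)),
    error = function(e) NULL
  )
  if (is.null(fit) || !is.finite(fit$estimate[1]) || !is.finite(fit$estimate[2]) ||
      any(fit$estimate <= 0)) {
    return(list(shape1 = NA_real_, shape2 = NA_real_, converged = FALSE))
  }
  list(shape1 = unname(fit$estimate["shape1"]),
       shape2 = unname(fit$estimate["shape2"]), converged = TRUE)
}

#' Permutation pass: beta-approximated empirical p-values
#'
#' For each trait, permutes sample labels `n_permutations` times, records
#' the minimum nominal p-value across the trait's window per permutation,
#' fits a Beta distribution to those minima by maximum likelihood, and
#' reports the Beta CDF at the observed minimum as the adjusted empirical
#' p-value, alongside the direct empirical estimate
#' `(1 + #\{perm <= obs\}) / (R + 1)`. The top variant is the nominal-p
#' argmin, ties broken by smallest `|tss_distance|` then variant id. Each
#' trait draws its permutations from its own stream (`seed +` trait index)
#' so results do not depend on trait subsetting.
#'
#' @inheritParams nominal_scan
#' @param seed Integer seed for the permutation streams.
#' @return A tibble of class `qtl_scan`, one row per trait: top-variant
#'   `variant_id`, `beta`, `se`, `nominal_p`, `adjusted_p`,
#'   `direct_empirical_p`, `beta_shape1`, `beta_shape2`, `fit_converged`,
#'   `effective_tests`, `tss_distance`, `n_tested_variants`.
#' @export
permutation_pass <- function(traits, geno, window = window_config(),
                             mode = "cis", seed = 1L) {
  align_samples(traits, geno)
  R <- window$n_permutations
  rows <- vector("list", nrow(traits$values))
  for (i in seq_len(nrow(traits$values))) {
    tr <- traits$traits[i, ]
    idx <- window_variants(tr, geno$variants, window, mode)
    if (length(idx) == 0) {
      rows[[i]] <- tibble::tibble(
        trait_id = tr$trait_id, variant_id = NA_character_,
        beta = NA_real_, se = NA_real_, nominal_p = NA_real_,
        adjusted_p = NA_real_, direct_empirical_p = NA_real_,
        beta_shape1 = NA_real_, beta_shape2 = NA_real_,
        fit_converged = NA, effective_tests = NA_real_,
        tss_distance = NA_real_, n_tested_variants = 0L
      )
      next
    }
    y <- traits$values[i, ]
    nom <- marginal_scan(y, 2 - geno$dosages[, idx, drop = FALSE])
    ord <- order(nom$p, abs(geno$variants$pos[idx] - tr$tss),
                 geno$variants$variant_id[idx])
    top <- ord[1]
    obs_p <- max(nom$p[top], .Machine$double.xmin)
    pmin_null <- perm_min_pvalues(y, geno$dosages[, idx, drop = FALSE],
                                  R, seed + i)
    fit <- if (length(idx) > 1) fit_beta_null(pmin_null) else
      list(shape1 = 1, shape2 = 1, converged = TRUE)
    direct <- (1 + sum(pmin_null <= nom$p[top])) / (R + 1)
    adj <- if (fit$converged) pbeta(obs_p, fit$shape1, fit$shape2) else direct
    rows[[i]] <- tibble::tibble(
      trait_id = tr$trait_id,
      variant_id = geno$variants$variant_id[idx][top],
      beta = nom$beta[top], se = nom$se[top], nominal_p = nom$p[top],
      adjusted_p = adj, direct_empirical_p = direct,
      beta_shape1 = fit$shape1, beta_shape2 = fit$shape2,
      fit_converged = fit$converged,
      effective_tests = if (fit$converged) fit$shape2 else NA_real_,
      tss_distance = geno$variants$pos[idx][top] - tr$tss,
      n_tested_variants = length(idx)
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("qtl_scan", class(out))
  out
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 on the lambda grid 0.05, 0.10, ...,
#' 0.95 with a cubic-smoother extrapolation at the last lambda, clipped to
#' (0, 1], then computes `q_i = pi0 * min_{p_j >= p_i} (m * p_j / rank_j)`.
#' With fewer than 100 p-values pi0 is fixed at 1 (Benjamini-Hochberg
#' equivalent) with a warning.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed,
#'   propagated).
#' @param pi0 Optional fixed pi0 overriding estimation.
#' @return Vector of q-values, monotone nondecreasing in `p`.
#' @export
storey_qvalues <- function(p, pi0 = NULL) {
  ok <- !is.na(p)
  abort_if(any(p[ok] < 0 | p[ok] > 1), "p-values must lie in [0, 1]")
  pv <- p[ok]
  m <- length(pv)
  if (is.null(pi0)) {
    if (m < 100) {
      warning("fewer than 100 p-values; fixing pi0 = 1 (BH-equivalent)")
      pi0 <- 1
    } else {
      lambda <- seq(0.05, 0.95, by = 0.05)
      pi0_l <- vapply(lambda, function(l) mean(pv > l) / (1 - l), 0)
      sp <- smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(sp, x = max(lambda))$y
      pi0 <- min(max(pi0, .Machine$double.eps), 1)
    }
  }
  ord <- order(pv, decreasing = TRUE)
  q <- pi0 * m * pv[ord] / rank(pv, ties.method = "max")[ord]
  q <- pmin(cummin(q), 1)
  out <- rep(NA_real_, length(p))
  out[ok] <- q[order(ord)]
  attr(out, "pi0") <- pi0
  out
}

#' Append q-values to a permutation-pass result
#'
#' @param scan A `qtl_scan` tibble from [permutation_pass()].
#' @param ... Passed to [storey_qvalues()].
#' @return The tibble with a `qvalue` column; pi0 attached as attribute.
#' @export
add_qvalues <- function(scan, ...) {
  q <- storey_qvalues(scan$adjusted_p, ...)
  scan$qvalue <- as.numeric(q)
  attr(scan, "pi0") <- attr(q, "pi0")
  scan
}

#' @rdname permutation_pass
#' @param x A `qtl_scan`.
#' @param q_cutoff Cutoff counted as significant when `qvalue` is present.
#' @param ... Unused.
#' @export
glance.qtl_scan <- function(x, q_cutoff = 0.05, ...) {
  tibble::tibble(
    n_traits = nrow(x),
    n_tested = sum(x$n_tested_variants > 0),
    n_significant = if ("qvalue" %in% names(x)) {
      sum(x$qvalue < q_cutoff, na.rm = TRUE)
    } else {
      NA_integer_
    },
    pi0 = attr(x, "pi0") %||% NA_real_
  )
}

#' Genome-wide Bonferroni threshold for trans scans
#'
#' @param n_variants,n_traits Numbers of genotyped variants and tested
#'   traits.
#' @param alpha Family-wise error target (default 0.05).
#' @return `alpha / (n_variants * n_traits)`.
#' @export
trans_threshold <- function(n_variants, n_traits, alpha = 0.05) {
  abort_if(!is_count(n_variants) || !is_count(n_traits),
           "variant and trait counts must be positive")
  alpha / (n_variants * n_traits)
}

#' Annotation and positional summary of significant QTLs
#'
#' @param records A `qtl_scan` with `qvalue` (see [add_qvalues()]).
#' @param variants Variant metadata tibble with `variant_id`, `anno_class`.
#' @param q_cutoff Significance cutoff (default 0.05).
#' @param tss_window Distance for the TSS-proximity fraction (default
#'   10 kb).
#' @return A list of tibbles: `by_class` (fraction per annotation class),
#'   `tss` (fraction of QTLs within `tss_window` of the TSS),
#'   `nonsynonymous` (exonic fraction, non-synonymous fraction within
#'   exonic, and their product — the overall non-synonymous fraction),
#'   `pleiotropy` (fraction of QTL variants associated with more than one
#'   trait).
#' @export
summarize_annotations <- function(records, variants, q_cutoff = 0.05,
                                  tss_window = 10000) {
  sig <- records[!is.na(records$qvalue) & records$qvalue < q_cutoff, ]
  sig <- dplyr::left_join(sig, variants[, c("variant_id", "anno_class")],
                          by = "variant_id")
  n <- nrow(sig)
  by_class <- sig |>
    dplyr::count(.data$anno_class) |>
    dplyr::mutate(fraction = .data$n / !!n)
  exonic <- mean(sig$anno_class %in% c("exonic_nonsyn", "exonic_syn"))
  nonsyn_within <- if (exonic > 0) {
    mean(sig$anno_class[sig$anno_class %in% c("exonic_nonsyn", "exonic_syn")] ==
           "exonic_nonsyn")
  } else {
    NA_real_
  }
  list(
    by_class = by_class,
    tss = tibble::tibble(
      n_within = sum(abs(sig$tss_distance) <= tss_window),
      n_total = n,
      fraction = mean(abs(sig$tss_distance) <= tss_window)
    ),
    nonsynonymous = tibble::tibble(
      exonic_fraction = exonic,
      nonsyn_within_exonic = nonsyn_within,
      overall_nonsyn = exonic * nonsyn_within
    ),
    pleiotropy = tibble::tibble(
      n_variants = length(unique(sig$variant_id)),
      fraction_multi_trait = if (n > 0) {
        mean(table(sig$variant_id) > 1)
      } else {
        NA_real_
      }
    )
  )
}

#' Map QTLs: permutation pass plus genome-wide FDR
#'
#' Convenience wrapper running [permutation_pass()] and [add_qvalues()].
#'
#' @inheritParams permutation_pass
#' @param ... Passed to [storey_qvalues()].
#' @return A `qtl_scan` tibble with `qvalue`.
#' @export
map_qtl <- function(traits, geno, window = window_config(), mode = "cis",
                    seed = 1L, ...) {
  add_qvalues(permutation_pass(traits, geno, window, mode, seed), ...)
}
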