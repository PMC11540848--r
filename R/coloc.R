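# Five-hypothesis Bayesian colocalization of two association signals over
# a shared variant window, from per-variant summary statistics via
# Wakefield approximate Bayes factors.

# accept either the AssocSummary dialect (b) or nominal_scan output (beta)
normalize_assoc <- function(assoc) {
  if (!("b" %in% names(assoc)) && "beta" %in% names(assoc)) {
    assoc$b <- assoc$beta
  }
  abort_if(!all(c("variant_id", "b") %in% names(assoc)),
           "association summaries need variant_id and b (or beta)")
  assoc
}

#' Approximate Bayes factors from association summaries
#'
#' Per variant, `log ABF = 0.5 * (log(V / (V + W)) + z^2 * W / (V + W))`
#' with `V = se^2` and prior effect variance `W`. When `se` is absent it is
#' reconstructed as `1 / sqrt(2 * n * maf * (1 - maf))` (standardized
#' phenotype approximation).
#'
#' @param assoc Tibble with `variant_id`, `b`, `se` (or `p`, `maf`, `n`).
#' @param W Prior variance of the effect size (default `0.15^2`).
#' @return The tibble with a `labf` column; variants with nonpositive `se`
#'   are dropped with a message.
#' @export
approximate_bayes_factors <- function(assoc, W = 0.15^2) {
  abort_if(W <= 0, "prior variance W must be positive")
  assoc <- normalize_assoc(assoc)
  if (!("se" %in% names(assoc)) || all(is.na(assoc$se))) {
    abort_if(!all(c("maf", "n") %in% names(assoc)),
             "need se, or maf and n to reconstruct it")
    assoc$se <- 1 / sqrt(2 * assoc$n * assoc$maf * (1 - assoc$maf))
  }
  bad <- !is.finite(assoc$se) | assoc$se <= 0
  if (any(bad)) {
    message(sprintf("dropping %d variant(s) with nonpositive se", sum(bad)))
    assoc <- assoc[!bad, , drop = FALSE]
  }
  V <- assoc$se^2
  z2 <- (assoc$b / assoc$se)^2
  assoc$labf <- 0.5 * (log(V / (V + W)) + z2 * W / (V + W))
  assoc
}

#' Colocalize two association signals
#'
#' Computes posterior probabilities of the five hypotheses over
#' single-causal-variant configurations: H0 no causal variant for either
#' trait; H1/H2 a causal variant for one trait only; H3 two distinct
#' causal variants; H4 one shared causal variant. Variants are intersected
#' on id; when the two tables disagree on effect/other allele the slope of
#' the second is flipped before use (the posteriors themselves depend on z
#' only through its square).
#'
#' @param assoc1,assoc2 Summary tibbles (`variant_id`, `b`, `se`, and
#'   `A1`/`A2` if allele alignment is needed).
#' @param p1,p2 Prior probability a variant is causal for trait 1 / 2 only
#'   (defaults 1e-4).
#' @param p12 Prior probability a variant is causal for both (default
#'   1e-5).
#' @param W Prior effect variance for both traits.
#' @return A one-row tibble of class `coloc_result`: `PP0` .. `PP4`,
#'   `n_snps`.
#' @export
colocalize <- function(assoc1, assoc2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                       W = 0.15^2) {
  abort_if(p1 + p2 + p12 >= 1, "priors must sum to < 1")
  shared <- intersect(assoc1$variant_id, assoc2$variant_id)
  abort_if(length(shared) < 2,
           "need at least 2 shared variants to colocalize")
  a1 <- assoc1[match(shared, assoc1$variant_id), ]
  a2 <- assoc2[match(shared, assoc2$variant_id), ]
  if (all(c("A1", "A2") %in% names(a1)) && all(c("A1", "A2") %in% names(a2))) {
    swapped <- a1$A1 == a2$A2 & a1$A2 == a2$A1
    a2$b[swapped] <- -a2$b[swapped]
    mism <- !(swapped | (a1$A1 == a2$A1 & a1$A2 == a2$A2))
    if (any(mism)) {
      message(sprintf("dropping %d variant(s) with incompatible alleles", sum(mism)))
      a1 <- a1[!mism, ]; a2 <- a2[!mism, ]
      abort_if(nrow(a1) < 2, "fewer than 2 allele-compatible shared variants")
    }
  }
  l1 <- approximate_bayes_factors(a1, W)$labf
  l2 <- approximate_bayes_factors(a2, W)$labf

  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)
  lH0 <- 0
  lH1 <- log(p1) + s1
  lH2 <- log(p2) + s2
  lH3 <- log(p1) + log(p2) + logdiffexp(s1 + s2, s12)
  lH4 <- log(p12) + s12
  lse <- logsumexp(c(lH0, lH1, lH2, lH3, lH4))
  pp <- exp(c(lH0, lH1, lH2, lH3, lH4) - lse)
  out <- tibble::tibble(
    PP0 = pp[1], PP1 = pp[2], PP2 = pp[3], PP3 = pp[4], PP4 = pp[5],
    n_snps = length(l1)
  )
  structure(out, class = c("coloc_result", class(out)))
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "<coloc_result> %d SNPs | PP0=%.3f PP1=%.3f PP2=%.3f PP3=%.3f PP4=%.3f\n",
    x$n_snps, x$PP0, x$PP1, x$PP2, x$PP3, x$PP4
  ))
  invisible(x)
}

#' @rdname colocalize
#' @param x A `coloc_result`.
#' @param ... Unused.
#' @export
tidy.coloc_result <- function(x, ...) {
  tibble::tibble(
    hypothesis = paste0("H", 0:4),
    description = c("no causal variant",
                    "causal variant for trait 1 only",
                    "causal variant for trait 2 only",
                    "two distinct causal variants",
                    "one shared causal variant"),
    posterior = c(x$PP0, x$PP1, x$PP2, x$PP3, x$PP4)
  )
}

#' @rdname colocalize
#' @param pp4_cutoff Colocalization call threshold; 0.8 is the stringent
#'   convention, 0.5 the permissive one — both are in circulation, so the
#'   cutoff is explicit.
#' @export
glance.coloc_result <- function(x, pp4_cutoff = 0.8, ...) {
  tibble::tibble(
    n_snps = x$n_snps, PP4 = x$PP4,
    colocalized = x$PP4 > pp4_cutoff,
    pp4_cutoff = pp4_cutoff
  )
}

#' Colocalize a QTL pair over a window around the top variant
#'
#' Restricts both summary tables to `window` around the lead variant's
#' position before calling [colocalize()].
#'
#' @inheritParams colocalize
#' @param variants Variant metadata with `variant_id`, `chrom`, `pos`.
#' @param lead_variant Variant id anchoring the window (typically the top
#'   pQTL).
#' @param window Half-width in bp (default 500 kb each side).
#' @param ... Passed to [colocalize()].
#' @return A `coloc_result`.
#' @export
colocalize_window <- function(assoc1, assoc2, variants, lead_variant,
                              window = 5e5, ...) {
  v <- variants[match(lead_variant, variants$variant_id), ]
  abort_if(nrow(v) != 1 || is.na(v$variant_id), "lead_variant not found")
  keep <- variants$variant_id[variants$chrom == v$chrom &
                                abs(variants$pos - v$pos) <= window]
  colocalize(assoc1[assoc1$variant_id %in% keep, ],
             assoc2[assoc2$variant_id %in% keep, ], ...)
}
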