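# Hidden-factor correction of molecular trait matrices: principal-component
# factors on centred/scaled traits, OLS residualization against known
# covariates plus factors, and rank-based inverse-normal transformation.

trait_values <- function(traits) {
  if (inherits(traits, "trait_matrix")) traits$values
  else if (inherits(traits, "protein_matrix")) unclass(traits)
  else as.matrix(traits)
}

#' Estimate hidden-factor scores by PCA
#'
#' Traits are centred and unit-scaled; missing values are mean-imputed for
#' factor estimation only. Sample scores of the leading principal
#' components serve as hidden-factor estimates; with `n_factors = "auto"`
#' the smallest number of components whose cumulative explained variance
#' reaches `variance_target` is used.
#'
#' @param traits A [trait_matrix()], `protein_matrix`, or traits x samples
#'   numeric matrix.
#' @param n_factors Number of factors, or `"auto"`.
#' @param variance_target Cumulative explained-variance target for
#'   `"auto"` (default 0.99).
#' @return An object of class `factor_fit`: `scores` (samples x K),
#'   `sdev`, `var_explained`, `k`.
#' @export
estimate_factors <- function(traits, n_factors = "auto", variance_target = 0.99) {
  abort_if(!(variance_target > 0 && variance_target <= 1),
           "variance_target must be in (0, 1]")
  X <- t(trait_values(traits))            # samples x traits
  n <- nrow(X)
  keep <- apply(X, 2, function(x) var(x, na.rm = TRUE) > 0)
  if (!all(keep)) {
    warning(sprintf("dropping %d constant trait(s) before factor estimation",
                    sum(!keep)))
    X <- X[, keep, drop = FALSE]
  }
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- mean(X[, j], na.rm = TRUE)
  }
  if (!identical(n_factors, "auto")) {
    abort_if(!is_count(n_factors), "n_factors must be a count or \"auto\"")
    abort_if(n >= 2 && n < n_factors + 2, "need n_samples >= n_factors + 2")
  }
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- if (identical(n_factors, "auto")) {
    max(1L, which(cumsum(ve) >= variance_target)[1])
  } else {
    as.integer(n_factors)
  }
  abort_if(is.na(k) || k >= n, "cannot estimate that many factors")
  structure(
    list(scores = pc$x[, seq_len(k), drop = FALSE], sdev = pc$sdev,
         var_explained = ve, k = k),
    class = "factor_fit"
  )
}

#' @export
print.factor_fit <- function(x, ...) {
  cat(sprintf("<factor_fit> %d factor(s) explaining %.1f%% of variance\n",
              x$k, 100 * sum(x$var_explained[seq_len(x$k)])))
  invisible(x)
}

#' @rdname estimate_factors
#' @param x A `factor_fit`.
#' @param ... Unused.
#' @export
tidy.factor_fit <- function(x, ...) {
  tibble::as_tibble(x$scores, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "factor", values_to = "score")
}

#' @rdname estimate_factors
#' @export
glance.factor_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    var_explained = sum(x$var_explained[seq_len(x$k)]),
    n_samples = nrow(x$scores)
  )
}

#' Residualize traits against covariates and hidden factors
#'
#' Per trait, replaces values by OLS residuals against an intercept, the
#' known covariates and the factor scores. Collinear design columns are
#' dropped with a warning; samples missing a trait keep their missing
#' status.
#'
#' @param traits A [trait_matrix()] or traits x samples matrix.
#' @param factors A `factor_fit` or samples x K score matrix (optional).
#' @param covariates Samples x covariates numeric matrix (optional).
#' @return Same container type as `traits`, residualized.
#' @export
residualize <- function(traits, factors = NULL, covariates = NULL) {
  Y <- trait_values(traits)
  n <- ncol(Y)
  F <- if (inherits(factors, "factor_fit")) factors$scores else factors
  X <- cbind(`(Intercept)` = rep(1, n), covariates, F)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning(sprintf("dropping %d collinear design column(s)", ncol(X) - qrX$rank))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  out <- Y
  complete <- !apply(Y, 1, anyNA)
  if (any(complete)) {
    # one QR serves every complete trait
    res <- t(qr.resid(qrX, t(Y[complete, , drop = FALSE])))
    out[complete, ] <- res
  }
  for (i in which(!complete)) {
    ok <- !is.na(Y[i, ])
    out[i, ok] <- qr.resid(qr(X[ok, , drop = FALSE]), Y[i, ok])
  }
  if (inherits(traits, "trait_matrix")) set_values(traits, out) else out
}

#' Rank-based inverse-normal transform
#'
#' Per trait, replaces values by standard-normal quantiles of
#' `(rank - 0.5) / n` over non-missing entries, ties averaged. Traits with
#' fewer than `min_n` non-missing values are excluded with a message.
#'
#' @param traits A [trait_matrix()] or traits x samples matrix.
#' @param min_n Minimum non-missing values per trait (default 10).
#' @return Same container type, transformed (excluded traits dropped).
#' @export
inverse_normal_transform <- function(traits, min_n = 10L) {
  Y <- trait_values(traits)
  n_ok <- rowSums(!is.na(Y))
  drop <- n_ok < min_n
  if (any(drop)) {
    message(sprintf("excluding %d trait(s) with < %d non-missing values",
                    sum(drop), min_n))
    Y <- Y[!drop, , drop = FALSE]
  }
  out <- t(apply(Y, 1, int_values))
  colnames(out) <- colnames(Y)
  if (inherits(traits, "trait_matrix")) {
    trait_matrix(out, traits$traits[!drop, , drop = FALSE])
  } else {
    out
  }
}

#' Full trait-correction chain
#'
#' Estimates hidden factors, residualizes against them (plus any known
#' covariates) and applies the inverse-normal transform — the preprocessing
#' applied to every trait matrix before QTL mapping.
#'
#' @inheritParams estimate_factors
#' @inheritParams residualize
#' @return A corrected container of the same type, with the `factor_fit`
#'   attached as attribute `factor_fit`.
#' @export
correct_traits <- function(traits, covariates = NULL, n_factors = "auto",
                           variance_target = 0.99) {
  fit <- estimate_factors(traits, n_factors, variance_target)
  out <- residualize(traits, fit, covariates)
  out <- inverse_normal_transform(out)
  attr(out, "factor_fit") <- fit
  out
}
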