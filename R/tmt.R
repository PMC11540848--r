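# PSM-to-protein quantification for isobaric (TMT) reporter-ion data:
# impurity correction -> intensity filters -> trimmed-median channel
# normalization -> protein summarization -> internal-standard bridging.

channel_cols <- function(psm) {
  grep("^channel_\\d+$", names(psm), value = TRUE)
}

psm_matrix <- function(psm) {
  as.matrix(psm[, channel_cols(psm)])
}

#' Validate a label-impurity matrix
#'
#' @param M Square channel-by-channel spillover matrix; `M[i, j]` is the
#'   fraction of channel `j`'s signal read in channel `i`.
#' @param n_channels Expected dimension.
#' @return `M` invisibly; the estimated condition number is attached as
#'   attribute `kappa`.
#' @export
validate_impurity <- function(M, n_channels = 11L) {
  abort_if(!is.matrix(M) || nrow(M) != ncol(M), "impurity matrix must be square")
  abort_if(nrow(M) != n_channels,
           sprintf("impurity matrix must be %d x %d", n_channels, n_channels))
  abort_if(any(colSums(M) > 1 + 1e-9), "impurity columns must sum to <= 1")
  abort_if(any(diag(M) <= 0.5), "impurity matrix must be diagonally dominant")
  k <- kappa(M)
  abort_if(!is.finite(k) || k > 1e12, "impurity matrix is numerically singular")
  invisible(structure(M, kappa = k))
}

#' Build a banded TMT impurity matrix
#'
#' Convenience constructor with a given fraction of signal spilling into
#' each adjacent channel (reporter-isotope +/-1 contamination).
#'
#' @param spill Fraction of each channel's signal read in each neighbour.
#' @param n_channels Number of channels.
#' @return The impurity matrix.
#' @export
impurity_matrix <- function(spill = 0.05, n_channels = 11L) {
  M <- diag(1 - 2 * spill, n_channels)
  idx <- seq_len(n_channels - 1)
  M[cbind(idx, idx + 1)] <- spill
  M[cbind(idx + 1, idx)] <- spill
  M[1, 1] <- M[n_channels, n_channels] <- 1 - spill
  M
}

#' Correct reporter intensities for label impurity
#'
#' Solves `M %*% t = observed` per PSM and replaces the observed intensity
#' vector by the solution `t`; negative solutions are clipped to zero.
#'
#' @param psm PSM tibble with `channel_*` columns.
#' @param M Impurity matrix (see [validate_impurity()]).
#' @return The PSM tibble with corrected intensities.
#' @export
correct_impurity <- function(psm, M) {
  validate_impurity(M, n_channels = length(channel_cols(psm)))
  X <- psm_matrix(psm)
  corrected <- t(solve(M, t(X)))
  corrected[corrected < 0] <- 0
  psm[, channel_cols(psm)] <- as.data.frame(corrected)
  psm
}

#' Filter low-intensity PSMs
#'
#' Retains PSMs whose per-channel minimum and median intensities reach the
#' thresholds (boundaries inclusive).
#'
#' @param psm PSM tibble.
#' @param min_intensity Minimum per-channel intensity (default 1000).
#' @param median_intensity Minimum per-channel median intensity
#'   (default 5000).
#' @return Filtered PSM tibble; warns when nothing survives.
#' @export
filter_psms <- function(psm, min_intensity = 1000, median_intensity = 5000) {
  X <- psm_matrix(psm)
  keep <- apply(X, 1, min) >= min_intensity &
    apply(X, 1, median) >= median_intensity
  out <- psm[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no PSMs survive the intensity filters")
  out
}

# channel medians over PSMs kept after trimming by overall (row-mean)
# intensity; returns the kept row index, per-channel medians and the grand
# trimmed median
trimmed_channel_medians <- function(X, trim_fraction) {
  n <- nrow(X)
  drop_k <- floor(n * trim_fraction)
  ord <- order(rowMeans(X))
  keep <- if (drop_k > 0) ord[(drop_k + 1):(n - drop_k)] else ord
  kept <- X[keep, , drop = FALSE]
  ch <- apply(kept, 2, median)
  # batch target = median of the channel medians, so balanced channels get
  # unit factors exactly
  list(keep = keep, channel = ch, grand = median(ch))
}

#' Normalize channel abundances by trimmed median
#'
#' Per batch, ranks PSMs by overall (row-mean) intensity, drops the top and
#' bottom `trim_fraction`, and scales every channel so its median over the
#' kept PSMs equals the batch's grand trimmed median. Batches with fewer
#' than 10 PSMs fall back to untrimmed medians with a warning.
#'
#' @param psm Filtered PSM tibble.
#' @param trim_fraction Fraction trimmed from each tail (default 0.1).
#' @return Normalized PSM tibble; per-batch scale factors attached as
#'   attribute `scale_factors`.
#' @export
normalize_channels <- function(psm, trim_fraction = 0.1) {
  cc <- channel_cols(psm)
  sf <- list()
  for (b in unique(psm$batch_id)) {
    rows <- which(psm$batch_id == b)
    X <- as.matrix(psm[rows, cc])
    tf <- trim_fraction
    if (length(rows) < 10) {
      warning(sprintf("batch %s has < 10 PSMs; using untrimmed medians", b))
      tf <- 0
    }
    tm <- trimmed_channel_medians(X, tf)
    fac <- tm$grand / tm$channel
    psm[rows, cc] <- as.data.frame(sweep(X, 2, fac, `*`))
    sf[[b]] <- fac
  }
  attr(psm, "scale_factors") <- sf
  psm
}

#' Summarize PSMs to protein-level intensities
#'
#' Per PSM, relative intensity is channel over PSM mean; per protein,
#' relative intensity is the mean over its PSMs (linear scale), and
#' absolute intensity is the relative intensity times the grand mean of the
#' protein's three most intense PSMs (all PSMs when fewer than three).
#' Output is log2-transformed.
#'
#' @param psm Normalized PSM tibble (one batch, or use the `batch_id`
#'   grouping via [quantify_batches()]).
#' @param log_scale_average Average relative intensities on the log scale
#'   instead of the linear scale (default linear).
#' @return A `protein_matrix`: proteins x channels matrix of log2
#'   intensities with a `n_psm` attribute.
#' @export
summarize_proteins <- function(psm, log_scale_average = FALSE) {
  abort_if(length(unique(psm$batch_id)) > 1,
           "summarize_proteins works on one batch; see quantify_batches()")
  X <- psm_matrix(psm)
  keep <- rowMeans(X) > 0
  if (!all(keep)) {
    message(sprintf("dropping %d PSM(s) with zero total intensity", sum(!keep)))
    psm <- psm[keep, , drop = FALSE]
    X <- X[keep, , drop = FALSE]
  }
  rel <- X / rowMeans(X)
  prots <- unique(psm$protein_id)
  out <- matrix(NA_real_, length(prots), ncol(X),
                dimnames = list(prots, channel_cols(psm)))
  n_psm <- integer(length(prots))
  for (i in seq_along(prots)) {
    rows <- which(psm$protein_id == prots[i])
    n_psm[i] <- length(rows)
    prel <- if (log_scale_average) {
      2^colMeans(log2(rel[rows, , drop = FALSE]))
    } else {
      colMeans(rel[rows, , drop = FALSE])
    }
    top <- rows[order(rowMeans(X)[rows], decreasing = TRUE)]
    top <- top[seq_len(min(3L, length(top)))]
    grand <- mean(X[top, , drop = FALSE])
    out[i, ] <- log2(prel * grand)
  }
  structure(out, n_psm = setNames(n_psm, prots), class = "protein_matrix")
}

#' Bridge batches on the internal-standard channel
#'
#' Subtracts (on log2 scale) each batch's internal-standard channel from
#' its sample channels, removing batch-level shifts, then concatenates
#' batches over the union of proteins; proteins unobserved in a batch are
#' missing for that batch's samples.
#'
#' @param per_batch Named list of `protein_matrix` objects, one per batch.
#' @param sample_map Tibble with `batch_id`, `channel`, `sample_id`; the
#'   internal-standard channel is identified by `is_channel`.
#' @param is_channel Index of the internal-standard channel (default 11).
#' @return A `protein_matrix` of IS-centred log2 ratios, proteins x
#'   samples.
#' @export
bridge_batches <- function(per_batch, sample_map, is_channel = 11L) {
  abort_if(length(per_batch) == 0, "no batches supplied")
  prots <- sort(unique(unlist(lapply(per_batch, rownames))))
  cols <- list()
  for (b in names(per_batch)) {
    pm <- per_batch[[b]]
    abort_if(ncol(pm) < is_channel,
             sprintf("batch %s lacks the internal-standard channel", b))
    centred <- pm[, -is_channel, drop = FALSE] - pm[, is_channel]
    smap <- sample_map[sample_map$batch_id == b & sample_map$channel != is_channel, ]
    abort_if(nrow(smap) != ncol(centred), "sample_map does not cover the sample channels")
    colnames(centred) <- smap$sample_id[order(smap$channel)]
    padded <- matrix(NA_real_, length(prots), ncol(centred),
                     dimnames = list(prots, colnames(centred)))
    padded[rownames(centred), ] <- centred
    cols[[b]] <- padded
  }
  out <- do.call(cbind, cols)
  colnames(out) <- unlist(lapply(cols, colnames), use.names = FALSE)
  structure(out, class = "protein_matrix")
}

#' Run the full PSM-to-protein quantification chain
#'
#' Applies impurity correction, intensity filtering, trimmed-median channel
#' normalization and protein summarization per batch, then internal-standard
#' bridging across batches.
#'
#' @param psm PSM tibble covering one or more batches.
#' @param sample_map Batch/channel/sample mapping (see [bridge_batches()]).
#' @param impurity Impurity matrix; identity skips correction.
#' @param min_intensity,median_intensity Filter thresholds.
#' @param trim_fraction Normalization trim fraction.
#' @param normalize Apply trimmed-median channel normalization (default
#'   TRUE; turn off when channels are known to be load-balanced).
#' @param is_channel Internal-standard channel index.
#' @return A `protein_matrix` of log2 IS-centred abundances.
#' @export
quantify_batches <- function(psm, sample_map, impurity = diag(11),
                             min_intensity = 1000, median_intensity = 5000,
                             trim_fraction = 0.1, normalize = TRUE,
                             is_channel = 11L) {
  psm <- correct_impurity(psm, impurity)
  psm <- filter_psms(psm, min_intensity, median_intensity)
  if (normalize) psm <- normalize_channels(psm, trim_fraction)
  batches <- split(psm, psm$batch_id)
  per_batch <- lapply(batches, summarize_proteins)
  bridge_batches(per_batch, sample_map, is_channel)
}
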