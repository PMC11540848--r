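#' Genotype dosage container
#'
#' Bundles a samples-by-variants dosage matrix (ALT-allele dosage in
#' `[0, 2]`, the VCF `DS` convention) with a per-variant metadata table.
#'
#' @param dosages Numeric matrix, samples in rows, variants in columns;
#'   entries in `[0, 2]`. Row names are sample ids, column names variant ids.
#' @param variants A data frame with one row per variant: `variant_id`,
#'   `chrom`, `pos` (1-based), `ref`, `alt`, `maf`, `anno_class`.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosages, variants) {
  variants <- tibble::as_tibble(variants)
  abort_if(!is.matrix(dosages) || !is.numeric(dosages), "dosages must be a numeric matrix")
  abort_if(ncol(dosages) != nrow(variants), "one metadata row per variant column required")
  abort_if(any(dosages < 0 | dosages > 2, na.rm = TRUE), "dosages must lie in [0, 2]")
  abort_if(anyDuplicated(rownames(dosages)) > 0, "sample ids must be unique")
  abort_if(anyDuplicated(variants$variant_id) > 0, "variant ids must be unique")
  v <- apply(dosages, 2, var)
  abort_if(any(v == 0), "constant dosage columns are not allowed")
  colnames(dosages) <- variants$variant_id
  structure(list(dosages = dosages, variants = variants), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d samples x %d variants on %d chromosome(s)\n",
    nrow(x$dosages), ncol(x$dosages), length(unique(x$variants$chrom))
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Molecular trait container
#'
#' Holds a traits-by-samples abundance matrix together with gene-level
#' coordinates used to define cis windows (TSS anchored) and trans
#' distances (gene boundaries).
#'
#' @param values Numeric matrix, traits in rows, samples in columns.
#' @param traits A data frame with one row per trait: `trait_id`, `gene_id`,
#'   `chrom`, `tss`, `gene_start`, `gene_end`, `strand`.
#' @return An object of class `trait_matrix`.
#' @export
trait_matrix <- function(values, traits) {
  traits <- tibble::as_tibble(traits)
  abort_if(!is.matrix(values) || !is.numeric(values), "values must be a numeric matrix")
  abort_if(nrow(values) != nrow(traits), "one metadata row per trait required")
  abort_if(anyDuplicated(traits$trait_id) > 0, "trait ids must be unique")
  all_na <- apply(values, 1, function(r) all(is.na(r)))
  abort_if(any(all_na), "traits with all-missing values are not allowed")
  plus <- traits$strand == "+"
  ok <- ifelse(plus,
    traits$gene_start <= traits$tss & traits$tss <= traits$gene_end,
    traits$gene_start <= traits$tss & traits$tss <= traits$gene_end
  )
  abort_if(any(!ok), "tss must lie within [gene_start, gene_end]")
  rownames(values) <- traits$trait_id
  structure(list(values = values, traits = traits), class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf(
    "<trait_matrix> %d traits x %d samples\n",
    nrow(x$values), ncol(x$values)
  ))
  invisible(x)
}

#' @export
dim.trait_matrix <- function(x) dim(x$values)

#' @rdname geno_matrix
#' @param x A `geno_matrix`.
#' @param ... Unused.
#' @export
tidy.geno_matrix <- function(x, ...) {
  tibble::as_tibble(x$dosages, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "variant_id", values_to = "dosage") |>
    dplyr::left_join(x$variants, by = "variant_id")
}

#' @rdname trait_matrix
#' @param x A `trait_matrix`.
#' @param ... Unused.
#' @export
tidy.trait_matrix <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "trait_id") |>
    tidyr::pivot_longer(-"trait_id", names_to = "sample_id", values_to = "value") |>
    dplyr::left_join(x$traits, by = "trait_id")
}

# replace the value matrix, keeping metadata aligned
set_values <- function(traits, values) {
  trait_matrix(values, traits$traits)
}
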