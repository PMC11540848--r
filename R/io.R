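# Readers and writers for the pipeline's file dialects: VCF v4.2 with a DS
# dosage field, dosage TSV, QTLtools-style phenotype BED (0-based start,
# 1-based end), GCTA ".ma" GWAS summary TSV, and PSM TSV.
# Coordinates are 1-based inclusive in memory; BED conversion happens at
# the file boundary.

#' Write genotype dosages as VCF v4.2 (DS format field)
#'
#' @param geno A [geno_matrix()].
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_dosage_vcf <- function(geno, path) {
  v <- geno$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated ALT dose\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno$dosages)), collapse = "\t")
  ), con)
  body <- cbind(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS", ".",
                "DS", t(format(geno$dosages, trim = TRUE, digits = 10)))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read genotype dosages from a VCF with a DS field
#'
#' @param path VCF path (plain or gzipped).
#' @param anno Optional tibble `variant_id`, `anno_class` supplying
#'   annotation labels (annotation is input metadata, not computed).
#' @return A [geno_matrix()].
#' @export
read_dosage_vcf <- function(path, anno = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcf@fix, stringsAsFactors = FALSE))
  ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  abort_if(is.null(ds) || all(is.na(ds)), sprintf("%s: no DS field found", path))
  abort_if(anyDuplicated(fix$ID) > 0, sprintf("%s: duplicate variant ids", path))
  dosages <- t(ds)
  maf <- fold_maf(colMeans(dosages) / 2)
  variants <- tibble::tibble(
    variant_id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, maf = maf,
    anno_class = NA_character_
  )
  if (!is.null(anno)) {
    variants$anno_class <- anno$anno_class[match(variants$variant_id,
                                                 anno$variant_id)]
  }
  geno_matrix(dosages, variants)
}

#' Write / read a plain dosage TSV
#'
#' Columns: `variant_id`, `chrom`, `pos`, `ref`, `alt`, `maf`,
#' `anno_class`, then one column per sample.
#'
#' @param geno A [geno_matrix()]; `path` a file path.
#' @return `path` / a [geno_matrix()].
#' @export
write_dosage_tsv <- function(geno, path) {
  df <- dplyr::bind_cols(geno$variants,
                         tibble::as_tibble(t(geno$dosages)))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @param path File path.
#' @export
read_dosage_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta_cols <- c("variant_id", "chrom", "pos", "ref", "alt", "maf", "anno_class")
  abort_if(!all(meta_cols %in% names(df)),
           sprintf("%s: missing dosage TSV metadata columns", path))
  ds <- t(as.matrix(df[, setdiff(names(df), meta_cols)]))
  geno_matrix(ds, df[, meta_cols])
}

#' Write a phenotype BED (QTLtools dialect)
#'
#' Tab-separated with header `#chr start end id strand` followed by one
#' column per sample; `start` is the 0-based TSS position, `end` the
#' 1-based TSS.
#'
#' @param traits A [trait_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotype_bed <- function(traits, path) {
  tr <- traits$traits
  df <- dplyr::bind_cols(
    tibble::tibble(
      `#chr` = tr$chrom, start = tr$tss - 1L, end = tr$tss,
      id = tr$trait_id, gene_id = tr$gene_id,
      gene_start = tr$gene_start, gene_end = tr$gene_end,
      strand = tr$strand
    ),
    tibble::as_tibble(traits$values)
  )
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a phenotype BED (QTLtools dialect)
#'
#' @param path BED path as written by [write_phenotype_bed()].
#' @return A [trait_matrix()].
#' @export
read_phenotype_bed <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(df)[1] <- sub("^#", "", names(df)[1])
  meta_cols <- c("chr", "start", "end", "id", "gene_id",
                 "gene_start", "gene_end", "strand")
  abort_if(!all(meta_cols %in% names(df)),
           sprintf("%s: missing phenotype BED columns", path))
  bad <- which(df$end != df$start + 1L)
  abort_if(length(bad) > 0,
           sprintf("%s: BED start/end violate the 0/1-based convention at line %d",
                   path, bad[1] + 1L))
  traits <- tibble::tibble(
    trait_id = df$id, gene_id = df$gene_id, chrom = df$chr,
    tss = as.integer(df$end), gene_start = as.integer(df$gene_start),
    gene_end = as.integer(df$gene_end), strand = df$strand
  )
  vals <- as.matrix(df[, setdiff(names(df), c(meta_cols, "#chr"))])
  trait_matrix(vals, traits)
}

#' Write / read GWAS summary statistics (GCTA ".ma" dialect)
#'
#' Header `SNP A1 A2 freq b se p n`; `A1` is the effect allele.
#'
#' @param gwas A tibble with columns `variant_id`, `A1`, `A2`, `freq`,
#'   `b`, `se`, `p`, `n`.
#' @param path File path.
#' @return `path` / a `gwas_summary` tibble (with `z` recomputed).
#' @export
write_gwas_ma <- function(gwas, path) {
  readr::write_tsv(
    dplyr::transmute(gwas, SNP = .data$variant_id, A1 = .data$A1,
                     A2 = .data$A2, freq = .data$freq, b = .data$b,
                     se = .data$se, p = .data$p, n = .data$n),
    path
  )
  invisible(path)
}

#' @rdname write_gwas_ma
#' @export
read_gwas_ma <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("SNP", "A1", "A2", "freq", "b", "se", "p", "n")
  abort_if(!identical(names(df)[seq_along(need)], need),
           sprintf("%s: header must be '%s'", path, paste(need, collapse = " ")))
  abort_if(any(df$se <= 0, na.rm = TRUE), sprintf("%s: nonpositive se", path))
  abort_if(anyDuplicated(df$SNP) > 0, sprintf("%s: duplicate SNP ids", path))
  out <- tibble::tibble(
    variant_id = df$SNP, A1 = df$A1, A2 = df$A2, freq = df$freq,
    b = df$b, se = df$se, z = df$b / df$se, p = df$p, n = df$n
  )
  structure(out, class = c("gwas_summary", class(out)))
}

#' Align GWAS effect alleles to a genotype panel
#'
#' Flips `b` (and `freq`) for records whose effect/other alleles are
#' swapped relative to the panel's REF/ALT orientation (the panel's
#' effect allele is REF); records with incompatible alleles are dropped
#' with a message.
#'
#' @param gwas A `gwas_summary` tibble.
#' @param variants Panel variant metadata (`variant_id`, `ref`, `alt`).
#' @return The aligned tibble.
#' @export
align_gwas_alleles <- function(gwas, variants) {
  m <- match(gwas$variant_id, variants$variant_id)
  keep <- !is.na(m)
  gwas <- gwas[keep, ]; m <- m[keep]
  same <- gwas$A1 == variants$ref[m] & gwas$A2 == variants$alt[m]
  swapped <- gwas$A1 == variants$alt[m] & gwas$A2 == variants$ref[m]
  if (any(swapped)) {
    gwas$b[swapped] <- -gwas$b[swapped]
    gwas$z[swapped] <- -gwas$z[swapped]
    gwas$freq[swapped] <- 1 - gwas$freq[swapped]
    tmp <- gwas$A1[swapped]
    gwas$A1[swapped] <- gwas$A2[swapped]
    gwas$A2[swapped] <- tmp
  }
  bad <- !(same | swapped)
  if (any(bad)) {
    message(sprintf("dropping %d variant(s) with incompatible alleles", sum(bad)))
    gwas <- gwas[!bad, ]
  }
  gwas
}

#' Write / read a PSM reporter-intensity TSV
#'
#' Columns `psm_id`, `protein_id`, `batch_id`, `jscore`,
#' `channel_1` .. `channel_11`.
#'
#' @param psm PSM tibble; `path` a file path.
#' @return `path` / the PSM tibble.
#' @export
write_psm_tsv <- function(psm, path) {
  readr::write_tsv(psm, path)
  invisible(path)
}

#' @rdname write_psm_tsv
#' @param path File path.
#' @export
read_psm_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  abort_if(!all(c("psm_id", "protein_id", "batch_id") %in% names(df)),
           sprintf("%s: missing PSM columns", path))
  abort_if(length(channel_cols(df)) == 0,
           sprintf("%s: no channel_* columns", path))
  df
}
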