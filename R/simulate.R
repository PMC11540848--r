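#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: a proteogenomic
#' cohort with block-structured linkage disequilibrium, standardized cis
#' effects, hidden confounding factors, and a split between
#' transcript-mediated and transcript-independent protein regulation.
#'
#' Defaults mirror a frontal-cortex proteogenomic cohort: 268 samples,
#' standardized cis effect 0.5 (the large-effect regime), 79% of protein
#' traits transcript-mediated, with transcript-independent direct effects
#' drawn larger than mediated ones.
#'
#' @param n_samples Number of samples in the QTL cohort (>= 30).
#' @param n_variants Total number of variants, split evenly across blocks.
#' @param n_blocks Number of independent LD blocks; each block is placed on
#'   its own synthetic chromosome.
#' @param ld_rho Lag-1 correlation of the latent AR(1) haplotype process
#'   within a block, in `[0, 1)`.
#' @param maf_range Length-2 numeric, allele-frequency range in
#'   `[0.01, 0.5]`.
#' @param cis_effect_beta Standardized slope of the causal cis variant on
#'   the mRNA trait (reference-allele orientation).
#' @param mediation_fraction Proportion of genes whose protein is regulated
#'   through the transcript (`protein = b * mRNA + noise`); the remainder
#'   get a direct SNP effect with no transcript term.
#' @param mediation_slope Slope `b` of protein on mRNA for mediated genes.
#' @param independent_effect_scale Multiplier on `cis_effect_beta` for the
#'   direct protein effect of transcript-independent genes (> 1 encodes the
#'   observation that direct protein effects tend to be stronger than
#'   mediated ones).
#' @param n_hidden_factors Number of latent confounding factors added to
#'   both trait layers.
#' @param n_genes Number of simulated genes (default: one per block).
#' @param noise_sd Residual standard deviation of the trait models.
#' @param variant_spacing Distance in bp between adjacent variants.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 268,
                       n_variants = 500,
                       n_blocks = 10,
                       ld_rho = 0.6,
                       maf_range = c(0.05, 0.5),
                       cis_effect_beta = 0.5,
                       mediation_fraction = 0.79,
                       mediation_slope = 0.8,
                       independent_effect_scale = 1.5,
                       n_hidden_factors = 5,
                       n_genes = 50L,
                       noise_sd = 1,
                       variant_spacing = 10000L,
                       seed = 1L) {
  abort_if(!is_count(n_samples) || n_samples < 30,
           "n_samples must be a count >= 30 (association undefined below)")
  abort_if(!is_count(n_variants) || !is_count(n_blocks) || !is_count(n_genes),
           "n_variants, n_blocks and n_genes must be positive counts")
  abort_if(!(length(maf_range) == 2 && maf_range[1] >= 0.01 &&
             maf_range[2] <= 0.5 && maf_range[1] <= maf_range[2]),
           "maf_range must be within [0.01, 0.5]")
  abort_if(!(ld_rho >= 0 && ld_rho < 1), "ld_rho must be in [0, 1)")
  abort_if(!(mediation_fraction >= 0 && mediation_fraction <= 1),
           "mediation_fraction must be in [0, 1]")
  abort_if(noise_sd <= 0, "noise_sd must be positive")
  abort_if(n_hidden_factors < 0, "n_hidden_factors must be >= 0")
  structure(
    list(
      n_samples = as.integer(n_samples), n_variants = as.integer(n_variants),
      n_blocks = as.integer(n_blocks), ld_rho = ld_rho, maf_range = maf_range,
      cis_effect_beta = cis_effect_beta, mediation_fraction = mediation_fraction,
      mediation_slope = mediation_slope,
      independent_effect_scale = independent_effect_scale,
      n_hidden_factors = as.integer(n_hidden_factors),
      n_genes = as.integer(n_genes), noise_sd = noise_sd,
      variant_spacing = as.integer(variant_spacing), seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# AR(1) latent Gaussian haplotypes for one block: n_hap x m matrix of
# alleles (0/1), allele j carried when the latent normal falls below
# qnorm(freq_j); adjacent-variant LD decays geometrically with ld_rho.
sim_block_haplotypes <- function(n_hap, freqs, ld_rho) {
  m <- length(freqs)
  z <- matrix(rnorm(n_hap * m), n_hap, m)
  if (ld_rho > 0 && m > 1) {
    for (j in 2:m) {
      z[, j] <- ld_rho * z[, j - 1] + sqrt(1 - ld_rho^2) * z[, j]
    }
  }
  th <- qnorm(freqs)
  alleles <- sweep(z, 2, th, `<`)
  storage.mode(alleles) <- "double"
  alleles
}

anno_classes <- c("exonic_nonsyn", "exonic_syn", "intronic", "intergenic", "regulatory")

#' Simulate genotype dosages under HWE with block LD
#'
#' Variants are arranged in `n_blocks` blocks, one synthetic chromosome per
#' block. Within a block, two haplotypes per sample are drawn from a latent
#' Gaussian AR(1) process thresholded at each variant's allele frequency,
#' so Hardy-Weinberg equilibrium holds by construction and adjacent-variant
#' dosage correlation decays with `ld_rho`. Dosage counts the ALT allele.
#'
#' @param cfg A [sim_config()].
#' @return A [geno_matrix()].
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  m_per <- rep(cfg$n_variants %/% cfg$n_blocks, cfg$n_blocks)
  extra <- cfg$n_variants %% cfg$n_blocks
  if (extra > 0) m_per[seq_len(extra)] <- m_per[seq_len(extra)] + 1L
  samples <- sprintf("S%04d", seq_len(cfg$n_samples))

  blocks <- purrr::map(seq_len(cfg$n_blocks), function(b) {
    m <- m_per[b]
    freqs <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
    h1 <- sim_block_haplotypes(cfg$n_samples, freqs, cfg$ld_rho)
    h2 <- sim_block_haplotypes(cfg$n_samples, freqs, cfg$ld_rho)
    ds <- h1 + h2
    # monomorphic columns (possible at low MAF) redrawn independently
    for (j in which(apply(ds, 2, var) == 0)) {
      repeat {
        col <- rbinom(cfg$n_samples, 1L, freqs[j]) + rbinom(cfg$n_samples, 1L, freqs[j])
        if (var(col) > 0) break
      }
      ds[, j] <- col
    }
    pos <- cfg$variant_spacing * seq_len(m)
    info <- tibble::tibble(
      variant_id = sprintf("chr%d:%d", b, pos),
      chrom = paste0("chr", b),
      pos = as.integer(pos),
      ref = sample(c("A", "C", "G", "T"), m, replace = TRUE),
      alt = NA_character_,
      maf = fold_maf(colMeans(ds) / 2),
      anno_class = sample(anno_classes, m, replace = TRUE,
                          prob = c(0.05, 0.05, 0.35, 0.45, 0.10))
    )
    bases <- c("A", "C", "G", "T")
    info$alt <- unname(vapply(info$ref, function(r) sample(setdiff(bases, r), 1), ""))
    list(ds = ds, info = info)
  })

  dosages <- do.call(cbind, purrr::map(blocks, "ds"))
  rownames(dosages) <- samples
  geno_matrix(dosages, dplyr::bind_rows(purrr::map(blocks, "info")))
}

#' Simulate mRNA and protein traits with a known causal structure
#'
#' Each gene is assigned one causal cis variant (the central variant of its
#' block). The mRNA trait is `beta * g_ref + loadings %*% factors + noise`,
#' where `g_ref = 2 - dosage` counts the reference allele so positive
#' effects mean higher expression with the reference allele. A
#' `mediation_fraction` of genes get transcript-mediated proteins
#' (`protein = b * mRNA + noise`, no direct SNP term); the remainder get a
#' direct SNP effect (`protein = beta' * g_ref + noise`, no mRNA term) with
#' `beta' = independent_effect_scale * cis_effect_beta`.
#'
#' @param geno A [geno_matrix()] from [simulate_genotypes()].
#' @param cfg The same [sim_config()].
#' @return A list with elements `mrna` and `protein` (both
#'   [trait_matrix()]), `truth` (tibble: gene, causal variant, class and all
#'   coefficients) and `factors` (samples x factors score matrix).
#' @export
simulate_traits <- function(geno, cfg) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  n <- nrow(geno$dosages)
  vinfo <- geno$variants
  chroms <- unique(vinfo$chrom)
  g_ids <- seq_len(cfg$n_genes)
  gene_chrom <- chroms[((g_ids - 1L) %% length(chroms)) + 1L]

  fac <- if (cfg$n_hidden_factors > 0) {
    matrix(rnorm(n * cfg$n_hidden_factors), n, cfg$n_hidden_factors)
  } else {
    matrix(0, n, 0)
  }

  n_dep <- round(cfg$mediation_fraction * cfg$n_genes)
  classes <- sample(rep(c("dependent", "independent"),
                        c(n_dep, cfg$n_genes - n_dep)))

  rows <- vector("list", cfg$n_genes)
  mrna <- matrix(NA_real_, cfg$n_genes, n)
  prot <- matrix(NA_real_, cfg$n_genes, n)
  rounds <- ceiling(cfg$n_genes / length(chroms))
  for (i in g_ids) {
    in_chr <- which(vinfo$chrom == gene_chrom[i])
    # genes sharing a block get causal variants spread across it
    rd <- (i - 1L) %/% length(chroms)
    causal <- in_chr[ceiling(length(in_chr) * (2 * rd + 1) / (2 * rounds))]
    tss <- max(1L, vinfo$pos[causal] - sample(0:20000, 1))
    abort_if(abs(vinfo$pos[causal] - tss) > 1e6,
             "internal error: causal variant outside the cis window")
    strand <- sample(c("+", "-"), 1)
    g_start <- if (strand == "+") tss else max(1L, tss - 30000L)
    g_end <- if (strand == "+") tss + 30000L else tss
    g_ref <- 2 - geno$dosages[, causal]

    lam_m <- rnorm(cfg$n_hidden_factors, 0, 0.5)
    lam_p <- rnorm(cfg$n_hidden_factors, 0, 0.5)
    fm <- if (cfg$n_hidden_factors > 0) drop(fac %*% lam_m) else 0
    fp <- if (cfg$n_hidden_factors > 0) drop(fac %*% lam_p) else 0

    y_m <- cfg$cis_effect_beta * g_ref + fm + rnorm(n, 0, cfg$noise_sd)
    if (classes[i] == "dependent") {
      b_med <- cfg$mediation_slope
      beta_p <- NA_real_
      y_p <- b_med * y_m + fp + rnorm(n, 0, cfg$noise_sd)
    } else {
      b_med <- NA_real_
      beta_p <- cfg$independent_effect_scale * cfg$cis_effect_beta
      y_p <- beta_p * g_ref + fp + rnorm(n, 0, cfg$noise_sd)
    }
    mrna[i, ] <- y_m
    prot[i, ] <- y_p
    rows[[i]] <- tibble::tibble(
      gene_id = sprintf("G%03d", i), chrom = gene_chrom[i],
      tss = as.integer(tss), gene_start = as.integer(g_start),
      gene_end = as.integer(g_end), strand = strand,
      causal_variant = vinfo$variant_id[causal], class = classes[i],
      beta_mrna = cfg$cis_effect_beta, mediation_slope = b_med,
      beta_protein_direct = beta_p
    )
  }
  truth <- dplyr::bind_rows(rows)

  meta <- truth |>
    dplyr::transmute(
      trait_id = .data$gene_id, gene_id = .data$gene_id, chrom = .data$chrom,
      tss = .data$tss, gene_start = .data$gene_start,
      gene_end = .data$gene_end, strand = .data$strand
    )
  colnames(mrna) <- colnames(prot) <- rownames(geno$dosages)
  list(
    mrna = trait_matrix(mrna, meta),
    protein = trait_matrix(prot, meta),
    truth = truth,
    factors = fac
  )
}

#' Simulate GWAS summary statistics under a known mechanism
#'
#' Builds a disease phenotype in an independently drawn cohort (two-sample
#' setting; set `independent_cohort = FALSE` to reuse the QTL cohort) under
#' one of four mechanisms, then computes per-variant marginal regression
#' summaries in reference-allele orientation:
#' \describe{
#'   \item{causal}{phenotype proportional to the target gene's molecular
#'     trait (`effect_ratio` times the trait, plus noise), so the
#'     GWAS-to-QTL effect ratio at the causal variant is `effect_ratio`.}
#'   \item{pleiotropic}{phenotype built directly from the causal variant.}
#'   \item{linkage}{phenotype built from a different variant of the same
#'     block, in LD with the molecular QTL.}
#'   \item{null}{pure noise.}
#' }
#'
#' @param geno QTL-cohort genotypes (defines variant frequencies and LD).
#' @param truth Truth table from [simulate_traits()].
#' @param scenario One of `"causal"`, `"pleiotropic"`, `"linkage"`, `"null"`.
#' @param cfg The [sim_config()] used to generate `geno`.
#' @param target_gene Gene id the mechanism acts through (default: first).
#' @param effect_ratio True GWAS-to-molecular effect ratio under
#'   `"causal"`; also scales the direct effects of the other scenarios.
#' @param trait Which molecular layer drives the causal scenario.
#' @param n_gwas GWAS cohort size.
#' @param linkage_offset Distance, in variants, from the causal variant to
#'   the variant driving the `"linkage"` phenotype.
#' @param independent_cohort Draw a fresh cohort for the GWAS (default).
#' @param seed Integer seed.
#' @return A tibble of class `gwas_summary` with columns `variant_id`,
#'   `A1` (effect allele = REF), `A2`, `freq`, `b`, `se`, `z`, `p`, `n`;
#'   attributes `scenario` and `trait_name`.
#' @export
simulate_gwas <- function(geno, truth, scenario, cfg,
                          target_gene = truth$gene_id[1],
                          effect_ratio = 0.3,
                          trait = c("mrna", "protein"),
                          n_gwas = 2L * cfg$n_samples,
                          linkage_offset = 3L,
                          independent_cohort = TRUE,
                          seed = cfg$seed + 2L) {
  scenario <- match.arg(scenario, c("causal", "pleiotropic", "linkage", "null"))
  trait <- match.arg(trait)
  tr <- truth[truth$gene_id == target_gene, ]
  abort_if(nrow(tr) != 1, "target_gene not found in truth table")

  if (independent_cohort) {
    cfg2 <- cfg
    cfg2$n_samples <- as.integer(n_gwas)
    cfg2$seed <- as.integer(seed)
    geno_g <- simulate_genotypes(cfg2)
  } else {
    geno_g <- geno
  }
  set.seed(seed + 13L)
  n <- nrow(geno_g$dosages)
  ds <- geno_g$dosages
  causal_j <- match(tr$causal_variant, geno_g$variants$variant_id)
  g_ref <- 2 - ds[, causal_j]

  y <- switch(scenario,
    causal = {
      # rebuild the molecular trait from the truth coefficients in this cohort
      y_m <- tr$beta_mrna * g_ref + rnorm(n, 0, cfg$noise_sd)
      mol <- if (trait == "mrna") y_m else {
        if (tr$class == "dependent") {
          tr$mediation_slope * y_m + rnorm(n, 0, cfg$noise_sd)
        } else {
          tr$beta_protein_direct * g_ref + rnorm(n, 0, cfg$noise_sd)
        }
      }
      effect_ratio * mol + rnorm(n)
    },
    pleiotropic = effect_ratio * tr$beta_mrna * g_ref + rnorm(n),
    linkage = {
      in_chr <- which(geno_g$variants$chrom == tr$chrom)
      j <- causal_j + linkage_offset
      abort_if(!(j %in% in_chr), "linkage_offset leaves the causal variant's block")
      effect_ratio * tr$beta_mrna * (2 - ds[, j]) + rnorm(n)
    },
    null = rnorm(n)
  )

  marg <- marginal_scan(y, 2 - ds)
  out <- tibble::tibble(
    variant_id = geno_g$variants$variant_id,
    A1 = geno_g$variants$ref, A2 = geno_g$variants$alt,
    freq = fold_maf(colMeans(ds) / 2),
    b = marg$beta, se = marg$se, z = marg$beta / marg$se, p = marg$p,
    n = n
  )
  structure(out, class = c("gwas_summary", class(out)),
            scenario = scenario, trait_name = target_gene)
}

# marginal simple-regression summaries of y on each column of X
marginal_scan <- function(y, X) {
  n <- length(y)
  yc <- y - mean(y)
  Xc <- sweep(X, 2, colMeans(X))
  sxx <- colSums(Xc^2)
  sxy <- drop(crossprod(Xc, yc))
  beta <- unname(sxy / sxx)
  rss <- sum(yc^2) - beta * unname(sxy)
  se <- unname(sqrt(pmax(rss, 0) / (n - 2) / sxx))
  tstat <- beta / se
  list(beta = beta, se = se, t = tstat,
       p = 2 * pt(abs(tstat), n - 2, lower.tail = FALSE))
}

#' Simulate a multi-batch isobaric-labelling PSM table
#'
#' Emulates 11-plex TMT batches: 10 sample channels plus one
#' internal-standard channel carrying the mean of the batch's 10 samples.
#' Each PSM's true intensity is the protein's per-channel ground truth
#' times a PSM-specific loading and lognormal noise; observed intensities
#' are the true ones mixed through the label-impurity matrix. A
#' configurable fraction of PSMs is drawn at low loadings so they fall
#' below the minimum-1000/median-5000 intensity filters.
#'
#' @param n_proteins Number of proteins.
#' @param n_batches Number of 11-plex batches (10 new samples per batch).
#' @param impurity Channel-by-channel impurity (spillover) matrix; columns
#'   sum to at most 1. Default: identity (no spillover).
#' @param n_psm_range Range of PSM counts per protein per batch.
#' @param noise_sd SD of the lognormal measurement noise on log2 scale.
#' @param bio_sd SD of per-sample biological variation on log2 scale.
#' @param low_fraction Fraction of PSMs drawn at sub-threshold loadings.
#' @param channel_loadings Length-11 multiplicative channel efficiencies
#'   (labelling/pipetting distortion; what trimmed-median channel
#'   normalization is designed to remove). Default: no distortion.
#' @param seed Integer seed.
#' @return A list: `psm` (tibble with `psm_id`, `protein_id`, `batch_id`,
#'   `jscore`, `channel_1` .. `channel_11`), `truth` (proteins x samples
#'   log2 relative-abundance matrix), `sample_map` (tibble mapping batch and
#'   channel to sample id; channel 11 is the internal standard).
#' @export
simulate_psm_table <- function(n_proteins, n_batches,
                               impurity = diag(11),
                               n_psm_range = c(2L, 6L),
                               noise_sd = 0.05, bio_sd = 0.25,
                               low_fraction = 0.05,
                               channel_loadings = rep(1, 11), seed = 1L) {
  validate_impurity(impurity, n_channels = 11L)
  abort_if(length(channel_loadings) != 11 || any(channel_loadings <= 0),
           "channel_loadings must be 11 positive values")
  set.seed(seed)
  n_samples <- 10L * n_batches
  samples <- sprintf("S%04d", seq_len(n_samples))
  base <- 2^runif(n_proteins, 14, 20)      # protein base intensity
  rel <- matrix(2^rnorm(n_proteins * n_samples, 0, bio_sd), n_proteins, n_samples,
                dimnames = list(sprintf("P%04d", seq_len(n_proteins)), samples))
  proteins <- rownames(rel)

  maps <- vector("list", n_batches)
  tabs <- vector("list", n_batches)
  psm_counter <- 0L
  for (b in seq_len(n_batches)) {
    s_idx <- (10L * (b - 1L) + 1L):(10L * b)
    truth_b <- cbind(rel[, s_idx, drop = FALSE], IS = rowMeans(rel[, s_idx, drop = FALSE]))
    maps[[b]] <- tibble::tibble(
      batch_id = sprintf("B%02d", b), channel = seq_len(11L),
      sample_id = c(samples[s_idx], paste0("IS_B", sprintf("%02d", b)))
    )
    n_psm <- sample(n_psm_range[1]:n_psm_range[2], n_proteins, replace = TRUE)
    rows <- vector("list", n_proteins)
    for (i in seq_len(n_proteins)) {
      k <- n_psm[i]
      loading <- 2^runif(k, -2, 2)
      low <- runif(k) < low_fraction
      loading[low] <- loading[low] * 1e-4
      true_int <- (base[i] * loading) %o% channel_loadings *
        (rep(1, k) %o% truth_b[i, ]) *
        matrix(2^rnorm(k * 11, 0, noise_sd), k, 11)
      obs <- t(impurity %*% t(true_int))
      rows[[i]] <- tibble::tibble(
        psm_id = sprintf("PSM%06d", psm_counter + seq_len(k)),
        protein_id = proteins[i],
        batch_id = sprintf("B%02d", b),
        jscore = round(runif(k, 30, 100), 2)
      ) |>
        dplyr::bind_cols(tibble::as_tibble(setNames(
          as.data.frame(obs), paste0("channel_", seq_len(11L))
        )))
      psm_counter <- psm_counter + k
    }
    tabs[[b]] <- dplyr::bind_rows(rows)
  }
  list(
    psm = dplyr::bind_rows(tabs),
    truth = log2(rel),
    sample_map = dplyr::bind_rows(maps)
  )
}
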