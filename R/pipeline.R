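# End-to-end pipeline driver: simulate -> quantify -> correct -> map (cis,
# trans) -> colocalize -> mediate -> SMR -> prioritize, with a manifest of
# stages, parameters and output checksums. Every intermediate is a file, so
# any stage can be re-run from the previous stage's outputs.

#' Pipeline configuration
#'
#' @param out_dir Output directory (created if absent).
#' @param sim A [sim_config()] defining the simulated study.
#' @param window A [window_config()] for QTL mapping.
#' @param smr An [smr_config()].
#' @param q_cutoff Significance cutoff on q-values (default 0.05).
#' @param pp4_cutoff Colocalization call threshold (default 0.8; 0.5 is
#'   the permissive alternative).
#' @param coloc_window Colocalization half-window in bp (default 500 kb).
#' @param n_mediation_permutations Permutations for the mediation null.
#' @param seed Global seed; every stage derives its stream from it.
#' @param stages Character vector of stages to run, in order.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            sim = sim_config(),
                            window = window_config(),
                            smr = smr_config(),
                            q_cutoff = 0.05,
                            pp4_cutoff = 0.8,
                            coloc_window = 5e5,
                            n_mediation_permutations = 1000L,
                            seed = 1L,
                            stages = c("simulate", "quantify", "correct",
                                       "map_cis", "map_trans", "coloc",
                                       "mediate", "smr", "prioritize")) {
  structure(list(
    out_dir = out_dir, sim = sim, window = window, smr = smr,
    q_cutoff = q_cutoff, pp4_cutoff = pp4_cutoff,
    coloc_window = coloc_window,
    n_mediation_permutations = as.integer(n_mediation_permutations),
    seed = as.integer(seed), stages = stages
  ), class = "pipeline_config")
}

stage_record <- function(stage, outputs, params, t0, status = "ok") {
  tibble::tibble(
    stage = stage, status = status,
    outputs = paste(basename(outputs), collapse = ","),
    checksums = paste(substr(unname(tools::md5sum(outputs)), 1, 8),
                      collapse = ","),
    parameters = params,
    elapsed_s = round(as.numeric(Sys.time()) - t0, 2)
  )
}

#' Run the integrative pipeline end to end
#'
#' Executes the configured stages on a simulated study and writes every
#' intermediate as a plain-text table under `out_dir`. With a fixed seed
#' the run is byte-identical across repetitions.
#'
#' @param cfg A [pipeline_config()].
#' @return A manifest tibble (stage, status, outputs, checksums,
#'   parameters, elapsed seconds), invisibly also written to
#'   `manifest.tsv`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  man <- list()
  env <- new.env(parent = emptyenv())
  failed <- FALSE

  run_stage <- function(stage, fn, params = "") {
    if (!(stage %in% cfg$stages)) return(invisible(NULL))
    if (failed) {
      man[[stage]] <<- tibble::tibble(
        stage = stage, status = "skipped", outputs = "", checksums = "",
        parameters = params, elapsed_s = 0
      )
      return(invisible(NULL))
    }
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      failed <<- TRUE
      man[[stage]] <<- tibble::tibble(
        stage = stage, status = paste0("failed: ", conditionMessage(res)),
        outputs = "", checksums = "", parameters = params, elapsed_s = 0
      )
    } else {
      man[[stage]] <<- stage_record(stage, res, params, t0)
    }
    invisible(NULL)
  }
  out <- function(...) file.path(cfg$out_dir, ...)

  run_stage("simulate", function() {
    env$geno <- simulate_genotypes(cfg$sim)
    tr <- simulate_traits(env$geno, cfg$sim)
    env$mrna <- tr$mrna; env$protein_true <- tr$protein; env$truth <- tr$truth
    env$gwas <- simulate_gwas(env$geno, tr$truth, "causal", cfg$sim,
                              trait = "protein", seed = cfg$sim$seed + 2L)
    write_dosage_vcf(env$geno, out("genotypes.vcf"))
    write_phenotype_bed(env$mrna, out("mrna.bed"))
    write_phenotype_bed(env$protein_true, out("protein_true.bed"))
    readr::write_tsv(env$truth, out("truth.tsv"))
    write_gwas_ma(env$gwas, out("gwas.ma"))
    out(c("genotypes.vcf", "mrna.bed", "protein_true.bed", "truth.tsv",
          "gwas.ma"))
  }, params = sprintf("n=%d genes=%d seed=%d", cfg$sim$n_samples,
                      cfg$sim$n_genes, cfg$sim$seed))

  run_stage("quantify", function() {
    # protein trait matrix re-derived from a PSM-level simulation of the
    # same samples' true abundances
    n_batches <- ceiling(cfg$sim$n_samples / 10)
    sim_psm <- simulate_psm_table(
      n_proteins = cfg$sim$n_genes, n_batches = n_batches,
      impurity = impurity_matrix(0.03), seed = cfg$seed + 11L
    )
    write_psm_tsv(sim_psm$psm, out("psm.tsv"))
    pm <- quantify_batches(sim_psm$psm, sim_psm$sample_map,
                           impurity = impurity_matrix(0.03))
    readr::write_tsv(tibble::as_tibble(unclass(pm), rownames = "protein_id"),
                     out("protein_quant.tsv"))
    env$protein_quant <- pm
    out(c("psm.tsv", "protein_quant.tsv"))
  }, params = "impurity=banded(0.03)")

  run_stage("correct", function() {
    env$mrna_c <- correct_traits(env$mrna, n_factors = cfg$sim$n_hidden_factors)
    env$protein_c <- correct_traits(env$protein_true,
                                    n_factors = cfg$sim$n_hidden_factors)
    write_phenotype_bed(env$mrna_c, out("mrna_corrected.bed"))
    write_phenotype_bed(env$protein_c, out("protein_corrected.bed"))
    out(c("mrna_corrected.bed", "protein_corrected.bed"))
  }, params = sprintf("n_factors=%d", cfg$sim$n_hidden_factors))

  run_stage("map_cis", function() {
    env$eqtl <- map_qtl(env$mrna_c, env$geno, cfg$window, "cis",
                        seed = cfg$seed + 21L)
    env$pqtl <- map_qtl(env$protein_c, env$geno, cfg$window, "cis",
                        seed = cfg$seed + 22L)
    readr::write_tsv(tibble::as_tibble(env$eqtl), out("cis_eqtl.tsv"))
    readr::write_tsv(tibble::as_tibble(env$pqtl), out("cis_pqtl.tsv"))
    out(c("cis_eqtl.tsv", "cis_pqtl.tsv"))
  }, params = sprintf("window=%g perms=%d q<%g", cfg$window$cis_window,
                      cfg$window$n_permutations, cfg$q_cutoff))

  run_stage("map_trans", function() {
    thr <- trans_threshold(ncol(env$geno$dosages), nrow(env$protein_c$values))
    nom <- nominal_scan(env$protein_c, env$geno, cfg$window, "trans")
    env$trans <- nom[nom$p < thr, ]
    readr::write_tsv(env$trans, out("trans_pqtl.tsv"))
    out("trans_pqtl.tsv")
  }, params = "bonferroni")

  run_stage("coloc", function() {
    sig <- env$pqtl[!is.na(env$pqtl$qvalue) & env$pqtl$qvalue < cfg$q_cutoff, ]
    rows <- purrr::map_dfr(sig$trait_id, function(tid) {
      lead <- sig$variant_id[sig$trait_id == tid]
      w <- window_config(cis_window = cfg$window$cis_window,
                         n_permutations = cfg$window$n_permutations)
      a_p <- nominal_scan(subset_traits(env$protein_c, tid), env$geno, w, "cis")
      a_e <- nominal_scan(subset_traits(env$mrna_c, tid), env$geno, w, "cis")
      cc <- colocalize_window(a_p, a_e, env$geno$variants, lead,
                              window = cfg$coloc_window)
      dplyr::bind_cols(tibble::tibble(trait_id = tid, lead_variant = lead),
                       tibble::as_tibble(cc))
    })
    env$coloc <- rows
    readr::write_tsv(rows, out("coloc.tsv"))
    out("coloc.tsv")
  }, params = sprintf("window=%g priors=1e-4,1e-4,1e-5 PP4>%g",
                      cfg$coloc_window, cfg$pp4_cutoff))

  run_stage("mediate", function() {
    hits <- env$coloc[env$coloc$PP4 > cfg$pp4_cutoff, ]
    pairs <- tibble::tibble(trait_id = hits$trait_id,
                            variant_id = hits$lead_variant)
    med <- mediation_classify(env$protein_c, env$mrna_c, env$geno, pairs,
                              seed = cfg$seed + 31L,
                              n_permutations = cfg$n_mediation_permutations)
    env$mediation <- med
    readr::write_tsv(med, out("mediation.tsv"))
    readr::write_tsv(mediation_summary(med, env$protein_c, env$mrna_c),
                     out("mediation_summary.tsv"))
    out(c("mediation.tsv", "mediation_summary.tsv"))
  }, params = sprintf("perms=%d z<=-4.26", cfg$n_mediation_permutations))

  run_stage("smr", function() {
    w <- cfg$window
    qs <- lapply(setNames(env$pqtl$trait_id, env$pqtl$trait_id), function(tid) {
      nominal_scan(subset_traits(env$protein_c, tid), env$geno, w, "cis")
    })
    env$smr <- run_smr(qs, env$gwas, env$geno, cfg$smr)
    readr::write_tsv(tibble::as_tibble(env$smr), out("smr.tsv"))
    out("smr.tsv")
  }, params = sprintf("correction=%s p_heidi>%g", cfg$smr$correction,
                      cfg$smr$p_heidi_pass))

  run_stage("prioritize", function() {
    src <- list(
      pqtl = tibble::tibble(gene_id = env$pqtl$trait_id,
                            rank = rank(env$pqtl$nominal_p)),
      eqtl = tibble::tibble(gene_id = env$eqtl$trait_id,
                            rank = rank(env$eqtl$nominal_p)),
      coloc = tibble::tibble(gene_id = env$coloc$trait_id,
                             rank = rank(-env$coloc$PP4))
    )
    env$ranking <- aggregate_and_rank(src)
    readr::write_tsv(tibble::as_tibble(env$ranking), out("ranking.tsv"))
    out("ranking.tsv")
  }, params = "order-statistics over pqtl,eqtl,coloc ranks")

  manifest <- dplyr::bind_rows(man)
  readr::write_tsv(manifest, out("manifest.tsv"))
  manifest
}

# single-trait view of a trait matrix, metadata kept aligned
subset_traits <- function(traits, trait_ids) {
  idx <- match(trait_ids, traits$traits$trait_id)
  trait_matrix(traits$values[idx, , drop = FALSE],
               traits$traits[idx, , drop = FALSE])
}
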