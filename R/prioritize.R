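# Multi-evidence candidate-gene prioritization: order-statistics rank
# aggregation over ranked evidence sources, a PPI-connectivity score, and
# assignment of top-ranked genes to GWAS loci.

#' Joint order-statistic tail probability
#'
#' Probability that `k` independent Uniform(0,1) variables have order
#' statistics jointly below the supplied rank ratios, via the recursion
#' `Q = k! * V_k` with `V_0 = 1`,
#' `V_i = sum_{j=1..i} (-1)^(j-1) * V_{i-j} * q_{k-i+j}^j / j!`.
#' Small Q means ranks jointly better than chance.
#'
#' @param rank_ratios Rank ratios `r_i / n_i` in `(0, 1]`, sorted
#'   ascending (an unsorted vector is an error, not silently sorted).
#' @param k Number of sources (default `length(rank_ratios)`).
#' @return The tail probability Q in `[0, 1]`.
#' @export
order_statistic_q <- function(rank_ratios, k = length(rank_ratios)) {
  abort_if(k < 1 || length(rank_ratios) != k, "need k >= 1 ratios")
  abort_if(any(rank_ratios <= 0 | rank_ratios > 1), "ratios must be in (0, 1]")
  abort_if(is.unsorted(rank_ratios), "rank_ratios must be sorted ascending")
  qd <- rev(rank_ratios)         # recursion consumes descending ratios
  V <- numeric(k + 1)
  V[1] <- 1                      # V_0
  for (i in seq_len(k)) {
    j <- seq_len(i)
    V[i + 1] <- sum((-1)^(j - 1) * V[i - j + 1] *
                      qd[k - i + j]^j / factorial(j))
  }
  min(max(factorial(k) * V[k + 1], 0), 1)
}

#' PPI connectivity score
#'
#' Filters a protein-protein interaction edge list to high-confidence
#' edges, restricts nodes to the eligible set (genes with a cis pGene or
#' eGene signal), and counts, per gene, its distinct neighbours among the
#' known risk genes.
#'
#' @param edges Tibble with `gene_a`, `gene_b`, `combined_score`
#'   (integer score, conventionally 150-999).
#' @param risk_genes Character vector of known risk genes.
#' @param eligible Character vector of eligible node genes; `NULL` keeps
#'   all nodes.
#' @param min_score Edge-score cutoff (default 700).
#' @return Tibble `gene_id`, `connectivity` (descending), covering every
#'   retained network node.
#' @export
connectivity_score <- function(edges, risk_genes, eligible = NULL,
                               min_score = 700) {
  ed <- edges[edges$combined_score >= min_score &
                edges$gene_a != edges$gene_b, c("gene_a", "gene_b")]
  # undirected dedup
  key <- ifelse(ed$gene_a < ed$gene_b,
                paste(ed$gene_a, ed$gene_b), paste(ed$gene_b, ed$gene_a))
  ed <- ed[!duplicated(key), ]
  if (!is.null(eligible)) {
    ed <- ed[ed$gene_a %in% eligible & ed$gene_b %in% eligible, ]
  }
  if (nrow(ed) == 0) {
    warning("no edges survive filtering; all connectivity scores are 0")
    return(tibble::tibble(gene_id = character(), connectivity = integer()))
  }
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  nodes <- igraph::V(g)$name
  conn <- vapply(nodes, function(v) {
    nb <- igraph::neighbors(g, v)$name
    length(intersect(unique(nb), risk_genes))
  }, 0L)
  tibble::tibble(gene_id = nodes, connectivity = unname(conn)) |>
    dplyr::arrange(dplyr::desc(.data$connectivity), .data$gene_id)
}

#' Aggregate ranked evidence sources by order statistics
#'
#' Takes the union of genes over the sources; per gene, computes rank
#' ratios over its available sources (ties in a source resolved by average
#' rank), sorts them and evaluates [order_statistic_q()] with that gene's
#' own source count `k`. Final ranking is by ascending Q, ties broken by
#' more sources available, then gene id.
#'
#' @param sources Named list of tibbles, each with `gene_id` and either
#'   `rank` (1 = best) or `score` plus a `direction` attribute
#'   (`"desc"`: larger score is better).
#' @return A tibble of class `evidence_ranks`: `gene_id`, `n_sources`,
#'   `q_score`, `final_rank`, plus one `ratio_*` column per source.
#' @export
aggregate_and_rank <- function(sources) {
  abort_if(length(sources) == 0, "no sources supplied")
  if (is.null(names(sources))) names(sources) <- paste0("source", seq_along(sources))
  ratios <- purrr::imap(sources, function(src, nm) {
    r <- if ("rank" %in% names(src)) {
      rank(src$rank, ties.method = "average")
    } else {
      desc <- identical(attr(src, "direction"), "desc") ||
        is.null(attr(src, "direction"))
      rank(if (desc) -src$score else src$score, ties.method = "average")
    }
    tibble::tibble(gene_id = src$gene_id,
                   "ratio_{nm}" := r / nrow(src))
  })
  wide <- purrr::reduce(ratios, dplyr::full_join, by = "gene_id")
  rmat <- as.matrix(wide[, -1, drop = FALSE])
  keep <- rowSums(!is.na(rmat)) > 0
  wide <- wide[keep, ]
  rmat <- rmat[keep, , drop = FALSE]
  qs <- apply(rmat, 1, function(rr) {
    rr <- sort(rr[!is.na(rr)])
    order_statistic_q(rr)
  })
  out <- wide |>
    dplyr::mutate(
      n_sources = rowSums(!is.na(rmat)),
      q_score = qs
    ) |>
    dplyr::arrange(.data$q_score, dplyr::desc(.data$n_sources), .data$gene_id) |>
    dplyr::mutate(final_rank = dplyr::row_number()) |>
    dplyr::relocate("gene_id", "n_sources", "q_score", "final_rank")
  structure(out, class = c("evidence_ranks", class(out)))
}

#' Assign top-ranked genes to GWAS loci
#'
#' A gene is assigned to a locus when its TSS falls inside the locus
#' interval. Loci carry a significance tier (`"significant"`, GWAS
#' p < 5e-8, or `"suggestive"`, 5e-8 < p < 1e-6). Genes overlapping no
#' locus are retained unassigned.
#'
#' @param ranked An `evidence_ranks` tibble (or any tibble with
#'   `gene_id`, `final_rank`).
#' @param gene_info Tibble with `gene_id`, `chrom`, `tss`.
#' @param loci Tibble with `chrom`, `start`, `end`, `tier` (1-based
#'   inclusive intervals).
#' @param top_n Restrict to the best `top_n` final ranks (default 60).
#' @return A tibble: the top genes with `locus` (e.g. `"chr1:100-200"`)
#'   and `tier` (`NA` when unassigned); per-tier counts as attribute
#'   `tier_counts`.
#' @export
map_to_loci <- function(ranked, gene_info, loci, top_n = 60L) {
  abort_if(!all(c("chrom", "start", "end", "tier") %in% names(loci)),
           "loci need chrom, start, end, tier")
  bad <- which(!is.finite(loci$start) | !is.finite(loci$end) |
                 loci$start > loci$end)
  abort_if(length(bad) > 0,
           sprintf("malformed locus interval at line %d", bad[1]))
  top <- ranked[order(ranked$final_rank), ]
  top <- head(top, top_n)
  top <- dplyr::left_join(top, gene_info[, c("gene_id", "chrom", "tss")],
                          by = "gene_id")
  hit <- purrr::map_dfr(seq_len(nrow(top)), function(i) {
    inl <- which(loci$chrom == top$chrom[i] &
                   loci$start <= top$tss[i] & top$tss[i] <= loci$end)
    if (length(inl) == 0) {
      tibble::tibble(locus = NA_character_, tier = NA_character_)
    } else {
      tibble::tibble(
        locus = sprintf("%s:%d-%d", loci$chrom[inl[1]],
                        loci$start[inl[1]], loci$end[inl[1]]),
        tier = loci$tier[inl[1]]
      )
    }
  })
  out <- dplyr::bind_cols(top, hit)
  attr(out, "tier_counts") <- out |>
    dplyr::filter(!is.na(.data$tier)) |>
    dplyr::count(.data$tier)
  out
}
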