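test_that("order-statistic Q has its trivial anchors and contract", {
  expect_equal(order_statistic_q(0.3), 0.3)
  expect_equal(order_statistic_q(c(1, 1, 1, 1)), 1)
  expect_error(order_statistic_q(c(0.5, 0.2)), "sorted")
  expect_error(order_statistic_q(c(0, 0.5)), "ratios")
})

test_that("Q matches a Monte-Carlo joint-order-statistic estimate", {
  set.seed(1)
  cases <- list(c(0.1, 0.2, 0.5), c(0.05, 0.5, 0.9), c(0.3, 0.35, 0.4, 0.8))
  for (r in cases) {
    k <- length(r)
    draws <- 1e6
    U <- matrix(runif(draws * k), draws, k)
    U <- matrix(U[order(row(U), U)], draws, k, byrow = TRUE)  # row-wise sort
    hit <- rep(TRUE, draws)
    for (j in seq_len(k)) hit <- hit & (U[, j] <= r[j])
    mc <- mean(hit)
    se <- sqrt(mc * (1 - mc) / draws)
    expect_lt(abs(order_statistic_q(r) - mc), 3 * se + 1e-12)
  }
})

test_that("Q is monotone: improving any single rank never increases it", {
  set.seed(2)
  for (i in 1:20) {
    r <- sort(runif(4, 0.1, 1))
    j <- sample(4, 1)
    r2 <- r
    r2[j] <- r2[j] * 0.5
    expect_lte(order_statistic_q(sort(r2)), order_statistic_q(r) + 1e-12)
  }
})

test_that("connectivity scores count distinct risk-gene neighbours", {
  edges <- tibble::tibble(
    gene_a = c("hub", "hub", "hub", "hub", "hub", "x"),
    gene_b = c("r1", "r2", "r3", "r4", "r5", "r1"),
    combined_score = c(rep(900, 5), 650)
  )
  cs <- connectivity_score(edges, risk_genes = paste0("r", 1:5))
  expect_equal(cs$connectivity[cs$gene_id == "hub"], 5)
  expect_true(all(cs$connectivity[cs$gene_id != "hub"] <= 1))
  # the sub-threshold edge keeps x out of the network entirely
  expect_false("x" %in% cs$gene_id)
})

test_that("connectivity matches a brute-force adjacency count on a random graph", {
  set.seed(3)
  n <- 1000
  ed <- tibble::tibble(
    gene_a = sprintf("g%04d", sample(n, 3000, replace = TRUE)),
    gene_b = sprintf("g%04d", sample(n, 3000, replace = TRUE)),
    combined_score = sample(150:999, 3000, replace = TRUE)
  )
  risk <- sprintf("g%04d", sample(n, 100))
  cs <- connectivity_score(ed, risk)
  # naive recount
  keep <- ed$combined_score >= 700 & ed$gene_a != ed$gene_b
  ed2 <- ed[keep, ]
  nb <- list()
  for (i in seq_len(nrow(ed2))) {
    nb[[ed2$gene_a[i]]] <- union(nb[[ed2$gene_a[i]]], ed2$gene_b[i])
    nb[[ed2$gene_b[i]]] <- union(nb[[ed2$gene_b[i]]], ed2$gene_a[i])
  }
  for (gid in sample(cs$gene_id, 50)) {
    expect_equal(cs$connectivity[cs$gene_id == gid],
                 length(intersect(nb[[gid]], risk)))
  }
})

test_that("aggregation behaves on the edges: best-everywhere and one source", {
  n <- 20
  mk <- function(order) tibble::tibble(gene_id = order, rank = seq_along(order))
  genes <- sprintf("G%02d", 1:n)
  best <- genes
  sources <- list(a = mk(best), b = mk(best), c = mk(best), d = mk(best),
                  e = mk(best))
  agg <- aggregate_and_rank(sources)
  expect_equal(agg$gene_id[agg$final_rank == 1], "G01")
  expect_equal(agg$q_score[1], min(agg$q_score))
  # single source: final ranking equals that source's ranking
  set.seed(6)
  shuffled <- sample(genes)
  one <- aggregate_and_rank(list(a = mk(shuffled)))
  expect_equal(one$gene_id[order(one$final_rank)], shuffled)
})

test_that("aggregation is invariant to source order and handles missingness", {
  set.seed(4)
  genes <- sprintf("G%02d", 1:30)
  mk <- function() {
    keep <- sort(sample(30, sample(20:30, 1)))
    tibble::tibble(gene_id = genes[keep], rank = sample(length(keep)))
  }
  sources <- list(a = mk(), b = mk(), c = mk(), d = mk(), e = mk())
  agg1 <- aggregate_and_rank(sources)
  agg2 <- aggregate_and_rank(rev(sources))
  expect_equal(agg1$q_score[order(agg1$gene_id)],
               agg2$q_score[order(agg2$gene_id)], tolerance = 1e-12)
  expect_equal(agg1$gene_id[order(agg1$final_rank)],
               agg2$gene_id[order(agg2$final_rank)])
  # identical available ranks: deterministic adjacent final ranks
  dup <- list(a = tibble::tibble(gene_id = c("X", "Y"), rank = c(1, 1)))
  aggd <- aggregate_and_rank(dup)
  expect_equal(sort(aggd$final_rank), 1:2)
  expect_equal(aggd$gene_id[order(aggd$final_rank)], c("X", "Y"))
})

test_that("aggregating noisy sources beats any single source on average", {
  set.seed(5)
  n <- 60
  quality <- seq_len(n)                      # true ordering
  gains <- replicate(40, {
    noisy <- function() {
      tibble::tibble(gene_id = sprintf("G%03d", 1:n),
                     rank = rank(quality + rnorm(n, 0, 15)))
    }
    sources <- list(a = noisy(), b = noisy(), c = noisy(), d = noisy(),
                    e = noisy())
    agg <- aggregate_and_rank(sources)
    agg_cor <- cor(agg$final_rank[order(agg$gene_id)], quality,
                   method = "spearman")
    single_cor <- mean(vapply(sources, function(s) {
      cor(s$rank[order(s$gene_id)], quality, method = "spearman")
    }, 0))
    agg_cor - single_cor
  })
  expect_gt(mean(gains > 0), 0.9)
})

test_that("locus assignment respects interval containment and tiers", {
  ranked <- tibble::tibble(gene_id = c("A", "B", "C"), final_rank = 1:3)
  info <- tibble::tibble(gene_id = c("A", "B", "C"),
                         chrom = c("chr1", "chr1", "chr2"),
                         tss = c(150L, 900L, 500L))
  loci <- tibble::tibble(chrom = c("chr1", "chr2"),
                         start = c(100L, 1000L), end = c(200L, 2000L),
                         tier = c("significant", "suggestive"))
  out <- map_to_loci(ranked, info, loci)
  expect_equal(out$tier[out$gene_id == "A"], "significant")
  expect_true(is.na(out$tier[out$gene_id == "B"]))
  expect_true(is.na(out$tier[out$gene_id == "C"]))
  expect_equal(nrow(out), 3)                 # unassigned genes retained
  counts <- attr(out, "tier_counts")
  expect_equal(counts$n[counts$tier == "significant"], 1)
  bad <- loci; bad$start[1] <- 500L
  expect_error(map_to_loci(ranked, info, bad), "line 1")
})
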