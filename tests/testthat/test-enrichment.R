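# small helper: expression tibble with genes higher in class A where stated
make_expr <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), n_genes,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%03d", seq_len(n_samples))))
  dplyr::bind_cols(tibble::tibble(gene = rownames(m)),
                   tibble::as_tibble(as.data.frame(m)))
}

test_that("signal-to-noise ranking matches the floored direct formula", {
  expr <- make_expr(40, 20, seed = 5)
  pheno <- rep(c("hi", "lo"), each = 10)
  ranked <- rank_genes(expr, pheno, positive_class = "hi")
  # direct computation for one gene
  g <- "G007"
  v <- as.numeric(expr[expr$gene == g, -1])
  a <- v[1:10]; b <- v[11:20]
  sa <- max(sd(a), 0.2 * abs(mean(a)), 0.2)
  sb <- max(sd(b), 0.2 * abs(mean(b)), 0.2)
  expect_equal(ranked$score[ranked$gene == g], (mean(a) - mean(b)) / (sa + sb),
               tolerance = 1e-12)
  expect_true(all(diff(ranked$score) <= 0))

  # planted up-shift in class A gives a positive score
  expr2 <- expr
  expr2[expr2$gene == "G001", 2:11] <- expr2[expr2$gene == "G001", 2:11] + 5
  r2 <- rank_genes(expr2, pheno, positive_class = "hi")
  expect_gt(r2$score[r2$gene == "G001"], 0)
  expect_equal(r2$gene[1], "G001")

  # identical class distributions: score exactly zero
  expr3 <- expr
  expr3[1, -1] <- as.list(rep(c(1, 2), 10))
  pheno3 <- rep(c("hi", "hi", "lo", "lo"), 5)  # both classes see {1, 2} x 5
  r3 <- rank_genes(expr3, pheno3, positive_class = "hi")
  expect_equal(r3$score[r3$gene == expr3$gene[1]], 0)

  expect_error(rank_genes(expr, rep(c("hi", "lo"), c(2, 18))), "at least 3")
})

test_that("enrichment score hand-walks: singleton sets at the extremes", {
  ranked <- tibble::tibble(gene = paste0("g", 1:8), score = seq(4, -3, length.out = 8))
  top <- enrichment_score(ranked, "g1", weight_p = 0)
  expect_equal(top$es, 1)
  expect_equal(top$running_sum$running[1], 1)
  expect_equal(top$leading_edge, "g1")

  bottom <- enrichment_score(ranked, "g8", weight_p = 0)
  expect_equal(bottom$es, brute_force_es(ranked$gene, ranked$score, "g8", 0))
  expect_equal(bottom$es, -7 / 7)  # seven misses of 1/(N-1) each before the hit
  expect_equal(bottom$leading_edge, "g8")

  # reversing the ranking negates the unweighted statistic
  rev_ranked <- tibble::tibble(gene = rev(ranked$gene), score = ranked$score)
  expect_equal(enrichment_score(rev_ranked, "g8", weight_p = 0)$es, 1)

  expect_error(enrichment_score(ranked, "absent"), "does not intersect")
  expect_error(enrichment_score(ranked, ranked$gene), "full universe")
})

test_that("enrichment score equals the brute-force running sum exhaustively (N <= 12, |set| <= 4, p in {0,1})", {
  set.seed(55)
  for (n in 3:12) {
    genes <- sprintf("g%02d", 1:n)
    scores <- sort(round(rnorm(n), 3), decreasing = TRUE)
    ranked <- tibble::tibble(gene = genes, score = scores)
    for (k in 1:min(4, n - 1)) {
      sets <- utils::combn(genes, k, simplify = FALSE)
      for (p in c(0, 1)) {
        agree <- vapply(sets, function(s) {
          es_agrees(enrichment_score(ranked, s, p)$es,
                    brute_force_es_extrema(genes, scores, s, p))
        }, logical(1))
        expect_true(all(agree))
      }
    }
  }
})

test_that("unweighted statistic reduces to the classic KS hit/miss deviation", {
  set.seed(66)
  genes <- sprintf("g%02d", 1:40)
  ranked <- tibble::tibble(gene = genes, score = sort(rnorm(40), decreasing = TRUE))
  set <- sample(genes, 8)
  es <- enrichment_score(ranked, set, weight_p = 0)$es
  hit <- genes %in% set
  cdf_hit <- cumsum(hit) / sum(hit)
  cdf_miss <- cumsum(!hit) / sum(!hit)
  dev <- cdf_hit - cdf_miss
  expect_equal(es, dev[which.max(abs(dev))], tolerance = 1e-12)
})

test_that("weighted ES agrees with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(91)
  n <- 200
  genes <- sprintf("g%03d", 1:n)
  scores <- sort(rnorm(n, 0, 2), decreasing = TRUE)
  ranked <- tibble::tibble(gene = genes, score = scores)
  stats_vec <- stats::setNames(scores, genes)
  for (k in c(5, 20, 60)) {
    set <- sample(genes, k)
    ours <- enrichment_score(ranked, set, weight_p = 1)$es
    theirs <- fgsea::calcGseaStat(stats_vec, selectedStats = which(genes %in% set),
                                  gseaParam = 1)
    expect_equal(ours, theirs, tolerance = 1e-6)
  }
})

test_that("null gene sets yield uniform nominal p-values", {
  set.seed(12)
  expr <- make_expr(120, 30, seed = 12)
  pheno <- rep(c("hi", "lo"), each = 15)
  sets <- stats::setNames(
    lapply(1:200, function(i) sample(expr$gene, 10)),
    paste0("null", 1:200)
  )
  res <- run_gsea(expr, pheno, sets, n_perm = 200, mode = "gene_set", seed = 3)
  ks <- suppressWarnings(stats::ks.test(res$nominal_p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("gsea results are reproducible for identical seeds and auto-switch modes", {
  expr <- make_expr(60, 10, seed = 8)
  pheno <- rep(c("hi", "lo"), each = 5)   # < 7 per class
  sets <- list(s1 = expr$gene[1:10], s2 = expr$gene[21:35])
  expect_message(
    r1 <- run_gsea(expr, pheno, sets, n_perm = 100, mode = "phenotype", seed = 5),
    "gene_set"
  )
  r2 <- suppressMessages(
    run_gsea(expr, pheno, sets, n_perm = 100, mode = "phenotype", seed = 5)
  )
  expect_identical(r1$es, r2$es)
  expect_identical(r1$nominal_p, r2$nominal_p)
  expect_identical(r1$fdr, r2$fdr)
})

test_that("FDR is monotone non-increasing in |NES| within each sign class", {
  set.seed(19)
  expr <- make_expr(150, 40, seed = 19)
  pheno <- rep(c("hi", "lo"), each = 20)
  expr[1:12, 2:21] <- expr[1:12, 2:21] + 1.5  # a few shifted sets
  sets <- c(
    list(up1 = expr$gene[1:6], up2 = expr$gene[7:12]),
    stats::setNames(lapply(1:10, function(i) sample(expr$gene, 8)),
                    paste0("rnd", 1:10))
  )
  res <- run_gsea(expr, pheno, sets, n_perm = 200, seed = 4)
  for (sgn in c(1, -1)) {
    sub <- res[!is.na(res$nes) & sign(res$nes) == sgn, ]
    if (nrow(sub) > 1) {
      sub <- sub[order(-abs(sub$nes)), ]
      expect_true(all(diff(sub$fdr) >= -1e-12))
    }
  }
})

test_that("leading edge from one cohort can be re-tested as a derived set on another", {
  set.seed(23)
  expr1 <- make_expr(100, 30, seed = 23)
  pheno1 <- rep(c("hi", "lo"), each = 15)
  expr1[1:15, 2:16] <- expr1[1:15, 2:16] + 2
  sets <- list(planted = expr1$gene[1:15])
  r1 <- run_gsea(expr1, pheno1, sets, n_perm = 200, seed = 6)
  derived <- r1$leading_edge[[1]]
  expect_gt(length(derived), 0)
  expect_true(all(derived %in% sets$planted))

  expr2 <- make_expr(100, 24, seed = 24)
  pheno2 <- rep(c("hi", "lo"), each = 12)
  expr2[expr2$gene %in% derived, 2:13] <-
    expr2[expr2$gene %in% derived, 2:13] + 2
  r2 <- run_gsea(expr2, pheno2, list(derived = derived), n_perm = 200, seed = 7)
  expect_lt(r2$nominal_p, 0.05)
  expect_gt(r2$es, 0)
})

test_that("Fisher over-representation matches hypergeometric tails and OR conventions", {
  # balanced table: hits proportional to set membership -> OR exactly 1
  universe <- sprintf("u%04d", 1:1000)
  set <- universe[1:100]
  hits <- c(universe[1:10], universe[101:190])  # 10/100 in set, 90/900 out
  r <- ora_fisher(hits, list(s = set), universe)
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$log2_or, 0)

  # disjoint hits and set: depleted, one-sided p = 1
  r2 <- ora_fisher(universe[501:520], list(s = set), universe)
  expect_lt(r2$odds_ratio, 1)
  expect_equal(r2$p_value, 1)

  # worked 2x2 [[8,2],[12,978]] against a direct hypergeometric tail sum
  uni <- sprintf("g%04d", 1:1000)
  st <- uni[1:20]                       # 8 + 12 in set
  ht <- c(uni[1:8], uni[21:22])         # 8 in set, 2 out
  r3 <- ora_fisher(ht, list(s = st), uni)
  expect_equal(r3$p_value, hypergeom_tail(8, 20, 1000, 10), tolerance = 1e-12)
})

test_that("Fisher p equals the hypergeometric tail sum on 100 random tables", {
  set.seed(33)
  for (i in 1:100) {
    n_uni <- sample(50:500, 1)
    uni <- sprintf("x%04d", seq_len(n_uni))
    set <- sample(uni, sample(5:min(50, n_uni - 5), 1))
    hits <- sample(uni, sample(5:min(60, n_uni - 1), 1))
    a <- length(intersect(hits, set))
    got <- ora_fisher(hits, list(s = set), uni)$p_value
    want <- hypergeom_tail(a, length(set), n_uni, length(hits))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("volcano table carries log2 OR against -log10 adjusted p, sorted", {
  universe <- sprintf("v%03d", 1:300)
  sets <- list(big = universe[1:40], null = universe[101:140])
  hits <- universe[1:30]
  res <- ora_fisher(hits, sets, universe)
  vt <- volcano_table(res)
  expect_equal(nrow(vt), 2)
  expect_true(!is.unsorted(-vt$neg_log10_adj_p))
  expect_equal(vt$neg_log10_adj_p,
               -log10(sort(res$adjusted_p)), tolerance = 1e-12)
  p <- plot_volcano(res)
  expect_s3_class(p, "ggplot")
})
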