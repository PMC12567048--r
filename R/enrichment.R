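#' Rank genes by differential expression between two phenotype classes
#'
#' Produces the ranked list feeding the enrichment score. The default
#' metric is signal-to-noise, `(mu_A - mu_B) / (sd_A + sd_B)`, with each
#' class standard deviation floored at `max(0.2 * |mean|, 0.2)` so that
#' near-constant genes cannot dominate the ranking. Positive scores mean
#' higher expression in the first (positive) class. Ties are broken
#' lexicographically by gene symbol so rankings are reproducible
#' bit-for-bit.
#'
#' @param expression Gene x sample tibble (a `gene` column plus one numeric
#'   column per sample, as from [read_gct()]).
#' @param phenotype Character/factor vector of class labels, one per sample
#'   column, with exactly two distinct values.
#' @param metric `"signal_to_noise"`, `"t_stat"` or `"log2_ratio"`.
#' @param positive_class Label treated as class A (default: first level /
#'   first encountered).
#'
#' @return A tibble with columns `gene`, `score`, sorted by decreasing
#'   score.
#' @export
rank_genes <- function(expression, phenotype,
                       metric = c("signal_to_noise", "t_stat", "log2_ratio"),
                       positive_class = NULL) {
  metric <- match.arg(metric)
  E <- expression_matrix(expression)
  phenotype <- as.character(phenotype)
  if (length(phenotype) != ncol(E)) {
    abort("phenotype length must equal the number of sample columns")
  }
  classes <- unique(phenotype)
  if (length(classes) != 2) abort("phenotype must have exactly 2 classes")
  positive_class <- positive_class %||% classes[[1]]
  if (!positive_class %in% classes) abort("positive_class not among phenotype labels")
  in_a <- phenotype == positive_class
  if (sum(in_a) < 3 || sum(!in_a) < 3) {
    abort("each phenotype class needs at least 3 samples")
  }
  score <- metric_scores(E, in_a, metric)
  ord <- order(-score, rownames(E), method = "radix")
  tibble::tibble(gene = rownames(E)[ord], score = unname(score[ord]))
}

# Per-gene differential scores for a logical class-A indicator.
metric_scores <- function(E, in_a, metric) {
  a <- E[, in_a, drop = FALSE]
  b <- E[, !in_a, drop = FALSE]
  ma <- rowMeans(a); mb <- rowMeans(b)
  switch(metric,
    signal_to_noise = {
      sa <- pmax(apply(a, 1, sd), 0.2 * abs(ma), 0.2)
      sb <- pmax(apply(b, 1, sd), 0.2 * abs(mb), 0.2)
      (ma - mb) / (sa + sb)
    },
    t_stat = {
      va <- apply(a, 1, var) / ncol(a)
      vb <- apply(b, 1, var) / ncol(b)
      (ma - mb) / sqrt(pmax(va + vb, .Machine$double.eps))
    },
    log2_ratio = {
      eps <- 1e-8
      log2((ma + eps) / (mb + eps))
    }
  )
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked gene list accumulating a running sum: a hit (gene in
#' the set) adds `|score|^p / sum(|score_hits|^p)`, a miss subtracts
#' `1 / (N - N_hits)`. The enrichment score is the signed maximum deviation
#' of the running sum from zero; at `weight_p = 0` it reduces to the
#' classic KS statistic between hit and miss positions. The leading edge
#' is the hit subset at or before the positive extremum (or at/after the
#' negative one).
#'
#' @param ranked Ranked tibble from [rank_genes()] (columns `gene`,
#'   `score`, non-increasing score).
#' @param gene_set Character vector of gene symbols; its intersection with
#'   the ranked universe must be non-empty and a proper subset.
#' @param weight_p Weighting exponent `p >= 0` (1 = canonical weighted KS).
#'
#' @return A list with elements `es`, `running_sum` (tibble `position`,
#'   `gene`, `hit`, `running`) and `leading_edge` (character vector).
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  stopifnot(is.data.frame(ranked), all(c("gene", "score") %in% names(ranked)))
  stopifnot(is.numeric(weight_p), length(weight_p) == 1, weight_p >= 0)
  genes <- ranked$gene
  n <- length(genes)
  hit <- genes %in% gene_set
  nh <- sum(hit)
  if (nh == 0) abort("gene_set does not intersect the ranked list")
  if (nh == n) abort("gene_set equals the full universe; miss decrement undefined")
  w <- abs(ranked$score)^weight_p
  wh <- w[hit]
  if (sum(wh) == 0) wh <- rep(1, nh)  # all-zero hit scores: unweighted fallback
  inc <- ifelse(hit, 0, -1 / (n - nh))
  inc[hit] <- wh / sum(wh)
  running <- cumsum(inc)
  i_max <- which.max(running); i_min <- which.min(running)
  es <- if (running[i_max] >= -running[i_min]) running[i_max] else running[i_min]
  leading_edge <- if (es >= 0) {
    genes[hit & seq_len(n) <= i_max]
  } else {
    genes[hit & seq_len(n) >= i_min]
  }
  list(
    es = es,
    running_sum = tibble::tibble(position = seq_len(n), gene = genes,
                                 hit = hit, running = running),
    leading_edge = leading_edge
  )
}

# Fast ES from sorted hit positions and their rank weights; mirrors
# enrichment_score() without materialising the running sum. Used inside the
# permutation loop.
es_from_positions <- function(hit_pos, hit_w, n) {
  nh <- length(hit_pos)
  if (sum(hit_w) == 0) hit_w <- rep(1, nh)
  cumw <- cumsum(hit_w) / sum(hit_w)
  miss <- (hit_pos - seq_len(nh)) / (n - nh)
  peaks <- cumw - miss                 # running sum at each hit
  troughs <- c(0, cumw[-nh]) - miss    # running sum just before each hit
  hi <- max(peaks)
  lo <- min(troughs, 0)
  if (hi >= -lo) hi else lo
}

#' GSEA with a permutation null: nominal p, NES and sign-pooled FDR
#'
#' Runs the weighted-KS enrichment of each gene set against a two-class
#' phenotype and calibrates it with a permutation null (1000 permutations
#' by default). In `"phenotype"` mode the class labels are permuted and
#' the whole ranking recomputed per permutation (preserving gene-gene
#' correlation); this requires at least 7 samples per class, below which
#' the engine falls back to `"gene_set"` mode (random gene labels) with a
#' message. The nominal p-value is the fraction of same-sign permuted
#' scores at least as extreme; NES divides the score by the mean absolute
#' same-sign permuted score; the FDR is the canonical ratio of pooled
#' permuted-NES tail mass to observed-NES tail mass within each sign
#' class, made monotone non-increasing in |NES|.
#'
#' @param expression Gene x sample tibble (`gene` column + sample columns).
#' @param phenotype Two-class label vector, one per sample column.
#' @param gene_sets Long tibble (`set_name`, `gene`) as from [read_gmt()],
#'   or a named list of gene vectors.
#' @param n_perm Number of permutations (>= 100).
#' @param mode `"phenotype"` or `"gene_set"`.
#' @param weight_p Weighting exponent of the running sum.
#' @param metric Ranking metric, see [rank_genes()].
#' @param positive_class Label treated as class A.
#' @param seed Integer seed making the permutation stream reproducible.
#' @param min_set_size Sets with fewer ranked genes than this are dropped.
#'
#' @return A tibble with one row per gene set: `set_name`, `size`, `es`,
#'   `nes`, `nominal_p`, `fdr`, `leading_edge` (list column).
#' @export
run_gsea <- function(expression, phenotype, gene_sets, n_perm = 1000,
                     mode = c("phenotype", "gene_set"), weight_p = 1,
                     metric = "signal_to_noise", positive_class = NULL,
                     seed = NULL, min_set_size = 2) {
  mode <- match.arg(mode)
  if (n_perm < 100) abort("n_perm must be at least 100")
  if (!is.null(seed)) set.seed(seed)

  if (is.data.frame(gene_sets)) gene_sets <- gene_set_list(gene_sets)
  if (is.null(names(gene_sets)) || any(!nzchar(names(gene_sets)))) {
    abort("gene_sets must be named")
  }
  E <- expression_matrix(expression)
  phenotype <- as.character(phenotype)
  classes <- unique(phenotype)
  if (length(classes) != 2) abort("phenotype must have exactly 2 classes")
  positive_class <- positive_class %||% classes[[1]]
  in_a <- phenotype == positive_class
  if (mode == "phenotype" && min(sum(in_a), sum(!in_a)) < 7) {
    inform("Fewer than 7 samples in a class: switching to gene_set permutation mode")
    mode <- "gene_set"
  }

  ranked <- rank_genes(expression, phenotype, metric = metric,
                       positive_class = positive_class)
  universe <- ranked$gene
  n <- length(universe)
  sets <- lapply(gene_sets, function(g) intersect(universe, unique(g)))
  sizes <- lengths(sets)
  keep <- sizes >= min_set_size & sizes < n
  if (!any(keep)) abort("no gene set passes the size filter after universe intersection")
  sets <- sets[keep]

  obs <- lapply(sets, function(g) enrichment_score(ranked, g, weight_p))
  obs_es <- vapply(obs, `[[`, numeric(1), "es")

  rank_of <- stats::setNames(seq_len(n), universe)
  w_ranked <- abs(ranked$score)^weight_p

  perm_es <- matrix(NA_real_, n_perm, length(sets),
                    dimnames = list(NULL, names(sets)))
  if (mode == "gene_set") {
    set_sizes <- lengths(sets)
    for (b in seq_len(n_perm)) {
      for (k in seq_along(sets)) {
        pos <- sort.int(sample.int(n, set_sizes[[k]]))
        perm_es[b, k] <- es_from_positions(pos, w_ranked[pos], n)
      }
    }
  } else {
    perm_scores <- permuted_metric_scores(E, in_a, metric, n_perm)
    gene_names <- rownames(E)
    for (b in seq_len(n_perm)) {
      sc <- perm_scores[, b]
      ord <- order(-sc, gene_names, method = "radix")
      pr <- integer(n); pr[ord] <- seq_len(n)   # rank of each gene this perm
      wp <- abs(sc[ord])^weight_p
      for (k in seq_along(sets)) {
        pos <- sort.int(pr[rank_of[sets[[k]]]])
        perm_es[b, k] <- es_from_positions(pos, wp[pos], n)
      }
    }
  }

  res <- gsea_calibrate(obs_es, perm_es, n_perm)
  res$leading_edge <- lapply(obs, `[[`, "leading_edge")
  res$size <- lengths(sets)
  res[, c("set_name", "size", "es", "nes", "nominal_p", "fdr", "leading_edge")]
}

# Per-gene metric scores under n_perm label permutations, computed with
# matrix products (class sums and sums of squares against a permuted
# indicator matrix) so phenotype mode stays tractable at cohort scale.
permuted_metric_scores <- function(E, in_a, metric, n_perm) {
  n_samp <- ncol(E)
  na <- sum(in_a); nb <- n_samp - na
  P <- vapply(seq_len(n_perm), function(b) as.numeric(sample(in_a)),
              numeric(n_samp))
  SA <- E %*% P
  tot <- rowSums(E)
  MA <- SA / na
  MB <- (tot - SA) / nb
  if (metric == "log2_ratio") {
    eps <- 1e-8
    return(log2((MA + eps) / (MB + eps)))
  }
  SSA <- (E^2) %*% P
  tot2 <- rowSums(E^2)
  VA <- (SSA - SA^2 / na) / (na - 1)
  VB <- ((tot2 - SSA) - (tot - SA)^2 / nb) / (nb - 1)
  VA <- pmax(VA, 0); VB <- pmax(VB, 0)
  if (metric == "signal_to_noise") {
    SDA <- pmax(sqrt(VA), 0.2 * abs(MA), 0.2)
    SDB <- pmax(sqrt(VB), 0.2 * abs(MB), 0.2)
    (MA - MB) / (SDA + SDB)
  } else {
    (MA - MB) / sqrt(pmax(VA / na + VB / nb, .Machine$double.eps))
  }
}

# Nominal p, NES and sign-pooled FDR from observed and permuted ES.
gsea_calibrate <- function(obs_es, perm_es, n_perm) {
  k <- length(obs_es)
  nes <- numeric(k); nominal_p <- numeric(k)
  perm_nes <- vector("list", k)
  for (i in seq_len(k)) {
    pe <- perm_es[, i]
    pos <- pe[pe >= 0]; neg <- pe[pe < 0]
    mean_pos <- if (length(pos) > 0) mean(pos) else NA_real_
    mean_neg <- if (length(neg) > 0) mean(abs(neg)) else NA_real_
    if (obs_es[i] >= 0) {
      if (length(pos) == 0) {
        nominal_p[i] <- 1 / (n_perm + 1)   # reported below 1/n_perm
        nes[i] <- NA_real_
      } else {
        nominal_p[i] <- sum(pos >= obs_es[i]) / length(pos)
        nes[i] <- obs_es[i] / mean_pos
      }
    } else {
      if (length(neg) == 0) {
        nominal_p[i] <- 1 / (n_perm + 1)
        nes[i] <- NA_real_
      } else {
        nominal_p[i] <- sum(neg <= obs_es[i]) / length(neg)
        nes[i] <- obs_es[i] / mean_neg
      }
    }
    # normalize this set's permuted ES by the same sign means (for FDR pooling)
    pn <- pe
    pn[pe >= 0] <- if (is.na(mean_pos)) NA_real_ else pe[pe >= 0] / mean_pos
    pn[pe < 0] <- if (is.na(mean_neg)) NA_real_ else pe[pe < 0] / mean_neg
    perm_nes[[i]] <- pn
  }
  pool <- unlist(perm_nes)
  pool <- pool[is.finite(pool)]
  fdr <- rep(NA_real_, k)
  pos_obs <- nes[!is.na(nes) & nes >= 0]
  neg_obs <- nes[!is.na(nes) & nes < 0]
  pool_pos <- pool[pool >= 0]; pool_neg <- pool[pool < 0]
  for (i in seq_len(k)) {
    if (is.na(nes[i])) { fdr[i] <- 0; next }
    if (nes[i] >= 0) {
      num <- if (length(pool_pos) > 0) mean(pool_pos >= nes[i]) else 0
      den <- mean(pos_obs >= nes[i])
    } else {
      num <- if (length(pool_neg) > 0) mean(pool_neg <= nes[i]) else 0
      den <- mean(neg_obs <= nes[i])
    }
    fdr[i] <- min(num / max(den, .Machine$double.eps), 1)
  }
  # enforce monotone non-increasing FDR in |NES| within each sign class:
  # walk from the least extreme set to the most extreme, taking running minima,
  # so a more extreme set never reports a larger FDR than a less extreme one
  pos_idx <- which(!is.na(nes) & nes >= 0)
  if (length(pos_idx) > 1) {
    ord <- pos_idx[order(nes[pos_idx])]
    fdr[ord] <- cummin(fdr[ord])
  }
  neg_idx <- which(!is.na(nes) & nes < 0)
  if (length(neg_idx) > 1) {
    ord <- neg_idx[order(-nes[neg_idx])]
    fdr[ord] <- cummin(fdr[ord])
  }
  tibble::tibble(set_name = names(obs_es) %||% colnames(perm_es),
                 es = unname(obs_es), nes = unname(nes),
                 nominal_p = unname(nominal_p), fdr = unname(fdr))
}

#' Fisher over-representation analysis of gene sets against a hit list
#'
#' One-sided (enrichment) Fisher exact test of each gene set's overlap
#' with a hit list inside a fixed universe, with Benjamini-Hochberg
#' adjustment across sets. The odds ratio is the sample cross-product
#' ratio with Haldane's +0.5 continuity correction applied when any cell
#' is zero, so `log2_or` is always finite.
#'
#' @param hits Character vector of hit gene symbols (subset of universe).
#' @param gene_sets Long tibble (`set_name`, `gene`) or named list.
#' @param universe Character vector of all testable gene symbols.
#'
#' @return A tibble with one row per set: `set_name`, `n_hit_in_set`,
#'   `n_set`, `n_hit`, `n_universe`, `odds_ratio`, `log2_or`, `p_value`,
#'   `adjusted_p`, `neg_log10_adj_p`.
#' @export
ora_fisher <- function(hits, gene_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("universe is empty")
  hits <- unique(intersect(hits, universe))
  if (is.data.frame(gene_sets)) gene_sets <- gene_set_list(gene_sets)
  res <- purrr::imap_dfr(gene_sets, function(set, name) {
    set <- unique(intersect(set, universe))
    a <- length(intersect(hits, set))
    b <- length(hits) - a
    c_ <- length(set) - a
    d <- length(universe) - a - b - c_
    p <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                     alternative = "greater")$p.value
    cells <- c(a, b, c_, d)
    if (any(cells == 0)) cells <- cells + 0.5
    or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    tibble::tibble(
      set_name = name, n_hit_in_set = a, n_set = length(set),
      n_hit = length(hits), n_universe = length(universe),
      odds_ratio = or, log2_or = log2(or), p_value = p
    )
  })
  res$adjusted_p <- bh_adjust(res$p_value)
  res$neg_log10_adj_p <- -log10(pmax(res$adjusted_p, .Machine$double.xmin))
  res
}

#' Volcano table for over-representation results
#'
#' @param results Tibble from [ora_fisher()].
#'
#' @return Tibble `set_name`, `log2_or`, `neg_log10_adj_p`, sorted by
#'   adjusted p.
#' @export
volcano_table <- function(results) {
  stopifnot(all(c("set_name", "log2_or", "adjusted_p") %in% names(results)))
  out <- dplyr::arrange(results, .data$adjusted_p)
  if (!"neg_log10_adj_p" %in% names(out)) {
    out$neg_log10_adj_p <- -log10(pmax(out$adjusted_p, .Machine$double.xmin))
  }
  out[, c("set_name", "log2_or", "neg_log10_adj_p")]
}

#' Volcano plot of over-representation odds ratios
#'
#' @param results Tibble from [ora_fisher()].
#' @param alpha Adjusted-p significance line (default 0.05).
#'
#' @return A ggplot object: log2 OR vs -log10 adjusted p.
#' @export
plot_volcano <- function(results, alpha = 0.05) {
  tab <- volcano_table(results)
  ggplot2::ggplot(tab, ggplot2::aes(.data$log2_or, .data$neg_log10_adj_p)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "log2 odds ratio", y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' Running-sum plot for one gene set
#'
#' @param es_result Result of [enrichment_score()].
#' @param set_name Optional label for the subtitle.
#'
#' @return A ggplot object of the running enrichment sum.
#' @export
plot_enrichment <- function(es_result, set_name = NULL) {
  rs <- es_result$running_sum
  ggplot2::ggplot(rs, ggplot2::aes(.data$position, .data$running)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_rug(data = rs[rs$hit, ], sides = "b") +
    ggplot2::labs(
      x = "Rank", y = "Running enrichment score",
      subtitle = paste0(if (!is.null(set_name)) paste0(set_name, ": "),
                        "ES = ", format(es_result$es, digits = 3))
    ) +
    ggplot2::theme_minimal()
}
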