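#' Remove known fusion-positive samples
#'
#' Set-difference row filter for excluding samples with structural-variant
#' confirmed NTRK fusions before cryptic-fusion analysis. Exclusion ids
#' absent from the cohort produce a warning but no effect.
#'
#' @param samples Character vector of sample ids.
#' @param exclusion_list Character vector of ids to drop.
#'
#' @return The retained ids, in the original order.
#' @export
#'
#' @examples
#' exclude_known_fusions(c("a", "b", "c"), c("b"))
exclude_known_fusions <- function(samples, exclusion_list) {
  missing <- setdiff(exclusion_list, samples)
  if (length(missing) > 0) {
    warn(paste0(length(missing), " exclusion id(s) not present in the cohort: ",
                paste(utils::head(missing, 5), collapse = ", ")))
  }
  kept <- setdiff(samples, exclusion_list)
  inform(paste0("Excluded ", length(samples) - length(kept), " of ",
                length(samples), " samples; ", length(kept), " retained"))
  kept
}

# Read one cohort layer bundle from a directory written by write_cohort().
read_cohort_bundle <- function(directory) {
  list(
    expression = read_gct(file.path(directory, "expression.gct")),
    segments = read_seg(file.path(directory, "segments.seg")),
    gene_cna = readr::read_tsv(file.path(directory, "gene_cna.tsv"),
                               show_col_types = FALSE),
    methylation = readr::read_tsv(file.path(directory, "methylation.tsv"),
                                  show_col_types = FALSE),
    clinical = readr::read_tsv(file.path(directory, "clinical.tsv"),
                               show_col_types = FALSE)
  )
}

# Per-cohort preprocessing: winsorize + minmax each NTRK gene row, return a
# per-sample profile tibble.
preprocess_cohort <- function(bundle, recipe) {
  expr <- bundle$expression
  samples <- setdiff(names(expr), c("gene", "description"))
  prof <- tibble::tibble(sample = samples)
  for (g in names(recipe$trim_fraction)) {
    row <- which(toupper(expr$gene) == g)
    if (length(row) != 1) next
    vals <- as.numeric(unlist(expr[row, samples]))
    vals <- winsorize(vals, recipe$trim_fraction[[g]], per_tail = recipe$per_tail)
    prof[[paste0(tolower(g), "_expr")]] <- minmax_normalize(vals)
  }
  prof
}

#' Default preprocessing recipe for the NTRK genes
#'
#' Winsorization trimmed mass 0.15 for NTRK1 and NTRK3 and 0.30 for NTRK2
#' (split symmetrically across tails unless `per_tail = TRUE`), followed by
#' per-cohort zero-to-one normalization and per-gene pooled-median
#' dichotomization.
#'
#' @param trim_fraction Named list/vector of per-gene trimmed mass.
#' @param per_tail Whether `trim_fraction` applies per tail.
#' @param dichotomy_rule `"per_gene_pooled_median"` or
#'   `"pooled_all_genes_median"`.
#'
#' @return A list of class `"normalization_recipe"`.
#' @export
normalization_recipe <- function(trim_fraction = c(NTRK1 = 0.15, NTRK2 = 0.30,
                                                   NTRK3 = 0.15),
                                 per_tail = FALSE,
                                 dichotomy_rule = c("per_gene_pooled_median",
                                                    "pooled_all_genes_median")) {
  dichotomy_rule <- match.arg(dichotomy_rule)
  if (any(trim_fraction < 0 | trim_fraction >= 0.5)) {
    abort("trim fractions must lie in [0, 0.5)")
  }
  structure(list(trim_fraction = as.list(trim_fraction), per_tail = per_tail,
                 dichotomy_rule = dichotomy_rule),
            class = "normalization_recipe")
}

#' Run the integrated NTRK analysis pipeline on two cohorts
#'
#' Executes the full analysis flow: per-cohort winsorization and
#' zero-to-one normalization of NTRK1/2/3 expression, cohort pooling with
#' a bias report, pooled-median dichotomization, segment-based deletion
#' calling at the stringent threshold, NFS1/NFS2 cryptic-fusion scoring,
#' inter-gene and methylation-expression Spearman correlations, the
#' deregulation regressions of expression on methylation, copy number,
#' fusion score and cohort, the clinicopathological association battery
#' with per-block FDR, log-rank survival comparisons, and (when gene sets
#' are supplied) per-cohort GSEA against the chosen marker phenotype. A
#' manifest records thresholds, seeds, per-stage row counts and content
#' hashes so reruns are verifiable.
#'
#' @param cohort_a,cohort_b Either `synthetic_cohort` objects, bundle
#'   lists with elements `expression`, `segments`, `gene_cna`,
#'   `methylation`, `clinical`, or directories written by [write_cohort()].
#' @param labels Cohort labels (length 2).
#' @param recipe A [normalization_recipe()].
#' @param deletion_threshold Segment-mean deletion threshold (default -0.3).
#' @param loci Gene locus registry (default [gene_registry()]).
#' @param exclusion_list Sample ids with known fusions to drop up front.
#' @param gene_sets Optional gene sets (long tibble or named list) for the
#'   enrichment stage.
#' @param gsea_marker Profile column used as the GSEA phenotype (default
#'   `"nfs2_high"`).
#' @param n_perm Permutations for the enrichment null.
#' @param seed Seed for the stochastic stages (mandatory when `gene_sets`
#'   is supplied).
#'
#' @return An object of class `"ntrk_pipeline_result"`: a list with
#'   `profiles`, `bias_report`, `deletions`, `fusion_scores`,
#'   `fusion_summary`, `correlations`, `regressions` (tidy coefficient
#'   table), `regression_fits`, `associations`, `survival`, `enrichment`
#'   (or NULL) and `manifest`.
#' @export
run_ntrk_pipeline <- function(cohort_a, cohort_b, labels = c("A", "B"),
                              recipe = normalization_recipe(),
                              deletion_threshold = -0.3,
                              loci = gene_registry(),
                              exclusion_list = character(0),
                              gene_sets = NULL, gsea_marker = "nfs2_high",
                              n_perm = 1000, seed = NULL) {
  if (!is.null(gene_sets) && is.null(seed)) {
    abort("seed is mandatory when the enrichment stage runs")
  }
  as_bundle <- function(x) {
    if (inherits(x, "synthetic_cohort")) return(unclass(x))
    if (is.character(x) && length(x) == 1) return(read_cohort_bundle(x))
    if (is.list(x) && all(c("expression", "segments", "clinical") %in% names(x))) {
      return(x)
    }
    abort("cohort must be a synthetic_cohort, a bundle list, or a directory path")
  }
  a <- as_bundle(cohort_a)
  b <- as_bundle(cohort_b)
  manifest <- list(
    deletion_threshold = deletion_threshold,
    recipe = unclass(recipe),
    seed = seed,
    n_perm = if (is.null(gene_sets)) NULL else n_perm,
    stages = list()
  )
  log_stage <- function(name, n_in, n_out, note = NULL) {
    manifest$stages[[name]] <<- list(n_in = n_in, n_out = n_out, note = note)
    inform(sprintf("[%s] in = %d, out = %d%s", name, n_in, n_out,
                   if (is.null(note)) "" else paste0(" (", note, ")")))
  }

  # exclusion of known fusion-positive samples -------------------------
  for (side in c("a", "b")) {
    bundle <- get(side)
    ids <- bundle$clinical$sample
    if (length(exclusion_list) > 0) {
      kept <- suppressMessages(
        exclude_known_fusions(ids, intersect(exclusion_list, ids))
      )
      bundle$clinical <- bundle$clinical[bundle$clinical$sample %in% kept, ]
      keep_cols <- c("gene", "description", kept)
      bundle$expression <- bundle$expression[
        , intersect(names(bundle$expression), keep_cols)]
      bundle$segments <- bundle$segments[bundle$segments$sample %in% kept, ]
      assign(side, bundle)
    }
  }

  # preprocess + pool ---------------------------------------------------
  prof_a <- preprocess_cohort(a, recipe)
  prof_b <- preprocess_cohort(b, recipe)
  prof_a <- dplyr::inner_join(prof_a, a$clinical, by = "sample")
  prof_b <- dplyr::inner_join(prof_b, b$clinical, by = "sample")
  dropped <- (nrow(a$clinical) + nrow(b$clinical)) - (nrow(prof_a) + nrow(prof_b))
  pooled <- pool_cohorts(prof_a, prof_b, labels = labels)
  log_stage("preprocess_pool", nrow(a$clinical) + nrow(b$clinical), nrow(pooled),
            if (dropped > 0) paste0(dropped, " samples without expression dropped"))
  expr_cols <- grep("_expr$", names(pooled), value = TRUE)
  bias_report <- cohort_bias(pooled, variables = expr_cols)

  # dichotomize ---------------------------------------------------------
  if (recipe$dichotomy_rule == "pooled_all_genes_median") {
    cut_all <- median(unlist(pooled[expr_cols]), na.rm = TRUE)
  }
  for (col in expr_cols) {
    cutoff <- if (recipe$dichotomy_rule == "per_gene_pooled_median") {
      median(pooled[[col]], na.rm = TRUE)
    } else {
      cut_all
    }
    lab <- dichotomize(pooled[[col]], cutoff)
    pooled[[sub("_expr$", "_high", col)]] <- lab == "high"
    manifest$stages[[paste0("cutoff_", col)]] <- list(cutoff = cutoff)
  }

  # deletion calling + NFS ----------------------------------------------
  segments <- dplyr::bind_rows(a$segments, b$segments)
  segments <- segments[segments$sample %in% pooled$sample, ]
  deletions <- call_deletion(segments, loci = loci,
                             threshold = deletion_threshold,
                             samples = pooled$sample)
  scores <- compute_nfs(
    deletions,
    tibble::tibble(sample = pooled$sample, ntrk3_high = pooled$ntrk3_high)
  )
  pooled <- dplyr::left_join(
    pooled,
    scores[, c("sample", "nfs1", "nfs2", "nfs1_high", "nfs2_high")],
    by = "sample"
  )
  fusion_summary <- summarize_fusion_cohort(scores)
  log_stage("nfs", nrow(segments), nrow(scores))

  # correlations ---------------------------------------------------------
  meth <- dplyr::bind_rows(a$methylation, b$methylation)
  meth_wide <- tidyr::pivot_wider(meth, names_from = "gene",
                                  values_from = "beta", names_prefix = "meth_")
  names(meth_wide) <- tolower(names(meth_wide))
  pooled <- dplyr::left_join(pooled, meth_wide, by = "sample")
  gene_pairs <- utils::combn(c("ntrk1", "ntrk2", "ntrk3"), 2, simplify = FALSE)
  correlations <- dplyr::bind_rows(
    purrr::map_dfr(gene_pairs, function(p) {
      r <- spearman_test(pooled, !!rlang::sym(paste0(p[1], "_expr")),
                         !!rlang::sym(paste0(p[2], "_expr")))
      dplyr::mutate(r, pair = paste(toupper(p[1]), "vs", toupper(p[2])),
                    kind = "inter-gene", .before = 1)
    }),
    purrr::map_dfr(c("ntrk1", "ntrk2", "ntrk3"), function(g) {
      mcol <- paste0("meth_", g)
      if (!mcol %in% names(pooled) || all(is.na(pooled[[mcol]]))) return(NULL)
      r <- spearman_test(pooled, !!rlang::sym(mcol),
                         !!rlang::sym(paste0(g, "_expr")))
      dplyr::mutate(r, pair = paste(toupper(g), "methylation vs expression"),
                    kind = "methylation", .before = 1)
    })
  )

  # deregulation regressions ---------------------------------------------
  cna <- dplyr::bind_rows(a$gene_cna, b$gene_cna)
  cna <- categorize_cna(cna[toupper(cna$gene) %in% c("NTRK1", "NTRK2", "NTRK3"), ])
  cna_step <- dplyr::mutate(cna, step = as.integer(.data$category) - 2L)
  cna_wide <- tidyr::pivot_wider(
    dplyr::transmute(cna_step, .data$sample, gene = tolower(.data$gene), .data$step),
    names_from = "gene", values_from = "step", names_prefix = "cna_"
  )
  pooled <- dplyr::left_join(pooled, cna_wide, by = "sample")
  regression_fits <- list()
  for (g in c("ntrk1", "ntrk2", "ntrk3")) {
    terms <- c(paste0("meth_", g), paste0("cna_", g), "cohort")
    if (g == "ntrk3") terms <- c(terms, "nfs2")
    terms <- terms[vapply(terms, function(t)
      t %in% names(pooled) && !all(is.na(pooled[[t]])), logical(1))]
    fml <- stats::as.formula(paste(paste0(g, "_expr"), "~",
                                   paste(terms, collapse = " + ")))
    dat <- pooled[complete.cases(pooled[c(paste0(g, "_expr"), terms)]), ]
    if (nrow(dat) > length(terms) + 2) {
      regression_fits[[g]] <- fit_linear(dat, fml)
    }
  }
  regressions <- purrr::imap_dfr(regression_fits, function(f, g) {
    dplyr::mutate(tidy(f), outcome = paste0(toupper(g), " expression"),
                  .before = 1)
  })

  # clinicopathological association battery ------------------------------
  clin_vars <- intersect(
    c("age", "sex", "location", "t_stage", "n_stage", "m_stage", "tnm_stage",
      "msi_status", "subtype", "braf_mut", "tp53_mut", "fga", "tmb",
      "aneuploidy"),
    names(pooled)
  )
  markers <- intersect(c("ntrk1_high", "ntrk2_high", "ntrk3_high",
                         "nfs1_high", "nfs2_high"), names(pooled))
  associations <- purrr::map_dfr(markers, function(m) {
    association_block(pooled, m, clin_vars)
  })

  # survival --------------------------------------------------------------
  survival_results <- NULL
  if (all(c("os_time", "os_event") %in% names(pooled))) {
    survival_results <- purrr::map_dfr(markers, function(m) {
      d <- pooled[!is.na(pooled[[m]]), ]
      fit <- tryCatch(
        km_logrank(d, os_time, os_event, !!rlang::sym(m)),
        error = function(e) NULL
      )
      if (is.null(fit)) return(NULL)
      dplyr::mutate(glance(fit), marker = m, endpoint = "OS", .before = 1)
    })
  }

  # enrichment -------------------------------------------------------------
  enrichment <- NULL
  if (!is.null(gene_sets)) {
    enrichment <- purrr::map_dfr(list(a, b), function(bundle) {
      samp <- intersect(
        setdiff(names(bundle$expression), c("gene", "description")),
        pooled$sample
      )
      expr <- bundle$expression[, c("gene", samp)]
      pheno_tbl <- pooled[match(samp, pooled$sample), ]
      pheno <- ifelse(pheno_tbl[[gsea_marker]], "high", "low")
      cohort_label <- pheno_tbl$cohort[1]
      res <- run_gsea(expr, pheno, gene_sets, n_perm = n_perm,
                      positive_class = "high", seed = seed)
      dplyr::mutate(res, cohort = cohort_label, .before = 1)
    })
    log_stage("enrichment", length(unique(enrichment$set_name)) * 2,
              nrow(enrichment))
  }

  manifest$checksums <- list(
    profiles = rlang::hash(pooled),
    fusion_scores = rlang::hash(scores),
    associations = rlang::hash(associations),
    enrichment = if (is.null(enrichment)) NULL else rlang::hash(enrichment)
  )
  structure(
    list(
      profiles = pooled, bias_report = bias_report, deletions = deletions,
      fusion_scores = scores, fusion_summary = fusion_summary,
      correlations = correlations, regressions = regressions,
      regression_fits = regression_fits, associations = associations,
      survival = survival_results, enrichment = enrichment,
      manifest = manifest
    ),
    class = "ntrk_pipeline_result"
  )
}

#' @export
print.ntrk_pipeline_result <- function(x, ...) {
  cat("<ntrk_pipeline_result> ", nrow(x$profiles), " pooled samples\n", sep = "")
  cat("Fusion summary:\n")
  print(x$fusion_summary)
  invisible(x)
}

#' Fusion-score composition plot
#'
#' Bar chart of the cohort fusion-score summary from a pipeline result.
#'
#' @param result An `ntrk_pipeline_result`.
#'
#' @return A ggplot object.
#' @export
plot_fusion_summary <- function(result) {
  tab <- result$fusion_summary
  tab <- tab[tab$measure != "samples", ]
  ggplot2::ggplot(tab, ggplot2::aes(.data$measure, .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Fraction of cohort") +
    ggplot2::theme_minimal()
}
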