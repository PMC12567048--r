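#' Specification of a synthetic cancer cohort
#'
#' Validates and freezes the parameters of one synthetic cohort: the
#' planted cryptic-fusion fraction, the dose-dependent copy-number effect
#' on NTRK2 expression, the (negative) methylation-expression coupling of
#' the three NTRK genes, the residual noise level, and the CIN/MSI/GS
#' molecular-subtype mix driving the clinical covariates. Defaults emulate
#' a colorectal-cancer cohort: fusion fraction 0.085 (the observed
#' NFS2-high rate scale), +1 expression unit per copy-number category step
#' for NTRK2, methylation slope -3 expression units per unit beta with
#' Beta(2,2) beta values, unit noise SD, and a 60/25/15 CIN/MSI/GS mix.
#'
#' @param n_samples Positive integer cohort size.
#' @param cohort_label Cohort name used as sample-id prefix.
#' @param fusion_fraction Proportion in `[0, 1]` of samples planted with a
#'   5'-half NTRK3 deletion, one partner deletion and an NTRK3
#'   overexpression shift of `+3 * noise_sd`.
#' @param cna_dose_effect Additive expression shift per CNA category step,
#'   applied to NTRK2.
#' @param methylation_slope Negative real: expression change per unit
#'   methylation beta for NTRK1/2/3.
#' @param noise_sd Positive residual SD of raw expression.
#' @param subtype_proportions Named 3-vector over CIN/MSI/GS summing to 1.
#' @param n_background_genes Number of background panel genes beyond the
#'   ten registry genes (use different values for the two cohorts to
#'   emulate unequal gene panels).
#' @param seed Integer seed; generation is fully deterministic given it.
#'
#' @return A validated object of class `"cohort_spec"`.
#' @export
#'
#' @examples
#' cohort_spec(50, seed = 1)
cohort_spec <- function(n_samples, cohort_label = "A", fusion_fraction = 0.085,
                        cna_dose_effect = 1, methylation_slope = -3,
                        noise_sd = 1,
                        subtype_proportions = c(CIN = 0.60, MSI = 0.25, GS = 0.15),
                        n_background_genes = 190, seed = 1) {
  if (!is.numeric(n_samples) || length(n_samples) != 1 || n_samples < 1 ||
      n_samples != round(n_samples)) {
    abort("n_samples must be a positive integer")
  }
  if (!is.numeric(fusion_fraction) || fusion_fraction < 0 || fusion_fraction > 1) {
    abort("fusion_fraction must lie in [0, 1]")
  }
  if (!is.numeric(methylation_slope) || methylation_slope > 0) {
    abort("methylation_slope must be a non-positive real")
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) abort("noise_sd must be positive")
  if (length(subtype_proportions) != 3 ||
      abs(sum(subtype_proportions) - 1) > 1e-9 || any(subtype_proportions < 0)) {
    abort("subtype_proportions must be a non-negative 3-vector summing to 1")
  }
  if (is.null(names(subtype_proportions))) {
    names(subtype_proportions) <- c("CIN", "MSI", "GS")
  }
  structure(
    list(
      n_samples = as.integer(n_samples), cohort_label = cohort_label,
      fusion_fraction = fusion_fraction, cna_dose_effect = cna_dose_effect,
      methylation_slope = methylation_slope, noise_sd = noise_sd,
      subtype_proportions = subtype_proportions,
      n_background_genes = as.integer(n_background_genes),
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", x$cohort_label, ": n = ", x$n_samples,
      ", fusion fraction = ", x$fusion_fraction,
      ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic cancer cohort
#'
#' Draws one cohort with the planted statistical structure the downstream
#' analysis assumes: a Binomial(`n`, `fusion_fraction`) subset of samples
#' carries a copy-number segment over the 5' half of NTRK3 (strand aware)
#' plus a whole-gene deletion of one randomly chosen 5' partner, both with
#' segment means drawn Uniform(-1.2, -0.35), together with an NTRK3
#' expression shift of `+3 * noise_sd`; NTRK2 expression rises by
#' `cna_dose_effect` per copy-number category step; NTRK1/2/3 expression
#' falls linearly in their Beta(2,2) methylation beta values; and clinical
#' covariates (MSI status, tumour location, BRAF/TP53 mutation, FGA, TMB,
#' aneuploidy, stage, survival) are drawn conditional on the planted
#' CIN/MSI/GS subtype. Background segment means are Normal(0, 0.1), so
#' spurious deletion calls at the -0.3 threshold are rare but possible.
#'
#' @param spec A [cohort_spec()].
#'
#' @return An object of class `"synthetic_cohort"`: a list of tibbles
#'   `expression` (gene x sample, wide, raw scale), `segments`,
#'   `gene_cna` (long, GISTIC codes), `methylation` (long, beta values),
#'   `clinical`, and `truth` (per-sample planted labels).
#' @export
#'
#' @examples
#' cohort <- generate_cohort(cohort_spec(30, seed = 7))
#' names(cohort)
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) abort("spec must be a cohort_spec object")
  set.seed(spec$seed)
  n <- spec$n_samples
  samples <- sprintf("%s-%04d", spec$cohort_label, seq_len(n))
  reg <- gene_registry()
  ntrk <- c("NTRK1", "NTRK2", "NTRK3")
  partners <- ntrk3_partners()
  bg_genes <- if (spec$n_background_genes > 0) {
    sprintf("BG%04d", seq_len(spec$n_background_genes))
  } else character(0)
  genes <- c(reg$symbol, bg_genes)

  # planted truth ------------------------------------------------------
  subtype <- sample(names(spec$subtype_proportions), n, replace = TRUE,
                    prob = spec$subtype_proportions)
  fusion <- runif(n) < spec$fusion_fraction
  partner_pick <- ifelse(fusion, sample(partners, n, replace = TRUE), NA_character_)
  fusion_seg_mean <- ifelse(fusion, runif(n, -1.2, -0.35), NA_real_)
  partner_seg_mean <- ifelse(fusion, runif(n, -1.2, -0.35), NA_real_)

  # methylation (NTRK1/2/3 betas) --------------------------------------
  beta <- matrix(rbeta(3 * n, 2, 2), nrow = 3,
                 dimnames = list(ntrk, samples))

  # gene-level CNA categories (GISTIC codes) ---------------------------
  gistic_probs <- c(`-2` = 0.02, `-1` = 0.15, `0` = 0.60, `1` = 0.18, `2` = 0.05)
  cna_code <- matrix(
    sample(c(-2L, -1L, 0L, 1L, 2L), length(genes) * n, replace = TRUE,
           prob = gistic_probs),
    nrow = length(genes), dimnames = list(genes, samples)
  )
  # keep the gene-level layer coherent with planted fusion deletions
  cna_code["NTRK3", fusion] <- -1L
  for (i in which(fusion)) cna_code[partner_pick[i], samples[i]] <- -1L

  # expression ---------------------------------------------------------
  baseline <- stats::setNames(c(rep(8, nrow(reg)), rnorm(length(bg_genes), 8, 1)),
                              genes)
  expr <- matrix(rnorm(length(genes) * n, 0, spec$noise_sd),
                 nrow = length(genes), dimnames = list(genes, samples))
  expr <- expr + baseline
  expr[ntrk, ] <- expr[ntrk, ] + spec$methylation_slope * beta
  expr["NTRK2", ] <- expr["NTRK2", ] + spec$cna_dose_effect * cna_code["NTRK2", ]
  expr["NTRK3", fusion] <- expr["NTRK3", fusion] + 3 * spec$noise_sd
  expr <- pmax(expr, 0)

  # copy-number segments ------------------------------------------------
  chroms <- unique(reg$chromosome)
  chrom_span <- dplyr::summarise(
    dplyr::group_by(reg, .data$chromosome),
    lo = max(min(.data$start) - 5e6, 1), hi = max(.data$end) + 5e6,
    .groups = "drop"
  )
  n_bg_seg <- nrow(chrom_span) * n
  bg_segments <- tibble::tibble(
    sample = rep(samples, each = nrow(chrom_span)),
    chromosome = rep(chrom_span$chromosome, times = n),
    start = as.integer(rep(chrom_span$lo, times = n)),
    end = as.integer(rep(chrom_span$hi, times = n)),
    num_probes = as.integer(round(runif(n_bg_seg, 50, 5000))),
    segment_mean = rnorm(n_bg_seg, 0, 0.1)
  )
  ntrk3_locus <- reg[reg$symbol == "NTRK3", ]
  mid3 <- floor((ntrk3_locus$start + ntrk3_locus$end) / 2)
  five_prime <- if (ntrk3_locus$strand == "+") {
    c(ntrk3_locus$start, mid3)
  } else {
    c(mid3, ntrk3_locus$end)
  }
  fusion_idx <- which(fusion)
  fus_segments <- if (length(fusion_idx) > 0) {
    partner_loci <- reg[match(partner_pick[fusion_idx], reg$symbol), ]
    dplyr::bind_rows(
      tibble::tibble(
        sample = samples[fusion_idx], chromosome = ntrk3_locus$chromosome,
        start = as.integer(five_prime[1]), end = as.integer(five_prime[2]),
        num_probes = as.integer(round(runif(length(fusion_idx), 100, 2000))),
        segment_mean = fusion_seg_mean[fusion_idx]
      ),
      tibble::tibble(
        sample = samples[fusion_idx], chromosome = partner_loci$chromosome,
        start = as.integer(partner_loci$start - 1000L),
        end = as.integer(partner_loci$end + 1000L),
        num_probes = as.integer(round(runif(length(fusion_idx), 100, 2000))),
        segment_mean = partner_seg_mean[fusion_idx]
      )
    )
  } else {
    empty_segments()
  }
  segments <- dplyr::arrange(dplyr::bind_rows(bg_segments, fus_segments),
                             .data$sample, .data$chromosome, .data$start)

  # clinical table ------------------------------------------------------
  is_msi <- subtype == "MSI"
  is_cin <- subtype == "CIN"
  stage_t <- sample(paste0("T", 1:4), n, TRUE, prob = c(0.10, 0.20, 0.40, 0.30))
  stage_n <- sample(paste0("N", 0:2), n, TRUE, prob = c(0.50, 0.30, 0.20))
  stage_m <- sample(paste0("M", 0:1), n, TRUE, prob = c(0.85, 0.15))
  tnm <- ifelse(stage_m == "M1", "IV",
                ifelse(stage_n != "N0", "III",
                       ifelse(stage_t %in% c("T3", "T4"), "II", "I")))
  stage_num <- match(tnm, c("I", "II", "III", "IV"))
  fga <- ifelse(is_cin, rbeta(n, 4, 4), ifelse(is_msi, rbeta(n, 2, 8), rbeta(n, 2, 12)))
  tmb <- round(rexp(n, rate = 1 / ifelse(is_msi, 40, 8)), 2)
  os_haz <- 0.004 * 1.6^(stage_num - 1)
  os_raw <- rexp(n, os_haz)
  cens <- pmin(rexp(n, 0.006), 120)
  dfs_raw <- os_raw * rbeta(n, 8, 2)
  clinical <- tibble::tibble(
    sample = samples,
    age = round(pmin(pmax(rnorm(n, 67, 11), 30), 92)),
    sex = sample(c("male", "female"), n, TRUE),
    location = ifelse(runif(n) < ifelse(is_msi, 0.70, 0.35), "right", "left"),
    t_stage = stage_t, n_stage = stage_n, m_stage = stage_m, tnm_stage = tnm,
    msi_status = ifelse(runif(n) < ifelse(is_msi, 0.90, 0.05), "MSI", "MSS"),
    subtype = subtype,
    braf_mut = ifelse(runif(n) < ifelse(is_msi, 0.35, 0.05), "mutant", "wild-type"),
    tp53_mut = ifelse(runif(n) < ifelse(is_cin, 0.60, 0.30), "mutant", "wild-type"),
    fga = round(fga, 4),
    tmb = tmb,
    aneuploidy = as.integer(round(fga * 39 + rnorm(n, 0, 1.5))),
    os_time = round(pmin(os_raw, cens), 2),
    os_event = as.integer(os_raw <= cens),
    dfs_time = round(pmin(dfs_raw, cens), 2),
    dfs_event = as.integer(dfs_raw <= cens)
  )
  clinical$aneuploidy <- pmax(clinical$aneuploidy, 0L)
  clinical$os_time <- pmax(clinical$os_time, 0.01)
  clinical$dfs_time <- pmax(clinical$dfs_time, 0.01)

  structure(
    list(
      expression = dplyr::bind_cols(
        tibble::tibble(gene = genes),
        tibble::as_tibble(as.data.frame(expr), .name_repair = "minimal")
      ),
      segments = segments,
      gene_cna = tidyr::pivot_longer(
        dplyr::bind_cols(tibble::tibble(gene = genes),
                         tibble::as_tibble(as.data.frame(cna_code),
                                           .name_repair = "minimal")),
        -"gene", names_to = "sample", values_to = "value"
      )[, c("sample", "gene", "value")],
      methylation = tidyr::pivot_longer(
        dplyr::bind_cols(tibble::tibble(gene = ntrk),
                         tibble::as_tibble(as.data.frame(beta),
                                           .name_repair = "minimal")),
        -"gene", names_to = "sample", values_to = "beta"
      )[, c("sample", "gene", "beta")],
      clinical = clinical,
      truth = tibble::tibble(
        sample = samples, fusion = fusion, partner = partner_pick,
        ntrk3_segment_mean = fusion_seg_mean, subtype = subtype,
        expression_shift = ifelse(fusion, 3 * spec$noise_sd, 0)
      ),
      spec = spec
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", x$spec$cohort_label, ": ", x$spec$n_samples,
      " samples, ", nrow(x$expression), " genes, ",
      sum(x$truth$fusion), " planted fusions\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the cohort as the standard file set the pipeline reads back:
#' `expression.gct` (GCT v1.2), `segments.seg` (SEG), `gene_cna.tsv` and
#' `methylation.tsv` (long TSV), `clinical.tsv`, and a `truth.json`
#' sidecar with the planted labels.
#'
#' @param cohort A `synthetic_cohort` object.
#' @param directory Output directory (created if missing).
#'
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_cohort <- function(cohort, directory) {
  if (!inherits(cohort, "synthetic_cohort")) abort("cohort must be a synthetic_cohort")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) abort(paste0("Cannot create directory: ", directory))
  paths <- c(
    expression = file.path(directory, "expression.gct"),
    segments = file.path(directory, "segments.seg"),
    gene_cna = file.path(directory, "gene_cna.tsv"),
    methylation = file.path(directory, "methylation.tsv"),
    clinical = file.path(directory, "clinical.tsv"),
    truth = file.path(directory, "truth.json")
  )
  write_gct(cohort$expression, paths[["expression"]])
  write_seg(cohort$segments, paths[["segments"]])
  readr::write_tsv(cohort$gene_cna, paths[["gene_cna"]])
  readr::write_tsv(cohort$methylation, paths[["methylation"]])
  readr::write_tsv(cohort$clinical, paths[["clinical"]])
  jsonlite::write_json(cohort$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(paths)
}
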