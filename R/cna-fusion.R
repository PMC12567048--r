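#' Call gene deletions from copy-number segments
#'
#' A gene is called deleted in a sample when at least one copy-number
#' segment overlaps the gene locus (closed 1-based intervals; any partial
#' overlap counts) with segment mean at or below the threshold. The default
#' threshold of -0.3 log2 copy-ratio is deliberately stringent relative to
#' the usual -0.2 shallow-loss convention. When several qualifying segments
#' overlap, the minimum segment mean (the strongest deletion evidence) is
#' reported as support. `mode = "five_prime"` restricts evidence to
#' segments overlapping the gene's 5' half (strand aware), for the cryptic
#' fusion interpretation where the 5' portion of the 3' partner is lost.
#'
#' @param segments Segment tibble as returned by [read_seg()]; may contain
#'   many samples.
#' @param loci Gene locus tibble (see [gene_registry()]).
#' @param threshold Deletion threshold on the segment mean (must be < 0).
#' @param mode `"any"` (default) or `"five_prime"` overlap requirement.
#' @param samples Optional character vector giving the full sample roster;
#'   samples without any segment are reported as not deleted (no-call is
#'   FALSE). Defaults to the samples present in `segments`.
#'
#' @return A tibble with one row per (sample, gene): `sample`, `gene`,
#'   `deleted`, `supporting_segment_mean` (NA when not deleted),
#'   `overlap_bp` (overlap of the supporting segment, 0 when not deleted).
#' @export
#'
#' @examples
#' segs <- tibble::tibble(
#'   sample = "S1", chromosome = "15", start = 87000000L, end = 88000000L,
#'   num_probes = 100L, segment_mean = -0.45
#' )
#' call_deletion(segs, gene_registry("NTRK3"))
call_deletion <- function(segments, loci = gene_registry(), threshold = -0.3,
                          mode = c("any", "five_prime"), samples = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(segments), is.data.frame(loci))
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold >= 0) {
    abort("threshold must be a single negative number")
  }
  samples <- samples %||% unique(segments$sample)

  loci <- dplyr::mutate(loci, chromosome = normalize_chromosome(.data$chromosome))
  if (mode == "five_prime") {
    mid <- floor((loci$start + loci$end) / 2)
    loci$ov_start <- ifelse(loci$strand == "+", loci$start, mid)
    loci$ov_end <- ifelse(loci$strand == "+", mid, loci$end)
  } else {
    loci$ov_start <- loci$start
    loci$ov_end <- loci$end
  }

  hits <- dplyr::inner_join(
    segments,
    dplyr::select(loci, gene = "symbol", "chromosome", "ov_start", "ov_end"),
    by = "chromosome", relationship = "many-to-many"
  )
  hits <- dplyr::filter(
    hits,
    .data$start <= .data$ov_end, .data$end >= .data$ov_start,
    .data$segment_mean <= threshold
  )
  hits <- dplyr::mutate(
    hits,
    overlap_bp = pmin(.data$end, .data$ov_end) - pmax(.data$start, .data$ov_start) + 1
  )
  best <- if (nrow(hits) == 0) {
    tibble::tibble(sample = character(), gene = character(),
                   supporting_segment_mean = double(), overlap_bp = integer())
  } else {
    dplyr::summarise(
      dplyr::group_by(hits, .data$sample, .data$gene),
      supporting_segment_mean = min(.data$segment_mean),
      overlap_bp = .data$overlap_bp[which.min(.data$segment_mean)],
      .groups = "drop"
    )
  }

  grid <- tidyr::expand_grid(sample = samples, gene = loci$symbol)
  out <- dplyr::left_join(grid, best, by = c("sample", "gene"))
  dplyr::mutate(
    out,
    deleted = !is.na(.data$supporting_segment_mean),
    overlap_bp = dplyr::coalesce(as.integer(.data$overlap_bp), 0L)
  )[, c("sample", "gene", "deleted", "supporting_segment_mean", "overlap_bp")]
}

#' Categorize gene-level copy-number values
#'
#' Maps gene-level copy-number calls onto the three analysis categories
#' `loss/deletion`, `wild-type` and `gain/amplification`. Two input
#' dialects are supported: GISTIC thresholded codes (-2, -1 -> loss;
#' 0 -> wild-type; 1, 2 -> gain) and linear log2 copy-ratios thresholded at
#' +/- 0.3.
#'
#' @param cna Long tibble with columns `sample`, `gene`, `value`.
#' @param dialect `"gistic_thresholded"` or `"linear"`.
#'
#' @return The input tibble with an added `category` factor column with
#'   levels `loss/deletion`, `wild-type`, `gain/amplification`.
#' @export
categorize_cna <- function(cna, dialect = c("gistic_thresholded", "linear")) {
  dialect <- match.arg(dialect)
  stopifnot(is.data.frame(cna), all(c("sample", "gene", "value") %in% names(cna)))
  v <- cna$value
  lv <- c("loss/deletion", "wild-type", "gain/amplification")
  if (dialect == "gistic_thresholded") {
    known <- v %in% c(-2, -1, 0, 1, 2) | is.na(v)
    if (!all(known)) {
      abort(paste0("Unknown GISTIC code(s): ",
                   paste(unique(v[!known])[1:min(5, sum(!known))], collapse = ", ")))
    }
    cat <- dplyr::case_when(v <= -1 ~ lv[1], v == 0 ~ lv[2], v >= 1 ~ lv[3])
  } else {
    if (!is.numeric(v)) abort("linear dialect requires numeric values")
    cat <- dplyr::case_when(v <= -0.3 ~ lv[1], v >= 0.3 ~ lv[3], TRUE ~ lv[2])
  }
  dplyr::mutate(cna, category = factor(cat, levels = lv))
}

#' Compute NTRK3 fusion scores (NFS1/NFS2) per sample
#'
#' The scores are additive indicator sums over per-sample evidence:
#' \deqn{NFS1 = [NTRK3\ deleted] + [any\ 5'\ partner\ deleted] + [NTRK3\ high]}
#' \deqn{NFS2 = [NTRK3\ deleted] + [NTRK3\ high]}
#' A sample is "NFS1-high" at the cut score 3 (all three components) and
#' "NFS2-high" at 2; the high states are the cryptic-fusion calls, while
#' intermediate scores remain reportable strata. By construction
#' NFS1-high implies NFS2-high.
#'
#' @param deletions Deletion-call tibble from [call_deletion()] covering
#'   NTRK3 and the partner registry genes.
#' @param ntrk3_high Tibble with columns `sample` and `ntrk3_high`
#'   (logical or a `low`/`high` factor from [dichotomize()]).
#' @param partners Character vector of 5' partner symbols (default the
#'   built-in registry, [ntrk3_partners()]).
#'
#' @return A tibble with one row per sample: `sample`, `ntrk3_deleted`,
#'   `partner_deleted` (any), `ntrk3_high`, `nfs1` (0-3), `nfs2` (0-2),
#'   `nfs1_high`, `nfs2_high`, `partners_deleted` (comma-joined symbols).
#' @export
compute_nfs <- function(deletions, ntrk3_high, partners = ntrk3_partners()) {
  stopifnot(is.data.frame(deletions),
            all(c("sample", "gene", "deleted") %in% names(deletions)))
  stopifnot(is.data.frame(ntrk3_high),
            all(c("sample", "ntrk3_high") %in% names(ntrk3_high)))
  hi <- ntrk3_high$ntrk3_high
  if (is.factor(hi) || is.character(hi)) hi <- as.character(hi) == "high"
  expr_tbl <- tibble::tibble(sample = ntrk3_high$sample, ntrk3_high = as.logical(hi))

  del_ntrk3 <- dplyr::filter(deletions, .data$gene == "NTRK3")
  if (nrow(del_ntrk3) == 0) abort("deletions contains no NTRK3 rows")
  del_part <- dplyr::filter(deletions, .data$gene %in% partners, .data$deleted)
  part_sum <- dplyr::summarise(
    dplyr::group_by(del_part, .data$sample),
    partner_deleted = TRUE,
    partners_deleted = paste(sort(unique(.data$gene)), collapse = ","),
    .groups = "drop"
  )

  out <- dplyr::left_join(
    tibble::tibble(sample = del_ntrk3$sample, ntrk3_deleted = del_ntrk3$deleted),
    part_sum, by = "sample"
  )
  out <- dplyr::inner_join(out, expr_tbl, by = "sample")
  out <- dplyr::mutate(
    out,
    partner_deleted = dplyr::coalesce(.data$partner_deleted, FALSE),
    partners_deleted = dplyr::coalesce(.data$partners_deleted, ""),
    ntrk3_high = dplyr::coalesce(.data$ntrk3_high, FALSE),
    nfs1 = as.integer(.data$ntrk3_deleted) + as.integer(.data$partner_deleted) +
      as.integer(.data$ntrk3_high),
    nfs2 = as.integer(.data$ntrk3_deleted) + as.integer(.data$ntrk3_high),
    nfs1_high = .data$nfs1 == 3L,
    nfs2_high = .data$nfs2 == 2L
  )
  out[, c("sample", "ntrk3_deleted", "partner_deleted", "ntrk3_high",
          "nfs1", "nfs2", "nfs1_high", "nfs2_high", "partners_deleted")]
}

#' Cohort-level summary of fusion scores
#'
#' Tabulates the deletion and fusion-call composition of a cohort: the
#' double NTRK3-plus-partner deletions, deletions of NTRK3 or any partner,
#' NTRK3 deletions alone, and the NFS1-high / NFS2-high cryptic fusion
#' calls, each as a count and a fraction of the scored samples.
#'
#' @param scores Per-sample score tibble from [compute_nfs()].
#'
#' @return A tibble with columns `measure`, `count`, `fraction`, plus an
#'   `n` attribute-free denominator row count via `measure == "samples"`.
#' @export
summarize_fusion_cohort <- function(scores) {
  stopifnot(is.data.frame(scores),
            all(c("ntrk3_deleted", "partner_deleted", "nfs1_high", "nfs2_high")
                %in% names(scores)))
  n <- nrow(scores)
  counts <- c(
    samples = n,
    ntrk3_and_partner_deleted = sum(scores$ntrk3_deleted & scores$partner_deleted),
    ntrk3_or_partner_deleted = sum(scores$ntrk3_deleted | scores$partner_deleted),
    ntrk3_deleted_alone = sum(scores$ntrk3_deleted & !scores$partner_deleted),
    nfs1_high = sum(scores$nfs1_high),
    nfs2_high = sum(scores$nfs2_high)
  )
  tibble::tibble(
    measure = names(counts),
    count = as.integer(counts),
    fraction = if (n > 0) unname(counts) / n else NA_real_
  )
}
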