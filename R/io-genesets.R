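#' Read gene sets from a GMT file
#'
#' Each GMT line holds a set name, a description and one or more gene
#' symbols, tab-delimited. Duplicate genes within a set are dropped
#' (first occurrence kept); a line with no genes is an error.
#'
#' @param path Path to a GMT file.
#'
#' @return A long tibble with one row per (set, gene): columns `set_name`,
#'   `description`, `gene`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("GMT file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("GMT file is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    abort(paste0("GMT line ", short[1], " has no genes (need name, description, >= 1 gene)"))
  }
  purrr::map_dfr(fields, function(f) {
    genes <- unique(trimws(f[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) abort("GMT line with empty gene fields")
    tibble::tibble(set_name = f[[1]], description = f[[2]], gene = genes)
  })
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets Long tibble with columns `set_name`, `gene` and
#'   optionally `description`.
#' @param path Output path.
#'
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(gene_sets, path) {
  stopifnot(is.data.frame(gene_sets), all(c("set_name", "gene") %in% names(gene_sets)))
  if (!"description" %in% names(gene_sets)) gene_sets$description <- "na"
  split_sets <- split(gene_sets, gene_sets$set_name)
  lines <- vapply(split_sets, function(s) {
    paste(c(s$set_name[[1]], s$description[[1]], unique(s$gene)), collapse = "\t")
  }, character(1))
  writeLines(unname(lines), path)
  invisible(path)
}

# Long tibble -> named list of gene vectors.
gene_set_list <- function(gene_sets) {
  stopifnot(all(c("set_name", "gene") %in% names(gene_sets)))
  lapply(split(gene_sets$gene, gene_sets$set_name), unique)
}

#' Read a categorical phenotype CLS file
#'
#' Parses the categorical CLS dialect: header `n_samples n_classes 1`, a
#' `#`-prefixed class-name line, then one label per sample on the third
#' line. The declared sample count must match the number of labels.
#'
#' @param path Path to a CLS file.
#'
#' @return A character vector of per-sample class labels (names taken from
#'   the `#` line when labels are given as 0-based indices).
#' @export
read_cls <- function(path) {
  if (!file.exists(path)) abort(paste0("CLS file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) abort("CLS file needs header, class-name and label lines")
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[[1]]), "\\s+")[[1]]))
  if (length(hdr) < 2 || anyNA(hdr[1:2])) abort("Malformed CLS header line")
  n_samples <- hdr[[1]]; n_classes <- hdr[[2]]
  cls_line <- strsplit(trimws(sub("^#", "", lines[[2]])), "\\s+")[[1]]
  if (length(cls_line) != n_classes) {
    abort(paste0("CLS declares ", n_classes, " classes but names ", length(cls_line)))
  }
  labels <- strsplit(trimws(lines[[3]]), "\\s+")[[1]]
  if (length(labels) != n_samples) {
    abort(paste0("CLS header declares ", n_samples, " samples but ",
                 length(labels), " labels found"))
  }
  if (all(grepl("^[0-9]+$", labels))) {
    idx <- as.integer(labels)
    if (any(idx >= n_classes)) abort("CLS numeric label exceeds declared class count")
    labels <- cls_line[idx + 1L]
  } else if (!all(labels %in% cls_line)) {
    abort("CLS labels not among the declared class names")
  }
  labels
}

#' Write a categorical phenotype CLS file
#'
#' @param labels Character (or factor) vector of per-sample class labels.
#' @param path Output path.
#'
#' @return Invisibly, `path`.
#' @export
write_cls <- function(labels, path) {
  labels <- as.character(labels)
  classes <- unique(labels)
  writeLines(c(
    paste(length(labels), length(classes), 1),
    paste("#", paste(classes, collapse = " ")),
    paste(labels, collapse = " ")
  ), path)
  invisible(path)
}
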