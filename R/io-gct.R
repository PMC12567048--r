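#' Read an expression matrix from a GCT v1.2 file
#'
#' Parses the Broad GCT v1.2 layout: a `#1.2` version line, a dimensions line
#' (`n_genes<TAB>n_samples`), a header row (`NAME`, `Description`, then sample
#' identifiers) and one row per gene. The declared dimensions must match the
#' body exactly.
#'
#' @param path Path to a GCT file.
#'
#' @return A tibble with columns `gene`, `description`, then one numeric
#'   column per sample.
#' @export
read_gct <- function(path) {
  if (!file.exists(path)) abort(paste0("GCT file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) abort("GCT file too short: need version, dimension and header lines")
  if (!grepl("^#1\\.2", lines[[1]])) abort("Not a GCT v1.2 file: first line must be '#1.2'")
  dims <- suppressWarnings(as.integer(strsplit(lines[[2]], "\t", fixed = TRUE)[[1]]))
  if (length(dims) < 2 || anyNA(dims[1:2])) abort("Malformed GCT dimension line")
  n_genes <- dims[[1]]; n_samples <- dims[[2]]
  header <- strsplit(lines[[3]], "\t", fixed = TRUE)[[1]]
  if (length(header) != n_samples + 2) {
    abort(paste0("GCT header declares ", length(header) - 2,
                 " samples but dimension line declares ", n_samples))
  }
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n_genes) {
    abort(paste0("GCT body has ", length(body), " gene rows but dimension line declares ", n_genes))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(fields) != n_samples + 2)) {
    bad <- which(lengths(fields) != n_samples + 2)[1]
    abort(paste0("GCT row ", bad, " has ", lengths(fields)[bad] - 2,
                 " values; expected ", n_samples))
  }
  genes <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(genes)) {
    abort(paste0("Duplicate gene symbols in GCT: ",
                 paste(unique(genes[duplicated(genes)])[1:min(3, sum(duplicated(genes)))],
                       collapse = ", ")))
  }
  desc <- vapply(fields, `[[`, character(1), 2)
  vals <- matrix(
    suppressWarnings(as.numeric(unlist(lapply(fields, `[`, -(1:2))))),
    nrow = n_genes, ncol = n_samples, byrow = TRUE
  )
  out <- tibble::as_tibble(
    stats::setNames(as.data.frame(vals), header[-(1:2)]),
    .name_repair = "minimal"
  )
  dplyr::bind_cols(tibble::tibble(gene = genes, description = desc), out)
}

#' Write an expression matrix to a GCT v1.2 file
#'
#' @param expression A tibble with a `gene` column, an optional `description`
#'   column, and one numeric column per sample.
#' @param path Output path.
#'
#' @return Invisibly, `path`.
#' @export
write_gct <- function(expression, path) {
  stopifnot(is.data.frame(expression), "gene" %in% names(expression))
  desc <- if ("description" %in% names(expression)) expression$description else
    rep("na", nrow(expression))
  vals <- expression[, setdiff(names(expression), c("gene", "description")), drop = FALSE]
  if (ncol(vals) == 0) abort("expression has no sample columns")
  lines <- c(
    "#1.2",
    paste(nrow(expression), ncol(vals), sep = "\t"),
    paste(c("NAME", "Description", names(vals)), collapse = "\t"),
    do.call(paste, c(
      list(expression$gene, desc),
      lapply(vals, function(v) format(v, digits = 15, trim = TRUE, scientific = FALSE)),
      sep = "\t"
    ))
  )
  tryCatch(
    writeLines(lines, path),
    error = function(e) abort(paste0("Failed writing GCT file '", path, "': ", conditionMessage(e)))
  )
  invisible(path)
}

# Convert a gene x sample expression tibble to a numeric matrix with gene
# rownames; accepts output of read_gct() or any gene-keyed wide tibble.
expression_matrix <- function(expression) {
  stopifnot(is.data.frame(expression), "gene" %in% names(expression))
  vals <- expression[, setdiff(names(expression), c("gene", "description")), drop = FALSE]
  m <- as.matrix(vals)
  if (!is.numeric(m)) abort("expression sample columns must be numeric")
  rownames(m) <- expression$gene
  m
}
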