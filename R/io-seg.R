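#' Read a copy-number segment (SEG) file
#'
#' Parses a tab-delimited SEG file in the cBioPortal/IGV dialect: columns
#' Sample, Chromosome, Start, End, Num_Probes, Segment_Mean (a header line is
#' tolerated and detected). Coordinates are treated as 1-based inclusive and
#' chromosome names are normalized so that "chr15" and "15" are identical.
#'
#' @param path Path to a tab-delimited SEG file with at least 6 columns.
#'
#' @return A tibble with columns `sample`, `chromosome`, `start`, `end`,
#'   `num_probes` (integer, may be NA) and `segment_mean` (log2 copy-ratio).
#' @export
read_seg <- function(path) {
  if (!file.exists(path)) abort(paste0("SEG file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(empty_segments())
  }
  first <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  has_header <- length(first) >= 4 && is.na(suppressWarnings(as.numeric(first[[3]])))
  body <- if (has_header) lines[-1] else lines
  offset <- if (has_header) 1L else 0L
  if (length(body) == 0) return(empty_segments())

  fields <- strsplit(body, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 6)) {
    bad <- which(n_fields < 6)[1]
    abort(paste0("Malformed SEG row at line ", bad + offset,
                 ": expected >= 6 tab-delimited fields, found ", n_fields[bad]))
  }
  mat <- t(vapply(fields, function(f) f[1:6], character(6)))
  start <- suppressWarnings(as.numeric(mat[, 3]))
  end <- suppressWarnings(as.numeric(mat[, 4]))
  seg_mean <- suppressWarnings(as.numeric(mat[, 6]))
  probes_raw <- trimws(mat[, 5])
  num_probes <- suppressWarnings(as.integer(probes_raw))
  num_probes[probes_raw %in% c("", "NA", ".")] <- NA_integer_

  bad_num <- which(!is.finite(start) | !is.finite(end) | !is.finite(seg_mean))
  if (length(bad_num) > 0) {
    abort(paste0("Malformed SEG row at line ", bad_num[1] + offset,
                 ": non-numeric start/end/segment_mean"))
  }
  bad_iv <- which(end < start)
  if (length(bad_iv) > 0) {
    abort(paste0("Invalid segment at line ", bad_iv[1] + offset,
                 ": end (", end[bad_iv[1]], ") < start (", start[bad_iv[1]], ")"))
  }
  if (any(num_probes < 0, na.rm = TRUE)) {
    abort("Negative Num_Probes values in SEG file")
  }
  tibble::tibble(
    sample = trimws(mat[, 1]),
    chromosome = normalize_chromosome(mat[, 2]),
    start = as.integer(start),
    end = as.integer(end),
    num_probes = num_probes,
    segment_mean = seg_mean
  )
}

empty_segments <- function() {
  tibble::tibble(
    sample = character(), chromosome = character(),
    start = integer(), end = integer(),
    num_probes = integer(), segment_mean = double()
  )
}

#' Write copy-number segments to a SEG file
#'
#' @param segments Tibble as returned by [read_seg()].
#' @param path Output path.
#'
#' @return Invisibly, `path`.
#' @export
write_seg <- function(segments, path) {
  stopifnot(is.data.frame(segments))
  req <- c("sample", "chromosome", "start", "end", "num_probes", "segment_mean")
  if (!all(req %in% names(segments))) {
    abort(paste0("segments must have columns: ", paste(req, collapse = ", ")))
  }
  header <- c("Sample", "Chromosome", "Start", "End", "Num_Probes", "Segment_Mean")
  out <- segments[, req]
  out$segment_mean <- format(out$segment_mean, digits = 15, trim = TRUE, scientific = FALSE)
  lines <- c(
    paste(header, collapse = "\t"),
    do.call(paste, c(lapply(out, as.character), sep = "\t"))
  )
  tryCatch(
    writeLines(lines, path),
    error = function(e) abort(paste0("Failed writing SEG file '", path, "': ", conditionMessage(e)))
  )
  invisible(path)
}
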