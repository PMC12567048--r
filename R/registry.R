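#' Gene locus registry for NTRK genes and their 5' fusion partners
#'
#' Returns the built-in registry of genomic intervals (GRCh38, 1-based,
#' closed) for the three NTRK receptor kinase genes and the seven recurrent
#' 5' fusion partners of NTRK3: ETV6 (alias TEL), TPM3, TPR, SQSTM1, EML4,
#' MYH9 and MYO5A. Coordinates are approximate gene spans intended for
#' segment-overlap deletion calling, not for base-precise annotation; users
#' with their own annotation can pass any tibble with the same columns to
#' every function that takes a `loci` argument.
#'
#' @param symbols Optional character vector restricting the registry to a
#'   subset of gene symbols (matched case-insensitively; "TEL" resolves to
#'   ETV6).
#'
#' @return A tibble with columns `symbol`, `chromosome` (un-prefixed,
#'   \{1..22, X, Y\}), `start`, `end` (1-based inclusive) and `strand`.
#' @export
#'
#' @examples
#' gene_registry()
#' gene_registry(c("NTRK3", "ETV6"))
gene_registry <- function(symbols = NULL) {
  reg <- tibble::tribble(
    ~symbol,  ~chromosome,    ~start,      ~end, ~strand,
    "NTRK1",  "1",         156815750, 156881850, "+",
    "NTRK2",  "9",          84668522,  85027070, "+",
    "NTRK3",  "15",         87859751,  88256768, "-",
    "ETV6",   "12",         11649601,  11895377, "+",
    "TPM3",   "1",         154155308, 154192100, "-",
    "TPR",    "1",         186311035, 186375690, "-",
    "SQSTM1", "5",         179806398, 179838078, "+",
    "EML4",   "2",          42169353,  42332548, "+",
    "MYH9",   "22",         36281280,  36388067, "-",
    "MYO5A",  "15",         52307290,  52529050, "-"
  )
  if (!is.null(symbols)) {
    wanted <- toupper(trimws(symbols))
    wanted[wanted == "TEL"] <- "ETV6"
    missing <- setdiff(wanted, reg$symbol)
    if (length(missing) > 0) {
      abort(paste0("Unknown registry symbol(s): ", paste(missing, collapse = ", ")))
    }
    reg <- reg[match(wanted, reg$symbol), ]
  }
  reg
}

#' Symbols of the recurrent 5' fusion partners of NTRK3
#'
#' @return Character vector of the seven partner gene symbols.
#' @export
ntrk3_partners <- function() {
  c("ETV6", "TPM3", "TPR", "SQSTM1", "EML4", "MYH9", "MYO5A")
}

# Normalize chromosome names to the canonical un-prefixed set.
# "chr17" and "17" map to "17"; "chrX"/"23" are not conflated (23 rejected).
normalize_chromosome <- function(x) {
  x <- sub("^[Cc][Hh][Rr]", "", trimws(as.character(x)))
  x[x %in% c("x", "y")] <- toupper(x[x %in% c("x", "y")])
  ok <- x %in% c(as.character(1:22), "X", "Y")
  if (!all(ok)) {
    bad <- unique(x[!ok])
    abort(paste0(
      "Chromosome name(s) outside the canonical set {1..22, X, Y}: ",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  x
}
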