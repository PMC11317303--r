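#' @keywords internal
"_PACKAGE"

## The 20 proteinogenic one-letter codes; B, J, O, U, X, Z are rejected.
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

AA_REGEX <- "^[ACDEFGHIKLMNPQRSTVWY]+$"

MIN_PEPTIDE_LEN <- 7L
MAX_PEPTIDE_LEN <- 30L

#' Normalize peptide sequence strings
#'
#' Strips post-translational-modification annotations (anything in round or
#' square brackets, e.g. `"M(ox)"`), removes whitespace, and upper-cases.
#' Peptide identity throughout the package is the bare sequence string.
#'
#' @param x character vector of raw peptide strings.
#' @return character vector of normalized sequences.
#' @export
normalize_peptides <- function(x) {
  x <- gsub("\\([^)]*\\)|\\[[^]]*\\]", "", as.character(x))
  x <- gsub("[[:space:]]", "", x)
  toupper(x)
}

## Validate normalized sequences; returns invisible(TRUE) or stops with the
## offending positions (1-based, reported as line numbers when offset given).
validate_sequences <- function(x, line_offset = 0L, what = "peptide") {
  bad_chr <- !grepl(AA_REGEX, x)
  if (any(bad_chr)) {
    i <- which(bad_chr)[1]
    stop(sprintf(
      "invalid %s sequence '%s' at line %d: characters outside ACDEFGHIKLMNPQRSTVWY",
      what, x[i], i + line_offset
    ), call. = FALSE)
  }
  n <- nchar(x)
  bad_len <- n < MIN_PEPTIDE_LEN | n > MAX_PEPTIDE_LEN
  if (any(bad_len)) {
    i <- which(bad_len)[1]
    stop(sprintf(
      "invalid %s sequence '%s' at line %d: length %d outside [%d, %d]",
      what, x[i], i + line_offset, n[i], MIN_PEPTIDE_LEN, MAX_PEPTIDE_LEN
    ), call. = FALSE)
  }
  invisible(TRUE)
}

## Require that a data.frame has exactly/at least the given columns.
check_columns <- function(df, required, path, exact = FALSE) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("file '%s': missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path) || file.size(path) == 0)
    stop(sprintf("file '%s' does not exist or is empty", path), call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = character())
  check_columns(df, required, path)
  df
}

read_csv_checked <- function(path, required) {
  if (!file.exists(path) || file.size(path) == 0)
    stop(sprintf("file '%s' does not exist or is empty", path), call. = FALSE)
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                        check.names = FALSE, na.strings = character())
  check_columns(df, required, path)
  df
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

as_hla_class <- function(x, path = "<input>") {
  x <- toupper(trimws(as.character(x)))
  bad <- !x %in% c("I", "II")
  if (any(bad))
    stop(sprintf("file '%s': invalid hla_class value '%s' (must be I or II)",
                 path, x[which(bad)[1]]), call. = FALSE)
  x
}

## Random amino-acid strings from the current RNG stream.
random_aa <- function(n, len) {
  vapply(rep_len(len, n), function(L) {
    paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
  }, character(1))
}
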