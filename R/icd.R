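#' Does an ICD code indicate ASD under the surveillance case definition?
#'
#' ASD indicator codes are ICD-9 codes in \[299.00, 299.99\] and ICD-10 codes
#' in the F84 family except Rett syndrome (F84.2 and its extensions).
#' Codes are normalized before matching: whitespace trimmed, case folded,
#' short ICD-9 billing dialects expanded ("299" and "299.0" count as in
#' range), and undotted ICD-10 forms ("F840") accepted.  Unparseable text is
#' never an error: it returns `FALSE` with a warning.
#'
#' @param code character vector of ICD code text.
#' @return logical vector, `TRUE` where the code is an ASD indicator.
#' @export
#' @examples
#' is_asd_indicator_code(c("299.00", "F84.0", "F84.2", "F83"))
is_asd_indicator_code <- function(code) {
  if (length(code) == 0) return(logical(0))
  x <- toupper(trimws(as.character(code)))
  out <- logical(length(x))

  bad <- is.na(x) | !nzchar(x)
  if (any(bad)) {
    warn(sprintf("%d empty or missing ICD code(s) treated as non-indicators",
                 sum(bad)))
  }

  # ICD-10: F84 family except F84.2 (with or without the dot)
  f84 <- !bad & grepl("^F84", x)
  if (any(f84)) {
    rest <- sub("^F84\\.?", "", x[f84])
    out[f84] <- !startsWith(rest, "2")
  }

  # ICD-9: numeric in [299.00, 299.99]; 3- and 4-digit forms normalized
  icd9 <- !bad & !f84 & grepl("^[0-9]{3}(\\.[0-9]{1,2})?$", x)
  if (any(icd9)) {
    val <- suppressWarnings(as.numeric(x[icd9]))
    out[icd9] <- !is.na(val) & val >= 299 & val < 300
  }

  unparsed <- !bad & !f84 & !icd9 & !grepl("^[A-Z][0-9]", x) &
    !grepl("^[0-9]", x)
  if (any(unparsed)) {
    warn(sprintf("%d unparseable ICD code(s) treated as non-indicators (e.g. '%s')",
                 sum(unparsed), x[unparsed][1]))
  }
  out
}
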