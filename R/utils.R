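#' Normalize a diagnosis or procedure code
#'
#' Strips dots and upper-cases, so `"E11.9"` and `"e119"` compare equal.
#'
#' @param code Character vector of raw codes.
#' @return Character vector of normalized codes.
#' @export
normalize_code <- function(code) {
  toupper(stringr::str_replace_all(as.character(code), stringr::fixed("."), ""))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# parse ISO-8601 dates strictly; names the offending rows on failure
parse_iso_date <- function(x, what) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d", optional = TRUE)
  bad <- which(!is.na(x) & x != "" & is.na(d))
  if (length(bad))
    stop(sprintf("unparseable date in %s (rows %s): expected YYYY-MM-DD",
                 what, paste(utils::head(bad, 5L), collapse = ", ")),
         call. = FALSE)
  d
}

# informational logging; suppressible via suppressMessages()
log_info <- function(fmt, ...) message(sprintf(fmt, ...))
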