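#' Read a plain-text or JSON configuration file
#'
#' Accepts either a JSON object or simple `key=value` lines (blank lines and
#' `#` comments ignored).  Recognised keys are the package's parameter names:
#' `alpha`, `alpha_x`, `alpha_z`, `beta`, `gamma`, `omega`, `a0`, `n`,
#' `reps`, `seed`, `level`.  Values that parse as numbers are returned
#' numeric; unknown keys are kept (callers decide what to use).
#'
#' @param path Path to the configuration file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) fp_domain_error(sprintf("config file not found: %s", path))
  txt <- readLines(path, warn = FALSE)
  first <- trimws(paste(txt, collapse = " "))
  if (startsWith(first, "{")) {
    out <- jsonlite::fromJSON(paste(txt, collapse = "\n"), simplifyVector = TRUE)
    return(as.list(out))
  }
  lines <- trimws(txt)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      fp_domain_error(sprintf("config line is not key=value: `%s`", ln))
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
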