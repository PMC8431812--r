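# Flat key-value configuration files: one "key = value" per line,
# '#' comments, numeric/logical values auto-coerced.

#' Read a flat key-value configuration file
#'
#' @param path File with \code{key = value} lines; blank lines and lines
#'   starting with \code{#} are ignored.  Values parse to numeric or
#'   logical when possible, else stay character.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(m) != 3L) {
      stop("config line is not 'key = value': ", ln, call. = FALSE)
    }
    key <- trimws(m[2]); val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
      else if (toupper(val) %in% c("TRUE", "FALSE")) as.logical(val)
      else val
  }
  out
}

# Apply config entries with a given prefix onto a constructor's defaults.
.config_args <- function(config, names) {
  if (is.null(config)) return(list())
  config[intersect(names(config), names)]
}
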