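#' Write a results table with a provenance header
#'
#' Writes a tab-delimited table preceded by a `#`-prefixed header block
#' recording the package version and any provenance items passed in
#' (resolved parameters, seed), so every output file documents the run
#' that produced it.
#'
#' @param x Data frame to write.
#' @param path Output file path, or `""` for standard output.
#' @param header Named list (or vector) of provenance items written as
#'   `# name: value` lines.
#' @return `path`, invisibly.
#' @export
write_model_table <- function(x, path = "", header = list()) {
  stopifnot(is.data.frame(x))
  lines <- c(
    sprintf("# accultdyn %s",
            as.character(utils::packageVersion("accultdyn"))),
    vapply(names(header), function(nm) {
      sprintf("# %s: %s", nm, paste(format(header[[nm]]), collapse = " "))
    }, character(1))
  )
  con <- if (identical(path, "")) stdout() else file(path, open = "wt")
  if (!identical(path, "")) on.exit(close(con))
  writeLines(lines, con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' Configuration files hold one `key = value` pair per line; blank lines
#' and lines starting with `#` are ignored. Keys match the command-line
#' flag names (without the leading `--`). Values that parse as numbers
#' are returned numeric; `true`/`false` become logical; everything else
#' stays character.
#'
#' @param path Path to the config file.
#' @return Named list of values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("malformed config line (expected `key = value`): ", ln,
           call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!nzchar(key)) {
      stop("malformed config line (empty key): ", ln, call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) {
      num
    } else if (tolower(val) %in% c("true", "false")) {
      tolower(val) == "true"
    } else {
      val
    }
  }
  out
}
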