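#' Read a pipeline configuration file
#'
#' Parses the flat TOML dialect the pipeline uses: `[section]` headers,
#' `key = value` pairs with strings (`"..."`), numbers, booleans
#' (`true`/`false`) and one-line arrays (`[1, 2]`), plus `#` comments. No
#' nested tables, dates or multi-line values — the configuration surface is
#' deliberately small.
#'
#' @param path Config file.
#' @return Nested named list (top-level keys plus one list per section).
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- NULL
  parse_scalar <- function(tok) {
    tok <- trimws(tok)
    if (grepl('^".*"$', tok)) return(gsub('^"|"$', "", tok))
    if (tok == "true") return(TRUE)
    if (tok == "false") return(FALSE)
    num <- suppressWarnings(as.numeric(tok))
    if (!is.na(num)) return(num)
    stop("cannot parse config value: ", tok)
  }
  for (raw in lines) {
    line <- sub("#.*$", "", raw)
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[.*\\]$", line)) {
      section <- gsub("^\\[|\\]$", "", line)
      out[[section]] <- out[[section]] %||% list()
      next
    }
    kv <- regmatches(line, regexpr("=", line), invert = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", raw)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    value <- if (grepl("^\\[.*\\]$", val)) {
      toks <- strsplit(gsub("^\\[|\\]$", "", val), ",")[[1]]
      toks <- toks[nzchar(trimws(toks))]
      vals <- lapply(toks, parse_scalar)
      unlist(vals)
    } else parse_scalar(val)
    if (is.null(section)) out[[key]] <- value
    else out[[section]][[key]] <- value
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
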