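## Minimal TOML subset I/O for flat key-value configuration files.
## Supports: [section] headers, `key = value` with numbers, booleans, quoted
## strings and one-line arrays of these, `#` comments and blank lines. That is
## the whole grammar the package's configuration files use; nested tables,
## multi-line arrays and dates are not supported and raise an error.

parse_toml_value <- function(txt) {
  txt <- trimws(txt)
  if (txt == "") stop("empty TOML value", call. = FALSE)
  if (grepl("^\\[", txt)) {
    inner <- sub("^\\[", "", sub("\\]$", "", txt))
    if (!grepl("\\]$", txt)) stop("unterminated TOML array: ", txt, call. = FALSE)
    if (trimws(inner) == "") return(list())
    parts <- strsplit(inner, ",")[[1]]
    return(unlist(lapply(parts, parse_toml_value)))
  }
  if (grepl('^".*"$', txt)) return(gsub('^"|"$', "", txt))
  if (txt %in% c("true", "false")) return(txt == "true")
  num <- suppressWarnings(as.numeric(txt))
  if (is.na(num)) stop("cannot parse TOML value: ", txt, call. = FALSE)
  num
}

#' Read and write flat TOML configuration files
#'
#' Reads the flat `[section]` / `key = value` TOML subset used for the
#' package's parameter and run configuration files into a named list of
#' sections (top-level keys, if any, appear before the first section header).
#' `write_flat_toml()` performs the inverse.
#'
#' @param path File path.
#' @param x For `write_flat_toml()`: a named list of named lists (sections) or
#'   scalar top-level values.
#' @return `read_flat_toml()`: a named list. `write_flat_toml()`: `path`, invisibly.
#' @export
read_flat_toml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (grepl("[\\[\\.]", section)) {
        stop("nested TOML tables are not supported: ", ln, call. = FALSE)
      }
      if (is.null(out[[section]])) out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", ln))
      val <- parse_toml_value(sub("^[^=]*=", "", ln))
      if (is.null(section)) out[[key]] <- val else out[[section]][[key]] <- val
    } else {
      stop("cannot parse TOML line: ", ln, call. = FALSE)
    }
  }
  out
}

format_toml_value <- function(v) {
  one <- function(x) {
    if (is.character(x)) paste0('"', x, '"')
    else if (is.logical(x)) tolower(as.character(x))
    else format(x, digits = 15, scientific = FALSE, trim = TRUE)
  }
  if (length(v) == 1) one(v) else paste0("[", paste(vapply(v, one, ""), collapse = ", "), "]")
}

#' @rdname read_flat_toml
#' @export
write_flat_toml <- function(x, path) {
  stopifnot(is.list(x), !is.null(names(x)))
  lines <- character()
  scalars <- x[!vapply(x, is.list, TRUE)]
  for (k in names(scalars)) {
    lines <- c(lines, paste0(k, " = ", format_toml_value(scalars[[k]])))
  }
  sections <- x[vapply(x, is.list, TRUE)]
  for (s in names(sections)) {
    lines <- c(lines, "", paste0("[", s, "]"))
    for (k in names(sections[[s]])) {
      lines <- c(lines, paste0(k, " = ", format_toml_value(sections[[s]][[k]])))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read and write parameter configuration files
#'
#' A parameter TOML file holds one `[section]` per construct preset (for
#' example `[digitalized]`, `[non_digitalized]`, `[promoterless]`), each a
#' flat table of [digitalizer_params()] fields. Missing fields fall back to
#' the package baseline; unknown fields are an error.
#'
#' @param path File path.
#' @param section Section name to read.
#' @return A `digitalizer_params` object.
#' @export
read_params_toml <- function(path, section = "digitalized") {
  cfg <- read_flat_toml(path)
  if (is.null(cfg[[section]])) {
    stop("section [", section, "] not found in ", path, call. = FALSE)
  }
  tab <- cfg[[section]]
  known <- names(formals(digitalizer_params))
  unknown <- setdiff(names(tab), known)
  if (length(unknown)) {
    stop("unknown parameter key(s) in [", section, "]: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(digitalizer_params, tab)
}

#' @rdname read_params_toml
#' @param params_list Named list of `digitalizer_params`, one per section.
#' @export
write_params_toml <- function(params_list, path) {
  stopifnot(is.list(params_list), !is.null(names(params_list)))
  write_flat_toml(lapply(params_list, unclass), path)
}
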