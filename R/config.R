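# Plain-text configuration: a flat `key = value` dialect (a TOML subset)
# with dotted key paths matching the parameter groups, e.g.
#   rates.mu_cc = 4
#   schedule.founder_affinities = [0.1, 0.3, 0.5]
#   shm.level = "peptide"
# An empty file yields the full default parameter set; unknown keys and
# out-of-range values are rejected with the offending key path.

parse_config_scalar <- function(x) {
  x <- trimws(x)
  if (x %in% c("true", "false")) return(x == "true")
  if (grepl('^".*"$', x) || grepl("^'.*'$", x)) {
    return(substr(x, 2, nchar(x) - 1))
  }
  num <- suppressWarnings(as.numeric(x))
  if (!is.na(num)) return(num)
  x
}

parse_config_value <- function(x) {
  x <- trimws(x)
  if (startsWith(x, "[")) {
    if (!endsWith(x, "]")) stop("unterminated array: ", x)
    inner <- trimws(substr(x, 2, nchar(x) - 1))
    if (inner == "") return(numeric(0))
    vapply(strsplit(inner, ",")[[1]], parse_config_scalar, numeric(1),
           USE.NAMES = FALSE)
  } else {
    parse_config_scalar(x)
  }
}

#' Load a simulation configuration
#'
#' Reads a flat `key = value` file (comments with `#`, dotted key paths,
#' numbers, booleans, quoted strings and `[..]` numeric arrays) on top of
#' the default parameter set. Every default is overridable; unknown keys and
#' invalid values raise an error naming the key.
#'
#' @param path config file path; an empty file gives the full defaults.
#' @param base parameter set the file overrides (default [gcr_params()]).
#' @return A validated `gcr_params` object.
#' @export
load_config <- function(path, base = gcr_params()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  p <- base
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("config line is not `key = value`: ", ln)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- parse_config_value(sub("^[^=]*=", "", ln))
    p <- set_param(p, key, val)
  }
  p
}

#' Save a simulation configuration
#'
#' Writes the flattened parameter set in the same `key = value` dialect that
#' [load_config()] reads; `load_config(save_config(p, f))` round-trips
#' losslessly.
#'
#' @param params a `gcr_params` object.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
save_config <- function(params, path) {
  flat <- flatten_params(params)
  fmt <- function(v) {
    if (is.character(v)) sprintf('"%s"', v)
    else if (is.logical(v)) tolower(as.character(v))
    else if (length(v) > 1) {
      sprintf("[%s]", paste(format(v, digits = 17, trim = TRUE),
                            collapse = ", "))
    } else format(v, digits = 17)
  }
  writeLines(paste(names(flat), vapply(flat, fmt, ""), sep = " = "), path)
  invisible(path)
}
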