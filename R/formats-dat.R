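## Reading/writing three-column ASCII scattering curves (.dat) and the
## shared text-handling helpers used by all legacy-format readers.

# Accept a path, a single string with embedded newlines, or a character
# vector of lines.
as_text_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  if (length(x) == 1L) return(strsplit(x, "\n", fixed = TRUE)[[1]])
  as.character(x)
}

# Tokenize a line on whitespace; returns character(0) for blank lines.
ws_tokens <- function(line) {
  t <- strsplit(trimws(line), "[ \t]+")[[1]]
  t[nzchar(t)]
}

is_numeric_token <- function(tok) {
  suppressWarnings(!is.na(as.numeric(tok)))
}

# Count of numeric tokens on a line; -1 when any token is non-numeric.
numeric_arity <- function(line) {
  t <- ws_tokens(line)
  if (length(t) == 0L) return(0L)
  if (all(is_numeric_token(t))) length(t) else -1L
}

fmt_num <- function(x) sprintf("%.6e", x)

#' One-dimensional scattering curve
#'
#' A tibble with columns `s` (momentum transfer), `I` (intensity) and,
#' when experimental errors are available, `err` (sigma of I). The
#' momentum-transfer unit and the experiment metadata (ordered name->value
#' text pairs: sample description, concentration, temperatures, frame
#' count, ...) ride along as attributes.
#'
#' @param s momentum transfer, strictly increasing, all `>= 0`.
#' @param I intensities (arbitrary or absolute units).
#' @param err per-point sigma of I, or `NULL` when not recorded.
#' @param unit momentum-transfer unit, `"1/angstrom"` or `"1/nm"`.
#' @param metadata named character vector of header metadata, in order.
#' @return a `saxs_curve` tibble.
#' @export
saxs_curve <- function(s, I, err = NULL, unit = "1/angstrom",
                       metadata = character()) {
  s <- as.numeric(s); I <- as.numeric(I)
  if (length(s) != length(I)) abort("s and I must have equal length")
  if (any(s < 0)) abort("momentum transfer s must be non-negative")
  if (length(s) > 1L && any(diff(s) <= 0)) {
    abort("momentum transfer s must be strictly increasing")
  }
  unit <- match.arg(unit, c("1/angstrom", "1/nm"))
  cols <- list(s = s, I = I)
  if (!is.null(err)) {
    err <- as.numeric(err)
    if (length(err) != length(s)) abort("err must match the length of s")
    cols$err <- err
  }
  out <- tibble::as_tibble(cols)
  attr(out, "unit") <- unit
  attr(out, "metadata") <- metadata
  class(out) <- c("saxs_curve", class(out))
  out
}

#' @export
print.saxs_curve <- function(x, ...) {
  cat(sprintf("<saxs_curve: %d points, s in [%g, %g] %s%s>\n",
              nrow(x), min(x$s), max(x$s), attr(x, "unit"),
              if ("err" %in% names(x)) ", with errors" else ""))
  if (length(attr(x, "metadata"))) {
    md <- attr(x, "metadata")
    cat(paste0("  ", names(md), " : ", md, collapse = "\n"), "\n")
  }
  NextMethod()
}

curve_metadata <- function(curve) attr(curve, "metadata") %||% character()
curve_unit <- function(curve) attr(curve, "unit") %||% "1/angstrom"

#' Read an ASCII scattering curve (.dat)
#'
#' Leading non-numeric lines are parsed as metadata name-value pairs
#' (split at the first `:` or `=`; lines without either are preserved
#' under `header_<i>` keys). The numeric block may have two columns
#' (s, I) or three (s, I, sigma). Trailing non-numeric text is ignored
#' with a warning.
#'
#' @param x path, single string, or character vector of lines.
#' @param unit momentum-transfer unit to record on the curve.
#' @return a [saxs_curve()].
#' @export
read_dat <- function(x, unit = "1/angstrom") {
  lines <- as_text_lines(x)
  arity <- vapply(lines, numeric_arity, integer(1), USE.NAMES = FALSE)
  first_num <- which(arity >= 2L)[1]
  if (is.na(first_num)) {
    abort("no numeric data rows with at least 2 columns found in .dat input")
  }
  ncol <- arity[first_num]
  run_end <- first_num
  while (run_end < length(lines) && arity[run_end + 1L] == ncol) {
    run_end <- run_end + 1L
  }
  if (run_end < length(lines) &&
      any(nzchar(trimws(lines[(run_end + 1L):length(lines)])))) {
    warn("ignoring trailing non-data lines in .dat input")
  }

  metadata <- character()
  hdr_i <- 0L
  for (line in lines[seq_len(first_num - 1L)]) {
    if (!nzchar(trimws(line))) next
    m <- regexpr("[:=]", line)
    if (m > 0L) {
      nm <- trimws(substr(line, 1L, m - 1L))
      val <- trimws(substr(line, m + 1L, nchar(line)))
      metadata[nm] <- val
    } else {
      hdr_i <- hdr_i + 1L
      metadata[paste0("header_", hdr_i)] <- trimws(line)
    }
  }

  rows <- lapply(lines[first_num:run_end], function(l) as.numeric(ws_tokens(l)))
  mat <- do.call(rbind, rows)
  if (ncol(mat) < 2L) abort("fewer than 2 numeric columns in .dat input")
  if (nrow(mat) > 1L && any(diff(mat[, 1]) <= 0)) {
    abort("momentum transfer column is not strictly increasing")
  }
  saxs_curve(mat[, 1], mat[, 2],
             err = if (ncol >= 3L) mat[, 3] else NULL,
             unit = unit, metadata = metadata)
}

#' Write a scattering curve as .dat text
#'
#' Metadata are emitted as leading `name : value` lines, then the data as
#' three whitespace-separated columns in fixed scientific notation. When
#' the curve has no error column, zeros are written in column 3 to keep
#' the three-column contract (set `three_columns = FALSE` for two-column
#' output).
#'
#' @param curve a [saxs_curve()].
#' @param path optional output path; when `NULL` the text is returned.
#' @param three_columns emit an all-zero third column when `err` is absent.
#' @return the .dat text (invisibly when `path` is given).
#' @export
write_dat <- function(curve, path = NULL, three_columns = TRUE) {
  md <- curve_metadata(curve)
  out <- if (length(md)) paste(names(md), ":", md) else character()
  err <- if ("err" %in% names(curve)) curve$err else NULL
  rows <- if (!is.null(err)) {
    paste(fmt_num(curve$s), fmt_num(curve$I), fmt_num(err))
  } else if (three_columns) {
    paste(fmt_num(curve$s), fmt_num(curve$I), fmt_num(0))
  } else {
    paste(fmt_num(curve$s), fmt_num(curve$I))
  }
  text <- paste0(paste(c(out, rows), collapse = "\n"), "\n")
  if (is.null(path)) return(text)
  writeLines(sub("\n$", "", text), path)
  invisible(text)
}
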