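## Model-fit files: three-column .fit (s, Iexp, Ifit) for atomic-model
## fitting and four-column .fir (s, Iexp, err, Ifit) for ab initio
## modelling. The header may carry the reduced chi-square and the
## correlation-map p value.

#' Model-versus-data scattering fit
#'
#' A tibble with columns `s`, `Iexp`, `Ifit` and, for .fir-style fits,
#' `err`. The fit statistics (reduced chi-square, correlation-map p value)
#' and the link to the fitted model ride along as attributes.
#'
#' @param s momentum transfer, strictly increasing.
#' @param Iexp experimental intensities.
#' @param Ifit calculated model intensities (already scaled to the data).
#' @param err experimental sigma, or `NULL` (.fit dialect).
#' @param chi2 reduced chi-square of the fit, or `NA`.
#' @param cormap_p correlation-map p value, or `NA`.
#' @param model_id integer id of the fitted model, or `NA`.
#' @return a `saxs_fit` tibble.
#' @export
saxs_fit <- function(s, Iexp, Ifit, err = NULL, chi2 = NA_real_,
                     cormap_p = NA_real_, model_id = NA_integer_) {
  s <- as.numeric(s)
  if (length(s) > 1L && any(diff(s) <= 0)) {
    abort("momentum transfer s must be strictly increasing")
  }
  cols <- list(s = s, Iexp = as.numeric(Iexp), Ifit = as.numeric(Ifit))
  if (!is.null(err)) cols$err <- as.numeric(err)
  lens <- lengths(cols)
  if (length(unique(lens)) > 1L) abort("fit columns must have equal length")
  out <- tibble::as_tibble(cols)
  attr(out, "chi2") <- as.numeric(chi2)
  attr(out, "cormap_p") <- as.numeric(cormap_p)
  attr(out, "model_id") <- as.integer(model_id)
  class(out) <- c("saxs_fit", class(out))
  out
}

#' @export
print.saxs_fit <- function(x, ...) {
  cat(sprintf("<saxs_fit: %d points%s, chi2 = %s, p = %s>\n",
              nrow(x), if ("err" %in% names(x)) " (with errors)" else "",
              format(attr(x, "chi2")), format(attr(x, "cormap_p"))))
  NextMethod()
}

fit_chi2 <- function(fit) attr(fit, "chi2")
fit_cormap_p <- function(fit) attr(fit, "cormap_p")
fit_model_id <- function(fit) attr(fit, "model_id")

chi2_from_header <- function(lines) {
  for (pat in c("[Cc][Hh][Ii]\\^2", "[Cc][Hh][Ii]2", "[Cc][Hh][Ii]-[Ss][Qq][Uu][Aa][Rr][Ee]")) {
    v <- label_number(lines, pat)
    if (!is.na(v)) return(v)
  }
  NA_real_
}

pvalue_from_header <- function(lines) {
  label_number(lines, "[Pp][- ]?value")
}

#' Read a .fit or .fir model-fit file
#'
#' `.fir` files have four numeric columns (s, Iexp, err, Ifit); `.fit`
#' files have three (s, Iexp, Ifit). With `dialect = "auto"` the dialect
#' is inferred from the file extension when `x` is a path, otherwise from
#' the column count. Header lines are scanned for a reduced chi-square
#' (`Chi^2`, `Chi2` or `chi-square` followed by a number) and a p value.
#'
#' @param x path, single string, or character vector of lines.
#' @param dialect `"auto"`, `"fit"` (3 columns) or `"fir"` (4 columns).
#' @return a [saxs_fit()].
#' @export
read_fitfile <- function(x, dialect = c("auto", "fit", "fir")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto" && length(x) == 1L && !grepl("\n", x, fixed = TRUE) &&
      file.exists(x)) {
    ext <- tolower(sub(".*\\.", "", x))
    if (ext %in% c("fit", "fir")) dialect <- ext
  }
  lines <- as_text_lines(x)
  arity <- vapply(lines, numeric_arity, integer(1), USE.NAMES = FALSE)
  data_ix <- which(arity >= 3L)
  if (length(data_ix) == 0L) abort("no numeric fit rows found")
  ncol <- arity[data_ix[1]]
  if (dialect == "auto") {
    dialect <- if (ncol >= 4L) "fir" else "fit"
  }
  want <- if (dialect == "fir") 4L else 3L
  if (ncol != want) {
    abort(sprintf("%d-column data rows are inconsistent with the %s dialect (%d columns)",
                  ncol, dialect, want))
  }
  if (any(arity[data_ix] != ncol)) {
    abort("inconsistent column counts in fit data rows")
  }
  mat <- do.call(rbind, lapply(lines[data_ix], function(l) as.numeric(ws_tokens(l))))
  hdr <- lines[setdiff(seq_along(lines), data_ix)]
  if (dialect == "fir") {
    saxs_fit(mat[, 1], mat[, 2], mat[, 4], err = mat[, 3],
             chi2 = chi2_from_header(hdr), cormap_p = pvalue_from_header(hdr))
  } else {
    saxs_fit(mat[, 1], mat[, 2], mat[, 3],
             chi2 = chi2_from_header(hdr), cormap_p = pvalue_from_header(hdr))
  }
}

#' Write a .fit or .fir model-fit file
#'
#' The header line carries the fit statistics when they are set
#' (`Chi^2: <value>`, `p-value: <value>`). Dialect `"fit"` emits three
#' numeric columns; `"fir"` emits four and requires the error column.
#'
#' @param fit a [saxs_fit()].
#' @param dialect `"fit"` or `"fir"`.
#' @param path optional output path; when `NULL` the text is returned.
#' @param title optional first header line.
#' @return the fit text (invisibly when `path` is given).
#' @export
write_fitfile <- function(fit, dialect = c("fit", "fir"), path = NULL,
                          title = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "fir" && !("err" %in% names(fit))) {
    abort("the .fir dialect requires an error column")
  }
  stats <- character()
  if (!is.na(fit_chi2(fit))) stats <- c(stats, paste0("Chi^2: ", fmt_num(fit_chi2(fit))))
  if (!is.na(fit_cormap_p(fit))) stats <- c(stats, paste0("p-value: ", fmt_num(fit_cormap_p(fit))))
  hdr <- trimws(paste(c(title, paste(stats, collapse = "  ")), collapse = "  "))
  rows <- if (dialect == "fir") {
    paste(fmt_num(fit$s), fmt_num(fit$Iexp), fmt_num(fit$err), fmt_num(fit$Ifit))
  } else {
    paste(fmt_num(fit$s), fmt_num(fit$Iexp), fmt_num(fit$Ifit))
  }
  lines <- c(if (nzchar(hdr)) hdr, rows)
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(text)
  writeLines(sub("\n$", "", text), path)
  invisible(text)
}
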