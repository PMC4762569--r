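## Indirect-transform (.out) files: the real-space pair-distance
## distribution p(r), the regularized reciprocal-space fit, and the
## derived parameters Rg, I(0) and Dmax.

#' Pair-distance distribution with its reciprocal-space fit
#'
#' Container for the content of an indirect-transform output file:
#' the real-space table `pr` (columns `r`, `p`, `perr`), the
#' reciprocal-space table `recip` (columns `s`, `Iexp`, `err`, `Ireg`,
#' `Iext`; rows extrapolated below the experimental range carry `NA` in
#' `Iexp`, `err` and `Ireg`), and the derived parameters.
#'
#' @param pr data frame with columns `r`, `p`, `perr`; `r` starts at 0,
#'   is strictly increasing and ends at `dmax`.
#' @param recip data frame with columns `s`, `Iexp`, `err`, `Ireg`,
#'   `Iext`; `s` strictly increasing, reaching down to (or near) 0.
#' @param rg radius of gyration from the second moment of p(r).
#' @param i0 forward scattering I(0) from p(r).
#' @param dmax maximum intra-particle distance.
#' @param software name of the program that produced the transform.
#' @return a `saxs_pofr` object.
#' @export
saxs_pofr <- function(pr, recip, rg, i0, dmax, software = NA_character_) {
  pr <- tibble::as_tibble(pr)[c("r", "p", "perr")]
  recip <- tibble::as_tibble(recip)[c("s", "Iexp", "err", "Ireg", "Iext")]
  if (nrow(pr) < 2L) abort("p(r) table needs at least 2 rows")
  if (abs(pr$r[1]) > 1e-9 * max(pr$r)) abort("p(r) grid must start at r = 0")
  if (any(diff(pr$r) <= 0)) abort("r must be strictly increasing")
  if (any(diff(recip$s) <= 0)) abort("reciprocal s must be strictly increasing")
  structure(
    list(pr = pr, recip = recip,
         rg = as.numeric(rg), i0 = as.numeric(i0), dmax = as.numeric(dmax),
         software = software),
    class = "saxs_pofr")
}

#' @export
print.saxs_pofr <- function(x, ...) {
  cat(sprintf(
    "<saxs_pofr: %d r-points, Dmax = %g, Rg = %g, I(0) = %g; %d reciprocal rows (%d extrapolated)>\n",
    nrow(x$pr), x$dmax, x$rg, x$i0, nrow(x$recip), sum(is.na(x$recip$Iexp))))
  invisible(x)
}

# Second-moment radius of gyration of a p(r) table:
# Rg^2 = integral(r^2 p dr) / (2 integral(p dr)), trapezoidal.
pofr_rg <- function(r, p) {
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  sqrt(trapz(r, r^2 * p) / (2 * trapz(r, p)))
}

label_number <- function(lines, pattern) {
  rx <- paste0(pattern, "[^0-9eE+.-]*([-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?)")
  for (line in lines) {
    m <- regexec(rx, line)
    g <- regmatches(line, m)[[1]]
    if (length(g) >= 2L) return(as.numeric(g[2]))
  }
  NA_real_
}

#' Read an indirect-transform .out file
#'
#' The parser is tolerant of layout: it locates the reciprocal-space fit
#' section as the run of numeric rows with five columns (`s`, `Iexp`,
#' `err`, `Ireg`, `Iext`; leading extrapolated rows may carry only `s` and
#' `Iext` as two columns), the real-space section as the trailing run of
#' three-column numeric rows (`r`, `p(r)`, `sigma p(r)`), and the derived
#' parameters by label search (`Dmax`, `Rg`, `I(0)`) in the surrounding
#' text.
#'
#' @param x path, single string, or character vector of lines.
#' @return a [saxs_pofr()].
#' @export
read_out <- function(x) {
  lines <- as_text_lines(x)
  arity <- vapply(lines, numeric_arity, integer(1), USE.NAMES = FALSE)

  # maximal runs of numeric rows with arity in a given set
  runs <- function(ok) {
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    idx <- which(r$values)
    Map(function(a, b) a:b, starts[idx], ends[idx])
  }
  recip_runs <- Filter(function(ix) any(arity[ix] == 5L), runs(arity %in% c(2L, 5L)))
  real_runs <- runs(arity == 3L)
  if (length(real_runs) == 0L) abort("no real-space p(r) section found in .out input")
  real_ix <- real_runs[[length(real_runs)]]
  if (length(recip_runs) == 0L) abort("no five-column reciprocal-space section found in .out input")
  recip_ix <- recip_runs[[1]]

  recip_rows <- lapply(lines[recip_ix], function(l) {
    v <- as.numeric(ws_tokens(l))
    if (length(v) == 2L) c(v[1], NA, NA, NA, v[2]) else v
  })
  recip <- do.call(rbind, recip_rows)
  colnames(recip) <- c("s", "Iexp", "err", "Ireg", "Iext")
  real <- do.call(rbind, lapply(lines[real_ix], function(l) as.numeric(ws_tokens(l))))
  colnames(real) <- c("r", "p", "perr")

  head_lines <- lines[setdiff(seq_along(lines), c(recip_ix, real_ix))]
  dmax <- label_number(head_lines, "[Dd][ ]?max")
  rg <- label_number(head_lines, "\\bR[gG]\\b")
  i0 <- label_number(head_lines, "I\\(0\\)")
  if (is.na(dmax)) dmax <- real[nrow(real), "r"]
  if (is.na(rg)) rg <- pofr_rg(real[, "r"], real[, "p"])

  saxs_pofr(tibble::as_tibble(real), tibble::as_tibble(recip),
            rg = rg, i0 = i0, dmax = dmax)
}

#' Write an indirect-transform .out file
#'
#' Canonical layout: a labelled header (`Dmax`, `Rg`, `I(0)`), the
#' five-column reciprocal-space fit (extrapolated rows written as two
#' tokens, `s` and `Iext`), then the three-column p(r) table.
#'
#' @param dist a [saxs_pofr()].
#' @param path optional output path; when `NULL` the text is returned.
#' @return the .out text (invisibly when `path` is given).
#' @export
write_out <- function(dist, path = NULL) {
  out <- c(
    "Indirect transform of the scattering curve",
    "",
    "Total estimate and derived parameters:",
    paste0("  Dmax : ", fmt_num(dist$dmax)),
    paste0("  Rg   : ", fmt_num(dist$rg)),
    paste0("  I(0) : ", fmt_num(dist$i0)),
    "",
    "Reciprocal space fit:  s  Iexp  err  Ireg  Iext",
    "")
  rc <- dist$recip
  rows <- vapply(seq_len(nrow(rc)), function(i) {
    if (is.na(rc$Iexp[i]) && is.na(rc$Ireg[i])) {
      paste(fmt_num(rc$s[i]), fmt_num(rc$Iext[i]))
    } else {
      paste(fmt_num(rc$s[i]), fmt_num(rc$Iexp[i]), fmt_num(rc$err[i]),
            fmt_num(rc$Ireg[i]), fmt_num(rc$Iext[i]))
    }
  }, character(1))
  out <- c(out, rows, "",
           "Real space distance distribution:  r  p(r)  err",
           "")
  out <- c(out, paste(fmt_num(dist$pr$r), fmt_num(dist$pr$p),
                      fmt_num(dist$pr$perr)))
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (is.null(path)) return(text)
  writeLines(sub("\n$", "", text), path)
  invisible(text)
}
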