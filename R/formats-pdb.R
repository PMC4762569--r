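## Fixed-column PDB coordinate files for atomic and ab initio (dummy-atom
## bead) models. Column layout: record name 1-6, serial 7-11, atom name
## 13-16, residue name 18-20, chain 22, residue number 23-26, x 31-38,
## y 39-46, z 47-54, occupancy 55-60, B 61-66, element 77-78.

#' Spatial model (atomic coordinates or ab initio beads)
#'
#' An ordered tibble of atom records with model-level metadata as
#' attributes: the model type (`"ab-initio"`, `"rigid-body"` or
#' `"atomic"`), the point-symmetry label (P1, P2, ...), the dummy-atom
#' bead radius in angstroms (ab initio models only) and the modelling
#' software name.
#'
#' @param atoms data frame with columns `record` (ATOM/HETATM), `serial`,
#'   `name`, `resname`, `chain`, `resid`, `x`, `y`, `z`, `occ`, `b`,
#'   `element`.
#' @param model_type one of `"ab-initio"`, `"rigid-body"`, `"atomic"`.
#' @param symmetry point-symmetry label.
#' @param bead_radius bead radius in angstroms (`NA` unless ab initio).
#' @param software modelling software name.
#' @return a `saxs_model` tibble.
#' @export
saxs_model <- function(atoms, model_type = "atomic", symmetry = "P1",
                       bead_radius = NA_real_, software = NA_character_) {
  atoms <- tibble::as_tibble(atoms)
  need <- c("record", "serial", "name", "resname", "chain", "resid",
            "x", "y", "z", "occ", "b", "element")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols)) {
    abort(paste("atom table lacks columns:", paste(missing_cols, collapse = ", ")))
  }
  atoms <- atoms[need]
  if (any(atoms$serial <= 0)) abort("atom serials must be positive")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("atom coordinates must be finite")
  }
  model_type <- match.arg(model_type, c("ab-initio", "rigid-body", "atomic"))
  out <- atoms
  attr(out, "model_type") <- model_type
  attr(out, "symmetry") <- symmetry
  attr(out, "bead_radius") <- as.numeric(bead_radius)
  attr(out, "software") <- software
  class(out) <- c("saxs_model", class(out))
  out
}

#' @export
print.saxs_model <- function(x, ...) {
  cat(sprintf("<saxs_model: %d atoms, type %s, symmetry %s%s>\n",
              nrow(x), attr(x, "model_type"), attr(x, "symmetry"),
              if (!is.na(attr(x, "bead_radius")))
                sprintf(", bead radius %g A", attr(x, "bead_radius")) else ""))
  NextMethod()
}

model_type <- function(m) attr(m, "model_type")
model_symmetry <- function(m) attr(m, "symmetry")
model_bead_radius <- function(m) attr(m, "bead_radius")
model_software <- function(m) attr(m, "software")

pdb_field <- function(line, from, to) {
  n <- nchar(line)
  if (from > n) return("")
  trimws(substr(line, from, min(to, n)))
}

#' Read a PDB coordinate file
#'
#' ATOM and HETATM records are captured in file order; every other record
#' type is ignored. Fields are cut at the standard fixed columns.
#'
#' @param x path, single string, or character vector of lines.
#' @param model_type,symmetry,bead_radius,software model metadata to attach
#'   (a plain .pdb file does not carry them).
#' @return a [saxs_model()].
#' @export
read_pdb <- function(x, model_type = "atomic", symmetry = "P1",
                     bead_radius = NA_real_, software = NA_character_) {
  lines <- as_text_lines(x)
  keep <- grepl("^(ATOM|HETATM)", lines)
  ix <- which(keep)
  if (length(ix) == 0L) abort("no ATOM/HETATM records found")
  num_field <- function(line, from, to, what, ln) {
    f <- pdb_field(line, from, to)
    v <- suppressWarnings(as.numeric(f))
    if (is.na(v) && what %in% c("x", "y", "z")) {
      abort(sprintf("line %d: unparsable %s coordinate field '%s'", ln, what, f))
    }
    v
  }
  rows <- lapply(ix, function(i) {
    l <- lines[i]
    tibble::tibble(
      record = pdb_field(l, 1, 6),
      serial = as.integer(num_field(l, 7, 11, "serial", i)),
      name = pdb_field(l, 13, 16),
      resname = pdb_field(l, 18, 20),
      chain = pdb_field(l, 22, 22),
      resid = as.integer(num_field(l, 23, 26, "resid", i)),
      x = num_field(l, 31, 38, "x", i),
      y = num_field(l, 39, 46, "y", i),
      z = num_field(l, 47, 54, "z", i),
      occ = num_field(l, 55, 60, "occ", i),
      b = num_field(l, 61, 66, "b", i),
      element = pdb_field(l, 77, 78))
  })
  atoms <- dplyr::bind_rows(rows)
  atoms$occ[is.na(atoms$occ)] <- 1
  atoms$b[is.na(atoms$b)] <- 0
  saxs_model(atoms, model_type = model_type, symmetry = symmetry,
             bead_radius = bead_radius, software = software)
}

#' Write a spatial model as PDB text
#'
#' Coordinates are emitted as fixed 8.3 fields at the standard columns;
#' the file is terminated with `END`.
#'
#' @param model a [saxs_model()].
#' @param path optional output path; when `NULL` the text is returned.
#' @return the PDB text (invisibly when `path` is given).
#' @export
write_pdb <- function(model, path = NULL) {
  a <- model
  name4 <- ifelse(nchar(a$name) <= 3L, paste0(" ", a$name), a$name)
  lines <- sprintf(
    "%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$record, a$serial, name4, a$resname, a$chain, a$resid,
    a$x, a$y, a$z, a$occ, a$b, a$element)
  text <- paste0(paste(c(lines, "END"), collapse = "\n"), "\n")
  if (is.null(path)) return(text)
  writeLines(sub("\n$", "", text), path)
  invisible(text)
}
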