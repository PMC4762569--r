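## The converter operation set: insert legacy SAS data into sasCIF files
## and extract it back. Insert tools touch only their target block; with
## `overwrite = "replace"` a re-run is idempotent, with `"error"` an
## existing target category is a conflict.

#' Insert a scattering curve into a sasCIF file
#'
#' Writes the intensity loop (`sas_scan_intensity`: id, s, I, sigma) into
#' the target MAIN-family block and routes the curve metadata to
#' `sas_scan` (title, unit, temperatures, frame count) and `sas_sample`
#' (name, concentration). The momentum-transfer range items are set to
#' the grid extremes.
#'
#' @param curve a [saxs_curve()].
#' @param file a `cif_file` (default: a new empty one).
#' @param block target block label.
#' @param overwrite `"replace"` (default) or `"error"` (conflict when the
#'   block already holds intensities).
#' @return the updated `cif_file`.
#' @export
dat2cif <- function(curve, file = cif_new(), block = "MAIN",
                    overwrite = c("replace", "error")) {
  put_curve(file, block, curve, match.arg(overwrite))
}

#' Extract the scattering curves from a sasCIF file
#'
#' One curve per MAIN-family block holding an intensity loop, with unit
#' and experiment metadata (temperatures, frame count, sample name and
#' concentration) reconstructed. An all-placeholder error column comes
#' back as an absent `err`.
#'
#' @param file a `cif_file`.
#' @return a list of [saxs_curve()] (empty, with a warning, when no block
#'   holds intensities).
#' @export
cif2dat <- function(file) {
  mains <- blocks_of_family(file, "MAIN")
  mains <- mains[order(vapply(mains, family_ordinal, integer(1), base = "MAIN"))]
  curves <- purrr::compact(lapply(mains, function(b) extract_curve(file, b)))
  if (length(curves) == 0L) warn("no intensity loop found in any MAIN-family block")
  curves
}

#' Insert a pair-distance distribution into a sasCIF file
#'
#' Writes the three p(r) categories into the target MAIN-family block:
#' the real-space loop `sas_p_of_r` (r, p, sigma), the reciprocal-space
#' loop `sas_p_of_r_extrapolated_intensity` (s, regularized and
#' extrapolated intensities; the regularized value is inapplicable on the
#' extrapolated rows below the experimental range) and the scalars
#' `sas_p_of_r_details` (Dmax, Rg, I(0), software).
#'
#' @param dist a [saxs_pofr()].
#' @inheritParams dat2cif
#' @export
out2cif <- function(dist, file = cif_new(), block = "MAIN",
                    overwrite = c("replace", "error")) {
  put_pofr(file, block, dist, match.arg(overwrite))
}

#' Reconstruct the distance distribution from a sasCIF file
#'
#' The stored regularized intensities are translated back to the same
#' angular increments as the initial scattering curve: they are re-binned
#' (via [rebin_to_grid()]) onto the experimental grid held in
#' `sas_scan_intensity`, while the extrapolated section below the
#' experimental minimum (down to s = 0) is kept on its stored grid.
#'
#' @param file a `cif_file`.
#' @param block MAIN-family block to read; default is the first block
#'   holding `sas_p_of_r`.
#' @return a [saxs_pofr()].
#' @export
cif2out <- function(file, block = NULL) {
  if (is.null(block)) {
    mains <- blocks_of_family(file, "MAIN")
    has <- mains[vapply(mains, function(b) cif_has_category(file, b, "sas_p_of_r"),
                        logical(1))]
    if (length(has) == 0L) abort("no sas_p_of_r category found in any MAIN-family block")
    block <- has[1]
  }
  d <- extract_pofr(file, block)
  if (is.null(d)) abort(sprintf("block '%s' holds no sas_p_of_r category", block))
  d
}

#' Insert a spatial model into a sasCIF file
#'
#' Writes a MODEL-family block holding the `sas_model` description (type,
#' symmetry, bead radius, software) and the `atom_site` coordinate loop
#' in PDBx naming (group_PDB, id, label_atom_id, label_comp_id,
#' auth_asym_id, auth_seq_id, Cartn_x/y/z, occupancy, B_iso_or_equiv,
#' type_symbol).
#'
#' @param model a [saxs_model()].
#' @param file a `cif_file`.
#' @param block target block label; default: next free MODEL-family label.
#' @param id model id; default: ordinal of the target block.
#' @inheritParams dat2cif
#' @export
pdb2cif <- function(model, file = cif_new(), block = NULL, id = NULL,
                    overwrite = c("replace", "error")) {
  if (is.null(block)) block <- next_family_label(file, "MODEL")
  if (is.null(id)) id <- family_ordinal(block, "MODEL")
  put_model(file, block, model, id = id, overwrite = match.arg(overwrite))
}

#' Extract the spatial models from a sasCIF file as PDB texts
#'
#' One PDB text per MODEL-family block, in file order. With `out_dir`
#' given, each model is also saved into its own .pdb file.
#'
#' @param file a `cif_file`.
#' @param out_dir optional output directory (created if missing).
#' @param name stem for written filenames.
#' @return named character vector of PDB texts (names are block labels);
#'   when `out_dir` is given, the names attribute carries the paths
#'   written.
#' @export
cif2pdb <- function(file, out_dir = NULL, name = entry_name(file)) {
  labs <- blocks_of_family(file, "MODEL")
  labs <- labs[order(vapply(labs, family_ordinal, integer(1), base = "MODEL"))]
  texts <- vapply(labs, function(l) write_pdb(extract_model(file, l)), character(1))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(out_dir, paste0(name, "_", tolower(labs), ".pdb"))
    for (i in seq_along(texts)) writeLines(sub("\n$", "", texts[i]), paths[i])
    names(texts) <- paths
  }
  texts
}

#' Insert a model fit into a sasCIF file
#'
#' Writes a FIT-family block: `sas_model_fitting` (s, I, Ifit) and
#' `sas_model_fitting_details` (reduced chi-square, correlation-map p
#' value, model id). Experimental errors are not stored here; they live
#' with the original scattering data in `sas_scan_intensity`. A fit
#' referencing a model id absent from the file is an error; a fit with no
#' model link is inserted with a warning and an inapplicable link.
#'
#' @param fit a [saxs_fit()].
#' @param file a `cif_file`.
#' @param block target block label; default: next free FIT-family label.
#' @param model_id id of the fitted model; default: the fit's own
#'   `model_id` attribute.
#' @inheritParams dat2cif
#' @export
fit2cif <- function(fit, file = cif_new(), block = NULL, model_id = NULL,
                    overwrite = c("replace", "error")) {
  if (is.null(block)) block <- next_family_label(file, "FIT")
  if (is.null(model_id)) model_id <- fit_model_id(fit)
  put_fit(file, block, fit, id = family_ordinal(block, "FIT"),
          model_id = as.integer(model_id), overwrite = match.arg(overwrite))
}

#' Extract the model fits from a sasCIF file as .fit texts
#'
#' One three-column .fit text per FIT-family block, with the reduced
#' chi-square and p value in the header. Pass `dialect = "fir"` to
#' recover four-column files with the experimental errors taken from
#' `sas_scan_intensity` (possible only where the fit grid matches the
#' stored experimental grid).
#'
#' @param file a `cif_file`.
#' @param out_dir optional output directory (created if missing).
#' @param dialect `"fit"` (default) or `"fir"`.
#' @param name stem for written filenames.
#' @return named character vector of fit texts (names are block labels,
#'   or paths when `out_dir` is given).
#' @export
cif2fit <- function(file, out_dir = NULL, dialect = c("fit", "fir"),
                    name = entry_name(file)) {
  dialect <- match.arg(dialect)
  labs <- blocks_of_family(file, "FIT")
  labs <- labs[order(vapply(labs, family_ordinal, integer(1), base = "FIT"))]
  texts <- vapply(labs, function(l) {
    fit <- extract_fit(file, l)
    if (dialect == "fir") {
      err <- fit_errors_from_main(file, fit)
      if (is.null(err)) {
        abort(sprintf(
          "cannot emit .fir for block '%s': no matching experimental errors in sas_scan_intensity",
          l))
      }
      fit <- saxs_fit(fit$s, fit$Iexp, fit$Ifit, err = err,
                      chi2 = fit_chi2(fit), cormap_p = fit_cormap_p(fit),
                      model_id = fit_model_id(fit))
    }
    write_fitfile(fit, dialect = dialect)
  }, character(1))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(out_dir, paste0(name, "_", tolower(labs), ".", dialect))
    for (i in seq_along(texts)) writeLines(sub("\n$", "", texts[i]), paths[i])
    names(texts) <- paths
  }
  texts
}

# Experimental errors for a fit grid, looked up in the MAIN blocks.
# Returns NULL unless some stored curve has errors on exactly the fit grid.
fit_errors_from_main <- function(file, fit) {
  for (b in blocks_of_family(file, "MAIN")) {
    curve <- extract_curve(file, b)
    if (is.null(curve) || !("err" %in% names(curve))) next
    ix <- match(round(fit$s, 9), round(curve$s, 9))
    if (!any(is.na(ix))) return(curve$err[ix])
  }
  NULL
}

# Filename stem derived from the entry title/sample name.
entry_name <- function(file) {
  for (b in blocks_of_family(file, "MAIN")) {
    t <- cif_get_column(file, b, "sas_scan", "title") %||%
      cif_get_column(file, b, "sas_sample", "name")
    if (!is.null(t) && !is.na(t[1]) && nzchar(t[1])) {
      stem <- gsub("[^A-Za-z0-9._-]+", "_", t[1])
      return(gsub("^_+|_+$", "", stem))
    }
  }
  "entry"
}
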