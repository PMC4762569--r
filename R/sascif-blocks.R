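## Internal bridges between the tabular SAS objects and sasCIF categories.
## Each put_* writes the categories for one kind of content into a block;
## each extract_* is its inverse. The public converters and the entry
## assembler are thin compositions of these.

fam_label <- function(base, i) if (i == 1L) base else paste0(base, i)

blocks_of_family <- function(file, base) {
  labs <- cif_blocks(file)
  labs[grepl(paste0("^", tolower(base), "[0-9]*$"), tolower(labs))]
}

next_family_label <- function(file, base) {
  existing <- blocks_of_family(file, base)
  fam_label(base, length(existing) + 1L)
}

# ordinal of a family block: MAIN -> 1, MAIN3 -> 3
family_ordinal <- function(label, base) {
  suf <- sub(paste0("^", tolower(base)), "", tolower(label))
  if (suf == "") 1L else as.integer(suf)
}

# Merge scalar items into a category without discarding the ones already
# there (cif_set_category replaces a category wholesale).
merge_scalars <- function(file, block, category, values, kinds = NULL) {
  if (length(values) == 0L) return(file)
  existing_items <- character()
  existing <- list()
  existing_kinds <- list()
  bi <- find_block(file, block)
  if (!is.na(bi)) {
    cc <- file$blocks[[bi]]$categories[[tolower(category)]]
    if (!is.null(cc)) {
      if (cc$loop) abort(sprintf("category '%s' is a loop; cannot merge scalars", category))
      existing_items <- cc$items
      existing <- cc$columns
      existing_kinds <- cc$kinds
    }
  }
  cols <- setNames(existing, existing_items)
  kns <- setNames(existing_kinds, existing_items)
  for (k in seq_along(values)) {
    nm <- tolower(names(values)[k])
    v <- as.character(values[[k]])
    kind <- if (!is.null(kinds)) kinds[[k]] else if (is.na(v)) "m" else "t"
    cols[[nm]] <- if (is.na(v)) "?" else v
    kns[[nm]] <- kind
  }
  cif_set_category(file, block, category, cols, loop = FALSE,
                   kinds = unname(kns))
}

# Populated scalar items of a category as a named character vector
# (placeholders excluded).
scalar_values <- function(file, block, category) {
  bi <- find_block(file, block)
  if (is.na(bi)) return(character())
  cc <- file$blocks[[bi]]$categories[[tolower(category)]]
  if (is.null(cc) || cc$loop) return(character())
  keep <- vapply(cc$kinds, function(k) k[1] == "t", logical(1))
  setNames(vapply(cc$columns[keep], `[`, character(1), 1L), cc$items[keep])
}

## ---- scattering curves ----------------------------------------------------

# Canonical .dat metadata keys and their category.item routes. The keys on
# the left are what the extractors emit, so generated files round-trip
# verbatim; the synonym table below absorbs common spellings on input.
dat_metadata_map <- c(
  title = "sas_scan.title",
  unit = "sas_scan.unit",
  sample_description = "sas_sample.name",
  sample_concentration = "sas_sample.specimen_concentration",
  storage_temperature = "sas_scan.storage_temperature",
  cell_temperature = "sas_scan.cell_temperature",
  number_of_frames = "sas_scan.number_of_frames")

dat_metadata_synonyms <- c(
  sample = "sample_description",
  description = "sample_description",
  concentration = "sample_concentration",
  conc = "sample_concentration",
  temperature = "cell_temperature",
  frames = "number_of_frames")

value_or <- function(v, name, default) {
  x <- v[name]
  if (length(x) == 0L || is.na(x)) default else unname(x)
}

sanitize_item <- function(key) {
  nm <- gsub("[^a-z0-9_]+", "_", tolower(key))
  gsub("^_+|_+$", "", nm)
}

check_conflict <- function(file, block, category, overwrite) {
  if (overwrite == "error" && cif_has_category(file, block, category)) {
    abort(sprintf("block '%s' already holds %s (overwrite policy is 'error')",
                  block, category))
  }
}

put_curve <- function(file, block, curve, overwrite = "replace") {
  overwrite <- match.arg(overwrite, c("replace", "error"))
  check_conflict(file, block, "sas_scan_intensity", overwrite)
  n <- nrow(curve)
  items <- list(id = as.character(seq_len(n)),
                momentum_transfer = fmt_num(curve$s),
                intensity = fmt_num(curve$I))
  if ("err" %in% names(curve)) items$error <- fmt_num(curve$err)
  file <- cif_set_category(file, block, "sas_scan_intensity", items, loop = TRUE)

  scan <- c(id = "1", unit = curve_unit(curve),
            momentum_transfer_min = fmt_num(curve$s[1]),
            momentum_transfer_max = fmt_num(curve$s[n]))
  sample <- c(id = "1")
  md <- curve_metadata(curve)
  for (key in names(md)) {
    canon <- tolower(key)
    canon <- dat_metadata_synonyms[canon] %||% canon
    if (is.na(canon)) canon <- tolower(key)
    route <- dat_metadata_map[canon]
    if (!is.na(route)) {
      parts <- strsplit(unname(route), ".", fixed = TRUE)[[1]]
      if (parts[1] == "sas_scan") scan[parts[2]] <- md[[key]]
      else sample[parts[2]] <- md[[key]]
    } else {
      scan[sanitize_item(key)] <- md[[key]]
    }
  }
  file <- merge_scalars(file, block, "sas_scan", as.list(scan))
  if (length(sample) > 1L) {
    file <- merge_scalars(file, block, "sas_sample", as.list(sample))
  }
  file
}

extract_curve <- function(file, block) {
  s <- cif_get_column(file, block, "sas_scan_intensity", "momentum_transfer")
  if (is.null(s)) return(NULL)
  I <- cif_get_column(file, block, "sas_scan_intensity", "intensity")
  err <- cif_get_column(file, block, "sas_scan_intensity", "error")
  if (!is.null(err) && all(is.na(err))) err <- NULL
  unit <- cif_get_column(file, block, "sas_scan", "unit") %||% "1/angstrom"

  scan <- scalar_values(file, block, "sas_scan")
  sample <- scalar_values(file, block, "sas_sample")
  md <- character()
  for (canon in names(dat_metadata_map)) {
    parts <- strsplit(unname(dat_metadata_map[canon]), ".", fixed = TRUE)[[1]]
    src <- if (parts[1] == "sas_scan") scan else sample
    if (!is.na(src[parts[2]] %||% NA)) md[canon] <- src[[parts[2]]]
  }
  md <- md[names(md) != "unit"]  # the unit is carried as the curve unit
  extra <- setdiff(names(scan),
                   c(registry_items("sas_scan"), "id"))
  for (nm in extra) md[nm] <- scan[[nm]]
  saxs_curve(as.numeric(s), as.numeric(I),
             err = if (is.null(err)) NULL else as.numeric(err),
             unit = unname(unit[1]), metadata = md)
}

## ---- distance distributions -----------------------------------------------

put_pofr <- function(file, block, dist, overwrite = "replace",
                     software = NULL) {
  overwrite <- match.arg(overwrite, c("replace", "error"))
  check_conflict(file, block, "sas_p_of_r", overwrite)
  pr <- dist$pr
  file <- cif_set_category(file, block, "sas_p_of_r", list(
    id = as.character(seq_len(nrow(pr))),
    r = fmt_num(pr$r), p = fmt_num(pr$p), p_error = fmt_num(pr$perr)),
    loop = TRUE)
  rc <- dist$recip
  reg <- ifelse(is.na(rc$Ireg), ".", fmt_num(rc$Ireg))
  reg_kinds <- ifelse(is.na(rc$Ireg), "i", "t")
  file <- cif_set_category(file, block, "sas_p_of_r_extrapolated_intensity", list(
    id = as.character(seq_len(nrow(rc))),
    momentum_transfer = fmt_num(rc$s),
    intensity_reg = reg,
    intensity_ext = fmt_num(rc$Iext)),
    loop = TRUE,
    kinds = list(rep("t", nrow(rc)), rep("t", nrow(rc)), reg_kinds,
                 rep("t", nrow(rc))))
  details <- list(id = "1", dmax = fmt_num(dist$dmax), rg = fmt_num(dist$rg),
                  i0 = fmt_num(dist$i0))
  sw <- software %||% dist$software
  if (!is.null(sw) && !is.na(sw)) details$software <- sw
  merge_scalars(file, block, "sas_p_of_r_details", details)
}

# Reconstruct a saxs_pofr from a block. The regularized intensities are
# re-binned onto the experimental grid stored in sas_scan_intensity of the
# same block (when present); stored points below the experimental minimum
# are kept on their own grid, extrapolated down to s = 0.
extract_pofr <- function(file, block) {
  r <- cif_get_column(file, block, "sas_p_of_r", "r")
  if (is.null(r)) return(NULL)
  p <- as.numeric(cif_get_column(file, block, "sas_p_of_r", "p"))
  perr <- cif_get_column(file, block, "sas_p_of_r", "p_error")
  perr <- if (is.null(perr)) rep(0, length(p)) else as.numeric(perr)
  pr <- tibble::tibble(r = as.numeric(r), p = p, perr = perr)

  s_st <- as.numeric(cif_get_column(
    file, block, "sas_p_of_r_extrapolated_intensity", "momentum_transfer"))
  reg_st <- cif_get_column(file, block, "sas_p_of_r_extrapolated_intensity",
                           "intensity_reg")
  ext_st <- cif_get_column(file, block, "sas_p_of_r_extrapolated_intensity",
                           "intensity_ext")
  reg_st <- if (is.null(reg_st)) rep(NA_real_, length(s_st)) else as.numeric(reg_st)
  ext_st <- if (is.null(ext_st)) rep(NA_real_, length(s_st)) else as.numeric(ext_st)

  dmax <- cif_get_column(file, block, "sas_p_of_r_details", "dmax")
  rg <- cif_get_column(file, block, "sas_p_of_r_details", "rg")
  i0 <- cif_get_column(file, block, "sas_p_of_r_details", "i0")
  software <- cif_get_column(file, block, "sas_p_of_r_details", "software")

  curve <- extract_curve(file, block)
  if (!is.null(curve) && length(s_st) >= 2L) {
    s_exp <- curve$s
    reg_def <- !is.na(reg_st)
    reg_new <- if (sum(reg_def) >= 2L) {
      rebin_to_grid(s_st[reg_def], reg_st[reg_def], s_exp)
    } else rep(NA_real_, length(s_exp))
    ext_new <- rebin_to_grid(s_st, ext_st, s_exp)
    below <- s_st < s_exp[1] & !reg_def
    recip <- tibble::tibble(
      s = c(s_st[below], s_exp),
      Iexp = c(rep(NA_real_, sum(below)), curve$I),
      err = c(rep(NA_real_, sum(below)),
              if ("err" %in% names(curve)) curve$err else rep(NA_real_, length(s_exp))),
      Ireg = c(rep(NA_real_, sum(below)), reg_new),
      Iext = c(ext_st[below], ext_new))
  } else {
    recip <- tibble::tibble(s = s_st, Iexp = NA_real_, err = NA_real_,
                            Ireg = reg_st, Iext = ext_st)
  }
  saxs_pofr(pr, recip,
            rg = as.numeric(rg %||% NA), i0 = as.numeric(i0 %||% NA),
            dmax = as.numeric(dmax %||% max(pr$r)),
            software = (software %||% NA_character_)[1])
}

## ---- models and fits ------------------------------------------------------

put_model <- function(file, label, model, id, overwrite = "replace") {
  overwrite <- match.arg(overwrite, c("replace", "error"))
  check_conflict(file, label, "sas_model", overwrite)
  details <- list(id = as.character(id), type = model_type(model),
                  symmetry = model_symmetry(model))
  if (!is.na(model_bead_radius(model))) {
    details$bead_radius <- fmt_num(model_bead_radius(model))
  }
  if (!is.na(model_software(model) %||% NA)) details$software <- model_software(model)
  file <- merge_scalars(file, label, "sas_model", details)
  a <- model
  cif_set_category(file, label, "atom_site", list(
    group_pdb = a$record,
    id = as.character(a$serial),
    label_atom_id = a$name,
    label_comp_id = a$resname,
    auth_asym_id = a$chain,
    auth_seq_id = as.character(a$resid),
    cartn_x = sprintf("%.3f", a$x),
    cartn_y = sprintf("%.3f", a$y),
    cartn_z = sprintf("%.3f", a$z),
    occupancy = sprintf("%.2f", a$occ),
    b_iso_or_equiv = sprintf("%.2f", a$b),
    type_symbol = a$element),
    loop = TRUE)
}

extract_model <- function(file, label) {
  g <- cif_get_column(file, label, "atom_site", "group_pdb")
  if (is.null(g)) return(NULL)
  col <- function(item) cif_get_column(file, label, "atom_site", item)
  n <- length(g)
  or_default <- function(v, default) if (is.null(v)) rep(default, n) else v
  atoms <- tibble::tibble(
    record = g,
    serial = as.integer(col("id")),
    name = or_default(col("label_atom_id"), ""),
    resname = or_default(col("label_comp_id"), ""),
    chain = or_default(col("auth_asym_id"), ""),
    resid = as.integer(or_default(col("auth_seq_id"), "0")),
    x = as.numeric(col("cartn_x")),
    y = as.numeric(col("cartn_y")),
    z = as.numeric(col("cartn_z")),
    occ = as.numeric(or_default(col("occupancy"), "1")),
    b = as.numeric(or_default(col("b_iso_or_equiv"), "0")),
    element = or_default(col("type_symbol"), ""))
  det <- scalar_values(file, label, "sas_model")
  saxs_model(atoms,
             model_type = value_or(det, "type", "atomic"),
             symmetry = value_or(det, "symmetry", "P1"),
             bead_radius = as.numeric(value_or(det, "bead_radius", NA)),
             software = value_or(det, "software", NA_character_))
}

model_id_of_block <- function(file, label) {
  v <- cif_get_column(file, label, "sas_model", "id")
  if (is.null(v)) NA_integer_ else as.integer(v[1])
}

put_fit <- function(file, label, fit, id, model_id, overwrite = "replace") {
  overwrite <- match.arg(overwrite, c("replace", "error"))
  check_conflict(file, label, "sas_model_fitting", overwrite)
  details <- list(id = as.character(id))
  if (is.na(model_id)) {
    warn("fit has no model link; sas_model_fitting_details.model_id left inapplicable")
    details$model_id <- NA  # placeholder
  } else {
    ids <- vapply(blocks_of_family(file, "MODEL"), function(l) {
      model_id_of_block(file, l)
    }, integer(1))
    if (!(model_id %in% ids)) {
      abort(sprintf("fit references unknown model id %d", model_id))
    }
    details$model_id <- as.character(model_id)
  }
  if (!is.na(fit_chi2(fit))) details$chi_square <- fmt_num(fit_chi2(fit))
  if (!is.na(fit_cormap_p(fit))) details$p_value <- fmt_num(fit_cormap_p(fit))
  file <- merge_scalars(file, label, "sas_model_fitting_details", details)
  # experimental errors are not stored here: they live with the original
  # scattering data in sas_scan_intensity
  cif_set_category(file, label, "sas_model_fitting", list(
    id = as.character(seq_len(nrow(fit))),
    momentum_transfer = fmt_num(fit$s),
    intensity = fmt_num(fit$Iexp),
    fitted_intensity = fmt_num(fit$Ifit)),
    loop = TRUE)
}

extract_fit <- function(file, label) {
  s <- cif_get_column(file, label, "sas_model_fitting", "momentum_transfer")
  if (is.null(s)) return(NULL)
  Iexp <- as.numeric(cif_get_column(file, label, "sas_model_fitting", "intensity"))
  Ifit <- as.numeric(cif_get_column(file, label, "sas_model_fitting", "fitted_intensity"))
  det <- scalar_values(file, label, "sas_model_fitting_details")
  saxs_fit(as.numeric(s), Iexp, Ifit,
           chi2 = as.numeric(det["chi_square"] %||% NA),
           cormap_p = as.numeric(det["p_value"] %||% NA),
           model_id = as.integer(det["model_id"] %||% NA))
}
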