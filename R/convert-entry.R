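## Entry-level operations: metadata dump (cif2sub), extract-everything
## (cif2all) and the collector that builds a complete sasCIF entry from a
## legacy file set plus flat metadata (the pipeline-integration path).

flat_prefix <- function(label) {
  if (tolower(label) == "main") "" else paste0(tolower(label), "_")
}

flat_name <- function(category, item) {
  paste0(sub("^sas_", "", category), "_", item)
}

# key -> c(category, item) lookup built from the registry (id items are
# structural and excluded from the flat view).
flat_map <- function() {
  if (is.null(.sascifr_env$flat_map)) {
    reg <- sascif_registry()
    reg <- reg[reg$item != "id", ]
    m <- split(reg[c("category", "item")], flat_name(reg$category, reg$item))
    .sascifr_env$flat_map <- lapply(m, function(d) c(d$category[1], d$item[1]))
  }
  .sascifr_env$flat_map
}

#' Flatten all scalar metadata of a sasCIF file to name-value pairs
#'
#' Walks every block in order and emits each populated scalar item (loops
#' and structural `id` items excluded) as a flat
#' `<category-without-sas-prefix>_<item>` name, e.g. `sample_name`,
#' `buffer_ph`, `result_dmax`. Items of blocks after the first MAIN are
#' prefixed with the lower-cased block label (`main2_`, `model_`, `fit2_`,
#' ...). The output is a valid metadata config for [sascif_collect()].
#'
#' @param file a `cif_file`.
#' @param path optional path; when given, `name : value` lines are written.
#' @return named character vector of metadata values, in file order.
#' @export
cif2sub <- function(file, path = NULL) {
  out <- character()
  for (b in file$blocks) {
    pre <- flat_prefix(b$name)
    for (cc in b$categories) {
      if (cc$loop) next
      for (k in seq_along(cc$items)) {
        if (cc$items[k] == "id") next
        if (cc$kinds[[k]][1] != "t") next
        out[paste0(pre, flat_name(cc$name, cc$items[k]))] <- cc$columns[[k]][1]
      }
    }
  }
  if (!is.null(path)) {
    writeLines(paste(names(out), ":", out), path)
  }
  out
}

read_flat_config <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
    out <- character()
    for (line in lines) {
      if (!nzchar(trimws(line)) || startsWith(trimws(line), "#")) next
      m <- regexpr("[:=]", line)
      if (m < 1L) next
      out[trimws(substr(line, 1L, m - 1L))] <-
        trimws(substr(line, m + 1L, nchar(line)))
    }
    return(out)
  }
  setNames(vapply(x, as.character, character(1)), names(x))
}

# Route one flat config key into the right category of the right block(s).
route_config_key <- function(file, key, value) {
  key_l <- tolower(key)
  key_l <- sub("^main_", "", key_l)
  hit <- flat_map()[[key_l]]
  if (is.null(hit)) {
    warn(sprintf("config key '%s' matches no sasCIF item; stored under sas_scan", key))
    return(merge_scalars(file, "MAIN", "sas_scan",
                         setNames(list(value), sanitize_item(key))))
  }
  cat_name <- hit[1]; item <- hit[2]
  targets <- if (cat_name == "sas_model") {
    blocks_of_family(file, "MODEL")
  } else if (cat_name %in% c("sas_model_fitting_details", "sas_model_fitting")) {
    blocks_of_family(file, "FIT")
  } else {
    "MAIN"
  }
  for (tgt in targets) {
    id_val <- if (cat_name == "citation") "primary" else "1"
    vals <- setNames(list(value), item)
    if (!cif_has_category(file, tgt, cat_name)) {
      vals <- c(list(id = id_val), vals)
    }
    file <- merge_scalars(file, tgt, cat_name, vals)
  }
  file
}

#' Build a complete sasCIF entry from a legacy file set
#'
#' Collects everything a processing-pipeline run produces for one
#' measurement into a single sasCIF file: the experimental curve (.dat,
#' mandatory), optionally the indirect-transform output (.out), spatial
#' models (.pdb) with their fits (.fit/.fir, paired by position), and a
#' flat metadata config. Equivalent to chaining [dat2cif()], [out2cif()],
#' [pdb2cif()] and [fit2cif()] by hand.
#'
#' @param dat path to the .dat scattering curve (required).
#' @param out optional path to the .out file.
#' @param pdb character vector of model .pdb paths (possibly empty).
#' @param fit character vector of fit file paths; `fit[i]` is the fit of
#'   `pdb[i]`.
#' @param config flat metadata: a named vector/list, or a path to a text
#'   file of `name : value` lines (the [cif2sub()] naming scheme, e.g.
#'   `sample_name`, `buffer_ph`, `beam_name`, `result_rg_from_guinier`).
#' @param unit momentum-transfer unit of the curve.
#' @return a `cif_file` with MAIN (+ MODEL/FIT) blocks.
#' @export
sascif_collect <- function(dat, out = NULL, pdb = character(),
                           fit = character(), config = NULL,
                           unit = "1/angstrom") {
  if (is.null(dat) || !file.exists(dat)) {
    abort("a .dat scattering curve is mandatory for collect")
  }
  for (p in c(out, pdb, fit)) {
    if (!file.exists(p)) abort(sprintf("input file not found: %s", p))
  }
  file <- dat2cif(read_dat(dat, unit = unit))
  if (!is.null(out)) file <- out2cif(read_out(out), file)
  for (i in seq_along(pdb)) {
    m <- read_pdb(pdb[i])
    if (all(m$resname == "DUM")) {
      m <- saxs_model(m, model_type = "ab-initio",
                      symmetry = model_symmetry(m),
                      bead_radius = model_bead_radius(m),
                      software = model_software(m))
    }
    file <- pdb2cif(m, file)
  }
  for (i in seq_along(fit)) {
    f <- read_fitfile(fit[i])
    file <- fit2cif(f, file,
                    model_id = if (i <= length(pdb)) i else NA_integer_)
  }
  if (!is.null(config)) {
    cfg <- read_flat_config(config)
    for (k in seq_along(cfg)) {
      file <- route_config_key(file, names(cfg)[k], cfg[[k]])
    }
  }
  file
}

#' Extract all available data from a sasCIF file at once
#'
#' Invokes the individual extractors — curves ([cif2dat()]), distance
#' distribution ([cif2out()]), models ([cif2pdb()]), fits ([cif2fit()])
#' and the flat metadata ([cif2sub()]) — and saves each output under
#' `out_dir` (created if missing). Failures of one component are recorded
#' in the manifest and do not stop the others.
#'
#' @param file a `cif_file`.
#' @param out_dir output directory.
#' @param name filename stem; defaults to a stem derived from the entry
#'   title or sample name.
#' @return a manifest tibble with columns `kind`, `path`, `status`
#'   (`"written"`/`"skipped"`/`"error"`) and `detail`.
#' @export
cif2all <- function(file, out_dir = ".", name = entry_name(file)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  add <- function(kind, path, status, detail = "") {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      kind = kind, path = path, status = status, detail = detail)
  }
  run <- function(kind, path, expr) {
    tryCatch({
      res <- expr()
      if (isTRUE(is.na(res))) add(kind, path, "skipped", "no such content")
      else add(kind, path, "written")
    }, error = function(e) add(kind, path, "error", conditionMessage(e)))
  }

  mains <- blocks_of_family(file, "MAIN")
  mains <- mains[order(vapply(mains, family_ordinal, integer(1), base = "MAIN"))]
  for (i in seq_along(mains)) {
    b <- mains[i]
    stem <- if (i == 1L) name else paste0(name, "_", tolower(b))
    path <- file.path(out_dir, paste0(stem, ".dat"))
    run("dat", path, function() {
      curve <- extract_curve(file, b)
      if (is.null(curve)) return(NA)
      write_dat(curve, path)
      TRUE
    })
    opath <- file.path(out_dir, paste0(stem, ".out"))
    run("out", opath, function() {
      if (!cif_has_category(file, b, "sas_p_of_r")) return(NA)
      write_out(cif2out(file, block = b), opath)
      TRUE
    })
  }
  tryCatch({
    texts <- cif2pdb(file, out_dir = out_dir, name = name)
    for (p in names(texts)) add("pdb", p, "written")
  }, error = function(e) add("pdb", out_dir, "error", conditionMessage(e)))
  tryCatch({
    texts <- cif2fit(file, out_dir = out_dir, name = name)
    for (p in names(texts)) add("fit", p, "written")
  }, error = function(e) add("fit", out_dir, "error", conditionMessage(e)))
  spath <- file.path(out_dir, paste0(name, "_metadata.txt"))
  run("sub", spath, function() {
    cif2sub(file, path = spath)
    TRUE
  })
  manifest <- dplyr::bind_rows(rows)
  manifest[manifest$status != "skipped", ]
}
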