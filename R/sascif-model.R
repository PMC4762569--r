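## The semantic view of a sasCIF entry: one measurement (curve, p(r),
## overall parameters, sample/buffer/instrument metadata, models and
## fits) spanning a MAIN block plus its MODEL and FIT blocks.

#' A semantic sasCIF entry
#'
#' Bundles everything describing one SAS measurement. Metadata groups are
#' named lists whose names are registry items of the corresponding
#' category (see [sascif_registry()]): `sample` -> `sas_sample`,
#' `buffer` -> `sas_buffer`, `beam` -> `sas_beam`, `detector` ->
#' `sas_detc`, `scan` -> `sas_scan`, `results` -> `sas_result`,
#' `citation` -> `citation`.
#'
#' @param curve a [saxs_curve()] (required).
#' @param distribution a [saxs_pofr()] or `NULL`.
#' @param results named list of overall parameters (Rg, I(0), Dmax,
#'   molecular-mass estimates, Porod volume); all must be non-negative
#'   and finite.
#' @param sample,buffer,beam,detector,scan,citation named lists of
#'   scalar metadata (see above), or `NULL`.
#' @param authors character vector of author names, in citation order.
#' @param struct_ref named list with external sequence-database reference
#'   items (`db_name`, `db_code`), or `NULL`.
#' @param models list of model/fit pairs, each `list(model = <saxs_model>,
#'   fit = <saxs_fit> or NULL)`.
#' @return a `sas_entry` object.
#' @export
sas_entry <- function(curve, distribution = NULL, results = NULL,
                      sample = NULL, buffer = NULL, beam = NULL,
                      detector = NULL, scan = NULL, models = list(),
                      citation = NULL, authors = NULL, struct_ref = NULL) {
  stopifnot(inherits(curve, "saxs_curve"))
  if (!is.null(distribution)) stopifnot(inherits(distribution, "saxs_pofr"))
  if (!is.null(results)) {
    vals <- suppressWarnings(as.numeric(unlist(results)))
    if (any(!is.finite(vals) | vals < 0)) {
      abort("overall parameters in `results` must be finite and non-negative")
    }
  }
  for (mf in models) {
    stopifnot(inherits(mf$model, "saxs_model"))
    if (!is.null(mf$fit)) stopifnot(inherits(mf$fit, "saxs_fit"))
  }
  structure(
    list(curve = curve, distribution = distribution, results = results,
         sample = sample, buffer = buffer, beam = beam, detector = detector,
         scan = scan, models = models, citation = citation,
         authors = authors, struct_ref = struct_ref),
    class = "sas_entry")
}

#' @export
print.sas_entry <- function(x, ...) {
  cat(sprintf("<sas_entry: %d-point curve%s, %d model(s), %d fit(s)>\n",
              nrow(x$curve),
              if (!is.null(x$distribution)) " + p(r)" else "",
              length(x$models),
              sum(vapply(x$models, function(m) !is.null(m$fit), logical(1)))))
  invisible(x)
}

entry_meta_categories <- c(sample = "sas_sample", buffer = "sas_buffer",
                           beam = "sas_beam", detector = "sas_detc",
                           scan = "sas_scan", results = "sas_result",
                           citation = "citation")

format_meta <- function(x) {
  vapply(x, function(v) {
    if (is.numeric(v)) fmt_num(v) else as.character(v)
  }, character(1))
}

#' Assemble sasCIF data blocks from semantic entries
#'
#' Each entry roots one MAIN-family data block holding the scan, the
#' intensity loop, sample/buffer/instrument metadata, overall parameters,
#' the p(r) categories, and citation/reference records as applicable. Each
#' model gets its own MODEL block (`sas_model` + `atom_site`), each fit its
#' own FIT block (`sas_model_fitting_details` + `sas_model_fitting`);
#' integer ids link FIT to MODEL. Blocks are labelled MAIN, MODEL, FIT for
#' the first of each family and MAIN2, MODEL2, FIT2, ... after that.
#'
#' @param entries a [sas_entry()] or a list of them (a concentration or
#'   contrast series maps to several MAIN-family blocks in one file).
#' @return a `cif_file`.
#' @seealso [sascif_split()] for the inverse.
#' @export
sascif_assemble <- function(entries) {
  if (inherits(entries, "sas_entry")) entries <- list(entries)
  file <- cif_new()
  model_counter <- 0L
  fit_counter <- 0L
  for (e in seq_along(entries)) {
    entry <- entries[[e]]
    main <- fam_label("MAIN", e)
    file <- put_curve(file, main, entry$curve)
    for (group in names(entry_meta_categories)) {
      vals <- entry[[group]]
      if (is.null(vals) || length(vals) == 0L) next
      cat_name <- entry_meta_categories[[group]]
      id_item <- if (cat_name == "citation") list(id = "primary") else list(id = "1")
      file <- merge_scalars(file, main, cat_name,
                            c(id_item, as.list(format_meta(vals))))
    }
    if (!is.null(entry$authors)) {
      file <- cif_set_category(file, main, "citation_author", list(
        citation_id = rep("primary", length(entry$authors)),
        name = entry$authors,
        ordinal = as.character(seq_along(entry$authors))), loop = TRUE)
    }
    if (!is.null(entry$struct_ref)) {
      file <- merge_scalars(file, main, "struct_ref",
                            c(list(id = "1"), as.list(format_meta(entry$struct_ref))))
    }
    if (!is.null(entry$distribution)) {
      file <- put_pofr(file, main, entry$distribution)
    }
    for (mf in entry$models) {
      model_counter <- model_counter + 1L
      file <- put_model(file, fam_label("MODEL", model_counter),
                        mf$model, id = model_counter)
      if (!is.null(mf$fit)) {
        fit_counter <- fit_counter + 1L
        file <- put_fit(file, fam_label("FIT", fit_counter), mf$fit,
                        id = fit_counter, model_id = model_counter)
      }
    }
  }
  file
}

#' Split a sasCIF file into semantic entries
#'
#' The inverse of [sascif_assemble()] up to numeric value formatting: each
#' MAIN-family block roots one entry; MODEL and FIT blocks are attached via
#' their integer id links. A fit whose `model_id` does not match any model
#' in the file is a dangling link and raises an error naming the offending
#' ids. In files holding several MAIN blocks (a measurement series) the
#' models and fits are attached to the first entry.
#'
#' @param file a `cif_file`.
#' @return a list of [sas_entry()] objects.
#' @export
sascif_split <- function(file) {
  mains <- blocks_of_family(file, "MAIN")
  if (length(mains) == 0L) abort("no MAIN-family data block found")
  mains <- mains[order(vapply(mains, family_ordinal, integer(1), base = "MAIN"))]

  models <- list()  # keyed by model id
  for (lab in blocks_of_family(file, "MODEL")) {
    id <- model_id_of_block(file, lab)
    if (is.na(id)) abort(sprintf("block '%s' has no sas_model.id", lab))
    models[[as.character(id)]] <- list(model = extract_model(file, lab), fit = NULL)
  }
  dangling <- character()
  for (lab in blocks_of_family(file, "FIT")) {
    fit <- extract_fit(file, lab)
    mid <- fit_model_id(fit)
    if (is.na(mid) || is.null(models[[as.character(mid)]])) {
      dangling <- c(dangling, sprintf("%s -> model id %s", lab,
                                      if (is.na(mid)) "?" else mid))
    } else {
      models[[as.character(mid)]]$fit <- fit
    }
  }
  if (length(dangling)) {
    abort(paste0("dangling fit link(s): ", paste(dangling, collapse = "; ")))
  }

  lapply(seq_along(mains), function(e) {
    main <- mains[[e]]
    curve <- extract_curve(file, main)
    if (is.null(curve)) {
      abort(sprintf("block '%s' holds no sas_scan_intensity loop", main))
    }
    meta <- lapply(entry_meta_categories, function(cat_name) {
      v <- scalar_values(file, main, cat_name)
      v <- v[names(v) != "id"]
      if (cat_name == "sas_scan") {
        # scan items reachable through the curve metadata are not repeated
        v <- v[!(names(v) %in% c("unit", "momentum_transfer_min",
                                 "momentum_transfer_max"))]
        v <- v[names(v) %in% registry_items("sas_scan")]
      }
      if (length(v) == 0L) NULL else as.list(v)
    })
    authors <- cif_get_column(file, main, "citation_author", "name")
    sref <- scalar_values(file, main, "struct_ref")
    sref <- sref[names(sref) != "id"]
    sas_entry(
      curve,
      distribution = extract_pofr(file, main),
      results = meta$results, sample = meta$sample, buffer = meta$buffer,
      beam = meta$beam, detector = meta$detector, scan = meta$scan,
      models = if (e == 1L) unname(models) else list(),
      citation = meta$citation, authors = authors,
      struct_ref = if (length(sref)) as.list(sref) else NULL)
  })
}

## ---- validation -----------------------------------------------------------

report_row <- function(severity, block, category, message) {
  tibble::tibble(severity = severity, block = block, category = category,
                 message = message)
}

#' Validate a sasCIF file against the category registry
#'
#' Checks performed per block: every category and item is defined in the
#' registry (unknown ones are warnings, so locally extended files stay
#' usable); required key items are present; enumerated domains (e.g. the
#' momentum-transfer unit) and numeric domains are respected; the
#' `sas_scan_intensity` momentum-transfer column is strictly increasing;
#' and parent-child id links (fit -> model, author -> citation,
#' reference -> entity) resolve. Category-per-block uniqueness is
#' enforced structurally by the parser and the in-memory model.
#'
#' Findings are report rows, never errors: an empty report means a valid
#' file.
#'
#' @param file a `cif_file`.
#' @return a tibble with columns `severity` (`"error"`/`"warning"`),
#'   `block`, `category`, `message`, of class `sascif_report`.
#' @export
sascif_validate <- function(file) {
  reg <- sascif_registry()
  rows <- list()
  note <- function(...) rows[[length(rows) + 1L]] <<- report_row(...)

  all_model_ids <- unlist(lapply(blocks_of_family(file, "MODEL"), function(l) {
    model_id_of_block(file, l)
  }))

  for (b in file$blocks) {
    for (cc in b$categories) {
      known <- cc$name %in% reg$category
      if (!known) {
        note("warning", b$name, cc$name, "category not defined in the registry")
        next
      }
      defs <- reg[reg$category == cc$name, ]
      unknown_items <- setdiff(cc$items, defs$item)
      for (it in unknown_items) {
        note("warning", b$name, cc$name,
             sprintf("item '%s' not defined in the registry (preserved verbatim)", it))
      }
      for (it in defs$item[defs$required]) {
        if (!(it %in% cc$items)) {
          note("error", b$name, cc$name, sprintf("required item '%s' missing", it))
        }
      }
      for (k in seq_along(cc$items)) {
        it <- cc$items[k]
        dom <- defs$domain[defs$item == it]
        if (length(dom) == 0L) next
        vals <- cc$columns[[k]][cc$kinds[[k]] == "t"]
        if (dom == "number") {
          bad <- suppressWarnings(is.na(as.numeric(vals)))
          if (any(bad)) {
            note("error", b$name, cc$name,
                 sprintf("item '%s' has %d non-numeric value(s), e.g. '%s'",
                         it, sum(bad), vals[bad][1]))
          }
        } else if (startsWith(dom, "enum:")) {
          allowed <- enum_values(dom)
          bad <- !(vals %in% allowed)
          if (any(bad)) {
            note("error", b$name, cc$name,
                 sprintf("item '%s' value '%s' not in {%s}", it, vals[bad][1],
                         paste(allowed, collapse = ", ")))
          }
        }
      }
      if (cc$name == "sas_scan_intensity") {
        k <- which(cc$items == "momentum_transfer")
        if (length(k)) {
          s <- suppressWarnings(as.numeric(cc$columns[[k]]))
          if (!any(is.na(s)) && length(s) > 1L && any(diff(s) <= 0)) {
            note("error", b$name, cc$name,
                 "momentum_transfer column is not strictly increasing")
          }
        }
      }
      if (cc$name == "sas_model_fitting_details") {
        k <- which(cc$items == "model_id")
        if (length(k) && cc$kinds[[k]][1] == "t") {
          mid <- suppressWarnings(as.integer(cc$columns[[k]][1]))
          if (!is.na(mid) && !(mid %in% all_model_ids)) {
            note("error", b$name, cc$name,
                 sprintf("model_id %d does not match any sas_model.id", mid))
          }
        }
      }
      if (cc$name == "citation_author") {
        k <- which(cc$items == "citation_id")
        cit <- cif_get_column(file, b$name, "citation", "id")
        if (length(k) && !is.null(cit)) {
          bad <- !(cc$columns[[k]] %in% cit)
          if (any(bad)) {
            note("error", b$name, cc$name,
                 sprintf("citation_id '%s' does not match any citation.id",
                         cc$columns[[k]][bad][1]))
          }
        }
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    report_row(character(), character(), character(), character())
  class(out) <- c("sascif_report", class(out))
  out
}

#' @export
print.sascif_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("<sascif_report: no findings (valid file)>\n")
    return(invisible(x))
  }
  cat(sprintf("<sascif_report: %d error(s), %d warning(s)>\n",
              sum(x$severity == "error"), sum(x$severity == "warning")))
  NextMethod()
}

#' @rdname sascif_validate
#' @param x a `sascif_report`.
#' @param ... unused.
#' @method glance sascif_report
#' @export
glance.sascif_report <- function(x, ...) {
  tibble::tibble(n_findings = nrow(x),
                 n_errors = sum(x$severity == "error"),
                 n_warnings = sum(x$severity == "warning"),
                 valid = !any(x$severity == "error"))
}
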