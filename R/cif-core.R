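#' @title Order-preserving CIF 1.1 model
#'
#' @description
#' A `cif_file` is an ordered list of data blocks; each block is an ordered
#' set of categories; each category holds one or more items with equal-length
#' value columns (length 1 for scalar categories). Order of blocks,
#' categories, items and rows is preserved through a parse/write cycle, so a
#' written file re-parses to a structurally identical model.
#'
#' Values are stored as character strings exactly as they appeared in the
#' source (the core never reformats numbers it did not create). Each value
#' also carries a kind: `"t"` ordinary text, `"m"` missing (serialized `?`),
#' `"i"` inapplicable (serialized `.`). A *text* value equal to `"?"` or
#' `"."` keeps kind `"t"` and is written quoted so it cannot be re-read as a
#' placeholder.
#'
#' @name cif-model
NULL

new_cif_category <- function(name, columns, kinds = NULL, loop = FALSE) {
  items <- names(columns)
  stopifnot(!is.null(items), !anyDuplicated(items))
  columns <- lapply(columns, as.character)
  if (is.null(kinds)) {
    kinds <- lapply(columns, function(v) ifelse(is.na(v), "m", "t"))
  }
  columns <- lapply(columns, function(v) ifelse(is.na(v), "?", v))
  lens <- lengths(columns)
  if (length(unique(lens)) > 1L) {
    abort(sprintf("ragged columns in category '%s': lengths %s",
                  name, paste(lens, collapse = ", ")))
  }
  if (!loop && any(lens != 1L)) {
    abort(sprintf("scalar category '%s' must have columns of length 1", name))
  }
  structure(
    list(name = tolower(name), items = tolower(items),
         columns = unname(columns), kinds = unname(kinds), loop = loop),
    class = "cif_category"
  )
}

new_cif_block <- function(name, categories = list()) {
  structure(list(name = name, categories = categories), class = "cif_block")
}

#' Construct an empty CIF file model
#'
#' @param blocks list of data blocks (internal use); usually empty.
#' @return a `cif_file` object.
#' @export
cif_new <- function(blocks = list()) {
  structure(list(blocks = blocks), class = "cif_file")
}

#' @export
print.cif_file <- function(x, ...) {
  cat(sprintf("<cif_file: %d block(s)>\n", length(x$blocks)))
  for (b in x$blocks) {
    cats <- vapply(b$categories, function(cc) {
      n <- length(cc$columns[[1]])
      sprintf("%s%s", cc$name, if (cc$loop) sprintf("[%d]", n) else "")
    }, character(1))
    cat(sprintf("  data_%s: %s\n", b$name, paste(cats, collapse = ", ")))
  }
  invisible(x)
}

#' Names of the data blocks in a CIF file
#' @param file a `cif_file`.
#' @return character vector of block labels, in file order.
#' @export
cif_blocks <- function(file) {
  vapply(file$blocks, function(b) b$name, character(1))
}

## ---- tokenizer ------------------------------------------------------------

# Tokens are (text, quoted, line). Quoted covers '..', ".." and ;-blocks.
cif_tokenize <- function(lines) {
  toks <- vector("list", length(lines) * 2L)
  nt <- 0L
  push <- function(text, quoted, line) {
    nt <<- nt + 1L
    if (nt > length(toks)) length(toks) <<- 2L * nt
    toks[[nt]] <<- list(text = text, quoted = quoted, line = line)
  }
  in_semi <- FALSE
  semi_start <- 0L
  semi_buf <- character()

  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (in_semi) {
      if (startsWith(line, ";")) {
        push(paste(semi_buf, collapse = "\n"), TRUE, semi_start)
        in_semi <- FALSE
        rest <- sub("^;", "", line)
        if (grepl("[^ \t]", rest)) {
          abort(sprintf("line %d: text after closing semicolon", ln))
        }
      } else {
        semi_buf <- c(semi_buf, line)
      }
      next
    }
    if (startsWith(line, ";")) {
      in_semi <- TRUE
      semi_start <- ln
      first <- sub("^;", "", line)
      semi_buf <- if (nzchar(first)) first else character()
      next
    }
    # fast path: nothing that needs character-level care
    if (!grepl("['\"#]", line)) {
      for (tok in strsplit(trimws(line), "[ \t]+")[[1]]) {
        if (nzchar(tok)) push(tok, FALSE, ln)
      }
      next
    }
    chars <- strsplit(line, "", fixed = TRUE)[[1]]
    i <- 1L
    n <- length(chars)
    while (i <= n) {
      ch <- chars[i]
      if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
      if (ch == "#") break  # comment to end of line (we are at token start)
      if (ch %in% c("'", '"')) {
        q <- ch
        j <- i + 1L
        val <- character()
        closed <- FALSE
        while (j <= n) {
          if (chars[j] == q && (j == n || chars[j + 1L] %in% c(" ", "\t"))) {
            closed <- TRUE
            break
          }
          val <- c(val, chars[j])
          j <- j + 1L
        }
        if (!closed) abort(sprintf("line %d: unterminated quoted string", ln))
        push(paste(val, collapse = ""), TRUE, ln)
        i <- j + 1L
      } else {
        j <- i
        while (j <= n && !(chars[j] %in% c(" ", "\t"))) j <- j + 1L
        push(paste(chars[i:(j - 1L)], collapse = ""), FALSE, ln)
        i <- j
      }
    }
  }
  if (in_semi) {
    abort(sprintf("line %d: unterminated semicolon text block", semi_start))
  }
  toks[seq_len(nt)]
}

## ---- parser ---------------------------------------------------------------

#' Parse CIF text into an ordered in-memory model
#'
#' Implements the CIF 1.1 subset used by sasCIF data files: `data_` blocks,
#' `_category.keyword` items, `loop_` tables, single/double quoted strings,
#' semicolon-delimited multi-line text, `#` comments, and the `?` / `.`
#' placeholders for missing / inapplicable values. Save frames, nested loops
#' and CIF2 syntax are out of scope.
#'
#' @param text CIF content: a single string or a character vector of lines.
#' @return a `cif_file`.
#' @seealso [read_cif()] to parse from a path, [cif_write()] for the inverse.
#' @examples
#' f <- cif_parse("data_MAIN\n_sas_scan.title 'Lysozyme run'")
#' cif_get_column(f, "MAIN", "sas_scan", "title")
#' @export
cif_parse <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(text)
  }
  toks <- cif_tokenize(lines)
  file <- cif_new()
  blocks <- list()
  cur <- NULL  # current block under construction (list form)

  flush_block <- function() {
    if (!is.null(cur)) blocks[[length(blocks) + 1L]] <<- cur
    cur <<- NULL
  }
  is_directive <- function(tok) {
    !tok$quoted && grepl("^(data_|loop_$|save_|stop_$|global_$)",
                         tolower(tok$text))
  }
  tok_kind <- function(tok) {
    if (tok$quoted) return("t")
    if (tok$text == "?") return("m")
    if (tok$text == ".") return("i")
    "t"
  }
  split_name <- function(tok) {
    nm <- tolower(sub("^_", "", tok$text))
    dot <- regexpr(".", nm, fixed = TRUE)
    if (dot < 1L) {
      abort(sprintf("line %d: item name '_%s' has no category.keyword period",
                    tok$line, nm))
    }
    c(substr(nm, 1L, dot - 1L), substr(nm, dot + 1L, nchar(nm)))
  }
  add_scalar <- function(cat_name, item, value, kind, line) {
    cats <- cur$categories
    if (!is.null(cats[[cat_name]])) {
      cc <- cats[[cat_name]]
      if (cc$loop) {
        abort(sprintf("line %d: scalar item for loop category '%s'",
                      line, cat_name))
      }
      if (item %in% cc$items) {
        abort(sprintf("line %d: duplicate item '%s.%s'", line, cat_name, item))
      }
      cc$items <- c(cc$items, item)
      cc$columns <- c(cc$columns, list(value))
      cc$kinds <- c(cc$kinds, list(kind))
      cats[[cat_name]] <- cc
    } else {
      cats[[cat_name]] <- structure(
        list(name = cat_name, items = item, columns = list(value),
             kinds = list(kind), loop = FALSE),
        class = "cif_category")
    }
    cur$categories <<- cats
  }

  i <- 1L
  n <- length(toks)
  while (i <= n) {
    tok <- toks[[i]]
    low <- tolower(tok$text)
    if (!tok$quoted && startsWith(low, "data_")) {
      flush_block()
      cur <- new_cif_block(substring(tok$text, 6L))
      i <- i + 1L
    } else if (!tok$quoted && low == "loop_") {
      if (is.null(cur)) {
        abort(sprintf("line %d: loop_ before any data_ block", tok$line))
      }
      i <- i + 1L
      hdr <- list()
      while (i <= n && !toks[[i]]$quoted && startsWith(toks[[i]]$text, "_")) {
        hdr[[length(hdr) + 1L]] <- toks[[i]]
        i <- i + 1L
      }
      if (length(hdr) == 0L) {
        abort(sprintf("line %d: loop_ with no item names", tok$line))
      }
      names2 <- lapply(hdr, split_name)
      cat_name <- unique(vapply(names2, `[`, character(1), 1L))
      if (length(cat_name) > 1L) {
        abort(sprintf("line %d: loop mixes categories: %s",
                      tok$line, paste(cat_name, collapse = ", ")))
      }
      items <- vapply(names2, `[`, character(1), 2L)
      if (anyDuplicated(items)) {
        abort(sprintf("line %d: duplicate item in loop header", tok$line))
      }
      vals <- list()
      kinds <- character()
      while (i <= n && !is_directive(toks[[i]]) &&
             !(!toks[[i]]$quoted && startsWith(toks[[i]]$text, "_"))) {
        vals[[length(vals) + 1L]] <- toks[[i]]$text
        kinds <- c(kinds, tok_kind(toks[[i]]))
        i <- i + 1L
      }
      nv <- length(vals)
      if (nv == 0L || nv %% length(items) != 0L) {
        abort(sprintf(
          "line %d: loop for '%s' has %d value(s), not a multiple of %d item name(s)",
          tok$line, cat_name, nv, length(items)))
      }
      vmat <- matrix(unlist(vals), ncol = length(items), byrow = TRUE)
      kmat <- matrix(kinds, ncol = length(items), byrow = TRUE)
      if (!is.null(cur$categories[[cat_name]])) {
        abort(sprintf("line %d: category '%s' appears twice in block '%s'",
                      tok$line, cat_name, cur$name))
      }
      cur$categories[[cat_name]] <- structure(
        list(name = cat_name, items = items,
             columns = lapply(seq_along(items), function(k) vmat[, k]),
             kinds = lapply(seq_along(items), function(k) kmat[, k]),
             loop = TRUE),
        class = "cif_category")
    } else if (!tok$quoted && startsWith(tok$text, "_")) {
      if (is.null(cur)) {
        abort(sprintf("line %d: item before any data_ block", tok$line))
      }
      nm <- split_name(tok)
      if (i + 1L > n || is_directive(toks[[i + 1L]]) ||
          (!toks[[i + 1L]]$quoted && startsWith(toks[[i + 1L]]$text, "_"))) {
        abort(sprintf("line %d: item '_%s.%s' has no value",
                      tok$line, nm[1], nm[2]))
      }
      vtok <- toks[[i + 1L]]
      add_scalar(nm[1], nm[2], vtok$text, tok_kind(vtok), tok$line)
      i <- i + 2L
    } else {
      abort(sprintf("line %d: stray value '%s' outside any item or loop",
                    tok$line, tok$text))
    }
  }
  flush_block()
  file$blocks <- blocks
  file
}

#' Read a CIF file from disk
#' @param path path to a CIF text file.
#' @return a `cif_file`.
#' @export
read_cif <- function(path) {
  cif_parse(readLines(path, warn = FALSE))
}

## ---- writer ---------------------------------------------------------------

needs_quoting <- function(v) {
  first <- substr(v, 1L, 1L)
  v == "" | grepl("[ \t'\"]", v) | v %in% c("?", ".") |
    first %in% c("_", "#", "$", "[", "]", ";") |
    grepl("^(data_|save_)", v, ignore.case = TRUE) |
    tolower(v) %in% c("loop_", "stop_", "global_")
}

# Serialize one value given its kind; returns the token text. Values with
# newlines are handled by the caller (semicolon block).
cif_format_value <- function(v, kind) {
  if (kind == "m") return("?")
  if (kind == "i") return(".")
  if (!needs_quoting(v)) return(v)
  can_single <- !grepl("'($|[ \t])", v)
  can_double <- !grepl('"($|[ \t])', v)
  if (can_single) return(paste0("'", v, "'"))
  if (can_double) return(paste0('"', v, '"'))
  NA_character_  # caller must fall back to a semicolon block
}

cif_semicolon_block <- function(v) {
  parts <- strsplit(v, "\n", fixed = TRUE)[[1]]
  if (length(parts) == 0L) parts <- ""
  if (any(startsWith(parts, ";"))) {
    abort("value contains a line starting with ';': not representable in CIF 1.1")
  }
  paste0(";", paste(parts, collapse = "\n"), "\n;")
}

#' Serialize a CIF model to text
#'
#' Blocks, categories, items and rows are emitted in stored order. Values
#' containing whitespace or quotes are quoted; values containing newlines
#' use semicolon blocks with the semicolons at column 1. The output
#' re-parses to a model structurally equal to the input, and a second
#' write of the re-parsed model is byte-identical.
#'
#' @param file a `cif_file`.
#' @return a single string of CIF text (ends with a newline).
#' @seealso [write_cif()] to write to a path.
#' @export
cif_write <- function(file) {
  stopifnot(inherits(file, "cif_file"))
  out <- character()
  for (b in file$blocks) {
    out <- c(out, paste0("data_", b$name))
    for (cc in b$categories) {
      out <- c(out, "#")
      if (cc$loop) {
        out <- c(out, "loop_",
                 paste0("_", cc$name, ".", cc$items))
        nrow <- length(cc$columns[[1]])
        for (r in seq_len(nrow)) {
          row <- character()
          for (k in seq_along(cc$items)) {
            v <- cc$columns[[k]][r]
            kind <- cc$kinds[[k]][r]
            if (kind == "t" && grepl("\n", v, fixed = TRUE)) {
              if (length(row)) { out <- c(out, paste(row, collapse = " ")); row <- character() }
              out <- c(out, cif_semicolon_block(v))
            } else {
              tok <- cif_format_value(v, kind)
              if (is.na(tok)) {
                if (length(row)) { out <- c(out, paste(row, collapse = " ")); row <- character() }
                out <- c(out, cif_semicolon_block(v))
              } else {
                row <- c(row, tok)
              }
            }
          }
          if (length(row)) out <- c(out, paste(row, collapse = " "))
        }
      } else {
        tags <- paste0("_", cc$name, ".", cc$items)
        width <- max(nchar(tags))
        for (k in seq_along(cc$items)) {
          v <- cc$columns[[k]][1]
          kind <- cc$kinds[[k]][1]
          tag <- formatC(tags[k], width = -width)
          if (kind == "t" && grepl("\n", v, fixed = TRUE)) {
            out <- c(out, tag, cif_semicolon_block(v))
          } else {
            tok <- cif_format_value(v, kind)
            if (is.na(tok)) {
              out <- c(out, tag, cif_semicolon_block(v))
            } else {
              out <- c(out, paste(tag, tok))
            }
          }
        }
      }
    }
    out <- c(out, "#")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Write a CIF model to disk
#' @param file a `cif_file`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cif <- function(file, path) {
  writeLines(sub("\n$", "", cif_write(file)), path)
  invisible(path)
}

## ---- accessors ------------------------------------------------------------

find_block <- function(file, block_label) {
  labs <- tolower(cif_blocks(file))
  idx <- which(labs == tolower(block_label))
  if (length(idx) == 0L) return(NA_integer_)
  idx[1]
}

#' Look up a value column
#'
#' Lookup is case-insensitive on block, category and item names. Absence
#' (of the block, the category, or the item) is not an error: the function
#' returns `NULL`, which is distinguishable from a present column of any
#' length.
#'
#' @param file a `cif_file`.
#' @param block_label data block label.
#' @param category,item lowercase (or any-case) category and keyword name.
#' @param what `"values"` (default) returns the column as character with
#'   `NA` where the stored value is a `?`/`.` placeholder; `"kinds"` returns
#'   the per-value kind codes (`"t"`, `"m"`, `"i"`); `"raw"` returns the
#'   stored text with placeholders as literal `?`/`.`.
#' @return character vector, or `NULL` when absent.
#' @export
cif_get_column <- function(file, block_label, category, item,
                           what = c("values", "kinds", "raw")) {
  what <- match.arg(what)
  bi <- find_block(file, block_label)
  if (is.na(bi)) return(NULL)
  cats <- file$blocks[[bi]]$categories
  ci <- which(names(cats) == tolower(category))
  if (length(ci) == 0L) return(NULL)
  cc <- cats[[ci[1]]]
  k <- which(cc$items == tolower(item))
  if (length(k) == 0L) return(NULL)
  vals <- cc$columns[[k]]
  kinds <- cc$kinds[[k]]
  switch(what,
         values = ifelse(kinds == "t", vals, NA_character_),
         kinds = kinds,
         raw = ifelse(kinds == "m", "?", ifelse(kinds == "i", ".", vals)))
}

#' Does a block contain a category?
#' @inheritParams cif_get_column
#' @return logical.
#' @export
cif_has_category <- function(file, block_label, category) {
  bi <- find_block(file, block_label)
  if (is.na(bi)) return(FALSE)
  tolower(category) %in% names(file$blocks[[bi]]$categories)
}

#' Category names present in a block
#' @inheritParams cif_get_column
#' @return character vector (empty when the block is absent).
#' @export
cif_categories <- function(file, block_label) {
  bi <- find_block(file, block_label)
  if (is.na(bi)) return(character())
  names(file$blocks[[bi]]$categories)
}

#' Set (replace or append) a category in a block
#'
#' The category is replaced in place if it already exists in the block
#' (a category can be present in a data block only once), otherwise
#' appended at the end of the block. A missing block is appended at the
#' end of the file.
#'
#' @param file a `cif_file`.
#' @param block_label target block label (created if absent).
#' @param category category name.
#' @param items named list of equal-length character vectors, one per
#'   keyword, in emission order. `NA` values become `?` placeholders.
#' @param loop `TRUE` for a loop table; default `NULL` infers a loop when
#'   any column has length > 1.
#' @param kinds optional named/ordered list of kind vectors parallel to
#'   `items` (internal use).
#' @return the updated `cif_file`.
#' @export
cif_set_category <- function(file, block_label, category, items,
                             loop = NULL, kinds = NULL) {
  stopifnot(inherits(file, "cif_file"), length(items) > 0L)
  lens <- lengths(items)
  if (length(unique(lens)) > 1L) {
    abort(sprintf("ragged columns for category '%s': lengths %s",
                  category, paste(lens, collapse = ", ")))
  }
  if (is.null(loop)) loop <- any(lens > 1L)
  cc <- new_cif_category(category, items, kinds = kinds, loop = loop)
  bi <- find_block(file, block_label)
  if (is.na(bi)) {
    file$blocks[[length(file$blocks) + 1L]] <- new_cif_block(block_label)
    bi <- length(file$blocks)
  }
  file$blocks[[bi]]$categories[[cc$name]] <- cc
  file
}

#' Remove a category from a block (no-op when absent)
#' @inheritParams cif_get_column
#' @return the updated `cif_file`.
#' @export
cif_drop_category <- function(file, block_label, category) {
  bi <- find_block(file, block_label)
  if (is.na(bi)) return(file)
  file$blocks[[bi]]$categories[[tolower(category)]] <- NULL
  file
}

#' View a category as a tibble
#'
#' Columns are character; placeholder values come through as `NA`.
#'
#' @inheritParams cif_get_column
#' @return a tibble with one column per item, or `NULL` when absent.
#' @export
cif_category_tibble <- function(file, block_label, category) {
  bi <- find_block(file, block_label)
  if (is.na(bi)) return(NULL)
  cc <- file$blocks[[bi]]$categories[[tolower(category)]]
  if (is.null(cc)) return(NULL)
  cols <- lapply(seq_along(cc$items), function(k) {
    ifelse(cc$kinds[[k]] == "t", cc$columns[[k]], NA_character_)
  })
  names(cols) <- cc$items
  tibble::as_tibble(cols)
}
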