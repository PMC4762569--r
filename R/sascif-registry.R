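## The sasCIF category/item registry: which categories exist, which items
## they hold, value domains (free text, number, enumerated), key items and
## parent-child links. Shipped as a plain-text asset so the vocabulary can
## evolve without code changes; items whose canonical dictionary names are
## not printed anywhere authoritative are flagged origin = "local".

.sascifr_env <- new.env(parent = emptyenv())

registry_path <- function() {
  p <- system.file("extdata", "sascif_categories.tsv", package = "sascifr")
  if (nzchar(p)) return(p)
  # fallback for a sourced (not installed) tree
  "inst/extdata/sascif_categories.tsv"
}

#' The sasCIF category registry
#'
#' One row per defined item: `category`, `item`, `required` (0/1), `domain`
#' (`text`, `number`, or `enum:<a>|<b>|...`), `key` (0/1), `parent`
#' (`category.item` of the parent key, or empty) and `origin`
#' (`dictionary` for names following the published sasCIF/PDBx naming,
#' `local` for names chosen here where no public spelling is available).
#'
#' @return a tibble.
#' @export
sascif_registry <- function() {
  if (is.null(.sascifr_env$registry)) {
    df <- utils::read.delim(registry_path(), stringsAsFactors = FALSE,
                            colClasses = "character")
    df$required <- df$required == "1"
    df$key <- df$key == "1"
    .sascifr_env$registry <- tibble::as_tibble(df)
  }
  .sascifr_env$registry
}

registry_categories <- function() unique(sascif_registry()$category)

registry_items <- function(category) {
  r <- sascif_registry()
  r$item[r$category == category]
}

registry_domain <- function(category, item) {
  r <- sascif_registry()
  d <- r$domain[r$category == category & r$item == item]
  if (length(d) == 0L) NA_character_ else d[1]
}

enum_values <- function(domain) {
  strsplit(sub("^enum:", "", domain), "|", fixed = TRUE)[[1]]
}
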