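# On-disk formats. The drug table is a 3-column UTF-8 TSV
# (drug_id / smiles / indications, tags pipe-separated); the interaction file
# follows the public STITCH chemical_chemical.links.detailed dialect. Both are
# read line-wise so that malformed input can be rejected with a line number
# instead of being silently repaired.

read_tsv_lines <- function(path) {
  con <- gzfile(path, open = "rt", encoding = "UTF-8")  # transparent for plain files
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Read a drug table
#'
#' Reads the canonical drug-table TSV: header `drug_id`, `smiles`,
#' `indications`, with indication tags pipe-separated. An empty `smiles`
#' field is stored as `NA` (the drug is unusable for structural similarity
#' but keeps its labels).
#'
#' @param path Path to a TSV file (gzip-transparent).
#' @param catalog Optional [indication_catalog()]. When supplied, a tag
#'   outside the catalog is an error; when `NULL` the catalog is induced from
#'   observed tags in first-seen order.
#' @return A [drug_dataset()].
#' @export
read_drug_table <- function(path, catalog = NULL) {
  lines <- read_tsv_lines(path)
  if (!length(lines)) stop("empty drug table: ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  expected <- c("drug_id", "smiles", "indications")
  if (!identical(header, expected)) {
    stop("drug table header must be 'drug_id\\tsmiles\\tindications', got: ",
         lines[[1]])
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  # strsplit drops a trailing empty field; restore it so that "id\tsmiles\t"
  # is a present-but-empty indications field, not a short row
  trailing <- endsWith(body, "\t") & lengths(fields) == 2L
  fields[trailing] <- lapply(fields[trailing], c, "")
  nf <- lengths(fields)
  bad <- which(nf != 3L)
  if (length(bad)) {
    stop("malformed drug table row at line ", bad[[1]] + 1L,
         " (expected 3 tab-separated fields): ", body[[bad[[1]]]])
  }
  drug_id <- vapply(fields, `[[`, "", 1L)
  smiles <- vapply(fields, `[[`, "", 2L)
  smiles[!nzchar(smiles) | smiles == "NA"] <- NA_character_
  tags <- strsplit(vapply(fields, `[[`, "", 3L), "|", fixed = TRUE)
  empty <- which(lengths(tags) == 0L | vapply(tags, function(x) all(!nzchar(x)), NA))
  if (length(empty)) {
    stop("drug with zero indication tags at line ", empty[[1]] + 1L, ": ",
         drug_id[[empty[[1]]]])
  }
  if (anyDuplicated(drug_id)) {
    stop("duplicate drug_id in ", path, ": ",
         paste(unique(drug_id[duplicated(drug_id)]), collapse = ", "))
  }
  drug_dataset(drug_id, smiles, tags, catalog = catalog)
}

#' Write a drug table
#'
#' Inverse of [read_drug_table()]: writes the canonical TSV so that
#' `read_drug_table(write_drug_table(ds, f))` reproduces the drugs, labels
#' and catalog tag order (catalog display names live in a separate catalog
#' file, see [write_catalog()]).
#'
#' @param dataset A [drug_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_drug_table <- function(dataset, path) {
  smiles <- dataset$drugs$smiles
  smiles[is.na(smiles)] <- ""
  lines <- c("drug_id\tsmiles\tindications",
             paste(dataset$drugs$drug_id, smiles,
                   vapply(dataset$labels, paste, "", collapse = "|"),
                   sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write / read an indication catalog
#'
#' Two-column TSV `tag` / `name`, preserving catalog order.
#'
#' @param catalog An [indication_catalog()].
#' @param path File path.
#' @return `write_catalog`: `path`, invisibly. `read_catalog`: an
#'   [indication_catalog()].
#' @export
write_catalog <- function(catalog, path) {
  writeLines(c("tag\tname", paste(catalog$tag, catalog$name, sep = "\t")),
             path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  lines <- read_tsv_lines(path)
  if (!length(lines) || lines[[1]] != "tag\tname") {
    stop("catalog header must be 'tag\\tname'")
  }
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  indication_catalog(vapply(fields, `[[`, "", 1L),
                     vapply(fields, `[[`, "", 2L))
}

#' Normalize PubChem CID identifiers
#'
#' Collapses zero-padded STITCH-style identifiers (`CID000005426`,
#' `CIDs00005426`, `CIDm00005426`) onto the compact `CID5426` form. This is
#' deliberately NOT applied automatically by any reader: silent identifier
#' coercion hides join bugs, so callers opt in explicitly (e.g. via the
#' `normalizer` argument of [read_stitch_links()]).
#'
#' @param ids Character vector of identifiers. Identifiers that do not match
#'   the CID pattern are returned unchanged.
#' @return Character vector of normalized identifiers.
#' @export
normalize_cid <- function(ids) {
  sub("^CID[sm]?0*([0-9])", "CID\\1", as.character(ids))
}

#' Read a STITCH-dialect interaction file
#'
#' Parses the `chemical_chemical.links.detailed` TSV dialect: two identifier
#' columns followed by score columns including `combined_score`
#' (gzip-transparent). Rows with raw score 0 are dropped — an unreported
#' interaction has confidence zero — as are self pairs. A pair listed twice
#' keeps the later row (with a warning), since STITCH dumps occasionally
#' repeat pairs in both orders.
#'
#' @param path Path to the TSV (optionally .gz).
#' @param id_filter Optional character vector: keep only rows whose both
#'   identifiers are in this set (applied after `normalizer`).
#' @param score_column Name of the score column to use (default
#'   `"combined_score"`).
#' @param scale Positive divisor applied to raw scores; STITCH publishes
#'   integers on a 0–1000 scale, so the default 1000 maps them to (0, 1].
#'   Ranking is scale-invariant, so this only fixes reported magnitudes.
#' @param normalizer Optional function applied to both identifier columns
#'   (e.g. [normalize_cid()]); `NULL` (default) leaves identifiers untouched.
#' @return An [interaction_table()].
#' @export
read_stitch_links <- function(path, id_filter = NULL,
                              score_column = "combined_score",
                              scale = 1000, normalizer = NULL) {
  stopifnot(is.numeric(scale), scale > 0)
  lines <- read_tsv_lines(path)
  if (!length(lines)) stop("empty interaction file: ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 3L) {
    stop("interaction file needs two identifier columns plus score columns")
  }
  sc <- match(score_column, header)
  if (is.na(sc)) {
    stop("score column '", score_column, "' not found; columns are: ",
         paste(header, collapse = ", "))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (!length(body)) return(interaction_table())
  fields <- strsplit(body, "\t", fixed = TRUE)
  short <- which(lengths(fields) < sc)
  if (length(short)) {
    stop("malformed interaction row at line ", short[[1]] + 1L, ": ",
         body[[short[[1]]]])
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  raw <- vapply(fields, `[[`, "", sc)
  score <- suppressWarnings(as.numeric(raw))
  nonnum <- which(is.na(score))
  if (length(nonnum)) {
    stop("non-numeric ", score_column, " at line ", nonnum[[1]] + 1L, ": '",
         raw[[nonnum[[1]]]], "'")
  }
  if (!is.null(normalizer)) {
    a <- normalizer(a); b <- normalizer(b)
  }
  keep <- score > 0 & a != b
  if (!is.null(id_filter)) keep <- keep & a %in% id_filter & b %in% id_filter
  interaction_table(a[keep], b[keep], score[keep] / scale)
}

#' Write ranked predictions
#'
#' One row per (drug, ranked indication): columns `drug_id`, `rank` (1-based
#' prediction order), `indication`, `score`. A drug whose ranking is empty
#' contributes no rows.
#'
#' @param predictions Named list mapping drug_id to [ranked_prediction()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  if (is.null(names(predictions)) && length(predictions)) {
    stop("'predictions' must be a named list keyed by drug_id")
  }
  rows <- character()
  for (id in names(predictions)) {
    rp <- predictions[[id]]
    if (!nrow(rp)) next
    rows <- c(rows, paste(id, seq_len(nrow(rp)), rp$tag,
                          format(rp$score, digits = 15, trim = TRUE,
                                 scientific = FALSE),
                          sep = "\t"))
  }
  writeLines(c("drug_id\trank\tindication\tscore", rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read ranked predictions
#'
#' Inverse of [write_predictions()]; ranks must be contiguous from 1 within
#' each drug.
#'
#' @param path Path written by [write_predictions()].
#' @return Named list mapping drug_id to [ranked_prediction()] (provenance is
#'   not stored on disk and is read back as `"file"`).
#' @export
read_predictions <- function(path) {
  lines <- read_tsv_lines(path)
  if (!length(lines) || lines[[1]] != "drug_id\trank\tindication\tscore") {
    stop("prediction file header must be 'drug_id\\trank\\tindication\\tscore'")
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  out <- list()
  if (!length(body)) return(out)
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 4L)
  if (length(bad)) stop("malformed prediction row at line ", bad[[1]] + 1L)
  df <- data.frame(drug_id = vapply(fields, `[[`, "", 1L),
                   rank = as.integer(vapply(fields, `[[`, "", 2L)),
                   tag = vapply(fields, `[[`, "", 3L),
                   score = as.numeric(vapply(fields, `[[`, "", 4L)),
                   stringsAsFactors = FALSE)
  for (id in unique(df$drug_id)) {
    sub <- df[df$drug_id == id, , drop = FALSE]
    sub <- sub[order(sub$rank), , drop = FALSE]
    if (!identical(sub$rank, seq_len(nrow(sub)))) {
      stop("non-contiguous ranks for drug ", id)
    }
    out[[id]] <- ranked_prediction(sub$tag, sub$score, provenance = "file")
  }
  out
}
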