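#' Indication catalog
#'
#' An ordered list of indication tags with human-readable names. The order is
#' fixed and is used throughout the package for deterministic tie-breaking
#' when two indications receive the same score.
#'
#' @param tags Character vector of unique indication tags (e.g. `"D_1"`).
#' @param names Character vector of human-readable names, recycled from
#'   `tags` when omitted (e.g. `"Antihypertensive"`).
#' @return An object of class `indication_catalog`: a data frame with columns
#'   `tag` and `name`, one row per indication, in fixed order.
#' @export
indication_catalog <- function(tags, names = tags) {
  tags <- as.character(tags)
  if (anyDuplicated(tags)) {
    stop("indication tags must be unique; duplicated: ",
         paste(unique(tags[duplicated(tags)]), collapse = ", "))
  }
  if (length(names) != length(tags)) stop("'names' must match 'tags' in length")
  out <- data.frame(tag = tags, name = as.character(names),
                    stringsAsFactors = FALSE)
  class(out) <- c("indication_catalog", "data.frame")
  out
}

#' @export
print.indication_catalog <- function(x, ...) {
  cat("<indication_catalog> ", nrow(x), " tags\n", sep = "")
  print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more\n")
  invisible(x)
}

#' Multi-label drug dataset
#'
#' Bundles drug records (identifier + SMILES + indication tag set), the
#' indication catalog and, optionally, an interaction table. A drug belongs to
#' category `S_i` iff it carries tag `D_i`; a drug with several tags is a
#' member of each of its categories.
#'
#' @param drug_id Character vector of unique drug identifiers.
#' @param smiles Character vector of SMILES strings (`NA` allowed: such drugs
#'   are unusable for structure-based similarity but still carry labels).
#' @param indications List of non-empty character vectors, one per drug.
#' @param catalog An [indication_catalog()]; induced from the observed tags in
#'   first-seen order when `NULL`.
#' @param interactions Optional [interaction_table()].
#' @return An object of class `drug_dataset`.
#' @export
drug_dataset <- function(drug_id, smiles, indications, catalog = NULL,
                         interactions = NULL) {
  drug_id <- as.character(drug_id)
  smiles <- as.character(smiles)
  if (length(smiles) != length(drug_id)) stop("'smiles' length mismatch")
  if (length(indications) != length(drug_id)) stop("'indications' length mismatch")
  if (anyDuplicated(drug_id)) {
    stop("duplicate drug_id: ",
         paste(unique(drug_id[duplicated(drug_id)]), collapse = ", "))
  }
  indications <- lapply(indications, function(x) unique(as.character(x)))
  nlab <- vapply(indications, length, 0L)
  if (any(nlab == 0L)) {
    stop("drugs with zero indication tags: ",
         paste(drug_id[nlab == 0L], collapse = ", "))
  }
  seen <- unique(unlist(indications, use.names = FALSE))
  if (is.null(catalog)) {
    catalog <- indication_catalog(seen)
  } else {
    if (!inherits(catalog, "indication_catalog")) catalog <- indication_catalog(catalog)
    unknown <- setdiff(seen, catalog$tag)
    if (length(unknown)) {
      stop("indication tags not in catalog: ", paste(unknown, collapse = ", "))
    }
  }
  names(indications) <- drug_id
  structure(list(drugs = data.frame(drug_id = drug_id, smiles = smiles,
                                    stringsAsFactors = FALSE),
                 labels = indications,
                 catalog = catalog,
                 interactions = interactions),
            class = "drug_dataset")
}

#' @export
print.drug_dataset <- function(x, ...) {
  cat("<drug_dataset> ", n_drugs(x), " drugs, ", nrow(x$catalog),
      " indication tags", sep = "")
  if (!is.null(x$interactions)) {
    cat(", ", nrow(interaction_pairs(x$interactions)), " interaction pairs", sep = "")
  }
  cat("\n")
  nlab <- vapply(x$labels, length, 0L)
  cat("labels per drug: ", paste(names(table(nlab)), table(nlab),
                                 sep = "x", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of drugs in a dataset
#' @param dataset A [drug_dataset()].
#' @return Integer count.
#' @export
n_drugs <- function(dataset) nrow(dataset$drugs)

#' Drug identifiers of a dataset
#' @param dataset A [drug_dataset()].
#' @return Character vector in dataset order.
#' @export
drug_ids <- function(dataset) dataset$drugs$drug_id

#' True label sets of a dataset
#' @param dataset A [drug_dataset()].
#' @return Named list mapping drug_id to its character vector of tags.
#' @export
truth_labels <- function(dataset) dataset$labels

#' Members of an indication category
#'
#' @param dataset A [drug_dataset()].
#' @param tag An indication tag present in the dataset's catalog.
#' @return Character vector of drug ids tagged with `tag` (category `S_i`).
#' @export
category_members <- function(dataset, tag) {
  if (!tag %in% dataset$catalog$tag) stop("unknown indication tag: ", tag)
  has <- vapply(dataset$labels, function(l) tag %in% l, NA)
  dataset$drugs$drug_id[has]
}

#' Per-category sizes
#' @param dataset A [drug_dataset()].
#' @return Named integer vector, one entry per catalog tag, in catalog order.
#' @export
category_sizes <- function(dataset) {
  tab <- table(factor(unlist(dataset$labels, use.names = FALSE),
                      levels = dataset$catalog$tag))
  out <- as.integer(tab)
  names(out) <- dataset$catalog$tag
  out
}

#' Restrict a dataset to a subset of drugs
#'
#' Keeps catalog and interaction table untouched; drugs are kept in their
#' original order.
#'
#' @param dataset A [drug_dataset()].
#' @param ids Drug identifiers to retain.
#' @return A `drug_dataset` with only the requested drugs.
#' @export
subset_drugs <- function(dataset, ids) {
  keep <- dataset$drugs$drug_id %in% ids
  drug_dataset(dataset$drugs$drug_id[keep], dataset$drugs$smiles[keep],
               dataset$labels[keep], catalog = dataset$catalog,
               interactions = dataset$interactions)
}
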