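curation_report <- function(removed_tags = character(),
                            removed_drugs = character(),
                            retained, sizes_before, sizes_after) {
  structure(list(removed_small_category_tags = removed_tags,
                 removed_duplicate_drug_ids = removed_drugs,
                 retained_count = retained,
                 sizes_before = sizes_before,
                 sizes_after = sizes_after),
            class = "curation_report")
}

#' @export
print.curation_report <- function(x, ...) {
  cat("<curation_report> retained ", x$retained_count, " drugs\n", sep = "")
  if (length(x$removed_small_category_tags)) {
    cat("removed small categories: ",
        paste(x$removed_small_category_tags, collapse = ", "), "\n", sep = "")
  }
  if (length(x$removed_duplicate_drug_ids)) {
    cat("removed near-duplicate drugs: ",
        length(x$removed_duplicate_drug_ids), "\n", sep = "")
  }
  invisible(x)
}

#' Drop statistically meaningless indication categories
#'
#' Removes every indication tag whose category holds fewer than `min_size`
#' drugs (both from the catalog and from each drug's label set), then drops
#' drugs left with no label at all, iterating to a fixed point. Removing a
#' tag can only shrink drugs' label sets, never another category, so the
#' iteration converges immediately; it is kept as a loop for safety.
#'
#' @param dataset A [drug_dataset()].
#' @param min_size Minimum category size to retain (default 8).
#' @return A list with elements `dataset` (filtered) and `report`
#'   (a `curation_report`).
#' @export
filter_small_categories <- function(dataset, min_size = 8L) {
  min_size <- as.integer(min_size)
  stopifnot(min_size >= 1L)
  before <- category_sizes(dataset)
  removed_tags <- character()
  repeat {
    sizes <- category_sizes(dataset)
    small <- names(sizes)[sizes < min_size]
    if (!length(small)) break
    removed_tags <- c(removed_tags, small)
    keep_tags <- setdiff(dataset$catalog$tag, small)
    catalog <- indication_catalog(
      keep_tags, dataset$catalog$name[match(keep_tags, dataset$catalog$tag)])
    labels <- lapply(dataset$labels, setdiff, y = small)
    keep <- lengths(labels) > 0L
    dataset <- drug_dataset(dataset$drugs$drug_id[keep],
                            dataset$drugs$smiles[keep],
                            labels[keep], catalog = catalog,
                            interactions = dataset$interactions)
  }
  list(dataset = dataset,
       report = curation_report(removed_tags = removed_tags,
                                retained = n_drugs(dataset),
                                sizes_before = before,
                                sizes_after = category_sizes(dataset)))
}

#' Remove near-duplicate structures via a maximal independent set
#'
#' Builds the similarity graph whose vertices are drugs and whose edges join
#' pairs with Tanimoto similarity `>= threshold`, then retains a maximal
#' independent set of it: after deduplication no retained pair is
#' near-duplicate, and every removed drug has at least one retained neighbor
#' at or above the threshold (maximality). The set is found greedily by
#' ascending degree in the shrinking graph, ties broken by dataset order —
#' deterministic, and biased toward retaining many drugs. Any maximal set
#' satisfies the curation goal; maximum cardinality is not sought.
#'
#' @param dataset A [drug_dataset()].
#' @param similarity A [similarity_provider()] covering the dataset's drugs.
#' @param threshold Edge threshold on Tanimoto similarity (default 0.7; the
#'   comparison is `>=`).
#' @param seed Reserved for a future randomized variant; the default greedy
#'   algorithm is deterministic and ignores it.
#' @return A list with elements `dataset` (deduplicated) and `report`.
#' @export
dedup_max_independent_set <- function(dataset, similarity, threshold = 0.7,
                                      seed = NULL) {
  ids <- drug_ids(dataset)
  n <- length(ids)
  sim <- outer(ids, ids, function(a, b) similarity(similarity, a, b))
  adj <- sim >= threshold
  diag(adj) <- FALSE
  alive <- rep(TRUE, n)
  retained <- logical(n)
  while (any(alive)) {
    deg <- colSums(adj[alive, , drop = FALSE])
    deg[!alive] <- NA
    pick <- which.min(deg)  # ties -> earliest dataset position
    retained[[pick]] <- TRUE
    drop <- alive & (adj[pick, ] | seq_len(n) == pick)
    alive[drop] <- FALSE
  }
  removed <- ids[!retained]
  out <- subset_drugs(dataset, ids[retained])
  list(dataset = out,
       report = curation_report(removed_drugs = removed,
                                retained = sum(retained),
                                sizes_before = category_sizes(dataset),
                                sizes_after = category_sizes(out)))
}

#' Full curation pipeline
#'
#' The dataset-construction order used throughout the package: first drop
#' small categories on the raw set, then remove near-duplicates at the
#' similarity threshold.
#'
#' @inheritParams filter_small_categories
#' @inheritParams dedup_max_independent_set
#' @return A list with `dataset`, `filter_report` and `dedup_report`.
#' @export
curate <- function(dataset, similarity, min_size = 8L, threshold = 0.7) {
  f <- filter_small_categories(dataset, min_size)
  d <- dedup_max_independent_set(f$dataset, similarity, threshold)
  list(dataset = d$dataset, filter_report = f$report, dedup_report = d$report)
}
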