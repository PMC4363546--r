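#' Ranked indication prediction
#'
#' A strictly ordered list of (indication tag, score) pairs: the tag in row 1
#' is the 1st order prediction, row 2 the 2nd order prediction, and so on.
#' Only strictly positive scores are kept, so the ranking may be empty (the
#' trivial outcome when the query has no interactive partner and no
#' structural neighbor).
#'
#' @param tags Character vector of unique indication tags.
#' @param scores Numeric vector of strictly positive, non-increasing scores.
#' @param provenance Which scoring path produced the ranking:
#'   `"interaction"`, `"similarity"`, `"integrated_score"` (or `"file"` /
#'   `"random"` for rankings not produced by a predictor).
#' @return A data frame of class `ranked_prediction` with columns `tag` and
#'   `score` and a `provenance` attribute.
#' @export
ranked_prediction <- function(tags = character(), scores = numeric(),
                              provenance = "interaction") {
  tags <- as.character(tags); scores <- as.numeric(scores)
  if (length(tags) != length(scores)) stop("'tags'/'scores' length mismatch")
  if (anyDuplicated(tags)) stop("ranked tags must be unique")
  if (any(scores <= 0)) stop("ranked scores must be strictly positive")
  if (is.unsorted(rev(scores))) stop("ranked scores must be non-increasing")
  out <- data.frame(tag = tags, score = scores, stringsAsFactors = FALSE)
  attr(out, "provenance") <- provenance
  class(out) <- c("ranked_prediction", "data.frame")
  out
}

#' Provenance of a ranked prediction
#' @param x A [ranked_prediction()].
#' @return Character scalar.
#' @export
provenance <- function(x) attr(x, "provenance")

#' @export
print.ranked_prediction <- function(x, ...) {
  cat("<ranked_prediction> [", provenance(x), "] ", nrow(x), " indications\n",
      sep = "")
  if (nrow(x)) print.data.frame(x)
  invisible(x)
}

#' Predictor configuration
#'
#' Holds the neighborhood sizes of the two scoring paths and the fingerprint
#' used for the similarity fallback. The defaults are the operating point of
#' the method: `k = 5` top interactions, `k = 2` top ECFP_4 similarities.
#'
#' @param k_interaction Positive integer: how many of the largest interaction
#'   confidence scores are summed per candidate indication.
#' @param k_similarity Positive integer: how many of the largest Tanimoto
#'   similarities are summed on the fallback path.
#' @param fingerprint A [fingerprint_spec()] for the similarity path.
#' @return An object of class `predictor_config`.
#' @export
predictor_config <- function(k_interaction = 5L, k_similarity = 2L,
                             fingerprint = fingerprint_spec("ECFP", 4)) {
  k_interaction <- as.integer(k_interaction)
  k_similarity <- as.integer(k_similarity)
  if (k_interaction < 1L || k_similarity < 1L) stop("k must be >= 1")
  stopifnot(inherits(fingerprint, "fingerprint_spec"))
  structure(list(k_interaction = k_interaction, k_similarity = k_similarity,
                 fingerprint = fingerprint),
            class = "predictor_config")
}

#' Pairwise weight functions
#'
#' Adapters turning an [interaction_table()] or a [similarity_provider()]
#' into the `weight(query, ids)` function consumed by [score_by_weights()]
#' and [rank_indications()].
#'
#' @param table An [interaction_table()].
#' @return A function `(query, ids) -> numeric` of pairwise weights.
#' @export
interaction_weight <- function(table) {
  force(table)
  function(query, ids) interaction_score(table, query, ids)
}

#' @rdname interaction_weight
#' @param provider A [similarity_provider()].
#' @export
similarity_weight <- function(provider) {
  force(provider)
  function(query, ids) similarity(provider, query, ids)
}

top_k_sum <- function(w, k) {
  w <- w[w > 0]
  if (!length(w)) return(0)
  sum(sort(w, decreasing = TRUE)[seq_len(min(k, length(w)))])
}

#' Top-k neighbor-weight score of one candidate indication
#'
#' The score that query drug `query` possesses indication `tag`: the sum of
#' the `k` largest pairwise weights between the query and the training drugs
#' carrying `tag` (all of them when fewer than `k` have positive weight).
#' With `k = 1` this is the single best neighbor's weight; with `k` equal to
#' the training-set size it is the full sum over the category.
#'
#' @param query Drug identifier of the query (must not be part of
#'   `training`; the query's own record never contributes a weight).
#' @param tag Candidate indication tag (must be in the training catalog).
#' @param training A [drug_dataset()] of training drugs.
#' @param weight A `function(query, ids) -> numeric` pairwise weight, e.g.
#'   [interaction_weight()] or [similarity_weight()].
#' @param k Positive integer neighborhood size.
#' @return Non-negative numeric score.
#' @export
score_by_weights <- function(query, tag, training, weight, k) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  members <- setdiff(category_members(training, tag), query)
  if (!length(members)) return(0)
  top_k_sum(weight(query, members), k)
}

rank_core <- function(query, members_by_tag, weight, k, tags) {
  scores <- vapply(tags, function(tg) {
    mem <- members_by_tag[[tg]]
    mem <- mem[mem != query]
    if (!length(mem)) return(0)
    top_k_sum(weight(query, mem), k)
  }, numeric(1))
  keep <- which(scores > 0)
  # sort by descending score; ties broken by catalog order (ascending index)
  keep <- keep[order(-scores[keep], keep)]
  list(tags = tags[keep], scores = unname(scores[keep]))
}

members_index <- function(training) {
  ids <- drug_ids(training)
  tags <- training$catalog$tag
  idx <- lapply(tags, function(tg) {
    ids[vapply(training$labels, function(l) tg %in% l, NA)]
  })
  names(idx) <- tags
  idx
}

#' Rank all candidate indications for a query drug
#'
#' Scores every catalog tag with [score_by_weights()], keeps strictly
#' positive scores, and sorts descending; equal scores are broken by catalog
#' order so that the ranking is deterministic. The result is empty iff every
#' tag scores 0 (the trivial outcome).
#'
#' @inheritParams score_by_weights
#' @param catalog Optional [indication_catalog()] (defaults to the training
#'   catalog).
#' @param provenance Provenance flag stored on the result.
#' @return A [ranked_prediction()].
#' @export
rank_indications <- function(query, training, weight, k, catalog = NULL,
                             provenance = "interaction") {
  if (is.null(catalog)) catalog <- training$catalog
  r <- rank_core(query, members_index(training), weight, as.integer(k),
                 catalog$tag)
  ranked_prediction(r$tags, r$scores, provenance = provenance)
}

#' Sequential integrated prediction
#'
#' The full method: rank by interaction confidence scores with
#' `k_interaction`; iff that ranking is empty (no interactive partner in the
#' training set), fall back to ranking by fingerprint similarity with
#' `k_similarity`. The provenance flag on the result records which path
#' fired.
#'
#' @param query Query drug identifier.
#' @param training A [drug_dataset()] (must not contain the query when
#'   evaluating).
#' @param interactions An [interaction_table()].
#' @param similarity A [similarity_provider()].
#' @param config A [predictor_config()].
#' @return A [ranked_prediction()] with provenance `"interaction"` or
#'   `"similarity"`.
#' @export
predict_integrated <- function(query, training, interactions, similarity,
                               config = predictor_config()) {
  idx <- members_index(training)
  tags <- training$catalog$tag
  ri <- rank_core(query, idx, interaction_weight(interactions),
                  config$k_interaction, tags)
  if (length(ri$tags)) {
    return(ranked_prediction(ri$tags, ri$scores, provenance = "interaction"))
  }
  rs <- rank_core(query, idx, similarity_weight(similarity),
                  config$k_similarity, tags)
  ranked_prediction(rs$tags, rs$scores, provenance = "similarity")
}

#' Averaged-score integrated prediction
#'
#' Instead of the sequential fallback, every indication is scored by the
#' arithmetic mean of its interaction-path score (with `k_interaction`) and
#' its similarity-path score (with `k_similarity`), then ranked. For a query
#' with no interaction partner this reproduces the similarity-only ranking
#' with all scores halved.
#'
#' @inheritParams predict_integrated
#' @return A [ranked_prediction()] with provenance `"integrated_score"`.
#' @export
predict_integrated_scores <- function(query, training, interactions,
                                      similarity,
                                      config = predictor_config()) {
  idx <- members_index(training)
  tags <- training$catalog$tag
  wi <- interaction_weight(interactions)
  ws <- similarity_weight(similarity)
  scores <- vapply(seq_along(tags), function(j) {
    mem <- idx[[j]]
    mem <- mem[mem != query]
    if (!length(mem)) return(0)
    (top_k_sum(wi(query, mem), config$k_interaction) +
       top_k_sum(ws(query, mem), config$k_similarity)) / 2
  }, numeric(1))
  keep <- which(scores > 0)
  keep <- keep[order(-scores[keep], keep)]
  ranked_prediction(tags[keep], unname(scores[keep]),
                    provenance = "integrated_score")
}
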