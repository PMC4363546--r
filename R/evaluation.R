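# Leave-one-out (jackknife) and repeated k-fold evaluation harnesses.
# Removing a drug from the training side automatically removes its
# interaction entries and similarity contributions: all scoring only ever
# consults pairs (query, training drug).

predict_one <- function(query, training, interactions, similarity, config,
                        mode) {
  switch(mode,
    sequential = predict_integrated(query, training, interactions, similarity,
                                    config),
    averaged = predict_integrated_scores(query, training, interactions,
                                         similarity, config),
    interaction = rank_indications(query, training,
                                   interaction_weight(interactions),
                                   config$k_interaction,
                                   provenance = "interaction"),
    similarity = rank_indications(query, training,
                                  similarity_weight(similarity),
                                  config$k_similarity,
                                  provenance = "similarity"),
    stop("unknown mode: ", mode))
}

eval_modes <- c("sequential", "averaged", "interaction", "similarity")

#' Aggregate ranked predictions into an evaluation report
#'
#' Computes the full metric set for one batch of predictions: `ACC_i` for
#' every order up to the number of catalog tags, recall/precision at the
#' canonical cutoff `t = ceiling(Average)`, per-category sensitivity of the
#' first two predictions, and the correlation between category size and
#' sensitivity (reported as `NA` when fewer than two categories vary).
#'
#' @param predictions Named list of [ranked_prediction()].
#' @param truth Named list of true tag sets.
#' @param catalog An [indication_catalog()].
#' @param sn_top Leading predictions scanned for per-category sensitivity.
#' @return A list of metrics (one evaluation repeat).
#' @export
evaluate_predictions <- function(predictions, truth, catalog, sn_top = 2L) {
  check_eval_input(predictions, truth)
  m <- nrow(catalog)
  acc <- vapply(seq_len(m), function(i) order_accuracy(predictions, truth, i),
                numeric(1))
  names(acc) <- paste0("ACC_", seq_len(m))
  al <- average_labels(truth)
  rp <- recall_precision_at_t(predictions, truth, al$t)
  sn <- per_category_sn(predictions, truth, catalog, top = sn_top)
  sizes <- vapply(names(sn), function(tg) {
    sum(vapply(truth, function(l) tg %in% l, NA))
  }, 0)
  r <- if (length(sn) >= 2L && stats::sd(sn) > 0 && stats::sd(sizes) > 0) {
    pearson_r(sizes, sn)
  } else {
    NA_real_
  }
  list(acc = acc, recall_t = rp$recall, precision_t = rp$precision,
       average_labels = al$average, t = al$t, per_category_sn = sn,
       size_sn_pearson_r = r, n_samples = length(truth))
}

new_evaluation_report <- function(repeats, scheme, mode, seed = NULL) {
  accs <- do.call(rbind, lapply(repeats, `[[`, "acc"))
  report <- list(
    scheme = scheme, mode = mode, seed = seed,
    n_repeats = length(repeats),
    acc = accs,
    acc_mean = colMeans(accs),
    acc_sd = apply(accs, 2L, stats::sd),  # sample (n-1) convention
    recall_t = vapply(repeats, `[[`, 0, "recall_t"),
    precision_t = vapply(repeats, `[[`, 0, "precision_t"),
    recall_t_mean = mean(vapply(repeats, `[[`, 0, "recall_t")),
    precision_t_mean = mean(vapply(repeats, `[[`, 0, "precision_t")),
    average_labels = repeats[[1L]]$average_labels,
    t = repeats[[1L]]$t,
    per_category_sn = lapply(repeats, `[[`, "per_category_sn"),
    size_sn_pearson_r = vapply(repeats, `[[`, 0, "size_sn_pearson_r"),
    n_samples = repeats[[1L]]$n_samples,
    per_repeat = repeats)
  class(report) <- "evaluation_report"
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", x$scheme, " / ", x$mode, ", ", x$n_samples,
      " drugs, ", x$n_repeats, " repeat(s)\n", sep = "")
  k <- min(5L, length(x$acc_mean))
  cat("ACC_1..", k, " (mean): ",
      paste(sprintf("%.4f", x$acc_mean[seq_len(k)]), collapse = " "),
      "\n", sep = "")
  cat(sprintf("Average = %.4f, t = %d, Recall_t = %.4f, Precision_t = %.4f\n",
              x$average_labels, x$t, x$recall_t_mean, x$precision_t_mean))
  invisible(x)
}

#' Jackknife (leave-one-out) evaluation
#'
#' Each drug in turn is predicted with itself removed from the training set;
#' both the training samples and the test sample are fixed, so the result is
#' fully deterministic.
#'
#' @param dataset A [drug_dataset()] with at least 2 drugs.
#' @param interactions An [interaction_table()].
#' @param similarity A [similarity_provider()].
#' @param config A [predictor_config()].
#' @param mode One of `"sequential"` (interaction path with similarity
#'   fallback), `"averaged"` (mean of the two path scores),
#'   `"interaction"`, `"similarity"`.
#' @return An `evaluation_report` with a single repeat.
#' @export
jackknife <- function(dataset, interactions, similarity,
                      config = predictor_config(), mode = "sequential") {
  mode <- match.arg(mode, eval_modes)
  if (n_drugs(dataset) < 2L) stop("need at least 2 drugs")
  ids <- drug_ids(dataset)
  predictions <- lapply(ids, function(id) {
    training <- subset_drugs(dataset, setdiff(ids, id))
    predict_one(id, training, interactions, similarity, config, mode)
  })
  names(predictions) <- ids
  rep1 <- evaluate_predictions(predictions, truth_labels(dataset),
                               dataset$catalog)
  out <- new_evaluation_report(list(rep1), "jackknife", mode)
  out$predictions <- predictions
  out
}

#' Repeated k-fold cross-validation
#'
#' Per repeat, the dataset is divided uniformly at random (unstratified)
#' into `folds` near-equal parts (sizes differ by at most 1); each part is
#' predicted with the remaining parts as training. Partitions are driven by
#' `(seed, repeat index)`, so a fixed seed reproduces the whole report.
#'
#' @inheritParams jackknife
#' @param folds Number of folds (>= 2; `folds = n` is the jackknife).
#' @param repeats How many independently re-partitioned repeats to run.
#' @param seed Integer seed for the partitions (required, logged on the
#'   report).
#' @return An `evaluation_report` with per-repeat metrics plus their mean
#'   and (sample) standard deviation.
#' @export
kfold <- function(dataset, interactions, similarity,
                  config = predictor_config(), mode = "sequential",
                  folds = 5L, repeats = 5L, seed) {
  mode <- match.arg(mode, eval_modes)
  folds <- as.integer(folds); repeats <- as.integer(repeats)
  n <- n_drugs(dataset)
  if (folds < 2L) stop("folds must be >= 2")
  if (n < folds) stop("dataset smaller than the number of folds")
  if (missing(seed)) stop("'seed' is required for reproducible partitions")
  ids <- drug_ids(dataset)
  truth <- truth_labels(dataset)
  reps <- lapply(seq_len(repeats), function(r) {
    # partition driven by (seed, repeat index)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed + r - 1L)
    shuffled <- sample(ids)
    fold_of <- rep(seq_len(folds), length.out = n)  # sizes differ by <= 1
    predictions <- vector("list", n)
    names(predictions) <- ids
    for (f in seq_len(folds)) {
      test_ids <- shuffled[fold_of == f]
      training <- subset_drugs(dataset, setdiff(ids, test_ids))
      for (id in test_ids) {
        predictions[[id]] <- predict_one(id, training, interactions,
                                         similarity, config, mode)
      }
    }
    evaluate_predictions(predictions, truth, dataset$catalog)
  })
  new_evaluation_report(reps, "kfold", mode, seed = seed)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Uniform random-ranking baseline predictions
#'
#' Replaces the predictor with a uniformly random permutation of all catalog
#' tags per drug (scores are the arbitrary strictly decreasing sequence
#' `m..1` scaled to (0, 1]; only the order matters). Used as the Monte-Carlo
#' null against which signal recovery is judged: its expected `ACC_1` is
#' `Average / m`.
#'
#' @param dataset A [drug_dataset()].
#' @param seed Integer seed.
#' @return Named list of [ranked_prediction()] with provenance `"random"`.
#' @export
random_ranking_predictions <- function(dataset, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tags <- dataset$catalog$tag
  m <- length(tags)
  out <- lapply(drug_ids(dataset), function(id) {
    ranked_prediction(sample(tags), seq(m, 1) / m, provenance = "random")
  })
  names(out) <- drug_ids(dataset)
  out
}
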