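# Order-accuracy metrics for multi-label ranked predictions. Throughout,
# `predictions` is a named list of ranked_prediction keyed by drug_id and
# `truth` a named list of character tag sets; every evaluated drug must have
# a non-empty truth set. Drugs whose ranking is shorter than the queried
# order stay in the denominator and contribute nothing to the numerator.

check_eval_input <- function(predictions, truth) {
  if (!length(truth)) stop("'truth' must be non-empty")
  if (any(lengths(truth) == 0L)) stop("every drug needs a non-empty truth set")
  missing <- setdiff(names(truth), names(predictions))
  if (length(missing)) {
    stop("no prediction for drug(s): ", paste(missing, collapse = ", "))
  }
}

#' i-th order prediction accuracy
#'
#' `ACC_i`: the fraction of evaluated drugs whose i-th ranked indication is
#' one of their true indications. The denominator is all drugs, including
#' those whose ranking has fewer than `i` entries (they count as incorrect).
#'
#' @param predictions Named list of [ranked_prediction()] keyed by drug_id.
#' @param truth Named list of true tag sets (non-empty for every drug).
#' @param i Prediction order, `>= 1`.
#' @return `ACC_i` in `[0, 1]`.
#' @export
order_accuracy <- function(predictions, truth, i = 1L) {
  i <- as.integer(i)
  if (i < 1L) stop("order must be >= 1")
  check_eval_input(predictions, truth)
  hit <- vapply(names(truth), function(id) {
    rp <- predictions[[id]]
    nrow(rp) >= i && rp$tag[[i]] %in% truth[[id]]
  }, NA)
  mean(hit)
}

#' Recall and precision of the first t order predictions
#'
#' Per-drug averages: `Recall_t = mean_j P_j^t / N^j` and
#' `Precision_t = mean_j P_j^t / t`, where `N^j` is the number of known
#' indications of drug j and `P_j^t` the number of correct indications among
#' its first `t` ranked predictions (rankings shorter than `t` contribute
#' only the ranks they have). `Precision_1` equals `ACC_1` identically.
#'
#' @inheritParams order_accuracy
#' @param t Cutoff order, `>= 1`; see [average_labels()] for the canonical
#'   choice `t = ceiling(Average)`.
#' @return Named list with elements `recall` and `precision`.
#' @export
recall_precision_at_t <- function(predictions, truth, t) {
  t <- as.integer(t)
  if (t < 1L) stop("t must be >= 1")
  check_eval_input(predictions, truth)
  p_t <- vapply(names(truth), function(id) {
    rp <- predictions[[id]]
    top <- rp$tag[seq_len(min(t, nrow(rp)))]
    sum(top %in% truth[[id]])
  }, 0)
  nj <- lengths(truth)
  list(recall = mean(p_t / nj), precision = mean(p_t / t))
}

#' Average label count and canonical cutoff t
#'
#' `Average` is the mean number of known indications per drug; the canonical
#' recall/precision cutoff is the smallest integer no less than it,
#' `t = ceiling(Average)`.
#'
#' @param truth Named list of true tag sets, or a numeric vector of per-drug
#'   label counts.
#' @return Named list with `average` and `t`.
#' @export
average_labels <- function(truth) {
  counts <- if (is.numeric(truth)) truth else lengths(truth)
  if (!length(counts)) stop("'truth' must be non-empty")
  if (any(counts < 1)) stop("every drug needs at least one label")
  avg <- sum(counts) / length(counts)
  list(average = avg, t = as.integer(ceiling(avg)))
}

#' Expected accuracy of uniform random ranking
#'
#' Under a uniformly random permutation of all `m` indication tags, the
#' probability that the 1st order prediction of a drug with `N^j` labels is
#' correct is `N^j / m`; averaging over drugs gives `Average / m`.
#'
#' @param average Mean label count (see [average_labels()]).
#' @param m Number of indication tags.
#' @return Expected `ACC_1` of the random-ranking baseline.
#' @export
random_guess_acc1 <- function(average, m) average / m

#' Per-category sensitivity of the first `top` predictions
#'
#' For category `S_i` (the `C^i` drugs truly tagged `D_i`),
#' `SN^i = TP^i / C^i` where `TP^i` counts members whose first `top` ranked
#' indications include `D_i`. Categories with no member in `truth` are
#' reported as absent.
#'
#' @inheritParams order_accuracy
#' @param catalog An [indication_catalog()] fixing which tags are reported.
#' @param top How many leading predictions to scan (default 2).
#' @return Named numeric vector of `SN^i`, one entry per catalog tag with at
#'   least one member.
#' @export
per_category_sn <- function(predictions, truth, catalog, top = 2L) {
  top <- as.integer(top)
  if (top < 1L) stop("top must be >= 1")
  check_eval_input(predictions, truth)
  retrieved <- lapply(names(truth), function(id) {
    rp <- predictions[[id]]
    rp$tag[seq_len(min(top, nrow(rp)))]
  })
  names(retrieved) <- names(truth)
  out <- vapply(catalog$tag, function(tg) {
    members <- names(truth)[vapply(truth, function(l) tg %in% l, NA)]
    if (!length(members)) return(NA_real_)
    mean(vapply(members, function(id) tg %in% retrieved[[id]], NA))
  }, numeric(1))
  out[!is.na(out)]
}

#' Pearson product-moment correlation
#'
#' Thin contract-checking wrapper around the standard product-moment
#' estimator: vectors must have equal length at least 2 and must not be
#' constant (a constant vector makes the denominator zero).
#'
#' @param x,y Equal-length numeric vectors.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 2L) stop("need at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  stats::cor(x, y)
}
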