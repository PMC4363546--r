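pair_key <- function(a, b) {
  # canonical unordered key; identifiers never contain "\t" in the supported
  # formats (tab is the field separator)
  ifelse(a < b, paste(a, b, sep = "\t"), paste(b, a, sep = "\t"))
}

#' Sparse symmetric chemical-chemical interaction table
#'
#' Stores confidence scores `w_i(a, b)` for unordered drug pairs. Only pairs
#' with strictly positive score are stored; looking up an absent pair returns
#' exactly 0, mirroring the convention that an interaction unreported in
#' STITCH has confidence zero.
#'
#' @param a,b Character vectors of drug identifiers (pair endpoints).
#' @param score Numeric vector of confidence scores in (0, 1]; rows with
#'   non-positive score are rejected (readers filter them out before
#'   construction).
#' @return An object of class `interaction_table`.
#' @seealso [read_stitch_links()], [interaction_score()]
#' @export
interaction_table <- function(a = character(), b = character(),
                              score = numeric()) {
  a <- as.character(a); b <- as.character(b); score <- as.numeric(score)
  if (length(a) != length(b) || length(a) != length(score)) {
    stop("'a', 'b' and 'score' must have equal length")
  }
  self <- a == b
  if (any(self)) {
    a <- a[!self]; b <- b[!self]; score <- score[!self]
  }
  if (any(!is.finite(score)) || any(score <= 0)) {
    stop("interaction scores must be finite and strictly positive")
  }
  key <- pair_key(a, b)
  if (anyDuplicated(key)) {
    warning("duplicate interaction pairs; keeping the last occurrence")
    last <- !duplicated(key, fromLast = TRUE)
    a <- a[last]; b <- b[last]; score <- score[last]; key <- key[last]
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  scores <- score
  names(scores) <- key
  structure(list(scores = scores,
                 pairs = data.frame(a = lo, b = hi, score = score,
                                    stringsAsFactors = FALSE)),
            class = "interaction_table")
}

#' @export
print.interaction_table <- function(x, ...) {
  cat("<interaction_table> ", length(x$scores), " pairs\n", sep = "")
  invisible(x)
}

#' Look up interaction confidence scores
#'
#' Total over all pairs: an absent pair (including any self pair) scores 0.
#' Symmetric: `interaction_score(t, a, b) == interaction_score(t, b, a)`.
#'
#' @param table An [interaction_table()].
#' @param a,b Character vectors of drug identifiers (recycled to a common
#'   length).
#' @return Numeric vector of confidence scores, 0 for unstored pairs.
#' @export
interaction_score <- function(table, a, b) {
  stopifnot(inherits(table, "interaction_table"))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n); b <- rep_len(as.character(b), n)
  idx <- match(pair_key(a, b), names(table$scores))
  out <- ifelse(is.na(idx), 0, unname(table$scores[idx]))
  out[a == b] <- 0
  out
}

#' Stored interaction pairs
#' @param table An [interaction_table()].
#' @return Data frame with columns `a`, `b` (with `a < b`) and `score`.
#' @export
interaction_pairs <- function(table) {
  stopifnot(inherits(table, "interaction_table"))
  table$pairs
}

#' Drug identifiers with at least one stored interaction
#' @param table An [interaction_table()].
#' @return Character vector of identifiers.
#' @export
interaction_partners <- function(table) {
  unique(c(table$pairs$a, table$pairs$b))
}
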