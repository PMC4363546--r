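#' Fingerprint specification
#'
#' Describes the 2D fingerprint family used for structural similarity.
#' Supported families:
#' \describe{
#'   \item{ECFP}{extended-connectivity circular fingerprint of diameter
#'     `diameter` (radius `diameter/2`), standard atom invariants.}
#'   \item{FCFP}{circular fingerprint of the same radius with
#'     functional-class atom invariants (donor/acceptor/ionizable/aromatic/
#'     halogen).}
#'   \item{MACCS}{the 166 structural keys; length fixed at 166.}
#'   \item{PATH}{hashed linear-path fingerprint up to 7 atoms (the Open Babel
#'     FP2 family), native length 1024.}
#' }
#'
#' @param family One of `"ECFP"`, `"FCFP"`, `"MACCS"`, `"PATH"`.
#' @param diameter Even integer in `{2, 4, 6}`; required for (and only
#'   meaningful for) ECFP/FCFP. `ECFP_4` means `diameter = 4`.
#' @param folded_length Bit count after folding. Defaults: 2048 for
#'   ECFP/FCFP, 1024 for PATH (its native size), 166 fixed for MACCS.
#' @return An object of class `fingerprint_spec`.
#' @export
fingerprint_spec <- function(family = c("ECFP", "FCFP", "MACCS", "PATH"),
                             diameter = NULL, folded_length = NULL) {
  family <- match.arg(family)
  circular <- family %in% c("ECFP", "FCFP")
  if (circular) {
    if (is.null(diameter)) diameter <- 4L
    if (!diameter %in% c(2L, 4L, 6L)) stop("diameter must be 2, 4 or 6")
    diameter <- as.integer(diameter)
  } else if (!is.null(diameter)) {
    stop("'diameter' applies only to ECFP/FCFP")
  }
  if (family == "MACCS") {
    if (!is.null(folded_length) && folded_length != 166L) {
      stop("MACCS length is fixed at 166")
    }
    folded_length <- 166L
  } else if (is.null(folded_length)) {
    folded_length <- if (circular) 2048L else 1024L
  }
  folded_length <- as.integer(folded_length)
  if (folded_length < 1L) stop("folded_length must be positive")
  structure(list(family = family, diameter = diameter,
                 folded_length = folded_length),
            class = "fingerprint_spec")
}

#' @export
print.fingerprint_spec <- function(x, ...) {
  cat("<fingerprint_spec> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.fingerprint_spec <- function(x, ...) {
  if (x$family %in% c("ECFP", "FCFP")) {
    paste0(x$family, "_", x$diameter, " (", x$folded_length, " bits)")
  } else {
    paste0(x$family, " (", x$folded_length, " bits)")
  }
}

#' Parse a fingerprint name such as "ECFP_4"
#'
#' Accepts `ECFP_2/4/6`, `FCFP_2/4/6`, `MACCS`, `PATH` and `FP2` (alias for
#' PATH).
#'
#' @param name Fingerprint name string.
#' @return A [fingerprint_spec()].
#' @export
parse_fingerprint_name <- function(name) {
  name <- toupper(name)
  if (name %in% c("PATH", "FP2")) return(fingerprint_spec("PATH"))
  if (name == "MACCS") return(fingerprint_spec("MACCS"))
  m <- regmatches(name, regexec("^(ECFP|FCFP)_([246])$", name))[[1]]
  if (!length(m)) stop("unrecognized fingerprint name: ", name)
  fingerprint_spec(m[[2]], as.integer(m[[3]]))
}

fold_bits <- function(v, n) {
  # OR-fold a raw bit vector down to n bits (standard modulo folding)
  if (length(v) <= n) return(as.numeric(v))
  idx <- ((seq_along(v) - 1L) %% n) + 1L
  as.numeric(rowsum(as.numeric(v), idx)[, 1L] > 0)
}

ob_fingerprint <- function(smiles, obname) {
  fp <- tryCatch(
    ChemmineOB::forEachMol("SMILES", smiles, function(mol) {
      ChemmineOB::fingerprint_OB(list(mol), obname)
    }),
    error = function(e) NULL)
  if (is.null(fp) || !length(fp)) {
    stop("unparseable SMILES: '", smiles, "'", call. = FALSE)
  }
  as.numeric(fp[[1]])
}

#' Compute a fingerprint bit vector
#'
#' Deterministic given `(smiles, spec)`: the same molecule written as a
#' different (but valid) SMILES yields the same bits.
#'
#' @param smiles A single SMILES string.
#' @param spec A [fingerprint_spec()].
#' @return Numeric 0/1 vector of length `spec$folded_length`.
#' @export
fingerprint <- function(smiles, spec = fingerprint_spec("ECFP", 4)) {
  stopifnot(inherits(spec, "fingerprint_spec"))
  if (length(smiles) != 1L || is.na(smiles) || !nzchar(smiles)) {
    stop("'smiles' must be a single non-empty string")
  }
  v <- switch(spec$family,
    ECFP = fold_bits(ob_fingerprint(smiles, paste0("ECFP", spec$diameter)),
                     spec$folded_length),
    FCFP = circular_fcfp(smiles, radius = spec$diameter / 2L,
                         nbits = spec$folded_length),
    MACCS = ob_fingerprint(smiles, "MACCS")[seq_len(166L)],
    PATH = fold_bits(ob_fingerprint(smiles, "FP2"), spec$folded_length))
  as.numeric(v)
}

#' Fingerprints for every drug in a dataset
#'
#' Drugs whose SMILES is missing or unparseable are skipped (recorded in the
#' `"skipped"` attribute) rather than aborting the whole set.
#'
#' @param dataset A [drug_dataset()].
#' @param spec A [fingerprint_spec()].
#' @return 0/1 matrix, one row per fingerprintable drug (rownames are drug
#'   ids), with attribute `skipped`: ids of drugs without a usable SMILES.
#' @export
fingerprints <- function(dataset, spec = fingerprint_spec("ECFP", 4)) {
  ids <- drug_ids(dataset)
  smiles <- dataset$drugs$smiles
  rows <- vector("list", length(ids))
  ok <- logical(length(ids))
  for (i in seq_along(ids)) {
    if (is.na(smiles[[i]]) || !nzchar(smiles[[i]])) next
    v <- tryCatch(fingerprint(smiles[[i]], spec), error = function(e) NULL)
    if (!is.null(v)) {
      rows[[i]] <- v
      ok[[i]] <- TRUE
    }
  }
  mat <- do.call(rbind, rows[ok])
  if (is.null(mat)) mat <- matrix(numeric(), 0L, spec$folded_length)
  rownames(mat) <- ids[ok]
  attr(mat, "skipped") <- ids[!ok]
  mat
}

#' Tanimoto similarity of two bit vectors
#'
#' `|a AND b| / |a OR b|`, defined as 0 when both vectors are all-zero.
#'
#' @param a,b Equal-length 0/1 (or logical) vectors.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    stop("fingerprint length mismatch: ", length(a), " vs ", length(b))
  }
  a <- as.logical(a); b <- as.logical(b)
  un <- sum(a | b)
  if (un == 0L) return(0)
  sum(a & b) / un
}

#' Pairwise Tanimoto similarity provider
#'
#' Precomputes the full symmetric Tanimoto matrix for a dataset under one
#' fingerprint spec. Drugs with no usable SMILES report similarity 0 to
#' everything (including themselves) and are listed in the provider's
#' skipped set.
#'
#' @param dataset A [drug_dataset()].
#' @param spec A [fingerprint_spec()].
#' @return A `similarity_provider`; query it with [similarity()].
#' @export
similarity_matrix <- function(dataset, spec = fingerprint_spec("ECFP", 4)) {
  fps <- fingerprints(dataset, spec)
  similarity_provider(tanimoto_matrix(fps), skipped = attr(fps, "skipped"))
}

#' Tanimoto matrix of a fingerprint matrix
#'
#' @param fps 0/1 matrix, one fingerprint per row (rownames = drug ids).
#' @return Symmetric similarity matrix with unit diagonal for non-empty
#'   fingerprints.
#' @export
tanimoto_matrix <- function(fps) {
  if (!nrow(fps)) {
    return(matrix(numeric(), 0L, 0L))
  }
  inter <- tcrossprod(fps)            # |a AND b| for 0/1 rows
  card <- rowSums(fps)
  un <- outer(card, card, "+") - inter
  sim <- ifelse(un > 0, inter / un, 0)
  dimnames(sim) <- list(rownames(fps), rownames(fps))
  sim
}

#' Construct a similarity provider from a precomputed matrix
#'
#' @param sim Symmetric numeric matrix in `[0, 1]` with drug-id dimnames.
#' @param skipped Ids of drugs excluded from `sim` (they report 0).
#' @return An object of class `similarity_provider`.
#' @export
similarity_provider <- function(sim, skipped = character()) {
  if (nrow(sim) != ncol(sim)) stop("'sim' must be square")
  if (nrow(sim) > 0) {
    if (is.null(rownames(sim))) stop("'sim' needs drug-id dimnames")
    if (any(sim < -1e-9 | sim > 1 + 1e-9)) stop("similarities must lie in [0, 1]")
    if (max(abs(sim - t(sim))) > 1e-9) stop("'sim' must be symmetric")
  }
  structure(list(sim = sim, skipped = as.character(skipped)),
            class = "similarity_provider")
}

#' @export
print.similarity_provider <- function(x, ...) {
  cat("<similarity_provider> ", nrow(x$sim), " drugs",
      if (length(x$skipped)) paste0(" (+", length(x$skipped), " skipped)"),
      "\n", sep = "")
  invisible(x)
}

#' Query pairwise similarities
#'
#' Total: ids outside the provider's support (including skipped drugs)
#' report 0; `similarity(p, a, a)` is 1 for supported drugs.
#'
#' @param provider A [similarity_provider()].
#' @param a,b Character vectors of drug ids (recycled to a common length).
#' @return Numeric vector of Tanimoto similarities.
#' @export
similarity <- function(provider, a, b) {
  stopifnot(inherits(provider, "similarity_provider"))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n); b <- rep_len(as.character(b), n)
  ia <- match(a, rownames(provider$sim))
  ib <- match(b, rownames(provider$sim))
  out <- numeric(n)
  ok <- !is.na(ia) & !is.na(ib)
  if (any(ok)) out[ok] <- provider$sim[cbind(ia[ok], ib[ok])]
  out
}

#' Write / read a cached pairwise-similarity table
#'
#' Upper-triangle TSV `drug_id_a` / `drug_id_b` / `similarity` (diagonal
#' implied 1, absent pairs implied 0), loadable in place of recomputation.
#'
#' @param provider A [similarity_provider()].
#' @param path File path.
#' @param ids For `read_similarity_table`: the full drug-id universe of the
#'   provider (ids never appearing in the file still get a row/column).
#' @return `write_similarity_table`: `path`, invisibly.
#'   `read_similarity_table`: a [similarity_provider()].
#' @export
write_similarity_table <- function(provider, path) {
  sim <- provider$sim
  ids <- rownames(sim)
  rows <- character()
  if (length(ids) > 1) {
    ut <- which(upper.tri(sim) & sim > 0, arr.ind = TRUE)
    rows <- paste(ids[ut[, 1L]], ids[ut[, 2L]],
                  format(sim[ut], digits = 15, trim = TRUE, scientific = FALSE),
                  sep = "\t")
  }
  writeLines(c("drug_id_a\tdrug_id_b\tsimilarity",
               paste0("# ids=", paste(ids, collapse = ",")),
               rows), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_similarity_table
#' @export
read_similarity_table <- function(path, ids = NULL) {
  lines <- read_tsv_lines(path)
  if (!length(lines) || lines[[1]] != "drug_id_a\tdrug_id_b\tsimilarity") {
    stop("similarity table header must be 'drug_id_a\\tdrug_id_b\\tsimilarity'")
  }
  body <- lines[-1]
  idline <- grep("^# ids=", body, value = TRUE)
  if (is.null(ids)) {
    if (!length(idline)) stop("no id universe: pass 'ids' or keep the '# ids=' line")
    ids <- strsplit(sub("^# ids=", "", idline[[1]]), ",", fixed = TRUE)[[1]]
  }
  body <- body[!startsWith(body, "#") & nzchar(body)]
  sim <- diag(length(ids))
  dimnames(sim) <- list(ids, ids)
  if (length(body)) {
    fields <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(fields) != 3L)
    if (length(bad)) stop("malformed similarity row at line ", bad[[1]] + 1L)
    a <- match(vapply(fields, `[[`, "", 1L), ids)
    b <- match(vapply(fields, `[[`, "", 2L), ids)
    if (anyNA(a) || anyNA(b)) stop("similarity row references unknown drug id")
    s <- as.numeric(vapply(fields, `[[`, "", 3L))
    sim[cbind(a, b)] <- s
    sim[cbind(b, a)] <- s
  }
  similarity_provider(sim)
}
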