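# In-code fixtures and independent brute-force oracles. The oracles share no
# code with the package internals they check: scoring enumerates and sorts by
# hand, accuracy counts hits with explicit loops.

make_toy_dataset <- function() {
  drug_dataset(
    drug_id = c("a", "b", "c", "d", "e"),
    smiles = rep(NA_character_, 5),
    indications = list("D_1", c("D_1", "D_2"), "D_2", "D_3", c("D_2", "D_3")),
    catalog = indication_catalog(c("D_1", "D_2", "D_3"))
  )
}

# random multi-label fixture with random interaction table and random
# similarity matrix; everything reproducible from `seed`
make_random_fixture <- function(seed, n_drugs = NULL, n_categories = NULL) {
  set.seed(seed)
  n <- if (is.null(n_drugs)) sample(5:30, 1) else n_drugs
  m <- if (is.null(n_categories)) sample(2:8, 1) else n_categories
  ids <- sprintf("q%02d", seq_len(n))
  tags <- paste0("D_", seq_len(m))
  labels <- lapply(seq_len(n), function(i) {
    sample(tags, min(m, sample(1:3, 1, prob = c(0.6, 0.3, 0.1))))
  })
  ds <- drug_dataset(ids, rep(NA_character_, n), labels,
                     catalog = indication_catalog(tags))
  # random sparse interactions
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  hit <- runif(nrow(pairs)) < 0.2
  itab <- interaction_table(ids[pairs[hit, 1]], ids[pairs[hit, 2]],
                            pmax(runif(sum(hit)), 1e-6))
  # random symmetric similarity matrix with unit diagonal; some zeros
  sim <- matrix(runif(n * n), n, n)
  sim[sim < 0.3] <- 0
  sim <- (sim + t(sim)) / 2
  diag(sim) <- 1
  dimnames(sim) <- list(ids, ids)
  list(dataset = ds, interactions = itab,
       similarity = similarity_provider(sim))
}

# ---- independent oracles -------------------------------------------------

oracle_topk_score <- function(query, tag, dataset, wfun, k) {
  members <- character()
  for (id in drug_ids(dataset)) {
    if (id != query && tag %in% truth_labels(dataset)[[id]]) {
      members <- c(members, id)
    }
  }
  if (!length(members)) return(0)
  w <- numeric(length(members))
  for (i in seq_along(members)) w[i] <- wfun(query, members[i])
  w <- w[w > 0]
  if (!length(w)) return(0)
  w <- sort(w, decreasing = TRUE)
  sum(w[seq_len(min(k, length(w)))])
}

oracle_rank <- function(query, dataset, wfun, k) {
  tags <- dataset$catalog$tag
  sc <- vapply(tags, function(tg) {
    oracle_topk_score(query, tg, dataset, wfun, k)
  }, numeric(1))
  ord <- order(-sc, seq_along(tags))
  ord <- ord[sc[ord] > 0]
  data.frame(tag = tags[ord], score = unname(sc[ord]),
             stringsAsFactors = FALSE)
}

oracle_sequential_predict <- function(query, dataset, itab, sprov, config) {
  wi <- function(a, b) interaction_score(itab, a, b)
  r <- oracle_rank(query, dataset, wi, config$k_interaction)
  if (nrow(r)) return(r)
  ws <- function(a, b) similarity(sprov, a, b)
  oracle_rank(query, dataset, ws, config$k_similarity)
}

# leave-one-out by explicit loops; returns per-order accuracies
oracle_jackknife_acc <- function(fixture, config, orders = 3) {
  ds <- fixture$dataset
  ids <- drug_ids(ds)
  hits <- matrix(FALSE, length(ids), orders)
  for (i in seq_along(ids)) {
    training <- subset_drugs(ds, ids[-i])
    r <- oracle_sequential_predict(ids[i], training, fixture$interactions,
                                   fixture$similarity, config)
    truth <- truth_labels(ds)[[ids[i]]]
    for (o in seq_len(orders)) {
      hits[i, o] <- nrow(r) >= o && r$tag[o] %in% truth
    }
  }
  colMeans(hits)
}

# exhaustive independent-set check on tiny graphs
assert_maximal_independent <- function(retained, ids, simfun, threshold) {
  for (i in seq_along(retained)) {
    for (j in seq_along(retained)) {
      if (i < j) {
        expect_lt(simfun(retained[i], retained[j]), threshold)
      }
    }
  }
  for (rm in setdiff(ids, retained)) {
    expect_true(any(vapply(retained, function(r) {
      simfun(rm, r) >= threshold
    }, NA)))
  }
}

rp_tags <- function(rp) rp$tag
rp_scores <- function(rp) rp$score

# plain data.frame view of a ranked prediction (drops class/provenance)
rp_df <- function(rp) {
  data.frame(tag = rp$tag, score = rp$score, stringsAsFactors = FALSE)
}
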