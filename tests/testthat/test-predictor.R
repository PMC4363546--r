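# training set where category D_1 holds drugs with interaction weights
# {0.9, 0.7, 0.2} to the query, used by the worked scoring examples
weights_fixture <- function() {
  ds <- drug_dataset(c("t1", "t2", "t3", "t4"), rep(NA_character_, 4),
                     list("D_1", "D_1", "D_1", "D_2"),
                     catalog = indication_catalog(c("D_1", "D_2")))
  itab <- interaction_table(rep("q", 3), c("t1", "t2", "t3"),
                            c(0.9, 0.7, 0.2))
  list(training = ds, weight = interaction_weight(itab))
}

test_that("top-k scoring sums the k largest weights", {
  fx <- weights_fixture()
  expect_equal(score_by_weights("q", "D_1", fx$training, fx$weight, k = 2), 1.6)
  # k = 1 reduces to the single best neighbor's weight
  expect_equal(score_by_weights("q", "D_1", fx$training, fx$weight, k = 1), 0.9)
  # k = n reduces to the full category sum
  expect_equal(score_by_weights("q", "D_1", fx$training, fx$weight,
                                k = n_drugs(fx$training)), 1.8)
  # no positive weight in the category
  expect_equal(score_by_weights("q", "D_2", fx$training, fx$weight, k = 2), 0)
  expect_error(score_by_weights("q", "D_9", fx$training, fx$weight, 2),
               "unknown indication")
  expect_error(score_by_weights("q", "D_1", fx$training, fx$weight, 0), ">= 1")
})

test_that("ranking keeps positive scores in descending order", {
  ds <- drug_dataset(c("t1", "t2", "t3"), rep(NA_character_, 3),
                     list(c("D_2", "D_6"), "D_2", "D_3"),
                     catalog = indication_catalog(c("D_2", "D_3", "D_6")))
  itab <- interaction_table(c("q", "q"), c("t1", "t2"), c(0.4, 1.5))
  rp <- rank_indications("q", ds, interaction_weight(itab), k = 5)
  expect_equal(rp_tags(rp), c("D_2", "D_6"))
  expect_equal(rp_scores(rp), c(1.9, 0.4))
  expect_equal(provenance(rp), "interaction")
})

test_that("all-zero scores give an empty ranking; ties follow catalog order", {
  ds <- make_toy_dataset()
  empty <- rank_indications("zz", ds, interaction_weight(interaction_table()),
                            k = 5)
  expect_equal(nrow(empty), 0)

  # equal score 0.5 on D_2 and D_3 (catalog order D_1 < D_2 < D_3)
  itab <- interaction_table(c("q", "q"), c("c", "d"), c(0.5, 0.5))
  rp <- rank_indications("q", ds, interaction_weight(itab), k = 1)
  expect_equal(rp_tags(rp), c("D_2", "D_3"))
})

test_that("query's own record never contributes to its scores", {
  ds <- make_toy_dataset()
  itab <- interaction_table(c("a", "a"), c("b", "c"), c(0.6, 0.2))
  # scoring drug "a" against a training set that still contains it
  s <- score_by_weights("a", "D_1", ds, interaction_weight(itab), k = 5)
  expect_equal(s, 0.6)  # only b; a itself (weight to a would be 0) excluded
  sim <- diag(3)
  dimnames(sim) <- list(c("a", "b", "c"), c("a", "b", "c"))
  prov <- similarity_provider(sim)
  expect_equal(score_by_weights("a", "D_1", ds, similarity_weight(prov), 5),
               0)  # self-similarity 1.0 must not leak in
})

test_that("sequential integration falls back only on the trivial outcome", {
  fx <- make_random_fixture(101, n_drugs = 12, n_categories = 4)
  ids <- drug_ids(fx$dataset)
  for (q in ids) {
    training <- subset_drugs(fx$dataset, setdiff(ids, q))
    rp <- predict_integrated(q, training, fx$interactions, fx$similarity)
    ri <- rank_indications(q, training, interaction_weight(fx$interactions),
                           5, provenance = "interaction")
    if (nrow(ri)) {
      expect_equal(provenance(rp), "interaction")
      expect_equal(rp_df(rp), rp_df(ri))
    } else {
      expect_equal(provenance(rp), "similarity")
      rs <- rank_indications(q, training, similarity_weight(fx$similarity),
                             2, provenance = "similarity")
      expect_equal(rp_df(rp), rp_df(rs))
    }
  }
})

test_that("with an empty interaction table the sequential predictor is the similarity predictor", {
  fx <- make_random_fixture(77, n_drugs = 15, n_categories = 5)
  none <- interaction_table()
  ids <- drug_ids(fx$dataset)
  for (q in ids[1:8]) {
    training <- subset_drugs(fx$dataset, setdiff(ids, q))
    rp <- predict_integrated(q, training, none, fx$similarity)
    rs <- rank_indications(q, training, similarity_weight(fx$similarity), 2,
                           provenance = "similarity")
    expect_equal(provenance(rp), "similarity")
    expect_equal(rp_df(rp), rp_df(rs))
  }
})

test_that("averaged scores are the mean of the two path scores", {
  ds <- drug_dataset(c("t1", "t2"), rep(NA_character_, 2),
                     list("D_3", "D_3"),
                     catalog = indication_catalog(c("D_1", "D_3")))
  itab <- interaction_table("q", "t1", 1.0)
  sim <- matrix(0, 3, 3, dimnames = list(c("q", "t1", "t2"),
                                         c("q", "t1", "t2")))
  diag(sim) <- 1
  sim["q", "t2"] <- sim["t2", "q"] <- 0.5
  prov <- similarity_provider(sim)
  rp <- predict_integrated_scores("q", ds, itab, prov,
                                  predictor_config(k_interaction = 5,
                                                   k_similarity = 1))
  expect_equal(provenance(rp), "integrated_score")
  expect_equal(rp_tags(rp), "D_3")
  expect_equal(rp_scores(rp), (1.0 + 0.5) / 2)  # = 0.75
})

test_that("averaged prediction on interaction-free queries halves the similarity ranking", {
  fx <- make_random_fixture(55, n_drugs = 14, n_categories = 4)
  none <- interaction_table()
  ids <- drug_ids(fx$dataset)
  for (q in ids[1:6]) {
    training <- subset_drugs(fx$dataset, setdiff(ids, q))
    ravg <- predict_integrated_scores(q, training, none, fx$similarity)
    rs <- rank_indications(q, training, similarity_weight(fx$similarity), 2)
    expect_equal(rp_tags(ravg), rp_tags(rs))
    expect_equal(rp_scores(ravg), rp_scores(rs) / 2)
  }
})

test_that("scores match the brute-force oracle on random fixtures", {
  for (seed in 1:10) {
    fx <- make_random_fixture(seed)
    ids <- drug_ids(fx$dataset)
    wfun_pkg <- interaction_weight(fx$interactions)
    wfun_ora <- function(a, b) interaction_score(fx$interactions, a, b)
    for (q in ids[1:min(5, length(ids))]) {
      training <- subset_drugs(fx$dataset, setdiff(ids, q))
      for (tg in fx$dataset$catalog$tag) {
        for (k in c(1L, 3L, n_drugs(training))) {
          expect_equal(score_by_weights(q, tg, training, wfun_pkg, k),
                       oracle_topk_score(q, tg, training, wfun_ora, k))
        }
      }
      rp <- rank_indications(q, training, wfun_pkg, 3)
      expect_equal(rp_df(rp), oracle_rank(q, training, wfun_ora, 3))
    }
  }
})

test_that("top-k scores are non-decreasing in k", {
  for (seed in 11:15) {
    fx <- make_random_fixture(seed)
    ids <- drug_ids(fx$dataset)
    q <- ids[[1]]
    training <- subset_drugs(fx$dataset, setdiff(ids, q))
    w <- similarity_weight(fx$similarity)
    for (tg in fx$dataset$catalog$tag) {
      sc <- vapply(1:6, function(k) {
        score_by_weights(q, tg, training, w, k)
      }, numeric(1))
      expect_false(is.unsorted(sc))
    }
  }
})

test_that("lowering a tag's score never improves its rank position", {
  ds <- make_toy_dataset()
  base <- interaction_table(c("q", "q", "q"), c("a", "c", "d"),
                            c(0.9, 0.6, 0.3))
  shrunk <- interaction_table(c("q", "q", "q"), c("a", "c", "d"),
                              c(0.9, 0.2, 0.3))  # D_2's weight drops
  pos <- function(tab, tg) {
    rp <- rank_indications("q", ds, interaction_weight(tab), 5)
    match(tg, rp_tags(rp))
  }
  expect_gte(pos(shrunk, "D_2"), pos(base, "D_2"))
})

test_that("ranked predictions enforce their invariants", {
  expect_error(ranked_prediction(c("D_1", "D_1"), c(1, 0.5)), "unique")
  expect_error(ranked_prediction("D_1", 0), "positive")
  expect_error(ranked_prediction(c("D_1", "D_2"), c(0.5, 1)),
               "non-increasing")
  expect_error(predictor_config(k_interaction = 0), ">= 1")
})
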