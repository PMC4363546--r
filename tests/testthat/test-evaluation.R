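rp <- function(tags, n = length(tags)) {
  ranked_prediction(tags, seq(n, 1) / n)
}

test_that("order accuracy counts i-th rank hits over all samples", {
  preds <- list(a = rp(c("D_1", "D_2")), b = rp("D_2"),
                c = rp(c("D_3", "D_1")), d = ranked_prediction())
  truth <- list(a = "D_1", b = "D_1", c = c("D_1", "D_3"), d = "D_2")
  # rank-1 correct for a and c only
  expect_equal(order_accuracy(preds, truth, 1), 0.5)
  # rank-2: a's D_2 wrong, c's D_1 right, b and d have no 2nd rank
  expect_equal(order_accuracy(preds, truth, 2), 0.25)
  # an empty ranking contributes 0 at every order but stays in N
  expect_equal(order_accuracy(preds["d"], truth["d"], 1), 0)
  expect_error(order_accuracy(preds, truth, 0), ">= 1")
})

test_that("perfect rank-1 predictions give ACC_1 = 1", {
  truth <- list(a = "D_1", b = c("D_2", "D_3"))
  preds <- list(a = rp("D_1"), b = rp(c("D_2", "D_1")))
  expect_equal(order_accuracy(preds, truth, 1), 1)
})

test_that("recall and precision follow the per-drug top-t averages", {
  # drug with truth {D_1, D_2} whose top-2 is (D_1, D_5): P = 1
  preds <- list(j = rp(c("D_1", "D_5")))
  truth <- list(j = c("D_1", "D_2"))
  rp2 <- recall_precision_at_t(preds, truth, t = 2)
  expect_equal(rp2$recall, 0.5)     # 1 of 2 true labels retrieved
  expect_equal(rp2$precision, 0.5)  # 1 of t = 2 slots correct
  # perfect single-label drug at t = 1 contributes 1 to both
  one <- recall_precision_at_t(list(k = rp("D_4")), list(k = "D_4"), 1)
  expect_equal(one$recall, 1)
  expect_equal(one$precision, 1)
})

test_that("Precision_1 equals ACC_1 on arbitrary prediction sets", {
  for (seed in 1:8) {
    fx <- make_random_fixture(seed, n_drugs = 15)
    preds <- random_ranking_predictions(fx$dataset, seed = seed + 100)
    truth <- truth_labels(fx$dataset)
    expect_equal(recall_precision_at_t(preds, truth, 1)$precision,
                 order_accuracy(preds, truth, 1))
  }
})

test_that("average label count and the cutoff t", {
  al <- average_labels(list(a = "D_1", b = "D_2", c = c("D_1", "D_3")))
  expect_equal(al$average, 4 / 3)
  expect_equal(al$t, 2L)
  expect_equal(average_labels(rep(1, 5)), list(average = 1, t = 1L))
  expect_error(average_labels(list()), "non-empty")
  # 2,005 category memberships over 1,573 drugs
  counts <- c(rep(1, 1141), rep(2, 432))
  al2 <- average_labels(counts)
  expect_equal(round(al2$average, 2), 1.27)
  expect_equal(al2$t, 2L)
})

test_that("per-category sensitivity of the top-2 predictions", {
  catalog <- indication_catalog(c("D_1", "D_2", "D_3"))
  truth <- list(a = "D_1", b = "D_1", c = "D_1", d = c("D_1", "D_2"))
  preds <- list(a = rp(c("D_1", "D_3")), b = rp(c("D_2", "D_1")),
                c = rp(c("D_2", "D_3")), d = rp(c("D_3", "D_1")))
  sn <- per_category_sn(preds, truth, catalog, top = 2)
  expect_equal(unname(sn[["D_1"]]), 0.75)  # 3 of 4 members retrieve D_1
  expect_equal(unname(sn[["D_2"]]), 0)     # never retrieved for d
  expect_false("D_3" %in% names(sn))       # no member: reported absent
  all_hit <- per_category_sn(list(a = rp("D_1")), list(a = "D_1"), catalog)
  expect_equal(unname(all_hit[["D_1"]]), 1)
})

test_that("pearson correlation matches the product-moment formula", {
  x <- c(1, 2, 3); y <- c(2, 4, 7)
  # independent evaluation of the product-moment formula
  byhand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), byhand)
  expect_equal(round(byhand, 4), 0.9934)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(x, c(1, 1, 1)), "constant")
  expect_error(pearson_r(x, c(1, 2)), "equal length")
})

test_that("jackknife hand-trace: mutual sole partners rank each other's tag first", {
  ds <- drug_dataset(c("u", "v"), rep(NA_character_, 2),
                     list("D_1", "D_1"),
                     catalog = indication_catalog(c("D_1", "D_2")))
  itab <- interaction_table("u", "v", 0.8)
  prov <- similarity_provider(matrix(1, 0, 0))
  rep <- jackknife(ds, itab, prov)
  expect_equal(unname(rep$acc_mean[[1]]), 1)
  expect_equal(rp_scores(rep$predictions$u), 0.8)
})

test_that("jackknife with no signal yields empty rankings and zero accuracy", {
  ds <- make_toy_dataset()
  prov <- similarity_provider(matrix(1, 0, 0))
  rep <- jackknife(ds, interaction_table(), prov)
  expect_equal(unname(rep$acc_mean[[1]]), 0)
  expect_true(all(vapply(rep$predictions, nrow, 0L) == 0))
})

test_that("jackknife equals a leave-one-out brute force", {
  for (seed in 21:24) {
    fx <- make_random_fixture(seed, n_drugs = 12)
    k <- min(3L, nrow(fx$dataset$catalog))
    rep <- jackknife(fx$dataset, fx$interactions, fx$similarity)
    ora <- oracle_jackknife_acc(fx, predictor_config(), orders = k)
    expect_equal(unname(rep$acc_mean[1:k]), ora)
  }
})

test_that("k-fold with as many folds as drugs is the jackknife", {
  fx <- make_random_fixture(31, n_drugs = 10)
  jk <- jackknife(fx$dataset, fx$interactions, fx$similarity)
  kf <- kfold(fx$dataset, fx$interactions, fx$similarity,
              folds = 10, repeats = 2, seed = 5)
  for (r in 1:2) {
    expect_equal(unname(kf$acc[r, ]), unname(jk$acc[1, ]))
  }
})

test_that("k-fold is reproducible from its seed and varies across seeds", {
  fx <- make_random_fixture(32, n_drugs = 20)
  a <- kfold(fx$dataset, fx$interactions, fx$similarity, folds = 5,
             repeats = 3, seed = 9)
  b <- kfold(fx$dataset, fx$interactions, fx$similarity, folds = 5,
             repeats = 3, seed = 9)
  expect_identical(a$acc, b$acc)
  expect_identical(a$recall_t, b$recall_t)
  expect_error(kfold(fx$dataset, fx$interactions, fx$similarity, folds = 5,
                     repeats = 3), "seed")
})

test_that("correct labels occupy at most one rank each (accuracy mass bound)", {
  for (seed in 41:44) {
    fx <- make_random_fixture(seed)
    rep <- jackknife(fx$dataset, fx$interactions, fx$similarity)
    truth <- truth_labels(fx$dataset)
    n <- length(truth)
    pd_total <- sum(rep$acc[1, ]) * n       # sum_i PD_i
    expect_lte(pd_total, sum(lengths(truth)) + 1e-9)
    # equivalently sum_i ACC_i <= Average
    expect_lte(sum(rep$acc[1, ]), rep$average_labels + 1e-9)
  }
})

test_that("evaluation report wires per-repeat metrics, sd and identity checks", {
  fx <- make_random_fixture(51, n_drugs = 25, n_categories = 5)
  kf <- kfold(fx$dataset, fx$interactions, fx$similarity, folds = 5,
              repeats = 4, seed = 2)
  expect_equal(dim(kf$acc), c(4L, 5L))
  expect_equal(unname(kf$acc_sd[1]), sd(kf$acc[, 1]))
  expect_equal(length(kf$per_category_sn), 4)
  expect_equal(kf$recall_t_mean, mean(kf$recall_t))
  expect_true(all(kf$acc >= 0 & kf$acc <= 1))
})

test_that("random rankings hit at the expected Average/m rate", {
  fx <- make_random_fixture(61, n_drugs = 150, n_categories = 6)
  truth <- truth_labels(fx$dataset)
  expected <- random_guess_acc1(average_labels(truth)$average, 6)
  accs <- vapply(1:20, function(r) {
    order_accuracy(random_ranking_predictions(fx$dataset, seed = r), truth, 1)
  }, numeric(1))
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - expected), 4 * se)
})
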