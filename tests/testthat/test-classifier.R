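test_that("stratified split preserves class proportions at 1:5", {
  tab <- separable_table(n_nuc = 100L, n_mito = 10L, n_plastid = 0L)
  tab <- tab[tab$label != "plastid", ]
  sp <- stratified_split(tab, test_fraction = 5 / 6, seed = 9)
  expect_equal(sum(sp$test$label == "nuclear"), 83)
  expect_equal(sum(sp$test$label == "mitochondrion"), 8)
  expect_equal(sum(sp$train$label == "nuclear"), 17)
  expect_equal(sum(sp$train$label == "mitochondrion"), 2)
  # disjoint and exhaustive
  expect_setequal(c(sp$train$seq_id, sp$test$seq_id), tab$seq_id)
  expect_length(intersect(sp$train$seq_id, sp$test$seq_id), 0)
  # deterministic given the seed
  sp2 <- stratified_split(tab, test_fraction = 5 / 6, seed = 9)
  expect_identical(sp, sp2)
  sp3 <- stratified_split(tab, test_fraction = 5 / 6, seed = 10)
  expect_false(identical(sp$train$seq_id, sp3$train$seq_id))
})

test_that("degenerate label sets are rejected with guidance", {
  tab <- separable_table(n_nuc = 20L, n_mito = 0L, n_plastid = 0L)
  tab <- tab[tab$label == "nuclear", ]
  expect_error(stratified_split(tab, seed = 1), "at least two classes")
  tab2 <- separable_table(n_nuc = 20L, n_mito = 1L, n_plastid = 0L)
  tab2 <- tab2[tab2$label != "plastid", ]
  expect_error(stratified_split(tab2, seed = 1), "fewer than 2")
  tab3 <- separable_table()
  tab3$label <- NULL
  expect_error(stratified_split(tab3, seed = 1), "no labels")
})

test_that("cross-validation separates a separable table perfectly", {
  tab <- separable_table(n_nuc = 60L, n_mito = 12L, n_plastid = 12L)
  cv <- cross_validate(tab, k = 4L, seed = 21)
  best <- cv$per_family[[cv$best_family]]
  expect_equal(best$mean_mcc, 1.0)
  # all families tie at MCC 1 here, so precedence picks adaboost
  mccs <- vapply(cv$per_family, `[[`, numeric(1), "mean_mcc")
  if (all(mccs == 1)) expect_equal(cv$best_family, "adaboost")
  expect_error(cross_validate(tab, families = character(0), seed = 1),
               "no model families")
  expect_error(cross_validate(tab, families = "svm", seed = 1), "unknown")
})

test_that("fold count is lowered to the smallest class with a warning", {
  tab <- separable_table(n_nuc = 40L, n_mito = 5L, n_plastid = 5L)
  expect_warning(cv <- cross_validate(tab, families = "linear", k = 10L,
                                      seed = 3), "lowered")
  expect_equal(cv$k, 5L)
})

test_that("label permutation destroys the cross-validated signal", {
  tab <- separable_table(n_nuc = 220L, n_mito = 40L, n_plastid = 40L,
                         seed = 77)
  tab$label <- withr::with_seed(123, sample(tab$label))
  cv <- cross_validate(tab, families = "random_forest", k = 5L, seed = 5)
  expect_lt(abs(cv$per_family$random_forest$mean_mcc), 0.2)
})

test_that("the trained bundle memorises a separable table and its scores normalise", {
  tab <- separable_table()
  cv <- cross_validate(tab, k = 4L, seed = 21)
  bundle <- train_best(tab, cv)
  pred <- predict(bundle, tab)
  expect_equal(pred$predicted_class, tab$label)
  scores <- as.matrix(pred[, c("score_nuclear", "score_mitochondrion",
                               "score_plastid")])
  expect_true(all(abs(rowSums(scores) - 1) < 1e-9))
  expect_true(all(scores >= 0 & scores <= 1))
  # argmax consistency with the fixed class order
  cls <- c("nuclear", "mitochondrion", "plastid")
  expect_equal(pred$predicted_class,
               cls[max.col(scores, ties.method = "first")])
})

test_that("an all-zero feature row falls to the majority class", {
  tab <- separable_table(n_nuc = 60L, n_mito = 8L, n_plastid = 8L)
  cv <- cross_validate(tab, families = "knn", k = 4L, seed = 2)
  bundle <- train_best(tab, cv)
  zero <- tab[1, ]
  zero$seq_id <- "zero"
  num <- vapply(zero, is.numeric, logical(1))
  zero[num] <- 0
  zero$length_bp <- 1e5
  zero$gc <- 0.41
  zero$label <- NULL
  pred <- predict(bundle, zero)
  expect_equal(pred$predicted_class, "nuclear")
})

test_that("model persistence reproduces predictions and is byte-stable", {
  tab <- separable_table()
  run_once <- function() {
    cv <- cross_validate(tab, families = c("adaboost", "linear"), k = 4L,
                         seed = 77)
    train_best(tab, cv)
  }
  b1 <- run_once()
  b2 <- run_once()
  p1 <- withr::local_tempfile(fileext = ".rds")
  p2 <- withr::local_tempfile(fileext = ".rds")
  save_model(b1, p1)
  save_model(b2, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  reloaded <- load_model(p1)
  expect_identical(predict(reloaded, tab), predict(b1, tab))
  # schema mismatch is an explicit error
  broken <- tab
  broken$gc <- NULL
  expect_error(predict(b1, broken), "missing column")
  expect_error(load_model(withr::local_tempfile()), "not found")
})

test_that("predictions on an empty table are an empty frame with the schema", {
  tab <- separable_table()
  cv <- cross_validate(tab, families = "linear", k = 3L, seed = 4)
  bundle <- train_best(tab, cv)
  out <- predict(bundle, tab[0, ])
  expect_equal(nrow(out), 0L)
  expect_named(out, c("seq_id", "predicted_class", "score_nuclear",
                      "score_mitochondrion", "score_plastid"))
})
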