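make_ddis <- function(a, b, type) tibble::tibble(drug_a = a, drug_b = b,
                                                 type = type)

test_that("filter_dataset applies the exclusion rules to a fixed point", {
  drugs <- drug_table(c("d1", "d2", "d3", "d4"),
                      targets = list("g1", "g2", character(), "g3"))
  # d3 has no targets; type 2 will fall under 5 records once d3's DDIs go
  ddis <- make_ddis(
    a = c(rep("d1", 5), "d3", "d2", "d2", "d2", "d2"),
    b = c(rep("d2", 5), "d1", "d4", "d4", "d4", "d3"),
    type = c(rep(1L, 5), rep(2L, 5)))
  res <- filter_dataset(ddis, drugs)
  # hand enumeration: d3 removed -> 2 of type 2's records drop -> type 2
  # has 3 < 5 -> type 2 gone entirely; type 1 (5 records) survives
  expect_equal(nrow(res$ddis), 5)
  expect_equal(unique(res$ddis$type), 1L)
  expect_false("d3" %in% res$drugs$drug_id)
  # exactly 5 records is retained ("fewer than five" is strict)
  expect_true(all(table(res$ddis$type) >= 5))
  # fixed point: re-applying changes nothing
  res2 <- filter_dataset(res$ddis, res$drugs)
  expect_equal(res2$ddis, res$ddis)
  expect_equal(res2$drugs$drug_id, res$drugs$drug_id)
  # a type with 4 records is dropped even with valid drugs
  ddis4 <- make_ddis(rep("d1", 9), rep("d2", 9),
                     c(rep(1L, 5), rep(3L, 4)))
  res3 <- filter_dataset(ddis4, drugs)
  expect_equal(unique(res3$ddis$type), 1L)
  expect_error(filter_dataset(ddis4[6:9, ], drugs), "removed every")
  expect_s3_class(res$log, "tbl_df")
})

test_that("kfold_split partitions exactly, stratifies, and is seeded", {
  ddis <- make_ddis(paste0("a", 1:10), paste0("b", 1:10), rep(1L, 10))
  f <- kfold_split(ddis, k = 5, seed = 3)
  expect_equal(sort(unique(f)), 1:5)
  expect_equal(as.integer(table(f)), rep(2L, 5))
  # stratified: a type with 10 records lands exactly twice per fold
  ddis2 <- make_ddis(paste0("a", 1:15), paste0("b", 1:15),
                     c(rep(1L, 10), rep(2L, 5)))
  f2 <- kfold_split(ddis2, k = 5, seed = 3)
  per_fold <- table(f2[ddis2$type == 1])
  expect_true(all(per_fold == 2))
  expect_identical(kfold_split(ddis2, k = 5, seed = 3), f2)
  expect_false(identical(kfold_split(ddis2, k = 5, seed = 4), f2))
  expect_error(kfold_split(ddis, k = 1), "at least 2")
  expect_error(kfold_split(ddis, k = 11), "exceeds")
})

test_that("run_experiment returns the full metric table per configuration", {
  w <- tiny_world()
  profs <- tiny_profiles()
  plan <- experiment_plan(list(c("ssp", "tsp", "gsp")), "ae", "ffn")
  exp <- run_experiment(w$ddis, profs, plan, k = 3,
                        config = quick_config(epochs = 6))
  expect_equal(nrow(exp$results), 1)
  expect_true(all(c("accuracy", "macro_recall", "macro_precision",
                    "micro_recall", "micro_precision", "auprc")
                  %in% names(exp$results)))
  expect_equal(nrow(exp$fold_metrics), 3)
  expect_equal(sort(unique(exp$per_type$type)),
               sort(unique(as.character(w$ddis$type))))
  sc <- exp$cv_scores[[plan$label[1]]]
  expect_equal(dim(sc), c(nrow(w$ddis), 4))
  expect_true(all(is.finite(sc)))
})

test_that("a failing configuration is recorded and the run continues", {
  w <- tiny_world()
  profs <- tiny_profiles()
  plan <- experiment_plan(list("gsp", "ssp"),
                          reducer = c("ae", "ae"),
                          classifier = c("ffn", "ffn"))
  exp <- run_experiment(w$ddis, profs["ssp"], plan, k = 2,
                        config = quick_config(epochs = 2))
  expect_length(exp$errors, 1) # the gsp config had no profile
  expect_equal(exp$results$label, plan$label[2])
})

test_that("pca and baseline classifier paths run through the experiment", {
  w <- tiny_world()
  profs <- tiny_profiles()
  ddis <- w$ddis[1:150, ]
  plan <- experiment_plan(list("ssp", c("ssp", "tsp")),
                          reducer = c("none", "pca"),
                          classifier = c("rf", "svm"))
  exp <- run_experiment(ddis, profs, plan, k = 2,
                        config = quick_config(epochs = 1))
  expect_equal(nrow(exp$results), 2)
  expect_length(exp$errors, 0)
  expect_true(all(exp$results$auprc >= 0 & exp$results$auprc <= 1))
})

test_that("baselines separate a separable toy and are seeded", {
  set.seed(5)
  n <- 60
  x <- rbind(matrix(rnorm(n * 4, 0), n, 4), matrix(rnorm(n * 4, 4), n, 4))
  y <- rep(c("t1", "t2"), each = n)
  for (which in c("svm", "rf")) {
    bl <- baseline_classifier(x, y, which, seed = 1)
    sc <- bl$score(x)
    expect_true(all(sc >= 0 & sc <= 1))
    expect_equal(mean(colnames(sc)[max.col(sc)] == y), 1.0,
                 tolerance = 0.02)
  }
  bl1 <- baseline_classifier(x, y, "rf", seed = 1)
  bl2 <- baseline_classifier(x, y, "rf", seed = 1)
  expect_equal(bl1$score(x), bl2$score(x))
})

test_that("shuffled labels drive held-out baseline accuracy to chance", {
  set.seed(6)
  n <- 120
  x <- rbind(matrix(rnorm(n * 6, 0), n, 6), matrix(rnorm(n * 6, 3), n, 6))
  y <- sample(rep(c("t1", "t2"), each = n)) # labels destroyed
  tr <- sample(2 * n, n)
  bl <- baseline_classifier(x[tr, ], y[tr], "rf", seed = 1)
  sc <- bl$score(x[-tr, ])
  acc <- mean(colnames(sc)[max.col(sc)] == y[-tr])
  expect_lt(abs(acc - 0.5), 0.15)
})

test_that("report_novel keeps true positives and other types above threshold", {
  scores <- rbind(c(0.9, 0.85, 0.1),
                  c(0.4, 0.99, 0.99),
                  c(0.7, 0.2, 0.3))
  colnames(scores) <- c("1", "2", "3")
  ddis <- make_ddis(c("a", "b", "c"), c("x", "y", "z"), c(1L, 1L, 1L))
  rep <- report_novel(scores, ddis)
  # pair b-y is not a true positive (0.4 < 0.5): excluded entirely
  expect_false("b" %in% rep$drug_a)
  # pair a-x reports type 2 at 0.85; pair c-z reports nothing
  expect_equal(nrow(rep), 1)
  expect_equal(rep$novel_type, "2")
  expect_equal(rep$novel_score, 0.85)
  expect_true(all(rep$novel_score >= 0.5))
  expect_true(all(rep$known_score >= 0.5))
  expect_true(all(rep$novel_type != rep$known_type))
})

test_that("cross-validated novel report never flags the known type", {
  w <- tiny_world()
  profs <- tiny_profiles()
  plan <- experiment_plan(list(c("ssp", "tsp", "gsp")), "ae", "ffn")
  exp <- run_experiment(w$ddis, profs, plan, k = 3,
                        config = quick_config(epochs = 30))
  rep <- report_novel(exp$cv_scores[[1]], w$ddis)
  if (nrow(rep) > 0) {
    expect_true(all(rep$novel_score >= 0.5))
    expect_true(all(rep$novel_type != rep$known_type))
    # sorted descending
    expect_true(all(diff(rep$novel_score) <= 0))
  }
  expect_s3_class(rep, "tbl_df")
})

test_that("full-rank pca is metric-neutral for a linear classifier", {
  w <- tiny_world()
  profs <- tiny_profiles()
  ddis <- w$ddis[1:120, ]
  fold <- kfold_split(ddis, k = 2, seed = 1)
  tr <- ddis[fold == 1, ]; te <- ddis[fold == 2, ]
  xtr <- suppressMessages(assemble_pair_inputs(tr, profs$ssp))
  xte <- suppressMessages(assemble_pair_inputs(te, profs$ssp))
  bl_raw <- baseline_classifier(xtr, tr$type, "svm", seed = 1)
  acc_raw <- ddi_accuracy(bl_raw$score(xte), te$type)
  # full-rank PCA is a rotation plus centering, which a linear kernel
  # cannot distinguish from the raw features
  red <- pca_reduce(xtr, min(nrow(xtr) - 1, ncol(xtr)))
  bl_pca <- baseline_classifier(red$scores, tr$type, "svm", seed = 1)
  acc_pca <- ddi_accuracy(bl_pca$score(predict(red, xte)), te$type)
  expect_lt(abs(acc_raw - acc_pca), 0.1)
})
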