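test_that("AUROC hits its analytic endpoints and random baseline", {
  labels <- c(1, 0, 1, 0, 1, 0)
  expect_equal(roc_and_auroc(labels, labels)$auroc, 1)
  expect_equal(roc_and_auroc(-labels, labels)$auroc, 0)

  roc <- roc_and_auroc(c(0.9, 0.4, 0.8, 0.3), c(1, 0, 1, 0))
  expect_equal(roc$curve$fpr[1L], 0)               # starts at (0,0)
  expect_equal(roc$curve$tpr[1L], 0)
  expect_equal(utils::tail(roc$curve$fpr, 1L), 1)  # ends at (1,1)
  expect_equal(utils::tail(roc$curve$tpr, 1L), 1)

  expect_error(roc_and_auroc(1:4, rep(1, 4)), "single-class")
})

test_that("rank-formula AUROC equals the trapezoidal curve area", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(20:200, 1L)
    pred <- sample(round(rnorm(n), 2))            # plenty of ties
    lab <- rbinom(n, 1, 0.3)
    if (length(unique(lab)) < 2L) next
    roc <- roc_and_auroc(pred, lab)
    trap <- sum(diff(roc$curve$fpr) *
                  (utils::head(roc$curve$tpr, -1L) +
                     utils::tail(roc$curve$tpr, -1L)) / 2)
    expect_equal(roc$auroc, trap, tolerance = 1e-10)
  }
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(22)
  pred <- rnorm(500)
  lab <- rbinom(500, 1, 0.25)
  ref <- as.numeric(pROC::auc(pROC::roc(lab, pred, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_and_auroc(pred, lab)$auroc, ref, tolerance = 1e-10)
})

test_that("step-wise AUPR matches hand enumeration and tie conventions", {
  expect_equal(pr_and_aupr(c(3, 2, 1), c(1, 1, 0))$aupr, 1)   # perfect
  # constant predictor scores the prevalence
  expect_equal(pr_and_aupr(rep(1, 10), rep(c(1, 0, 0, 0, 0), 2))$aupr, 0.2)
  # 4-point worked example: thresholds 0.9/.8/.7/.6 give precision
  # 1, 1/2, 2/3, 1/2 at recall 1/2, 1/2, 1, 1 -> area 1/2 + 1/3
  pr <- pr_and_aupr(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))
  expect_equal(pr$aupr, 1 / 2 + 1 / 3)
  expect_equal(pr$curve$precision, c(1, 1 / 2, 2 / 3, 1 / 2))
  expect_error(pr_and_aupr(1:3, c(0, 0, 0)), "no positive")
})

test_that("the MCC curve matches brute-force confusion matrices", {
  expect_equal(mcc_curve_and_max(c(5, 4, 1, 0), c(1, 1, 0, 0))$max_mcc, 1)

  pred <- c(0.9, 0.7, 0.7, 0.5, 0.3, 0.1)
  lab <- c(1, 0, 1, 1, 0, 0)
  res <- mcc_curve_and_max(pred, lab)
  for (i in seq_len(nrow(res$curve))) {
    expect_equal(res$curve$mcc[i],
                 brute_mcc(pred, lab, res$curve$threshold[i]))
  }
  expect_equal(res$max_mcc, max(res$curve$mcc))

  # a balanced 2x2 table scores exactly 0
  bal <- mcc_curve_and_max(c(4, 3, 2, 1), c(1, 0, 1, 0))
  expect_true(any(bal$curve$mcc == 0))
  # all-positive binarization has a zero marginal -> defined as 0
  expect_equal(utils::tail(bal$curve$mcc, 1L), 0)
})

test_that("the sensitivity-specificity curve mirrors the ROC curve", {
  pred <- c(0.8, 0.6, 0.4, 0.2)
  lab <- c(1, 1, 0, 0)
  ss <- ss_curve(pred, lab)
  expect_true(any(ss$specificity == 1 & ss$sensitivity == 1))  # perfect
  # lowest threshold calls everything positive: (0, 1)
  expect_equal(utils::tail(ss$specificity, 1L), 0)
  expect_equal(utils::tail(ss$sensitivity, 1L), 1)
  roc <- roc_and_auroc(pred, lab)
  expect_equal(ss$specificity, 1 - roc$curve$fpr)
  expect_equal(ss$sensitivity, roc$curve$tpr)
})

test_that("RMSE is the root mean squared residual", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2, 3) + 0.7, c(1, 2, 3)), 0.7)
  expect_equal(rmse(c(1, 2, 3), c(2, 2, 5)), sqrt(5 / 3))
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})

test_that("leave-one-gene-out partitions guides by gene without leakage", {
  sim <- toy_dataset(n = 160L, n_genes = 4L, seed = 51, noise_sd = 0.5)
  preds <- leave_one_gene_out_cv(
    sim$dataset, small_spec(),
    selection_config(n_trees = 60L, repeats = 1L, seed = 2L,
                     importance_threshold = 0.1),
    svm_config()
  )
  expect_s3_class(preds, "cv_predictions")
  # folds = distinct genes; every guide predicted exactly once
  expect_equal(sort(unique(preds$fold)), 1:4)
  expect_identical(preds$row, seq_len(160L))
  expect_false(anyNA(preds$predicted))
  # a guide's fold is its gene's fold
  expect_true(all(tapply(preds$fold, preds$gene_id,
                         function(f) length(unique(f))) == 1L))
  # leakage audit: held-out gene never among its fold's training genes
  details <- attr(preds, "fold_details")
  expect_equal(nrow(details), 4L)
  for (f in seq_len(4L)) {
    test_genes <- unique(preds$gene_id[preds$fold == f])
    expect_identical(test_genes, details$gene_id[details$fold == f])
    expect_equal(details$n_train[f], 160L - sum(preds$fold == f))
  }
})

test_that("degenerate cross-validation inputs fail with clear messages", {
  sim <- toy_dataset(n = 30L, n_genes = 2L, seed = 53)
  ds <- sim$dataset
  ds$gene_id <- "only_gene"
  expect_error(leave_one_gene_out_cv(ds, small_spec()), "at least 2 genes")

  ds2 <- sim$dataset
  ds2$binary_label <- ifelse(ds2$gene_id == "gene01", 1L, 0L)
  expect_error(
    leave_one_gene_out_cv(ds2, small_spec(),
                          selection_config(n_trees = 20L, repeats = 1L)),
    "single-class when holding out"
  )
})

test_that("evaluation reports bundle scalars and curves consistently", {
  set.seed(55)
  pred <- rnorm(300)
  lab <- as.integer(pred + rnorm(300) > 0.5)
  truth <- pred + rnorm(300, sd = 0.2)
  rep <- evaluation_report(pred, lab, truth)
  expect_equal(rep$auroc, roc_and_auroc(pred, lab)$auroc)
  expect_equal(rep$aupr, pr_and_aupr(pred, lab)$aupr)
  expect_equal(rep$max_mcc, mcc_curve_and_max(pred, lab)$max_mcc)
  expect_equal(rep$rmse, rmse(pred, truth))
  expect_equal(rep$prevalence, mean(lab))

  dir <- tempfile()
  write_evaluation_report(rep, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  scalars <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(scalars$auroc, rep$auroc, tolerance = 1e-12)
  curves <- utils::read.csv(file.path(dir, "roc_curve.csv"))
  expect_equal(nrow(curves), nrow(rep$roc_curve))
})
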