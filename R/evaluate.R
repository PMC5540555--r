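# Confusion counts at every unique prediction threshold, highest first.
# Threshold t classifies pred >= t as positive; tied predictions share one
# threshold. Row 0 (nothing positive) is included.
threshold_sweep <- function(predictions, labels) {
  stopifnot(length(predictions) == length(labels),
            all(labels %in% c(0, 1)))
  ord <- order(-predictions)
  p <- predictions[ord]
  y <- labels[ord]
  last <- cumsum(rle(p)$lengths)          # last index of each tie group
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  n_pos <- sum(y)
  n_neg <- length(y) - n_pos
  data.frame(
    threshold = c(Inf, p[last]),
    tp = c(0, tp), fp = c(0, fp),
    fn = n_pos - c(0, tp), tn = n_neg - c(0, fp)
  )
}

#' ROC curve and AUROC
#'
#' The curve visits one point per unique prediction threshold plus the
#' all-negative corner, so it always passes through (0, 0) and (1, 1).
#' AUROC is computed by the rank (Mann-Whitney) formula -- the probability
#' that a random positive outranks a random negative, ties counting one
#' half -- which equals the trapezoidal area under the point series.
#'
#' @param predictions numeric scores, higher = more likely positive.
#' @param labels binary 0/1 truth, both classes present.
#' @return list with `curve` (data frame: threshold, fpr, tpr) and `auroc`.
#' @export
roc_and_auroc <- function(predictions, labels) {
  check_two_classes(labels)
  sw <- threshold_sweep(predictions, labels)
  n_pos <- sum(labels)
  n_neg <- length(labels) - n_pos
  r <- rank(predictions)                   # mean ranks on ties = 1/2 credit
  auroc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  list(
    curve = data.frame(threshold = sw$threshold,
                       fpr = sw$fp / n_neg, tpr = sw$tp / n_pos),
    auroc = auroc
  )
}

#' Precision-recall curve and AUPR
#'
#' One point per unique threshold. The area uses the step-wise
#' (rectangular) rule, summing precision times the recall increment at
#' each threshold -- linear interpolation between PR points is biased and
#' is not used. A constant predictor therefore scores the positive
#' prevalence.
#'
#' @inheritParams roc_and_auroc
#' @return list with `curve` (threshold, recall, precision) and `aupr`.
#' @export
pr_and_aupr <- function(predictions, labels) {
  if (sum(labels) == 0L) stop("no positive labels", call. = FALSE)
  sw <- threshold_sweep(predictions, labels)
  sw <- sw[-1L, , drop = FALSE]            # precision undefined at TP+FP=0
  n_pos <- sum(labels)
  recall <- sw$tp / n_pos
  precision <- sw$tp / (sw$tp + sw$fp)
  aupr <- sum(diff(c(0, recall)) * precision)
  list(
    curve = data.frame(threshold = sw$threshold,
                       recall = recall, precision = precision),
    aupr = aupr
  )
}

# MCC of one confusion matrix; 0 by convention when any marginal is 0.
mcc_from_counts <- function(tp, fp, fn, tn) {
  denom <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
  ifelse(denom == 0, 0, (tp * tn - fp * fn) / denom)
}

#' MCC-vs-threshold curve and its maximum
#'
#' Matthews correlation coefficient of the binarization `pred >= t` at
#' every unique threshold `t` (plus the all-negative binarization). MCC
#' with a zero marginal is defined as 0.
#'
#' @inheritParams roc_and_auroc
#' @return list with `curve` (threshold, mcc) and `max_mcc`.
#' @export
mcc_curve_and_max <- function(predictions, labels) {
  check_two_classes(labels)
  sw <- threshold_sweep(predictions, labels)
  mcc <- mcc_from_counts(sw$tp, sw$fp, sw$fn, sw$tn)
  list(curve = data.frame(threshold = sw$threshold, mcc = mcc),
       max_mcc = max(mcc))
}

#' Sensitivity-specificity curve
#'
#' (specificity, sensitivity) at every threshold; identical information to
#' the ROC curve via specificity = 1 - FPR. Sweeping the threshold down
#' from above the maximum prediction traces sensitivity from 0 up to 1 as
#' specificity falls from 1 to 0.
#'
#' @inheritParams roc_and_auroc
#' @return data frame with `threshold`, `specificity`, `sensitivity`.
#' @export
ss_curve <- function(predictions, labels) {
  check_two_classes(labels)
  sw <- threshold_sweep(predictions, labels)
  n_pos <- sum(labels)
  n_neg <- length(labels) - n_pos
  data.frame(threshold = sw$threshold,
             specificity = sw$tn / n_neg,
             sensitivity = sw$tp / n_pos)
}

#' Root mean square error
#'
#' @param predictions predicted continuous scores.
#' @param true_scores observed continuous scores, same length.
#' @return `sqrt(mean((predictions - true_scores)^2))`.
#' @export
rmse <- function(predictions, true_scores) {
  if (length(predictions) == 0L) stop("empty input", call. = FALSE)
  stopifnot(length(predictions) == length(true_scores),
            all(is.finite(predictions)), all(is.finite(true_scores)))
  sqrt(mean((predictions - true_scores)^2))
}

check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2L) {
    stop("labels are single-class; both classes required", call. = FALSE)
  }
  invisible(TRUE)
}

#' Leave-one-gene-out cross-validation
#'
#' For each gene in turn, the whole pipeline downstream of featurization
#' -- importance ranking, threshold selection, the feature cap, the ANOVA
#' redundancy filter and SVM training -- is fitted on the guides of all
#' other genes and applied to the held-out gene's guides, so no gene ever
#' informs its own predictions. Held-out predictions are pooled across
#' folds into a single prediction vector.
#'
#' Feature construction itself is per-guide and fold-independent, so the
#' feature matrix is built once. By default feature selection is re-run
#' inside every training fold (leakage-safe); `selection = "global"`
#' selects once on the full data, which is faster but optimistic because
#' the held-out gene's labels inform its own feature set.
#'
#' @param dataset a [guide_dataset()] with >= 2 genes and activity scores.
#'   Binary labels are derived at `positive_fraction` per gene when absent.
#' @param spec a [feature_spec()].
#' @param config a [selection_config()].
#' @param svm a [svm_config()].
#' @param selection `"per_fold"` (default) or `"global"`.
#' @param positive_fraction label fraction used when labels are absent.
#' @param engine secondary-structure engine for featurization.
#' @param verbose print per-fold progress to stderr?
#' @return a `cv_predictions` data frame: `row`, `gene_id`, `fold`,
#'   `predicted`, `activity_score`, `binary_label`, plus an attribute
#'   `fold_details` (per-fold feature counts and training-gene audit).
#' @export
leave_one_gene_out_cv <- function(dataset, spec = feature_spec(),
                                  config = selection_config(),
                                  svm = svm_config(),
                                  selection = c("per_fold", "global"),
                                  positive_fraction = 0.2,
                                  engine = vienna_engine(),
                                  verbose = FALSE) {
  selection <- match.arg(selection)
  genes <- unique(dataset$gene_id)
  if (length(genes) < 2L) {
    stop("leave-one-gene-out needs at least 2 genes", call. = FALSE)
  }
  if (anyNA(dataset$activity_score)) {
    stop("all guides need an activity_score", call. = FALSE)
  }
  if (all(is.na(dataset$binary_label))) {
    dataset <- derive_binary_labels(dataset, positive_fraction)
  }
  fm <- featurize_dataset(dataset, spec, engine = engine)
  labels <- dataset$binary_label
  scores <- dataset$activity_score

  global_selected <- NULL
  if (selection == "global") {
    tab <- rank_features_by_importance(fm, labels, config)
    global_selected <- select_by_threshold(tab, config$importance_threshold)
  }

  predicted <- rep(NA_real_, nrow(dataset))
  fold_of <- match(dataset$gene_id, genes)
  details <- vector("list", length(genes))
  for (f in seq_along(genes)) {
    g <- genes[f]
    test_idx <- which(dataset$gene_id == g)
    train_idx <- which(dataset$gene_id != g)
    if (length(unique(labels[train_idx])) < 2L) {
      stop(sprintf("training labels single-class when holding out gene '%s'",
                   g), call. = FALSE)
    }
    if (verbose) message(sprintf("fold %d/%d: holding out %s (%d guides)",
                                 f, length(genes), g, length(test_idx)))
    if (selection == "per_fold") {
      tab <- rank_features_by_importance(
        fm[train_idx, , drop = FALSE], labels[train_idx], config
      )
      selected <- select_by_threshold(tab, config$importance_threshold)
    } else {
      selected <- global_selected
    }
    if (length(selected) == 0L) {
      stop(sprintf(
        "no features exceed importance threshold %g in fold '%s'; lower the threshold",
        config$importance_threshold, g
      ), call. = FALSE)
    }
    if (config$cap_features && length(selected) > length(train_idx) - 2L) {
      selected <- selected[seq_len(length(train_idx) - 2L)]
    }
    aliased <- character(0)
    if (!is.na(config$anova_alpha)) {
      flt <- anova_redundancy_filter(
        fm[train_idx, selected, drop = FALSE], scores[train_idx],
        alpha = config$anova_alpha
      )
      if (length(flt$retained) > 0L) {
        # keep importance order
        selected <- selected[selected %in% flt$retained]
        aliased <- flt$aliased
      }
    }
    model <- train_guide_model(
      fm[train_idx, selected, drop = FALSE], scores[train_idx], svm,
      imputation = attr(fm, "imputation"),
      provenance = sprintf("LOGO fold holding out %s", g)
    )
    predicted[test_idx] <- predict(model, fm[test_idx, , drop = FALSE])
    details[[f]] <- data.frame(
      fold = f, gene_id = g, n_train = length(train_idx),
      n_test = length(test_idx), n_selected = length(selected),
      n_aliased = length(aliased), stringsAsFactors = FALSE
    )
  }
  out <- data.frame(
    row = seq_len(nrow(dataset)),
    gene_id = dataset$gene_id,
    fold = fold_of,
    predicted = predicted,
    activity_score = scores,
    binary_label = labels,
    stringsAsFactors = FALSE
  )
  attr(out, "fold_details") <- do.call(rbind, details)
  class(out) <- c("cv_predictions", "data.frame")
  out
}

#' Summarize pooled predictions into an evaluation report
#'
#' Computes the full metric set from pooled predictions: ROC curve and
#' AUROC, PR curve and AUPR, sensitivity-specificity curve, MCC threshold
#' curve and its maximum, and the RMSE of the predicted versus observed
#' continuous scores.
#'
#' @param predictions predicted scores, or a `cv_predictions` object.
#' @param labels binary truth (ignored when `predictions` is a
#'   `cv_predictions`).
#' @param true_scores continuous truth for RMSE (ditto); optional.
#' @return an `evaluation_report` list: `auroc`, `aupr`, `max_mcc`,
#'   `rmse` (NA when no continuous truth), and the four curves.
#' @export
evaluation_report <- function(predictions, labels = NULL,
                              true_scores = NULL) {
  if (inherits(predictions, "cv_predictions")) {
    labels <- predictions$binary_label
    true_scores <- predictions$activity_score
    predictions <- predictions$predicted
  }
  roc <- roc_and_auroc(predictions, labels)
  pr <- pr_and_aupr(predictions, labels)
  mcc <- mcc_curve_and_max(predictions, labels)
  ss <- ss_curve(predictions, labels)
  structure(
    list(
      auroc = roc$auroc, aupr = pr$aupr, max_mcc = mcc$max_mcc,
      rmse = if (is.null(true_scores)) NA_real_ else
        rmse(predictions, true_scores),
      roc_curve = roc$curve, pr_curve = pr$curve,
      mcc_curve = mcc$curve, ss_curve = ss,
      n = length(predictions), prevalence = mean(labels)
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report (pooled predictions)\n")
  cat(sprintf("  n = %d guides, positive prevalence %.3f\n",
              x$n, x$prevalence))
  cat(sprintf("  AUROC   %.3f\n  AUPR    %.3f\n  max MCC %.3f\n",
              x$auroc, x$aupr, x$max_mcc))
  if (!is.na(x$rmse)) cat(sprintf("  RMSE    %.3f\n", x$rmse))
  invisible(x)
}

#' Write an evaluation report to a directory
#'
#' Scalars go to `report.json`, each curve to its own CSV.
#'
#' @param report an `evaluation_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_evaluation_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scalars <- report[c("auroc", "aupr", "max_mcc", "rmse", "n", "prevalence")]
  jsonlite::write_json(scalars, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in c("roc_curve", "pr_curve", "mcc_curve", "ss_curve")) {
    utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
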