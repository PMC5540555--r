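#' Feature-selection configuration
#'
#' Defaults are the study conditions of the reference workflow: forests of
#' up to 500 trees, importance averaged over 30 independently seeded fits,
#' raw Mean-Decrease-Gini threshold 0.18, ANOVA redundancy filter at
#' alpha = 0.05, and a guard that caps the number of features entering the
#' SVM at `n_rows - 2` (a linear model with more features than rows is
#' ill-posed).
#'
#' @param n_trees trees per forest (>= 1).
#' @param repeats independent forest fits to average over (>= 1).
#' @param seed base seed; fit r uses `seed + r - 1`.
#' @param importance_threshold keep features with mean importance strictly
#'   above this raw Mean-Decrease-Gini value.
#' @param anova_alpha drop selected features whose linear-model p-value
#'   exceeds this; `NA` disables the filter.
#' @param cap_features cap selection at `n_rows - 2` before SVM training?
#' @return a `selection_config` list.
#' @export
selection_config <- function(n_trees = 500L, repeats = 30L, seed = 1L,
                             importance_threshold = 0.18,
                             anova_alpha = 0.05, cap_features = TRUE) {
  stopifnot(n_trees >= 1L, repeats >= 1L,
            is.na(anova_alpha) || (anova_alpha > 0 && anova_alpha <= 1),
            importance_threshold >= 0)
  structure(
    list(n_trees = as.integer(n_trees), repeats = as.integer(repeats),
         seed = as.integer(seed),
         importance_threshold = as.numeric(importance_threshold),
         anova_alpha = as.numeric(anova_alpha),
         cap_features = isTRUE(cap_features)),
    class = "selection_config"
  )
}

#' Rank features by repeated random-forest Gini importance
#'
#' Fits `repeats` classification forests of the binary activity labels on
#' the feature matrix (seeds `seed`, `seed + 1`, ...), extracts each fit's
#' Mean Decrease Gini (impurity) importance, and averages. Averaging over
#' independently seeded forests stabilizes the ranking; a single forest's
#' Gini values are noticeably seed-dependent at p ~ 10^4.
#'
#' @param matrix feature matrix (rows = guides).
#' @param labels binary 0/1 labels, one per row, both classes present.
#' @param config a [selection_config()].
#' @return an `importance_table` data frame with columns `feature`,
#'   `mean_importance`, `rank`, sorted by descending importance (ties by
#'   column order), with the config attached as an attribute.
#' @export
rank_features_by_importance <- function(matrix, labels,
                                        config = selection_config()) {
  labels <- as.integer(labels)
  if (length(labels) != nrow(matrix)) {
    stop("need one label per matrix row", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("labels are single-class; importance needs both classes",
         call. = FALSE)
  }
  y <- factor(labels, levels = c(0L, 1L))
  acc <- numeric(ncol(matrix))
  for (r in seq_len(config$repeats)) {
    fit <- ranger::ranger(
      x = matrix, y = y,
      num.trees = config$n_trees,
      importance = "impurity",
      num.threads = 1L,
      seed = config$seed + r - 1L
    )
    acc <- acc + fit$variable.importance
  }
  imp <- acc / config$repeats
  ord <- order(-imp)  # stable: ties keep column order
  tab <- data.frame(
    feature = colnames(matrix)[ord],
    mean_importance = unname(imp[ord]),
    rank = seq_len(ncol(matrix)),
    stringsAsFactors = FALSE
  )
  attr(tab, "config") <- config
  class(tab) <- c("importance_table", "data.frame")
  tab
}

#' Select features above an importance threshold
#'
#' Strictly-greater-than selection, so the result is monotone in the
#' threshold: raising it can only shrink the feature set.
#'
#' @param table an importance table from [rank_features_by_importance()].
#' @param threshold raw mean-importance cutoff.
#' @return character vector of feature names in descending importance
#'   order (possibly empty).
#' @export
select_by_threshold <- function(table, threshold) {
  stopifnot(nrow(table) >= 1L, is.numeric(threshold))
  table$feature[table$mean_importance > threshold]
}

#' Single-pass ANOVA redundancy filter
#'
#' Fits one linear model of the continuous activity score on all selected
#' features jointly and drops, in a single pass (no refitting loop),
#' features whose coefficient p-value exceeds `alpha`. Features that are
#' inestimable because of exact collinearity (aliased columns) are dropped
#' too and reported separately. p-values are the marginal per-coefficient
#' t-tests of the joint fit, so retention does not depend on column order.
#'
#' @param matrix feature matrix restricted (by name) to the selected
#'   features.
#' @param scores continuous activity scores, one per row.
#' @param alpha significance level; features with p > alpha are dropped.
#' @return list with `retained` (feature names), `p_values` (named, for
#'   all estimable features) and `aliased` (names dropped for exact
#'   collinearity).
#' @export
anova_redundancy_filter <- function(matrix, scores, alpha = 0.05) {
  stopifnot(ncol(matrix) >= 1L, length(scores) == nrow(matrix),
            all(is.finite(scores)), alpha > 0, alpha <= 1)
  df <- as.data.frame(matrix, check.names = FALSE)
  fit <- stats::lm(scores ~ ., data = df)
  coefs <- summary(fit)$coefficients
  est <- rownames(coefs)[-1L]          # drop intercept
  est <- sub("^`", "", sub("`$", "", est))
  p <- coefs[-1L, "Pr(>|t|)"]
  names(p) <- est
  aliased <- setdiff(colnames(matrix), est)
  retained <- colnames(matrix)[colnames(matrix) %in% est[p <= alpha]]
  list(retained = retained, p_values = p, aliased = aliased)
}

# The 12 feature categories of the encoding, by name structure.
feature_category <- function(feature) {
  ord <- c("1st", "2nd", "3rd", "4th")
  psf <- grepl("^[ACGT]{1,4}_[0-9]+$", feature)
  pif <- grepl("^[ACGT]{1,4}$", feature)
  out <- rep(NA_character_, length(feature))
  out[psf] <- paste0(ord[nchar(sub("_.*$", "", feature[psf]))], "PSF")
  out[pif] <- paste0(ord[nchar(feature[pif])], "PIF")
  out[feature == "mfe"] <- "MFE"
  out[feature == "specific_heat"] <- "Heat"
  out[feature == "percent_peptide"] <- "PP"
  out[feature == "amino_acid_cut_position"] <- "AACP"
  if (anyNA(out)) {
    stop(sprintf("unrecognized feature name: '%s'",
                 feature[is.na(out)][1L]), call. = FALSE)
  }
  out
}

#' Category-wise normalized importance summary
#'
#' Sums mean importances within the 12 feature categories of the encoding
#' (position-specific and position-independent blocks for k = 1..4, MFE,
#' specific heat, percent peptide, amino-acid cut position) and normalizes
#' so the largest category equals 1. All 12 categories are always
#' reported, zero-valued ones included.
#'
#' @param table an importance table.
#' @return data frame with columns `category` and `normalized_importance`.
#' @export
category_importance_summary <- function(table) {
  categories <- c("1stPSF", "2ndPSF", "3rdPSF", "4thPSF",
                  "1stPIF", "2ndPIF", "3rdPIF", "4thPIF",
                  "MFE", "Heat", "PP", "AACP")
  cat_of <- feature_category(table$feature)
  sums <- vapply(categories,
                 function(cc) sum(table$mean_importance[cat_of == cc]),
                 numeric(1L))
  top <- max(sums)
  if (top > 0) sums <- sums / top
  data.frame(category = categories, normalized_importance = unname(sums),
             stringsAsFactors = FALSE)
}

#' Write an importance table as CSV plus JSON manifest
#'
#' @param table an importance table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_importance_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  cfg <- attr(table, "config")
  if (!is.null(cfg)) {
    jsonlite::write_json(unclass(cfg), paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
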