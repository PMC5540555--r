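#' SVM scorer configuration
#'
#' The scorer is an epsilon-regression support vector machine with a
#' linear kernel at library defaults: cost 1, epsilon tube 0.1, features
#' standardized to zero mean / unit variance before fitting. A
#' classification mode (probability of the positive class) is available
#' for completeness; regression on the continuous score, later thresholded
#' for the binary metrics, is the default.
#'
#' @param cost regularization cost (> 0).
#' @param epsilon regression tube half-width (>= 0).
#' @param standardize_features standardize columns before fitting?
#' @param mode `"regression"` (default) or `"classification"`.
#' @return an `svm_config` list.
#' @export
svm_config <- function(cost = 1, epsilon = 0.1,
                       standardize_features = TRUE,
                       mode = c("regression", "classification")) {
  mode <- match.arg(mode)
  stopifnot(cost > 0, epsilon >= 0)
  structure(
    list(kernel = "linear", cost = as.numeric(cost),
         epsilon = as.numeric(epsilon),
         standardize_features = isTRUE(standardize_features),
         mode = mode),
    class = "svm_config"
  )
}

#' Train the linear-kernel SVM activity scorer
#'
#' Fits an epsilon-SVR (or, in classification mode, a probability SVC on
#' the binary labels) of the target on the given feature columns.
#' Standardization parameters, the exact ordered feature-name list and any
#' auxiliary-covariate imputation values are stored in the model so
#' prediction inputs can be aligned by name and imputed consistently.
#' Zero-variance features cannot be standardized; they are passed through
#' unscaled with a warning.
#'
#' @param matrix feature matrix (rows = guides). Column subset and order
#'   define the model's feature list.
#' @param target continuous activity scores (regression mode) or 0/1
#'   labels (classification mode), one per row.
#' @param config an [svm_config()].
#' @param imputation optional named list of auxiliary imputation values to
#'   carry in the model (see [featurize_dataset()]).
#' @param provenance free-text training provenance for the manifest.
#' @return a `guide_model`.
#' @export
train_guide_model <- function(matrix, target, config = svm_config(),
                              imputation = NULL, provenance = "") {
  if (nrow(matrix) < 2L) {
    stop("need at least 2 rows to fit the SVM", call. = FALSE)
  }
  if (length(target) != nrow(matrix) || anyNA(target) ||
      !all(is.finite(target))) {
    stop("`target` must be finite, one value per row", call. = FALSE)
  }
  if (ncol(matrix) >= nrow(matrix)) {
    warning(paste0(
      "as many or more features than rows; consider a higher importance ",
      "threshold or the selection cap"
    ), call. = FALSE)
  }
  center <- rep(0, ncol(matrix))
  scale_ <- rep(1, ncol(matrix))
  if (config$standardize_features) {
    center <- colMeans(matrix)
    scale_ <- apply(matrix, 2L, stats::sd)
    zero_var <- scale_ == 0 | !is.finite(scale_)
    if (any(zero_var)) {
      warning(sprintf(
        "%d zero-variance feature(s) passed through unscaled (e.g. '%s')",
        sum(zero_var), colnames(matrix)[zero_var][1L]
      ), call. = FALSE)
      center[zero_var] <- 0
      scale_[zero_var] <- 1
    }
  }
  x <- sweep(sweep(matrix, 2L, center, "-"), 2L, scale_, "/")
  if (config$mode == "regression") {
    fit <- e1071::svm(x = x, y = as.numeric(target), type = "eps-regression",
                      kernel = "linear", cost = config$cost,
                      epsilon = config$epsilon, scale = FALSE)
  } else {
    yf <- factor(as.integer(target), levels = c(0L, 1L))
    if (length(unique(target)) < 2L) {
      stop("classification mode needs both classes in `target`",
           call. = FALSE)
    }
    set.seed(0L)  # probability calibration uses internal CV
    fit <- e1071::svm(x = x, y = yf, type = "C-classification",
                      kernel = "linear", cost = config$cost,
                      probability = TRUE, scale = FALSE)
  }
  structure(
    list(
      fit = fit,
      feature_names = colnames(matrix),
      center = stats::setNames(center, colnames(matrix)),
      scale = stats::setNames(scale_, colnames(matrix)),
      config = config,
      imputation = imputation,
      provenance = provenance
    ),
    class = "guide_model"
  )
}

#' @export
print.guide_model <- function(x, ...) {
  cat(sprintf(
    "guide_model: linear-kernel SVM (%s), %d features, %d support vectors\n",
    x$config$mode, length(x$feature_names), x$fit$tot.nSV
  ))
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' Predict guide activity
#'
#' Columns are matched to the model's feature list by name, so column
#' order and extra columns in `newdata` are irrelevant; a missing required
#' feature is an error.
#'
#' @param object a `guide_model`.
#' @param newdata feature matrix containing at least the model's features.
#' @param ... unused.
#' @return numeric predicted activity (probability of the positive class
#'   in classification mode), one value per row.
#' @export
predict.guide_model <- function(object, newdata, ...) {
  missing <- setdiff(object$feature_names, colnames(newdata))
  if (length(missing) > 0L) {
    stop(sprintf("newdata is missing model feature(s): %s",
                 paste(utils::head(missing, 5L), collapse = ", ")),
         call. = FALSE)
  }
  x <- newdata[, object$feature_names, drop = FALSE]
  x <- sweep(sweep(x, 2L, object$center, "-"), 2L, object$scale, "/")
  if (object$config$mode == "regression") {
    as.numeric(stats::predict(object$fit, x))
  } else {
    pr <- stats::predict(object$fit, x, probability = TRUE)
    as.numeric(attr(pr, "probabilities")[, "1"])
  }
}

#' Save / load a guide model
#'
#' The artifact is a single self-describing file (RDS serialization of the
#' model list, which bundles the fitted SVM, feature names, scaling and
#' imputation parameters and provenance); load-then-predict reproduces
#' predictions bitwise.
#'
#' @param model a `guide_model`.
#' @param path artifact path.
#' @return `path` (save) / the model (load).
#' @export
save_guide_model <- function(model, path) {
  stopifnot(inherits(model, "guide_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_guide_model
#' @export
load_guide_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "guide_model")) {
    stop("file does not contain a guide_model", call. = FALSE)
  }
  model
}
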