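#' Fit the random-forest cell-type classifier
#'
#' Trains a random-trees classifier on all numeric features, normalized by
#' mean and variance: each feature is z-scored with training-set statistics,
#' which are stored in the model and re-applied at prediction time.
#' Constant features receive a unit standard deviation and are flagged.
#'
#' @param x feature matrix or data.frame (cells x features), all numeric.
#' @param labels character or factor cell classes, conventionally
#'   `tumor` / `immune` / `stroma`; at least two classes with at least
#'   `min_per_class` examples each.
#' @param ntree number of trees (default 100).
#' @param mtry features tried per split; default `floor(sqrt(p))`.
#' @param min_per_class minimum training examples per class.
#' @param seed random seed; required so that refitting reproduces the same
#'   forest and hence the same predictions.
#' @return An object of class `cell_classifier`: the fitted forest plus the
#'   per-feature normalization statistics, feature names, class set and seed.
#' @examples
#' x <- data.frame(a = c(rnorm(20), rnorm(20, 8)),
#'                 b = c(rnorm(20), rnorm(20, -8)))
#' fit <- fit_cell_classifier(x, rep(c("tumor", "immune"), each = 20), seed = 1)
#' predict(fit, x)$class[1:3]
#' @export
fit_cell_classifier <- function(x, labels, ntree = 100, mtry = NULL,
                                min_per_class = 2, seed) {
  if (missing(seed)) stop("a seed is required for reproducible training")
  x <- as.data.frame(x)
  bad <- names(x)[!vapply(x, is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric feature column(s): ", paste(bad, collapse = ", "))
  labels <- as.character(labels)
  if (anyNA(labels)) stop("missing labels are not allowed")
  if (length(labels) != nrow(x)) stop("labels must match rows of x")
  tabl <- table(labels)
  if (length(tabl) < 2L) stop("training set must contain at least 2 classes")
  if (any(tabl < min_per_class))
    stop("every class needs at least ", min_per_class, " examples")
  mu <- vapply(x, mean, numeric(1))
  sd_ <- vapply(x, stats::sd, numeric(1))
  constant <- !is.finite(sd_) | sd_ == 0
  sd_[constant] <- 1
  z <- sweep(sweep(as.matrix(x), 2, mu), 2, sd_, "/")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  set.seed(seed)
  forest <- randomForest::randomForest(
    x = z, y = factor(labels), ntree = ntree, mtry = mtry)
  structure(list(forest = forest, center = mu, scale = sd_,
                 constant = names(x)[constant], features = names(x),
                 classes = sort(names(tabl)), seed = seed),
            class = "cell_classifier")
}

#' @export
print.cell_classifier <- function(x, ...) {
  cat(sprintf("cell classifier: random forest, %d trees, %d features\n",
              x$forest$ntree, length(x$features)))
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  if (length(x$constant))
    cat("  constant features:", paste(x$constant, collapse = ", "), "\n")
  invisible(x)
}

#' Predict cell classes
#'
#' Applies the stored mean/variance normalization and the fitted forest.
#' The predicted label is the class of maximum probability, with ties broken
#' alphabetically; prediction is invariant to the column order of `newdata`.
#'
#' @param object a [fit_cell_classifier()] model.
#' @param newdata feature table containing at least the model's feature
#'   columns (extra columns are ignored).
#' @param ... unused.
#' @return list with `class` (character vector) and `prob` (matrix cells x
#'   classes, rows summing to 1).
#' @export
predict.cell_classifier <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object$features, names(newdata))
  if (length(miss))
    stop("missing model feature column(s): ", paste(miss, collapse = ", "))
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  z <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  prob <- stats::predict(object$forest, z, type = "prob")
  prob <- prob[, sort(colnames(prob)), drop = FALSE]
  prob <- prob / rowSums(prob)
  cls <- colnames(prob)[apply(prob, 1, which.max)]
  list(class = cls, prob = prob)
}

#' Classification performance against a truth labelling
#'
#' @param predicted,truth equal-length label vectors over the same class set.
#' @param classes the class set; defaults to the union of observed labels.
#' @return list with `accuracy`, `confusion` (rows = truth, columns =
#'   prediction) and `by_class` (precision, recall, F1 per class).
#' @export
evaluate_classifier <- function(predicted, truth, classes = NULL) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  if (is.null(classes)) classes <- sort(union(predicted, truth))
  out_of_set <- setdiff(union(predicted, truth), classes)
  if (length(out_of_set))
    stop("label(s) outside the class set: ", paste(out_of_set, collapse = ", "))
  cm <- table(factor(truth, classes), factor(predicted, classes))
  acc <- sum(diag(cm)) / sum(cm)
  prec <- diag(cm) / pmax(colSums(cm), 0)
  rec <- diag(cm) / pmax(rowSums(cm), 0)
  f1 <- 2 * prec * rec / (prec + rec)
  by_class <- data.frame(class = classes, precision = as.numeric(prec),
                         recall = as.numeric(rec), f1 = as.numeric(f1))
  list(accuracy = acc, confusion = cm, by_class = by_class)
}

#' Serialize / restore a cell classifier
#'
#' The model is written as a single file with a format-version header so a
#' stale or foreign file is rejected on read.
#'
#' @param model a `cell_classifier`.
#' @param path file path.
#' @return `write_cell_classifier` returns `path` invisibly;
#'   `read_cell_classifier` returns the model.
#' @export
write_cell_classifier <- function(model, path) {
  stopifnot(inherits(model, "cell_classifier"))
  saveRDS(list(format = "spotCTA-cell-classifier-v1", model = model), path)
  invisible(path)
}

#' @rdname write_cell_classifier
#' @export
read_cell_classifier <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "spotCTA-cell-classifier-v1"))
    stop("not a spotCTA cell-classifier file (missing format header)")
  obj$model
}
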