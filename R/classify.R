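ALGORITHMS <- c("decision_tree", "knn", "naive_bayes", "svm")

validate_training_table <- function(table, class_col, features) {
  if (is.null(table[[class_col]]))
    .stop2("training table has no '", class_col, "' column")
  missing <- setdiff(features, names(table))
  if (length(missing) > 0)
    .stop2("training table lacks feature columns: ",
           paste(missing, collapse = ", "))
  x <- table[, features, drop = FALSE]
  bad <- which(!stats::complete.cases(x) |
                 apply(x, 1, function(r) any(!is.finite(r))))
  if (length(bad) > 0)
    .stop2("non-finite feature values in rows: ",
           paste(head(bad, 10), collapse = ", "))
  y <- table[[class_col]]
  tab <- table(y)
  if (length(tab) < 2)
    .stop2("training needs at least 2 distinct classes")
  if (any(tab < 2))
    .stop2("training needs at least 2 examples per class; short classes: ",
           paste(names(tab)[tab < 2], collapse = ", "))
  invisible(TRUE)
}

zscore_stats <- function(x) {
  mu <- vapply(x, mean, numeric(1))
  sdv <- vapply(x, sd, numeric(1))
  sdv[sdv == 0 | !is.finite(sdv)] <- 1   # constant columns pass through
  list(mu = mu, sd = sdv)
}

apply_zscore <- function(x, stats_) {
  as.data.frame(Map(function(v, m, s) (v - m) / s, x,
                    stats_$mu[names(x)], stats_$sd[names(x)]))
}

#' Train a comet damage-class predictor
#'
#' Fits one of the four classical algorithm families on a labelled
#' feature table: a CART decision tree (Gini impurity), k-nearest
#' neighbours (Euclidean, default `k = 5`), Gaussian naive Bayes (with a
#' small variance floor so features that are constant within a class stay
#' well-defined), or an RBF-kernel SVM (one-vs-one for multiclass).
#' Features are z-scored with training statistics stored in the model;
#' class labels are opaque positive integers, so any number of (sub)
#' classes is supported. Training is deterministic given `seed`.
#'
#' @param table data frame of features plus a class column.
#' @param algorithm `"decision_tree"`, `"knn"`, `"naive_bayes"` or
#'   `"svm"`.
#' @param features feature columns to use (an explicit include-list;
#'   default: the 21 standard features present in `table`).
#' @param class_col name of the class column (default `"class"`).
#' @param hyperparams optional list, e.g. `list(k = 5)` for kNN,
#'   `list(cost = , gamma = )` for SVM, passed through to the backend.
#' @param seed RNG seed controlling any stochastic fitting step.
#' @return Object of class `comet_classifier`.
#' @export
train_classifier <- function(table,
                             algorithm = c("decision_tree", "knn",
                                           "naive_bayes", "svm"),
                             features = NULL, class_col = "class",
                             hyperparams = list(), seed = 1) {
  algorithm <- match.arg(algorithm)
  features <- features %||% intersect(feature_columns(), names(table))
  if (length(features) == 0) .stop2("no feature columns selected")
  validate_training_table(table, class_col, features)
  x <- table[, features, drop = FALSE]
  y <- factor(table[[class_col]])
  stats_ <- zscore_stats(x)
  xz <- apply_zscore(x, stats_)
  fit <- with_seed(seed, switch(algorithm,
    decision_tree = {
      df <- cbind(xz, .class = y)
      rpart::rpart(.class ~ ., data = df, method = "class",
                   parms = list(split = "gini"))
    },
    knn = list(train = as.matrix(xz), labels = y,
               k = hyperparams$k %||% 5),
    naive_bayes = {
      m <- e1071::naiveBayes(xz, y)
      # variance floor: zero within-class spread (e.g. tail features in
      # class 1) would otherwise give degenerate Gaussian densities
      m$tables <- lapply(m$tables, function(tb) {
        tb[, 2] <- pmax(tb[, 2], 1e-3); tb
      })
      m
    },
    svm = e1071::svm(as.matrix(xz), y, kernel = "radial",
                     cost = hyperparams$cost %||% 1,
                     gamma = hyperparams$gamma %||% (1 / length(features)),
                     scale = FALSE)
  ))
  structure(list(algorithm = algorithm, fit = fit, schema = features,
                 class_col = class_col, normalization = stats_,
                 levels = levels(y), seed = seed,
                 version = as.character(utils::packageVersion("cometrics"))),
            class = "comet_classifier")
}

#' @export
print.comet_classifier <- function(x, ...) {
  cat(sprintf("comet_classifier: %s on %d features, classes {%s}\n",
              x$algorithm, length(x$schema),
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Predict damage classes for new comets
#'
#' @param object a `comet_classifier`.
#' @param newdata data frame containing the model's feature columns
#'   (extra columns are ignored; missing ones are an error).
#' @param type `"class"` for integer labels, `"score"` for per-class
#'   scores where the algorithm provides them (tree and naive Bayes:
#'   posterior probabilities; SVM: decision values; kNN: vote fraction of
#'   the winning class).
#' @param ... unused.
#' @return Integer labels (only labels seen in training can occur), or a
#'   score matrix.
#' @export
predict.comet_classifier <- function(object, newdata, type = "class", ...) {
  missing <- setdiff(object$schema, names(newdata))
  if (length(missing) > 0)
    .stop2("feature schema mismatch; missing columns: ",
           paste(missing, collapse = ", "))
  if (nrow(newdata) == 0) {
    return(if (type == "class") integer(0)
           else matrix(numeric(0), 0, length(object$levels)))
  }
  xz <- apply_zscore(newdata[, object$schema, drop = FALSE],
                     object$normalization)
  out <- with_seed(object$seed, switch(object$algorithm,
    decision_tree = {
      p <- predict(object$fit, xz, type = "prob")
      if (type == "class") colnames(p)[max.col(p, "first")] else p
    },
    knn = {
      cl <- class::knn(object$fit$train, as.matrix(xz),
                       object$fit$labels, k = object$fit$k, prob = TRUE,
                       use.all = TRUE)
      if (type == "class") as.character(cl) else attr(cl, "prob")
    },
    naive_bayes = {
      p <- predict(object$fit, xz, type = "raw", threshold = 1e-9)
      if (type == "class") colnames(p)[max.col(p, "first")] else p
    },
    svm = {
      cl <- predict(object$fit, as.matrix(xz), decision.values = TRUE)
      if (type == "class") as.character(cl)
      else attr(cl, "decision.values")
    }
  ))
  if (type == "class") as.integer(out) else out
}

#' Per-class counts and fractions
#'
#' @param labels vector of class labels.
#' @return Data frame with `class`, `count`, `fraction` (fractions sum to
#'   1 for nonempty input); zero rows for empty input.
#' @export
class_statistics <- function(labels) {
  if (length(labels) == 0)
    return(data.frame(class = integer(0), count = integer(0),
                      fraction = numeric(0)))
  tab <- table(labels)
  data.frame(class = as.integer(names(tab)),
             count = as.integer(tab),
             fraction = as.numeric(tab) / length(labels))
}

#' Save / load a trained classifier
#'
#' The model, feature schema, normalization statistics and format version
#' are serialized together; loading a file written by an incompatible
#' version is an explicit error.
#'
#' @param model a `comet_classifier`.
#' @param path file path.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "comet_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "comet_classifier"))
    .stop2("'", path, "' does not contain a comet classifier")
  m
}
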