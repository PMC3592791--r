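## Supervised phenotype classification. Per-cell functional parameters
## (EC50, Hill slope) from filter-accepted cells of pure populations train an
## axis-aligned decision tree (entropy/information-gain splits, minimum leaf
## size 5 — C4.5-like behavior on two numeric features); the tree then
## assigns cells from mixed populations to receptor phenotypes and the class
## fractions report the composition of the culture. EC50 enters the feature
## space as log10 (a monotone transform that leaves axis-aligned splits
## equivalent but makes reported thresholds readable).

phenotypeFeatures <- function(cells, features) {
  need <- sub("^log10_", "", features)
  miss <- setdiff(need, colnames(cells))
  if (length(miss))
    stop("missing feature column(s): ", paste(miss, collapse = ", "))
  out <- as.data.frame(lapply(seq_along(features), function(i) {
    v <- cells[[need[i]]]
    if (grepl("^log10_", features[i])) log10(v) else v
  }))
  names(out) <- features
  if (!all(vapply(out, function(v) all(is.finite(v)), logical(1))))
    stop("features must be finite (check for non-positive EC50)")
  out
}

treeControl <- function() rpart::rpart.control(
  minsplit = 10L, minbucket = 5L, cp = 0.005, xval = 0L,
  maxcompete = 0L, maxsurrogate = 0L, usesurrogate = 0L)

#' Train a decision-tree phenotype classifier with stratified k-fold CV
#'
#' Features default to (log10 EC50, Hill slope). Folds are stratified per
#' class with a fixed seed; for each fold a tree is grown on the remaining
#' data (information-gain splits, minimum leaf size 5) and the held-out cells
#' are predicted, accumulating a confusion matrix and per-class held-out
#' accuracy. The returned model's tree is refit on the full training set.
#'
#' @param train `data.frame` with columns `EC50`, `slope` (and any extra
#'   feature such as `dF`), plus `label`; admit only filter-accepted cells.
#' @param folds number of CV folds (default 10); every class needs at least
#'   this many members.
#' @param seed integer seed fixing the fold assignment.
#' @param features feature columns; prefix `log10_` requests a log10
#'   transform of the corresponding raw column.
#' @return a [PhenotypeModel-class].
#' @examples
#' tr <- rbind(data.frame(EC50 = 10^rnorm(50, 1, .1), slope = 1,
#'                        label = "low"),
#'             data.frame(EC50 = 10^rnorm(50, 3, .1), slope = 1,
#'                        label = "high"))
#' trainClassifier(tr, folds = 5, seed = 1)
#' @export
trainClassifier <- function(train, folds = 10L, seed = 1L,
                            features = c("log10_EC50", "slope")) {
  if (is.null(train$label)) stop("'train' needs a 'label' column")
  label <- factor(as.character(train$label))
  classes <- levels(label)
  if (length(classes) < 2L) stop("at least 2 classes are required")
  tab <- table(label)
  if (any(tab < folds))
    stop("every class needs at least ", folds, " members (",
         paste(names(tab)[tab < folds], collapse = ", "), " too small)")
  X <- phenotypeFeatures(train, features)
  df <- cbind(label = label, X)

  ## stratified fold assignment, deterministic per seed
  set.seed(as.integer(seed))
  fold <- integer(nrow(df))
  for (cl in classes) {
    idx <- which(label == cl)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }

  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(true = classes, predicted = classes))
  for (f in seq_len(folds)) {
    hold <- fold == f
    tr <- rpart::rpart(label ~ ., data = df[!hold, , drop = FALSE],
                       method = "class",
                       parms = list(split = "information"),
                       control = treeControl())
    pred <- predict(tr, df[hold, , drop = FALSE], type = "class")
    confusion <- confusion + unclass(table(factor(label[hold], classes),
                                           factor(pred, classes)))
  }
  cvAcc <- diag(confusion) / rowSums(confusion)

  full <- rpart::rpart(label ~ ., data = df, method = "class",
                       parms = list(split = "information"),
                       control = treeControl())
  new("PhenotypeModel", tree = full, features = features, classes = classes,
      folds = as.integer(folds), seed = as.integer(seed),
      cvAccuracy = cvAcc, confusion = confusion)
}

#' Classify cells with a trained phenotype model
#'
#' @param model a [PhenotypeModel-class].
#' @param cells `data.frame` with the raw feature columns the model was
#'   trained on (`EC50`, `slope`, ...).
#' @return a list: `labels` (character, one per cell) and `fractions`
#'   (named numeric over all model classes; `NA` for empty input).
#' @examples
#' tr <- rbind(data.frame(EC50 = 10^rnorm(50, 1, .1), slope = 1,
#'                        label = "low"),
#'             data.frame(EC50 = 10^rnorm(50, 3, .1), slope = 1,
#'                        label = "high"))
#' m <- trainClassifier(tr, folds = 5, seed = 1)
#' classifyCells(m, data.frame(EC50 = c(10, 1000), slope = 1))$labels
#' @export
classifyCells <- function(model, cells) {
  stopifnot(is(model, "PhenotypeModel"))
  if (nrow(cells) == 0L) {
    return(list(labels = character(),
                fractions = stats::setNames(rep(NA_real_,
                                                length(model@classes)),
                                            model@classes)))
  }
  X <- phenotypeFeatures(cells, model@features)
  labels <- as.character(predict(model@tree, X, type = "class"))
  counts <- table(factor(labels, model@classes))
  list(labels = labels,
       fractions = stats::setNames(as.numeric(counts) / length(labels),
                                   model@classes))
}

#' Serialize a phenotype model to JSON
#'
#' Writes the tree as a flat node list (node id, split feature and
#' threshold, child ids, leaf class and per-class counts) plus the training
#' metadata (features, classes, folds, seed, CV accuracy, confusion
#' matrix). The node ids follow the usual binary heap convention (children
#' of node `i` are `2i` and `2i + 1`).
#'
#' @param model a [PhenotypeModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePhenotypeModel <- function(model, path) {
  fr <- model@tree$frame
  ids <- as.integer(rownames(fr))
  sp <- model@tree$splits
  isLeaf <- fr$var == "<leaf>"
  thr <- rep(NA_real_, nrow(fr))
  dir <- rep(NA_character_, nrow(fr))
  if (!is.null(sp) && nrow(sp)) {
    ## with maxcompete = maxsurrogate = 0, splits rows follow the internal
    ## nodes in frame order
    thr[!isLeaf] <- sp[, "index"]
    dir[!isLeaf] <- ifelse(sp[, "ncat"] < 0, "left_if_less", "left_if_ge")
  }
  counts <- fr$yval2[, 1 + seq_along(model@classes), drop = FALSE]
  colnames(counts) <- model@classes
  nodes <- lapply(seq_len(nrow(fr)), function(i) {
    list(id = ids[i],
         leaf = isLeaf[i],
         var = if (isLeaf[i]) NULL else as.character(fr$var[i]),
         threshold = if (isLeaf[i]) NULL else thr[i],
         direction = if (isLeaf[i]) NULL else dir[i],
         children = if (isLeaf[i]) NULL else c(2L * ids[i], 2L * ids[i] + 1L),
         class = model@classes[fr$yval[i]],
         counts = as.list(counts[i, ]))
  })
  obj <- list(features = model@features, classes = model@classes,
              folds = model@folds, seed = model@seed,
              cv_accuracy = as.list(model@cvAccuracy),
              confusion = model@confusion,
              nodes = nodes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
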