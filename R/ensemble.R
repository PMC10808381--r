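# The 13 classifier families of the consensus. Each entry fits on a data
# frame with a `.class` factor (levels non-salt, salt) and standardized
# feature columns, and predicts hard labels. Families without an installed
# equivalent (KStar, LWL) are implemented as nearest-neighbour voters
# below. ZeroR (majority class) exists as a baseline via zero_rule() but
# is never part of the consensus.

fit_kstar <- function(df) {
  list(x = as.matrix(df[setdiff(names(df), ".class")]), y = df$.class)
}

cross_dist <- function(a, b) {
  # euclidean distances, rows of a x rows of b
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

predict_kstar <- function(m, nd) {
  x <- as.matrix(nd)
  d <- cross_dist(x, m$x)
  lev <- levels(m$y)
  out <- apply(d, 1, function(di) {
    b <- max(stats::median(di), 1e-8)
    w <- exp(-di / b)
    s <- sum(w[m$y == lev[2]])
    n <- sum(w[m$y == lev[1]])
    if (s > n) lev[2] else lev[1]
  })
  factor(out, levels = lev)
}

fit_lwl <- function(df) {
  list(x = as.matrix(df[setdiff(names(df), ".class")]), y = df$.class,
       k = min(50L, nrow(df)))
}

predict_lwl <- function(m, nd) {
  x <- as.matrix(nd)
  d <- cross_dist(x, m$x)
  lev <- levels(m$y)
  out <- apply(d, 1, function(di) {
    ord <- order(di)[seq_len(m$k)]
    dk <- di[ord[m$k]] + 1e-8
    w <- pmax(1 - di[ord] / dk, 1e-8)
    s <- sum(w[m$y[ord] == lev[2]])
    n <- sum(w[m$y[ord] == lev[1]])
    if (s > n) lev[2] else lev[1]
  })
  factor(out, levels = lev)
}

feature_frame <- function(df) df[setdiff(names(df), ".class")]

.algorithms <- list(
  NaiveBayes = list(
    fit = function(df) e1071::naiveBayes(.class ~ ., data = df),
    predict = function(m, nd) predict(m, nd, type = "class",
                                      threshold = 0.001)
  ),
  MultilayerPerceptron = list(
    fit = function(df) nnet::nnet(.class ~ ., data = df, size = 6,
                                  decay = 5e-3, maxit = 300, trace = FALSE),
    predict = function(m, nd) {
      p <- as.vector(predict(m, nd, type = "raw"))
      factor(ifelse(p > 0.5, "salt", "non-salt"), levels = CONDITION_LEVELS)
    }
  ),
  SMO = list(
    fit = function(df) kernlab::ksvm(.class ~ ., data = df,
                                     kernel = "rbfdot", C = 1,
                                     scaled = FALSE),
    predict = function(m, nd) predict(m, nd)
  ),
  IBk = list(
    fit = function(df) list(x = as.matrix(feature_frame(df)),
                            y = df$.class),
    predict = function(m, nd) class::knn(m$x, as.matrix(nd), m$y, k = 1,
                                         use.all = TRUE)
  ),
  KStar = list(fit = fit_kstar, predict = predict_kstar),
  LWL = list(fit = fit_lwl, predict = predict_lwl),
  DecisionStump = list(
    fit = function(df) rpart::rpart(
      .class ~ ., data = df,
      control = rpart::rpart.control(maxdepth = 1, cp = 0, minsplit = 2,
                                     xval = 0)),
    predict = function(m, nd) predict(m, nd, type = "class")
  ),
  HoeffdingTree = list(
    fit = function(df) tree::tree(.class ~ ., data = df),
    predict = function(m, nd) predict(m, nd, type = "class")
  ),
  J48 = list(
    fit = function(df) rpart::rpart(
      .class ~ ., data = df, parms = list(split = "information"),
      control = rpart::rpart.control(cp = 0.01, xval = 0)),
    predict = function(m, nd) predict(m, nd, type = "class")
  ),
  LMT = list(
    fit = function(df) suppressWarnings(
      glm(.class ~ ., data = df, family = binomial())),
    predict = function(m, nd) {
      p <- suppressWarnings(predict(m, nd, type = "response"))
      factor(ifelse(p > 0.5, "salt", "non-salt"), levels = CONDITION_LEVELS)
    }
  ),
  RandomForest = list(
    fit = function(df) randomForest::randomForest(.class ~ ., data = df,
                                                  ntree = 100),
    predict = function(m, nd) predict(m, nd, type = "class")
  ),
  RandomTree = list(
    fit = function(df) ranger::ranger(.class ~ ., data = df, num.trees = 1,
                                      replace = FALSE, sample.fraction = 1,
                                      min.node.size = 1),
    predict = function(m, nd) predict(m, nd)$predictions
  ),
  REPTree = list(
    fit = function(df) rpart::rpart(
      .class ~ ., data = df,
      control = rpart::rpart.control(cp = 0.01, xval = 0)),
    predict = function(m, nd) predict(m, nd, type = "class")
  )
)

#' Names of the 13 consensus classifiers
#' @return Character vector of algorithm identifiers.
#' @export
ensemble_algorithms <- function() names(.algorithms)

check_feature_records <- function(records, cols, need_condition = FALSE) {
  missing <- setdiff(cols, names(records))
  if (length(missing)) {
    abort(paste0("Records are missing feature column(s): ",
                 paste(missing, collapse = ", ")),
          class = "seedsalt_input_error")
  }
  if (anyNA(records[cols])) {
    abort("Records contain missing feature values.",
          class = "seedsalt_input_error")
  }
  if (need_condition) {
    if (!"condition" %in% names(records) || anyNA(records$condition)) {
      abort("Training records must carry a 'condition' label for every seed.",
            class = "seedsalt_input_error")
    }
    if (!all(records$condition %in% CONDITION_LEVELS)) {
      abort("Condition labels must be 'salt' or 'non-salt'.",
            class = "seedsalt_input_error")
    }
  }
  invisible(records)
}

#' Train the 13-classifier ensemble
#'
#' Fits one classifier per family on the standardized feature columns of
#' the chosen attribute subset. Every seed inherits its plate's condition
#' label. Feature standardization (zero mean, unit variance; constant
#' columns dropped) is estimated on the training data and stored with the
#' model. Fitting is reproducible for a given `seed`.
#'
#' @param records Labeled seed records: a tibble with the feature columns
#'   of `subset` and a `condition` column (`"salt"` / `"non-salt"`).
#' @param subset Attribute subset: `"all"`, `"morpho"` or `"color"`.
#' @param seed Integer RNG seed.
#' @return An object of class `seed_ensemble`.
#' @export
train_ensemble <- function(records, subset = c("all", "morpho", "color"),
                           seed = 1L) {
  subset <- match.arg(subset)
  cols <- feature_columns(subset)
  check_feature_records(records, cols, need_condition = TRUE)
  y <- factor(records$condition, levels = CONDITION_LEVELS)
  if (dplyr::n_distinct(y) < 2) {
    abort("Training data must contain both salt and non-salt seeds.",
          class = "seedsalt_training_error")
  }
  x <- as.matrix(records[cols])
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  keep <- scale_ > 1e-12
  xs <- scale(x[, keep, drop = FALSE], center = center[keep],
              scale = scale_[keep])
  df <- data.frame(.class = y, xs, check.names = FALSE)
  models <- purrr::imap(.algorithms, function(algo, name) {
    i <- match(name, names(.algorithms))
    withr::with_seed(seed + i, algo$fit(df))
  })
  structure(
    list(models = models, center = center[keep], scale = scale_[keep],
         subset = subset, columns = cols[keep], seed = seed,
         n_train = nrow(records)),
    class = "seed_ensemble"
  )
}

#' @export
print.seed_ensemble <- function(x, ...) {
  cat(sprintf(
    "<seed_ensemble> 13 classifiers, subset=%s, %d features, %d training seeds\n",
    x$subset, length(x$columns), x$n_train))
  invisible(x)
}

standardize_records <- function(model, records) {
  check_feature_records(records, model$columns)
  x <- as.matrix(records[model$columns])
  xs <- scale(x, center = model$center, scale = model$scale)
  as.data.frame(xs, check.names = FALSE)
}

#' Per-seed labels from every ensemble member
#'
#' @param model A [train_ensemble()] fit.
#' @param records Seed records carrying the model's feature columns.
#' @return Character matrix `13 x n_seeds` of `"salt"` / `"non-salt"`
#'   labels, one row per algorithm.
#' @export
predict_seeds <- function(model, records) {
  stopifnot(inherits(model, "seed_ensemble"))
  if (nrow(records) == 0) {
    return(matrix(character(), nrow = length(.algorithms), ncol = 0,
                  dimnames = list(names(.algorithms), NULL)))
  }
  nd <- standardize_records(model, records)
  out <- purrr::imap(.algorithms, function(algo, name) {
    i <- match(name, names(.algorithms))
    pred <- withr::with_seed(model$seed + 1000L + i,
                             algo$predict(model$models[[name]], nd))
    as.character(pred)
  })
  matrix(unlist(out), nrow = length(out), byrow = TRUE,
         dimnames = list(names(out), NULL))
}

#' Plate salt status by classifier consensus
#'
#' Each algorithm votes with the percentage of the plate's seeds it labels
#' salt; the consensus is the unweighted mean of the 13 percentages, and
#' the plate is called salt iff the consensus is strictly greater than 50
#' (a consensus of exactly 50 is non-salt).
#'
#' @param label_matrix `13 x n_seeds` label matrix from [predict_seeds()]
#'   for one plate (`n_seeds >= 1`).
#' @param plate Plate identifier for the output row.
#' @return One-row tibble: `plate`, the 13 per-algorithm percentages,
#'   `consensus` and `status`.
#' @export
classify_plate <- function(label_matrix, plate = "plate") {
  if (!is.matrix(label_matrix) || ncol(label_matrix) == 0) {
    abort("Cannot classify a plate with zero seeds.",
          class = "seedsalt_classification_error")
  }
  pct <- rowMeans(label_matrix == "salt") * 100
  consensus <- mean(pct)
  out <- dplyr::bind_cols(
    tibble(plate = plate),
    as_tibble(as.list(pct)),
    tibble(consensus = consensus,
           status = if (consensus > 50) "salt" else "non-salt")
  )
  class(out) <- c("plate_predictions", class(out))
  out
}

#' Classify every plate of a feature table
#'
#' Groups the records by `plate`, predicts per-seed labels with every
#' ensemble member and applies the consensus rule plate by plate.
#'
#' @param model A [train_ensemble()] fit.
#' @param records Seed records with a `plate` column.
#' @return Tibble of class `plate_predictions`, one row per plate.
#' @export
classify_plates <- function(model, records) {
  stopifnot(inherits(model, "seed_ensemble"))
  if (!"plate" %in% names(records)) {
    abort("Records must carry a 'plate' column.",
          class = "seedsalt_input_error")
  }
  labels <- predict_seeds(model, records)
  plates <- unique(records$plate)
  rows <- purrr::map(plates, function(p) {
    classify_plate(labels[, records$plate == p, drop = FALSE], plate = p)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("plate_predictions", class(out))
  out
}

#' ZeroR baseline
#'
#' Predicts the majority class of the training data for every seed. Kept
#' as a reference baseline only; it is never a member of the consensus.
#'
#' @param records Labeled training records (with `condition`).
#' @return Function of a record tibble returning a label vector.
#' @export
zero_rule <- function(records) {
  check_feature_records(records, character(), need_condition = TRUE)
  tab <- table(factor(records$condition, levels = CONDITION_LEVELS))
  majority <- names(tab)[which.max(tab)]
  function(newdata) rep(majority, nrow(newdata))
}
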