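# Organellar-DNA classifier: stratified train/test split, stratified
# k-fold cross-validation over four model families (multinomial logistic
# regression, random forest, k-nearest neighbours, AdaBoost/SAMME over
# small decision trees), selection of the best family by pooled multiclass
# MCC, and deterministic prediction with per-class scores.

.FAMILIES <- c("linear", "random_forest", "knn", "adaboost")
# tie-break precedence when families reach equal CV MCC
.FAMILY_PRECEDENCE <- c("adaboost", "random_forest", "linear", "knn")

# Run code under a fixed seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

.require_labels <- function(table) {
  if (is.null(table$label)) {
    stop("feature table has no labels; use attach_labels()", call. = FALSE)
  }
  factor(table$label, levels = intersect(ORGANELLR_CLASSES, unique(table$label)))
}

# Model matrix: numeric feature columns with length log10-transformed.
.model_frame <- function(table) {
  missing <- setdiff(.model_columns, colnames(table))
  extra <- setdiff(colnames(table), c(.feature_columns, "label"))
  if (length(missing) > 0L || length(extra) > 0L) {
    stop("feature schema mismatch; missing column(s): ",
         paste(missing, collapse = ", "),
         if (length(extra) > 0L) paste0("; unexpected column(s): ",
                                        paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  x <- as.data.frame(table)[, .model_columns, drop = FALSE]
  x$length_bp <- log10(x$length_bp)
  x
}

.fit_scaler <- function(x) {
  center <- vapply(x, mean, numeric(1))
  scale <- vapply(x, stats::sd, numeric(1))
  scale[!is.finite(scale) | scale == 0] <- 1
  list(columns = colnames(x), center = center, scale = scale)
}

.apply_scaler <- function(x, scaler) {
  x <- x[, scaler$columns, drop = FALSE]
  as.data.frame(scale(x, center = scaler$center, scale = scaler$scale))
}

.class_weights <- function(y, mode = c("balanced", "none")) {
  mode <- match.arg(mode)
  k <- nlevels(y)
  if (mode == "none") return(setNames(rep(1, k), levels(y)))
  n_c <- table(y)
  w <- length(y) / (k * as.numeric(n_c))
  setNames(w, names(n_c))
}

#' Stratified train/test split
#'
#' Splits a labeled feature table into disjoint, exhaustive train and test
#' parts, preserving class proportions within one member per class.
#' Deterministic given the seed. With the default `test_fraction` of 5/6
#' the training-to-test ratio is 1:5.
#'
#' @param table Labeled feature table (with a `label` column).
#' @param test_fraction Fraction of each class sent to the test part.
#' @param seed Integer RNG seed.
#' @return List with elements `train` and `test`, both labeled tables.
#' @export
stratified_split <- function(table, test_fraction = 5 / 6, seed) {
  y <- .require_labels(table)
  small <- names(which(table(y) < 2L))
  if (length(small) > 0L) {
    stop("class(es) with fewer than 2 members cannot be split: ",
         paste(small, collapse = ", "),
         " (consider the balanced class-weighting mode on more data)",
         call. = FALSE)
  }
  if (nlevels(y) < 2L) {
    stop("need at least two classes to split", call. = FALSE)
  }
  test_idx <- .with_seed(seed, {
    unlist(lapply(levels(y), function(cl) {
      idx <- which(y == cl)
      n_test <- round(length(idx) * test_fraction)
      n_test <- min(max(n_test, 1L), length(idx) - 1L)  # both sides non-empty
      sample(idx, n_test)
    }), use.names = FALSE)
  })
  list(train = table[-test_idx, , drop = FALSE],
       test = table[test_idx, , drop = FALSE])
}

# Stratified fold ids (1..k) per row, deterministic given seed.
.stratified_folds <- function(y, k, seed) {
  .with_seed(seed, {
    fold <- integer(length(y))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

## ---- model families ------------------------------------------------------

.fit_one <- function(family, x, y, case_w, seed) {
  df <- cbind(x, .label = y)
  switch(family,
    linear = {
      fit <- .with_seed(seed, nnet::multinom(
        .label ~ ., data = df, weights = case_w, trace = FALSE, maxit = 300))
      fit$call <- NULL
      environment(fit$terms) <- baseenv()
      list(family = family, fit = fit, levels = levels(y))
    },
    random_forest = {
      fit <- .with_seed(seed, randomForest::randomForest(
        x = x, y = y, ntree = 300,
        classwt = .norm_weights_by_level(case_w, y)))
      fit$call <- NULL
      list(family = family, fit = fit, levels = levels(y))
    },
    knn = {
      list(family = family, train_x = as.matrix(x), train_y = y,
           k = min(5L, nrow(x)), case_w = case_w, levels = levels(y))
    },
    adaboost = {
      list(family = family,
           fit = .with_seed(seed, .fit_adaboost(x, y, case_w)),
           levels = levels(y))
    },
    stop("unknown model family: ", family, call. = FALSE)
  )
}

.norm_weights_by_level <- function(case_w, y) {
  # one weight per class (randomForest classwt); case_w is constant in class
  vapply(levels(y), function(cl) case_w[which(y == cl)[1]], numeric(1))
}

# AdaBoost (SAMME) over shallow rpart trees.
.fit_adaboost <- function(x, y, case_w, n_rounds = 60L, maxdepth = 3L) {
  k <- nlevels(y)
  w <- case_w / sum(case_w)
  learners <- list()
  alphas <- numeric(0)
  df <- cbind(x, .label = y)
  ctrl <- rpart::rpart.control(maxdepth = maxdepth, minsplit = 4L,
                               cp = 0, xval = 0L)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.label ~ ., data = df, weights = w, method = "class",
                        control = ctrl)
    environment(fit$terms) <- baseenv()
    fit$call <- NULL
    pred <- predict(fit, x, type = "class")
    err <- sum(w[pred != y])
    if (err <= 1e-12) {          # perfect learner: take it with a large vote
      learners[[length(learners) + 1L]] <- fit
      alphas <- c(alphas, log(1e12) + log(k - 1))
      break
    }
    if (err >= 1 - 1 / k) {       # no better than chance: stop boosting
      if (length(learners) == 0L) {
        learners[[1L]] <- fit
        alphas <- 0
      }
      break
    }
    alpha <- log((1 - err) / err) + log(k - 1)
    learners[[length(learners) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * as.numeric(pred != y))
    w <- w / sum(w)
  }
  list(learners = learners, alphas = alphas, levels = levels(y))
}

# Per-class score matrix (rows sum to 1) for new data.
.predict_scores_one <- function(model, x) {
  lv <- model$levels
  n <- nrow(x)
  scores <- switch(model$family,
    linear = {
      p <- predict(model$fit, newdata = x, type = "probs")
      if (is.null(dim(p))) {  # two-class fit returns P(second level)
        p <- cbind(1 - p, p)
        colnames(p) <- lv
      }
      p <- as.matrix(p)
      if (n == 1L && nrow(p) != 1L) p <- matrix(p, nrow = 1L,
                                                dimnames = list(NULL, lv))
      p[, lv, drop = FALSE]
    },
    random_forest = {
      p <- predict(model$fit, newdata = x, type = "prob")
      p[, lv, drop = FALSE]
    },
    knn = {
      .knn_scores(model, as.matrix(x))
    },
    adaboost = {
      ab <- model$fit
      acc <- matrix(0, nrow = n, ncol = length(lv),
                    dimnames = list(NULL, lv))
      total <- sum(ab$alphas)
      for (i in seq_along(ab$learners)) {
        cl <- as.character(predict(ab$learners[[i]], x, type = "class"))
        acc[cbind(seq_len(n), match(cl, lv))] <-
          acc[cbind(seq_len(n), match(cl, lv))] + ab$alphas[i]
      }
      if (total > 0) acc / total
      else matrix(1 / length(lv), nrow = n, ncol = length(lv),
                  dimnames = list(NULL, lv))
    },
    stop("unknown model family", call. = FALSE)
  )
  scores <- pmax(scores, 0)
  scores / rowSums(scores)
}

.knn_scores <- function(model, newx) {
  lv <- model$levels
  tx <- model$train_x
  wts <- model$case_w
  k <- model$k
  out <- matrix(0, nrow = nrow(newx), ncol = length(lv),
                dimnames = list(NULL, lv))
  for (i in seq_len(nrow(newx))) {
    d <- sqrt(colSums((t(tx) - newx[i, ])^2))
    nn <- order(d)[seq_len(k)]   # order() breaks distance ties by index
    votes <- tapply(wts[nn], factor(model$train_y[nn], levels = lv), sum)
    votes[is.na(votes)] <- 0
    out[i, ] <- votes / sum(votes)
  }
  out
}

## ---- cross-validation and training ---------------------------------------

#' Stratified k-fold cross-validation over model families
#'
#' Runs stratified k-fold CV on a labeled feature table for each requested
#' model family and reports per-fold and mean pooled multiclass MCC plus
#' mean one-vs-rest MCC for each organellar class. When the smallest class
#' has fewer than `k` members, `k` is lowered to that count with a warning.
#' Deterministic given the seed.
#'
#' @param train Labeled feature table.
#' @param families Character vector of model families among
#'   `"linear"`, `"random_forest"`, `"knn"`, `"adaboost"`.
#' @param k Number of folds.
#' @param seed Integer RNG seed.
#' @param weight_mode Class-imbalance handling: `"balanced"` (classes
#'   weighted inversely to frequency, the default) or `"none"`.
#' @return An `odna_cv_report`: per-family fold/mean MCCs, the chosen fold
#'   count, seed, and the best family.
#' @export
cross_validate <- function(train, families = .FAMILIES, k = 10L, seed,
                           weight_mode = c("balanced", "none")) {
  weight_mode <- match.arg(weight_mode)
  if (length(families) == 0L) stop("no model families given", call. = FALSE)
  bad <- setdiff(families, .FAMILIES)
  if (length(bad) > 0L) stop("unknown model family: ",
                             paste(bad, collapse = ", "), call. = FALSE)
  y <- .require_labels(train)
  if (nlevels(y) < 2L) stop("need at least two classes", call. = FALSE)
  min_class <- min(table(y))
  if (k > min_class) {
    warning(sprintf("k lowered from %d to %d (smallest class has %d members)",
                    k, min_class, min_class), call. = FALSE)
    k <- min_class
  }
  if (k < 2L) stop("smallest class too small for cross-validation", call. = FALSE)

  x <- .model_frame(train)
  fold <- .stratified_folds(y, k, seed)
  org_classes <- intersect(c("mitochondrion", "plastid"), levels(y))

  per_family <- lapply(families, function(fam) {
    fold_mcc <- numeric(k)
    ovr <- matrix(NA_real_, nrow = k, ncol = length(org_classes),
                  dimnames = list(NULL, org_classes))
    for (f in seq_len(k)) {
      tr <- fold != f
      scaler <- .fit_scaler(x[tr, , drop = FALSE])
      xs_tr <- .apply_scaler(x[tr, , drop = FALSE], scaler)
      xs_te <- .apply_scaler(x[!tr, , drop = FALSE], scaler)
      y_tr <- droplevels(y[tr])
      cw <- .class_weights(y_tr, weight_mode)
      model <- .fit_one(fam, xs_tr, y_tr, unname(cw[as.character(y_tr)]),
                        seed = seed + f)
      scores <- .predict_scores_one(model, xs_te)
      pred <- colnames(scores)[max.col(scores, ties.method = "first")]
      truth <- as.character(y[!tr])
      cm <- table(factor(truth, levels = levels(y)),
                  factor(pred, levels = levels(y)))
      fold_mcc[f] <- mcc_multiclass(unclass(as.matrix(cm)))
      for (cl in org_classes) {
        ids <- as.character(seq_along(truth))
        m <- metrics(confusion(setNames(truth, ids), setNames(pred, ids), cl))
        ovr[f, cl] <- m$mcc
      }
    }
    list(fold_mcc = fold_mcc, mean_mcc = mean(fold_mcc),
         ovr_mean_mcc = colMeans(ovr))
  })
  names(per_family) <- families
  mean_mccs <- vapply(per_family, `[[`, numeric(1), "mean_mcc")
  prec <- match(families, .FAMILY_PRECEDENCE)
  best <- families[order(-mean_mccs, prec)][1]
  structure(list(families = families, k = k, seed = seed,
                 weight_mode = weight_mode, per_family = per_family,
                 best_family = best),
            class = "odna_cv_report")
}

#' @export
print.odna_cv_report <- function(x, ...) {
  cat(sprintf("%d-fold stratified CV (seed %d, %s class weights)\n",
              x$k, x$seed, x$weight_mode))
  for (fam in x$families) {
    pf <- x$per_family[[fam]]
    cat(sprintf("  %-14s mean pooled MCC %.4f", fam, pf$mean_mcc))
    if (length(pf$ovr_mean_mcc) > 0L) {
      cat("  [", paste(sprintf("%s %.4f", names(pf$ovr_mean_mcc),
                               pf$ovr_mean_mcc), collapse = ", "), "]")
    }
    cat("\n")
  }
  cat("  best family:", x$best_family, "\n")
  invisible(x)
}

#' Train the best cross-validated family on the full training table
#'
#' Refits the family with the highest pooled CV MCC (ties broken by the
#' fixed precedence adaboost > random_forest > linear > knn) on all of
#' `train`, with per-column standardisation (length log10-transformed
#' first) whose constants are stored in the returned bundle.
#'
#' @param train Labeled feature table.
#' @param cv_report Report from [cross_validate()].
#' @param seed Integer RNG seed for the refit.
#' @return An `odna_model` bundle: fitted model, feature schema with
#'   scaling constants, ordered class labels, training seed, and the CV
#'   report.
#' @export
train_best <- function(train, cv_report, seed = cv_report$seed) {
  stopifnot(inherits(cv_report, "odna_cv_report"))
  y <- .require_labels(train)
  x <- .model_frame(train)
  scaler <- .fit_scaler(x)
  xs <- .apply_scaler(x, scaler)
  cw <- .class_weights(y, cv_report$weight_mode)
  model <- .fit_one(cv_report$best_family, xs, y,
                    unname(cw[as.character(y)]), seed = seed)
  structure(list(model_family = cv_report$best_family, model = model,
                 feature_schema = scaler, class_labels = levels(y),
                 training_seed = as.integer(seed), cv_report = cv_report,
                 bundle_version = FEATURE_SCHEMA_VERSION),
            class = "odna_model")
}

#' @export
print.odna_model <- function(x, ...) {
  cat(sprintf("organellr model: %s over %d features, classes {%s}, seed %d\n",
              x$model_family, length(x$feature_schema$columns),
              paste(x$class_labels, collapse = ", "), x$training_seed))
  invisible(x)
}

#' Predict organellar class per sequence
#'
#' Applies a trained bundle to a feature table whose schema must match the
#' bundle's exactly. Scores per class are in \[0, 1\] and sum to 1; the
#' predicted class is the argmax, ties broken by the fixed class order
#' nuclear, mitochondrion, plastid. Classes absent from training score 0.
#'
#' @param object An `odna_model` bundle.
#' @param table Feature table (labels, if present, are ignored).
#' @param ... Unused.
#' @return Data.frame with `seq_id`, `predicted_class`, `score_nuclear`,
#'   `score_mitochondrion`, `score_plastid`.
#' @export
predict.odna_model <- function(object, table, ...) {
  x <- .model_frame(table)
  if (!identical(colnames(x), object$feature_schema$columns)) {
    stop("feature schema mismatch between table and model bundle", call. = FALSE)
  }
  out <- data.frame(seq_id = table$seq_id,
                    predicted_class = character(nrow(table)),
                    score_nuclear = numeric(nrow(table)),
                    score_mitochondrion = numeric(nrow(table)),
                    score_plastid = numeric(nrow(table)),
                    stringsAsFactors = FALSE)
  if (nrow(table) == 0L) return(out)
  xs <- .apply_scaler(x, object$feature_schema)
  scores <- .predict_scores_one(object$model, xs)
  full <- matrix(0, nrow = nrow(scores), ncol = length(ORGANELLR_CLASSES),
                 dimnames = list(NULL, ORGANELLR_CLASSES))
  full[, colnames(scores)] <- scores
  pred <- ORGANELLR_CLASSES[max.col(full, ties.method = "first")]
  out$predicted_class <- pred
  out$score_nuclear <- full[, "nuclear"]
  out$score_mitochondrion <- full[, "mitochondrion"]
  out$score_plastid <- full[, "plastid"]
  out
}

#' Save / load a model bundle
#'
#' The bundle (fitted model, feature schema and scaling constants, class
#' labels, seed, CV report) is written as a single versioned RDS archive;
#' a reloaded bundle reproduces identical predictions.
#'
#' @param bundle An `odna_model`.
#' @param path Archive path.
#' @return `save_model`: `path` invisibly; `load_model`: the bundle.
#' @export
save_model <- function(bundle, path) {
  stopifnot(inherits(bundle, "odna_model"))
  saveRDS(bundle, path, version = 3)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model archive not found: ", path, call. = FALSE)
  bundle <- readRDS(path)
  if (!inherits(bundle, "odna_model")) {
    stop("not an organellr model archive: ", path, call. = FALSE)
  }
  if (!identical(bundle$bundle_version, FEATURE_SCHEMA_VERSION)) {
    stop("incompatible model archive version", call. = FALSE)
  }
  bundle
}

#' Write predictions as TSV
#'
#' @param predictions Data.frame from [predict.odna_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  tab <- predictions
  for (cn in grep("^score_", colnames(tab), value = TRUE)) {
    tab[[cn]] <- .fmt_num(tab[[cn]])
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
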