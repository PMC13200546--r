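#' Train the Connection Disparity Index (CDI) classifier
#'
#' Fits one or more binary classifiers to the clusterability training set
#' (features -> clusterable yes/no), using a 75%/25% train/test split.
#' Accuracy, precision, recall and F1 are computed on the held-out 25%, and
#' the candidate with the best test F1 is returned. Its calibrated
#' probability output on a new graph is the CDI.
#'
#' @param ts A `cdi_training_set` from [build_training_set()].
#' @param model_kinds Candidates among `"logistic"`, `"svm"`,
#'   `"random_forest"`, `"knn"`, `"gradient_boosting"`, `"mlp"`.
#' @param split_seed Seed for the 75/25 split and the stochastic learners.
#' @param train_fraction Training fraction (default 0.75).
#' @return Object of class `cdi_model` carrying the winning fitted model,
#'   its kind, the binarization threshold `tau`, the feature type, and
#'   `metrics` (one row per candidate).
#' @export
train_cdi <- function(ts, model_kinds = c("logistic", "svm", "random_forest", "knn"),
                      split_seed = 1, train_fraction = 0.75) {
  stopifnot(inherits(ts, "cdi_training_set"))
  kinds <- match.arg(model_kinds,
                     c("logistic", "svm", "random_forest", "knn",
                       "gradient_boosting", "mlp"),
                     several.ok = TRUE)
  if (length(unique(ts$y_bin)) < 2) {
    stop("degenerate labels: training set contains a single class", call. = FALSE)
  }
  n <- nrow(ts$X)
  idx <- with_seed(split_seed, sample.int(n, floor(train_fraction * n)))
  X_tr <- ts$X[idx, , drop = FALSE]; y_tr <- ts$y_bin[idx]
  X_te <- ts$X[-idx, , drop = FALSE]; y_te <- ts$y_bin[-idx]
  if (length(unique(y_tr)) < 2) {
    stop("degenerate labels in the training split", call. = FALSE)
  }
  fits <- list(); rows <- list()
  for (kind in kinds) {
    fit <- with_seed(derive_seed(split_seed, kind),
                     fit_cdi_classifier(kind, X_tr, y_tr))
    prob <- predict_cdi_prob(fit, X_te)
    pred <- as.integer(prob >= 0.5)
    m <- binary_metrics(y_te, pred)
    fits[[kind]] <- fit
    rows[[kind]] <- data.frame(kind = kind, t(m))
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  best <- metrics$kind[which.max(metrics$f1)]
  structure(list(kind = best, fit = fits[[best]], tau = ts$tau,
                 features = ts$features, metrics = metrics,
                 split_seed = split_seed, n_train = nrow(X_tr),
                 n_test = nrow(X_te)),
            class = "cdi_model")
}

fit_cdi_classifier <- function(kind, X, y) {
  df <- data.frame(X, y = factor(y, levels = c(0, 1)))
  fit <- switch(kind,
    logistic = suppressWarnings(  # perfect separation on easy sweeps is fine
      stats::glm(y ~ ., data = df, family = stats::binomial())),
    svm = e1071::svm(y ~ ., data = df, probability = TRUE),
    random_forest = randomForest::randomForest(y ~ ., data = df),
    knn = list(X = X, y = y, k = 5),  # lazy learner: keep the data
    gradient_boosting = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3,
                    eta = 0.3, nthread = 1),
      data = xgboost::xgb.DMatrix(as.matrix(X), label = y), nrounds = 50),
    mlp = nnet::nnet(y ~ ., data = df, size = 8, decay = 1e-3,
                     maxit = 300, trace = FALSE))
  list(kind = kind, fit = fit, feature_names = colnames(X))
}

predict_cdi_prob <- function(model, X) {
  X <- matrix(as.numeric(X), ncol = length(model$feature_names),
              dimnames = list(NULL, model$feature_names))
  df <- as.data.frame(X)
  switch(model$kind,
    logistic = as.numeric(stats::predict(model$fit, newdata = df,
                                         type = "response")),
    svm = {
      p <- stats::predict(model$fit, newdata = df, probability = TRUE)
      as.numeric(attr(p, "probabilities")[, "1"])
    },
    random_forest = as.numeric(stats::predict(model$fit, newdata = df,
                                              type = "prob")[, "1"]),
    knn = {
      pr <- class::knn(model$fit$X, X, factor(model$fit$y, levels = c(0, 1)),
                       k = model$fit$k, prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == "1", win, 1 - win)
    },
    gradient_boosting = as.numeric(stats::predict(model$fit,
                                                  xgboost::xgb.DMatrix(as.matrix(X)))),
    mlp = as.numeric(stats::predict(model$fit, newdata = df, type = "raw")))
}

binary_metrics <- function(y_true, y_pred) {
  tp <- sum(y_pred == 1 & y_true == 1)
  fp <- sum(y_pred == 1 & y_true == 0)
  fn <- sum(y_pred == 0 & y_true == 1)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(accuracy = mean(y_pred == y_true), precision = prec, recall = rec, f1 = f1)
}

#' @export
print.cdi_model <- function(x, ...) {
  cat(sprintf("<cdi_model> %s (tau = %.2f, features = %s)\n", x$kind, x$tau,
              x$features))
  cat(sprintf("held-out metrics (n = %d):\n", x$n_test))
  print(transform(x$metrics, accuracy = round(accuracy, 3),
                  precision = round(precision, 3), recall = round(recall, 3),
                  f1 = round(f1, 3)))
  invisible(x)
}

#' @export
predict.cdi_model <- function(object, newdata, ...) {
  if (inherits(newdata, "igraph") || inherits(newdata, "pag_network")) {
    return(cdi_score(object, newdata))
  }
  predict_cdi_prob(object$fit, newdata)
}

#' CDI score of a graph
#'
#' Extracts the model's feature set from the graph and returns the
#' calibrated probability that the network contains recoverable cluster
#' structure. Values near 1 indicate a clearly clusterable network.
#'
#' @param model A fitted `cdi_model`.
#' @param graph An `igraph` graph or `pag_network`.
#' @return Probability in `[0, 1]`.
#' @export
cdi_score <- function(model, graph) {
  stopifnot(inherits(model, "cdi_model"))
  f <- if (model$features == "cc") cc_features(graph) else
    graph_features_extended(graph)
  p <- predict_cdi_prob(model$fit, matrix(f, nrow = 1,
                                          dimnames = list(NULL, names(f))))
  min(max(as.numeric(p), 0), 1)
}

#' Save / load a CDI model
#'
#' The model directory gets a JSON summary (kind, tau, features, held-out
#' metrics, format version) next to an RDS blob holding the fitted state.
#'
#' @param model A `cdi_model`.
#' @param path Output path (used as a prefix: `path.json` + `path.rds`).
#' @export
write_cdi_model <- function(model, path) {
  meta <- list(format = "pagfusion-cdi/1", kind = model$kind, tau = model$tau,
               features = model$features, metrics = model$metrics)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  saveRDS(model, paste0(path, ".rds"))
  invisible(path)
}

#' @rdname write_cdi_model
#' @export
read_cdi_model <- function(path) {
  readRDS(paste0(path, ".rds"))
}
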