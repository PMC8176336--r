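#' Training configuration for the shallow network
#'
#' Defaults follow the published setup: three fully connected hidden layers
#' of 32/64/24 rectified-linear units, 5000 epochs of full-batch gradient
#' descent at learning rate 0.015, an 80/20 stratified split and 5-fold
#' cross-validation.
#'
#' @param epochs number of full-batch gradient steps (>= 1).
#' @param learning_rate positive step size.
#' @param seed integer seed controlling weight initialization and any
#'   split/fold assignment derived from this config.
#' @param train_fraction fraction of rows in the training split, in (0, 1).
#' @param cv_folds number of cross-validation folds.
#' @param hidden hidden layer sizes.
#' @param momentum classical (heavy-ball) momentum coefficient in \[0, 1).
#'   The default 0 is plain gradient descent, matching the published setup at
#'   its full 5000-epoch budget; a value around 0.9 reaches the same accuracy
#'   in far fewer epochs and is used for reduced training budgets.
#' @param clip_norm global L2 gradient-norm ceiling; gradients larger than
#'   this are rescaled before the update. Heavy-ball momentum on a rectifier
#'   network can oscillate once the loss surface sharpens; clipping keeps the
#'   trajectory bounded. `Inf` disables clipping.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 5000, learning_rate = 0.015, seed = 1L,
                         train_fraction = 0.8, cv_folds = 5,
                         hidden = c(32, 64, 24), momentum = 0,
                         clip_norm = Inf) {
  stopifnot(epochs >= 1, learning_rate > 0,
            train_fraction > 0, train_fraction < 1, cv_folds >= 2,
            momentum >= 0, momentum < 1, clip_norm > 0)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 seed = as.integer(seed), train_fraction = train_fraction,
                 cv_folds = as.integer(cv_folds), hidden = as.integer(hidden),
                 momentum = momentum, clip_norm = clip_norm),
            class = "train_config")
}

# He-style scaled normal initialization: W ~ N(0, sqrt(2 / fan_in)), b = 0.
# Appropriate for rectified-linear hidden units; fully determined by the seed.
nn_init <- function(input_dim, hidden, n_classes = 3, seed = 1L) {
  set.seed(seed)
  sizes <- c(input_dim, hidden, n_classes)
  layers <- vector("list", length(sizes) - 1)
  for (l in seq_along(layers)) {
    fan_in <- sizes[l]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * sizes[l + 1], 0, sqrt(2 / fan_in)),
                 fan_in, sizes[l + 1]),
      b = rep(0, sizes[l + 1])
    )
  }
  structure(list(layers = layers, sizes = sizes), class = "hepadose_net")
}

#' Forward pass of the shallow network
#'
#' Deterministic composition of affine maps and rectified-linear activations
#' on the hidden layers; the output layer is affine and returns raw logits in
#' the class order (subtherapeutic, normal, supratherapeutic).
#'
#' @param net a `hepadose_net` (see [train_network()]; also accepts the `net`
#'   element of a fitted model).
#' @param x numeric vector (one input) or matrix (rows = inputs) conforming
#'   to the network's input dimension.
#' @return Matrix of logits, one row per input.
#' @export
nn_forward <- function(net, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != net$sizes[1]) {
    stop(sprintf("input has %d columns; network expects %d", ncol(x), net$sizes[1]))
  }
  a <- x
  nl <- length(net$layers)
  for (l in seq_len(nl)) {
    z <- a %*% net$layers[[l]]$W
    z <- sweep(z, 2, net$layers[[l]]$b, "+")
    a <- if (l < nl) pmax(z, 0) else z
  }
  a
}

# Forward pass retaining hidden activations (for backpropagation).
nn_forward_full <- function(net, x) {
  acts <- vector("list", length(net$layers) + 1)
  acts[[1]] <- x
  nl <- length(net$layers)
  for (l in seq_len(nl)) {
    z <- sweep(acts[[l]] %*% net$layers[[l]]$W, 2, net$layers[[l]]$b, "+")
    acts[[l + 1]] <- if (l < nl) pmax(z, 0) else z
  }
  acts
}

#' Numerically safe softmax over rows of a logit matrix
#'
#' p_i = exp(l_i) / sum_j exp(l_j), computed after subtracting the row
#' maximum (softmax is invariant to a constant shift, so this changes nothing
#' but avoids overflow).
#'
#' @param logits numeric vector (one observation) or matrix (rows =
#'   observations) of finite values.
#' @return Matrix of probabilities, rows summing to 1.
#' @export
nn_softmax <- function(logits) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1)
  if (any(!is.finite(logits))) stop("logits must be finite")
  shifted <- logits - apply(logits, 1, max)
  e <- exp(shifted)
  e / rowSums(e)
}

# Full-batch gradient descent on the mean categorical cross-entropy.
# X: normalized feature matrix; Y: n x 3 one-hot matrix.
nn_fit <- function(X, Y, config) {
  net <- nn_init(ncol(X), config$hidden, ncol(Y), seed = config$seed)
  n <- nrow(X)
  lr <- config$learning_rate
  mom <- if (is.null(config$momentum)) 0 else config$momentum
  clip <- if (is.null(config$clip_norm)) Inf else config$clip_norm
  nl <- length(net$layers)
  vel <- lapply(net$layers, function(l) list(W = l$W * 0, b = l$b * 0))
  for (epoch in seq_len(config$epochs)) {
    acts <- nn_forward_full(net, X)
    P <- nn_softmax(acts[[nl + 1]])
    delta <- (P - Y) / n                    # gradient at the logits
    grads <- vector("list", nl)
    for (l in rev(seq_len(nl))) {
      grads[[l]] <- list(W = crossprod(acts[[l]], delta), b = colSums(delta))
      if (l > 1) {
        delta <- (delta %*% t(net$layers[[l]]$W)) * (acts[[l]] > 0)
      }
    }
    if (is.finite(clip)) {
      gnorm <- sqrt(sum(vapply(grads, function(g) sum(g$W^2) + sum(g$b^2), 0)))
      if (gnorm > clip) grads <- lapply(grads, function(g) {
        list(W = g$W * (clip / gnorm), b = g$b * (clip / gnorm))
      })
    }
    for (l in seq_len(nl)) {
      vel[[l]]$W <- mom * vel[[l]]$W - lr * grads[[l]]$W
      vel[[l]]$b <- mom * vel[[l]]$b - lr * grads[[l]]$b
      net$layers[[l]]$W <- net$layers[[l]]$W + vel[[l]]$W
      net$layers[[l]]$b <- net$layers[[l]]$b + vel[[l]]$b
    }
  }
  net
}

#' Stratified train/test split
#'
#' Each class contributes `round(train_fraction * class size)` rows to the
#' training set, so the class proportions of the full cohort are maintained
#' in both parts. Deterministic for a fixed seed.
#'
#' @param labels factor/character vector of class labels.
#' @param train_fraction fraction in (0, 1).
#' @param seed integer seed.
#' @return A list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 0.8, seed = 1L) {
  labels <- as.character(labels)
  classes <- unique(labels)
  if (any(table(labels) == 0)) stop("every class needs at least one row")
  set.seed(seed)
  train <- integer(0)
  for (cl in sort(classes)) {
    idx <- which(labels == cl)
    n_tr <- round(train_fraction * length(idx))
    train <- c(train, sort(sample(idx, n_tr)))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Stratified cross-validation fold assignment
#'
#' Rows of each class are shuffled and dealt round-robin across folds, so
#' folds are disjoint, exhaustive and as class-balanced as rounding allows.
#'
#' @param labels factor/character vector of class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold ids in 1..k, one per row.
#' @export
make_folds <- function(labels, k = 5, seed = 1L) {
  labels <- as.character(labels)
  if (any(table(labels) < k)) stop("each class needs at least k rows")
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in sort(unique(labels))) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Extract feature matrix (raw scale) and labels from a hepadose_dataset.
dataset_matrix <- function(dataset, features = NULL) {
  if (is.null(features)) features <- dataset$schema$features
  X <- as.matrix(dataset$rows[, features, drop = FALSE])
  storage.mode(X) <- "double"
  y <- factor(as.character(dataset$rows$label), levels = therapeutic_classes())
  list(X = X, y = y, features = features)
}

one_hot_labels <- function(y) {
  Y <- matrix(0, length(y), 3)
  Y[cbind(seq_along(y), as.integer(y))] <- 1
  Y
}

#' Train the shallow network on a preprocessed dataset
#'
#' Fits min-max normalization on the supplied rows (training rows only in
#' split/CV workflows), then minimizes the mean categorical cross-entropy
#' between the softmax outputs and the one-hot labels by full-batch gradient
#' descent for `config$epochs` iterations at `config$learning_rate`. Weight
#' initialization and hence the final weights are fully determined by
#' `config$seed`.
#'
#' @param dataset a `hepadose_dataset` from [preprocess_cohort()].
#' @param config a [train_config()].
#' @param features optional subset of feature columns (used by the ablation
#'   importance analysis).
#' @param rows_idx optional integer indices of the rows to train on (default:
#'   all rows).
#' @return An object of class `hepadose_model`: the network, the fitted
#'   normalization parameters, the feature schema and the training config.
#' @export
train_network <- function(dataset, config, features = NULL, rows_idx = NULL) {
  stopifnot(inherits(dataset, "hepadose_dataset"), inherits(config, "train_config"))
  dm <- dataset_matrix(dataset, features)
  if (is.null(rows_idx)) rows_idx <- seq_len(nrow(dm$X))
  y_tr <- dm$y[rows_idx]
  if (length(unique(y_tr)) < 2) stop("training rows contain a single class")
  cont <- intersect(dataset$schema$continuous, dm$features)
  mm <- fit_minmax(as.data.frame(dm$X[rows_idx, , drop = FALSE]), cont)
  Xn <- normalize_matrix(dm$X[rows_idx, , drop = FALSE], mm)
  net <- nn_fit(Xn, one_hot_labels(y_tr), config)
  structure(list(net = net, minmax = mm, features = dm$features,
                 continuous = cont, dose = dataset$schema$dose,
                 dialect = dataset$schema$dialect, config = config),
            class = "hepadose_model")
}

normalize_matrix <- function(X, mm) {
  for (f in names(mm)) {
    lo <- mm[[f]]["min"]; hi <- mm[[f]]["max"]
    X[, f] <- if (hi > lo) pmin(1, pmax(0, (X[, f] - lo) / (hi - lo))) else 0
  }
  X
}

#' Predicted class probabilities and classes
#'
#' `predict_proba()` applies the model's stored normalization to the raw
#' feature rows and returns the softmax class probabilities;
#' `predict_classes()` returns the arg-max class, with exact ties broken
#' toward the normal class (clinically conservative), then subtherapeutic.
#'
#' @param model a `hepadose_model`.
#' @param rows data frame containing the model's feature columns on the raw
#'   scale, or a numeric matrix.
#' @return `predict_proba()`: matrix of 3 class probabilities per row;
#'   `predict_classes()`: factor of predicted classes.
#' @export
predict_proba <- function(model, rows) {
  stopifnot(inherits(model, "hepadose_model"))
  X <- if (is.matrix(rows)) rows[, model$features, drop = FALSE]
       else as.matrix(rows[, model$features, drop = FALSE])
  storage.mode(X) <- "double"
  P <- nn_softmax(nn_forward(model$net, normalize_matrix(X, model$minmax)))
  colnames(P) <- therapeutic_classes()
  P
}

#' @rdname predict_proba
#' @export
predict_classes <- function(model, rows) {
  P <- predict_proba(model, rows)
  pref <- c(2L, 1L, 3L)  # tie preference: normal, then sub, then supra
  idx <- apply(P[, pref, drop = FALSE], 1, which.max)
  factor(therapeutic_classes()[pref[idx]], levels = therapeutic_classes())
}

#' @export
print.hepadose_model <- function(x, ...) {
  cat(sprintf("shallow network model (%s): layers %s, %d input features\n",
              x$dialect, paste(x$net$sizes, collapse = "-"), length(x$features)))
  invisible(x)
}

#' Stratified k-fold cross-validation of the shallow network
#'
#' For each fold the network is trained from scratch on the remaining folds
#' (normalization refitted on those rows only) and evaluated on the held-out
#' fold. Fold assignment is stratified and seed-deterministic; passing
#' `folds` explicitly pins the assignment across runs, which the ablation
#' importance analysis relies on.
#'
#' @param dataset a `hepadose_dataset`.
#' @param config a [train_config()].
#' @param features optional feature subset.
#' @param folds optional integer fold vector from [make_folds()].
#' @return A list with `fold_metrics` (data frame, one row per fold), `mean`
#'   (named means of the five metrics), `folds`.
#' @export
cross_validate <- function(dataset, config, features = NULL, folds = NULL) {
  dm <- dataset_matrix(dataset, features)
  if (is.null(folds)) folds <- make_folds(dm$y, config$cv_folds, config$seed)
  k <- max(folds)
  res <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    model <- train_network(dataset, config, features = dm$features, rows_idx = tr)
    pred <- predict_classes(model, dm$X[te, , drop = FALSE])
    rep <- compute_metrics(confusion_matrix3(dm$y[te], pred))
    res[[f]] <- cbind(fold = f, as.data.frame(rep))
  }
  fold_metrics <- do.call(rbind, res)
  means <- colMeans(fold_metrics[, c("accuracy", "kappa", "macro_precision",
                                     "macro_recall", "macro_f1")])
  list(fold_metrics = fold_metrics, mean = means, folds = folds)
}

#' Serialize / restore a fitted model as structured text
#'
#' The model file is JSON holding layer sizes, row-major weight matrices and
#' biases, the ordered feature schema and the min-max normalization
#' parameters, so predictions are exactly reproducible across sessions.
#'
#' @param model a `hepadose_model`.
#' @param path file path.
#' @return `write_model()` returns `path` invisibly; `read_model()` returns
#'   the restored `hepadose_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "hepadose_model"))
  obj <- list(
    sizes = model$net$sizes,
    layers = lapply(model$net$layers, function(l) {
      list(W = as.vector(t(l$W)), b = l$b)   # row-major
    }),
    features = model$features,
    continuous = model$continuous,
    minmax = lapply(model$minmax, function(v) list(min = v[["min"]], max = v[["max"]])),
    dose = model$dose,
    dialect = model$dialect,
    config = unclass(model$config)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sizes <- as.integer(obj$sizes)
  layers <- vector("list", length(sizes) - 1)
  for (l in seq_along(layers)) {
    W <- matrix(obj$layers$W[[l]], sizes[l], sizes[l + 1], byrow = TRUE)
    layers[[l]] <- list(W = W, b = obj$layers$b[[l]])
  }
  mm <- lapply(obj$minmax, function(v) c(min = v$min, max = v$max))
  class(mm) <- "minmax_params"
  cfg <- do.call(train_config, obj$config[c("epochs", "learning_rate", "seed",
                                            "train_fraction", "cv_folds", "hidden")])
  structure(list(net = structure(list(layers = layers, sizes = sizes),
                                 class = "hepadose_net"),
                 minmax = mm, features = obj$features,
                 continuous = obj$continuous, dose = obj$dose,
                 dialect = obj$dialect, config = cfg),
            class = "hepadose_model")
}
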