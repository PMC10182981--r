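#' Train the deep feedforward cell classifier
#'
#' Fits a fully connected feedforward network on per-cell feature vectors to
#' assign each cell to one of four categories: tumor, lymphocyte, stromal or
#' other. The architecture follows the published configuration: eight hidden
#' layers and an iteration cap of 100; layer width is configurable (the source
#' does not state it). Features are z-scored internally (parameters stored in
#' the model); training uses ReLU activations, a softmax cross-entropy loss and
#' mini-batch Adam, and is exactly reproducible under `seed`.
#'
#' @param data data frame of labelled cells: a label column plus numeric
#'   feature columns.
#' @param label column name holding the class labels (>= 2 classes required).
#' @param features character vector of feature columns; defaults to all
#'   numeric columns except the label.
#' @param hidden_layers number of hidden layers.
#' @param width units per hidden layer.
#' @param max_iterations training epochs (cap).
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size.
#' @param input_dropout fraction of input features randomly zeroed per batch
#'   during training (inverted dropout). Discourages the network from leaning
#'   on any single correlated feature block (the neighbourhood-smoothed copies
#'   duplicate much of the per-cell signal) and markedly improves
#'   generalisation to cells in unusual neighbourhood contexts.
#' @param weight_decay L2 penalty on the weights (decoupled, AdamW-style).
#' @param seed RNG seed for initialisation, batch shuffling and dropout.
#' @return An object of class `cell_classifier`.
#' @export
train_cell_classifier <- function(data, label = "class", features = NULL,
                                  hidden_layers = 8, width = 64,
                                  max_iterations = 100, learning_rate = 1e-3,
                                  batch_size = 128, input_dropout = 0.2,
                                  weight_decay = 1e-4, seed = 1) {
  tb <- tibble::as_tibble(data)
  if (!label %in% names(tb)) stop("label column '", label, "' not found", call. = FALSE)
  y_raw <- as.character(tb[[label]])
  classes <- intersect(cell_classes(), unique(y_raw))
  if (length(classes) == 0) classes <- sort(unique(y_raw))
  extra <- setdiff(unique(y_raw), classes)
  classes <- c(classes, sort(extra))
  if (length(classes) < 2) {
    stop("training data must contain at least 2 classes", call. = FALSE)
  }
  if (is.null(features)) {
    # prefer the standard feature schema (base + smoothed copies) when present
    base <- intersect(eastils_feature_names(), names(tb))
    smoothed <- grep("_s[0-9]+$", names(tb), value = TRUE)
    smoothed <- smoothed[sub("_s[0-9]+$", "", smoothed) %in%
                           eastils_feature_names()]
    features <- c(base, smoothed)
    if (length(features) == 0) {
      features <- names(tb)[vapply(tb, is.numeric, TRUE)]
      features <- setdiff(features, c(label, "cell", "x_um", "y_um", "pair",
                                      "truth_cell"))
      features <- features[!startsWith(features, "prob_")]
    }
  }
  X <- as.matrix(tb[features])
  if (any(!is.finite(X))) stop("features must be finite", call. = FALSE)
  y <- match(y_raw, classes)
  n <- nrow(X); k <- length(classes)

  center <- colMeans(X)
  scale_ <- apply(X, 2, sd)
  scale_[scale_ < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale_, "/")

  dims <- c(ncol(X), rep(width, hidden_layers), k)
  nlay <- length(dims) - 1L

  with_seed(seed, {
    W <- lapply(seq_len(nlay), function(l)
      matrix(rnorm(dims[l] * dims[l + 1], 0, sqrt(2 / dims[l])),
             dims[l], dims[l + 1]))
    b <- lapply(seq_len(nlay), function(l) rep(0, dims[l + 1]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0L

    onehot <- matrix(0, n, k); onehot[cbind(seq_len(n), y)] <- 1
    bs <- min(batch_size, n)
    for (epoch in seq_len(max_iterations)) {
      ord <- sample.int(n)
      for (s0 in seq(1L, n, by = bs)) {
        ix <- ord[s0:min(n, s0 + bs - 1L)]
        xb <- Xs[ix, , drop = FALSE]; yb <- onehot[ix, , drop = FALSE]
        if (input_dropout > 0) {
          keep_mask <- matrix(rbinom(length(xb), 1, 1 - input_dropout),
                              nrow(xb), ncol(xb))
          xb <- xb * keep_mask / (1 - input_dropout)
        }
        # forward
        acts <- vector("list", nlay + 1L); acts[[1]] <- xb
        for (l in seq_len(nlay)) {
          z <- sweep(acts[[l]] %*% W[[l]], 2, b[[l]], "+")
          acts[[l + 1]] <- if (l < nlay) pmax(z, 0) else z
        }
        zm <- acts[[nlay + 1L]]
        zm <- zm - apply(zm, 1, max)
        p <- exp(zm); p <- p / rowSums(p)
        # backward
        delta <- (p - yb) / nrow(xb)
        for (l in rev(seq_len(nlay))) {
          gW <- crossprod(acts[[l]], delta)
          gb <- colSums(delta)
          if (l > 1L) {
            delta <- (delta %*% t(W[[l]])) * (acts[[l]] > 0)
          }
          mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
          vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
          mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
          vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
        }
        step <- step + 1L
        corr1 <- 1 - b1^step; corr2 <- 1 - b2^step
        for (l in seq_len(nlay)) {
          W[[l]] <- W[[l]] - learning_rate * ((mW[[l]] / corr1) /
            (sqrt(vW[[l]] / corr2) + eps) + weight_decay * W[[l]])
          b[[l]] <- b[[l]] - learning_rate * (mb[[l]] / corr1) /
            (sqrt(vb[[l]] / corr2) + eps)
        }
      }
    }

    model <- structure(
      list(weights = W, biases = b, center = center, scale = scale_,
           features = features, classes = classes,
           config = list(hidden_layers = hidden_layers, width = width,
                         max_iterations = max_iterations,
                         learning_rate = learning_rate,
                         batch_size = bs, input_dropout = input_dropout,
                         weight_decay = weight_decay, seed = seed)),
      class = "cell_classifier")
    pr <- predict_proba(model, X)
    model$training_accuracy <- mean(max.col(pr, ties.method = "first") == y)
    model$n_train <- n
    model
  })
}

# forward pass on raw (unscaled) feature matrix -> probability matrix
predict_proba <- function(model, X) {
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  a <- Xs
  nlay <- length(model$weights)
  for (l in seq_len(nlay)) {
    z <- sweep(a %*% model$weights[[l]], 2, model$biases[[l]], "+")
    a <- if (l < nlay) pmax(z, 0) else z
  }
  a <- a - apply(a, 1, max)
  p <- exp(a)
  p / rowSums(p)
}

#' @export
print.cell_classifier <- function(x, ...) {
  cat(sprintf(paste0("<cell_classifier> %d features -> %d hidden layers x %d",
                     " -> %d classes\n"),
              length(x$features), x$config$hidden_layers, x$config$width,
              length(x$classes)))
  cat(sprintf("  training accuracy %.3f on %d cells\n",
              x$training_accuracy, x$n_train))
  invisible(x)
}

#' @export
glance.cell_classifier <- function(x, ...) {
  tibble::tibble(n_train = x$n_train, n_features = length(x$features),
                 hidden_layers = x$config$hidden_layers,
                 width = x$config$width,
                 max_iterations = x$config$max_iterations,
                 training_accuracy = x$training_accuracy)
}

#' @export
tidy.cell_classifier <- function(x, ...) {
  tibble::tibble(layer = seq_along(x$weights),
                 inputs = vapply(x$weights, nrow, 0L),
                 units = vapply(x$weights, ncol, 0L),
                 n_parameters = vapply(x$weights, length, 0L) +
                   vapply(x$biases, length, 0L))
}

#' Classify cells with a trained model
#'
#' Scores every cell, stores the class probabilities (`prob_<class>` columns,
#' summing to 1) and assigns the argmax label; exact probability ties are
#' broken by the canonical class order (tumor, lymphocyte, stromal, other).
#'
#' @param data a [cell_set] or a tibble of cells carrying the model's feature
#'   columns (an unknown schema is an error).
#' @param model a [train_cell_classifier()] fit.
#' @return The input with `class` and probability columns filled.
#' @export
classify_cells <- function(data, model) {
  stopifnot(inherits(model, "cell_classifier"))
  tb <- if (inherits(data, "cell_set")) data$cells else tibble::as_tibble(data)
  missing <- setdiff(model$features, names(tb))
  if (length(missing)) {
    stop("feature schema mismatch; missing: ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ..." else "", call. = FALSE)
  }
  if (nrow(tb) == 0) {
    tb$class <- factor(character(), levels = model$classes)
    for (cl in model$classes) tb[[paste0("prob_", cl)]] <- numeric(0)
  } else {
    p <- predict_proba(model, as.matrix(tb[model$features]))
    # order columns canonically before the argmax so ties resolve by class order
    ord <- match(intersect(cell_classes(), model$classes), model$classes)
    ord <- c(ord, setdiff(seq_along(model$classes), ord))
    p <- p[, ord, drop = FALSE]
    classes <- model$classes[ord]
    lab <- classes[max.col(p, ties.method = "first")]
    tb$class <- factor(lab, levels = classes)
    for (j in seq_along(classes)) tb[[paste0("prob_", classes[j])]] <- p[, j]
  }
  if (inherits(data, "cell_set")) {
    data$cells <- tb
    data
  } else {
    tb
  }
}

#' Slide-level classification quality control
#'
#' Compares predicted labels against reference labels for the same cells and
#' applies the exclusion rule: a slide fails QC when more than 10% of its
#' cells are misclassified (a fraction of exactly 0.10 passes).
#'
#' @param predicted,reference vectors of class labels for the same cell set
#'   (equal length, non-empty).
#' @param max_fraction exclusion threshold (default 0.10).
#' @return One-row tibble: `n_cells`, `n_misclassified`, `fraction`, `pass`.
#' @export
qc_slide <- function(predicted, reference, max_fraction = 0.10) {
  if (length(predicted) != length(reference)) {
    stop("predicted and reference must describe the same cells", call. = FALSE)
  }
  n <- length(predicted)
  if (n == 0) stop("empty cell set: QC undefined", call. = FALSE)
  bad <- sum(as.character(predicted) != as.character(reference))
  tibble::tibble(n_cells = n, n_misclassified = bad, fraction = bad / n,
                 pass = bad / n <= max_fraction)
}

#' Serialize / restore a cell classifier
#'
#' Writes the full model (weights, scaling, schema, config) as portable JSON.
#'
#' @param model a `cell_classifier`.
#' @param path file path.
#' @return `write_classifier` returns `path` invisibly; `read_classifier`
#'   returns the model.
#' @export
write_classifier <- function(model, path) {
  payload <- list(
    weight_dims = lapply(model$weights, dim),
    weight_data = lapply(model$weights, as.numeric),
    biases = model$biases, center = model$center, scale = model$scale,
    features = model$features, classes = model$classes,
    config = model$config, training_accuracy = model$training_accuracy,
    n_train = model$n_train)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  dims <- x$weight_dims
  if (is.matrix(dims)) dims <- lapply(seq_len(nrow(dims)), function(i) dims[i, ])
  W <- mapply(function(d, dat) matrix(dat, d[1], d[2]),
              dims, x$weight_data, SIMPLIFY = FALSE)
  biases <- if (is.list(x$biases)) lapply(x$biases, as.numeric) else
    list(as.numeric(x$biases))
  structure(
    list(weights = W, biases = biases,
         center = setNames(as.numeric(x$center), x$features),
         scale = setNames(as.numeric(x$scale), x$features),
         features = x$features, classes = x$classes,
         config = as.list(x$config),
         training_accuracy = x$training_accuracy, n_train = x$n_train),
    class = "cell_classifier")
}
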