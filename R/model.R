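# Permutation-invariant single-layer convolutional network over multi-cell
# inputs, in the CellCNN lineage: one affine filter bank applied per cell,
# relu, pooling across the cells of an input (mean or max), and a linear
# head (softmax for classification, identity for regression). Training is
# plain minibatch Adam, written out by hand so the whole model fits in a
# few matrix products.

.init_params <- function(n_filters, n_feat, n_out) {
  list(W = matrix(rnorm(n_filters * n_feat, sd = sqrt(2 / n_feat)),
                  n_filters, n_feat),
       b = numeric(n_filters),
       W_out = matrix(rnorm(n_filters * n_out, sd = sqrt(1 / n_filters)),
                      n_filters, n_out),
       b_out = numeric(n_out))
}

# conv + relu + pool for a stacked feature matrix X ((n*K) x M).
# Returns pooled n x F matrix and what the backward pass needs.
.pool_forward <- function(X, W, b, pooling, K, n) {
  pre <- X %*% t(W)
  pre <- sweep(pre, 2, b, "+")
  A <- relu(pre)
  f <- ncol(A)
  if (pooling == "mean") {
    grp <- rep.int(seq_len(n), rep.int(K, n))
    P <- rowsum(A, grp, reorder = FALSE) / K
    list(P = P, A = A, argmax = NULL)
  } else {
    P <- matrix(0, n, f)
    amax <- matrix(0L, n, f)
    for (j in seq_len(f)) {
      m <- matrix(A[, j], nrow = K)
      w <- max.col(t(m), ties.method = "first")
      amax[, j] <- w
      P[, j] <- m[cbind(w, seq_len(n))]
    }
    list(P = P, A = A, argmax = amax)
  }
}

# route dP (n x F) back through pooling to dA ((n*K) x F)
.pool_backward <- function(dP, pooling, K, n, argmax) {
  f <- ncol(dP)
  if (pooling == "mean") {
    dP[rep.int(seq_len(n), rep.int(K, n)), , drop = FALSE] / K
  } else {
    dA <- matrix(0, n * K, f)
    for (j in seq_len(f)) {
      rows <- (seq_len(n) - 1L) * K + argmax[, j]
      dA[rows, j] <- dP[, j]
    }
    dA
  }
}

.softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

.adam_step <- function(state, grads, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    state$par[[nm]] <- state$par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

# loss (and no gradients) on a full set; Y is one-hot for classification
.net_loss <- function(par, X, Y, pooling, K, n, task) {
  fw <- .pool_forward(X, par$W, par$b, pooling, K, n)
  Z <- sweep(fw$P %*% par$W_out, 2, par$b_out, "+")
  if (task == "classification") {
    S <- .softmax(Z)
    -mean(log(pmax(rowSums(S * Y), 1e-12)))
  } else {
    mean((Z[, 1] - Y)^2)
  }
}

# Fit one network. Xtr/Xval are stacked (n*K) x M matrices; ytr/yval are
# integer class indices (classification) or numeric labels (regression).
.fit_net <- function(Xtr, ytr, Xval, yval, K, n_classes, task,
                     n_filters, lr, dropout, pooling,
                     epochs, batch_size, patience, seed) {
  n_tr <- length(ytr)
  n_val <- length(yval)
  n_out <- if (task == "classification") n_classes else 1L
  Ytr <- if (task == "classification") {
    diag(n_classes)[ytr, , drop = FALSE]
  } else ytr
  Yval <- if (task == "classification") {
    diag(n_classes)[yval, , drop = FALSE]
  } else yval

  withr::with_seed(seed, {
    par <- .init_params(n_filters, ncol(Xtr), n_out)
    zero <- lapply(par, function(p) p * 0)
    state <- list(par = par, m = zero, v = zero, t = 0)
    best <- list(loss = Inf, par = par, epoch = 0L)
    stale <- 0L

    for (epoch in seq_len(epochs)) {
      ord <- sample.int(n_tr)
      for (start in seq(1, n_tr, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n_tr)]
        nb <- length(idx)
        rows <- rep((idx - 1L) * K, each = K) + seq_len(K)
        Xb <- Xtr[rows, , drop = FALSE]
        par <- state$par
        fw <- .pool_forward(Xb, par$W, par$b, pooling, K, nb)
        P <- fw$P
        mask <- NULL
        if (dropout > 0) {
          mask <- matrix((runif(nb * n_filters) > dropout) / (1 - dropout),
                         nb, n_filters)
          P <- P * mask
        }
        Z <- sweep(P %*% par$W_out, 2, par$b_out, "+")
        if (task == "classification") {
          S <- .softmax(Z)
          dZ <- (S - Ytr[idx, , drop = FALSE]) / nb
        } else {
          dZ <- matrix(2 * (Z[, 1] - Ytr[idx]) / nb, ncol = 1)
        }
        dW_out <- crossprod(P, dZ)
        db_out <- colSums(dZ)
        dP <- dZ %*% t(par$W_out)
        if (!is.null(mask)) dP <- dP * mask
        dA <- .pool_backward(dP, pooling, K, nb, fw$argmax)
        dA <- dA * (fw$A > 0)
        dW <- crossprod(dA, Xb)
        db <- colSums(dA)
        state <- .adam_step(state,
                            list(W = dW, b = db,
                                 W_out = dW_out, b_out = db_out), lr)
      }
      val_loss <- .net_loss(state$par, Xval, Yval, pooling, K, n_val, task)
      if (!is.finite(val_loss)) stop("non-finite validation loss")
      if (val_loss < best$loss - 1e-9) {
        best <- list(loss = val_loss, par = state$par, epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= patience) break
      }
    }
    best
  })
}

# stack the feature list-column of an mc_inputs subset
.stack_features <- function(inputs) {
  do.call(rbind, inputs$features)
}

.score_set <- function(par, inputs, K, task, classes, pooling) {
  if (nrow(inputs) == 0) return(list(score = NA_real_, rmse = NA_real_))
  X <- .stack_features(inputs)
  fw <- .pool_forward(X, par$W, par$b, pooling, K, nrow(inputs))
  Z <- sweep(fw$P %*% par$W_out, 2, par$b_out, "+")
  if (task == "classification") {
    pred <- classes[max.col(Z, ties.method = "first")]
    list(score = mean(pred == inputs$label), rmse = NA_real_)
  } else {
    m <- regression_metrics(as.numeric(inputs$label), Z[, 1])
    list(score = m$r2, rmse = m$rmse)
  }
}

#' Train the permutation-invariant niche classifier or regressor
#'
#' Runs a random hyperparameter search (number of filters, learning rate,
#' dropout) over `n_trials` independently trained single-layer networks and
#' keeps the model with the best validation score (accuracy for
#' classification, R-squared for regression). Held-out test samples, if the
#' split defines any, are scored once with the winning model. Training uses
#' minibatch Adam with early stopping on validation loss; trials whose loss
#' diverges are dropped from model selection rather than scored zero.
#'
#' @param inputs An `mc_inputs` tibble. If it has no `set` column, `split`
#'   is used to assign one via [assign_sets()].
#' @param split A [make_split()] result (ignored when `inputs` already has a
#'   `set` column).
#' @param task `"classification"` (categorical labels) or `"regression"`
#'   (numeric labels).
#' @param n_trials Number of random-search trials (default 200).
#' @param seed Integer seed controlling the search, initialisations and
#'   batch order; results are reproducible under it.
#' @param pooling `"mean"` (default) or `"max"` pooling across cells.
#' @param search Search space: `n_filters` (integer choices),
#'   `learning_rate` (range, sampled log-uniformly) and `dropout` (choices).
#' @param epochs,batch_size,patience Optimisation settings.
#' @return A `niche_fit` object: `$model` (the winning `niche_model`),
#'   `$report` (one row per trial), `$val_score`, `$test_score` and, for
#'   regression, `$test_rmse`. Use [tidy()] and [glance()] to inspect it.
#' @export
niche_train <- function(inputs, split = NULL,
                       task = c("classification", "regression"),
                       n_trials = 200, seed = 1L,
                       pooling = c("mean", "max"),
                       search = list(n_filters = 1:8,
                                     learning_rate = c(1e-4, 1e-2),
                                     dropout = c(0, 0.25, 0.5)),
                       epochs = 50, batch_size = 64, patience = 5) {
  task <- match.arg(task)
  pooling <- match.arg(pooling)
  if (!"set" %in% names(inputs)) {
    if (is.null(split)) {
      abort("inputs carry no 'set' column and no split was given")
    }
    inputs <- assign_sets(inputs, split)
  }
  K <- attr(inputs, "k")
  feature_markers <- attr(inputs, "feature_markers")

  tr <- inputs[inputs$set == "train", ]
  va <- inputs[inputs$set == "validation", ]
  te <- inputs[inputs$set == "test", ]
  if (nrow(tr) == 0 || nrow(va) == 0) {
    abort("training and validation sets must both be non-empty")
  }

  if (task == "classification") {
    classes <- sort(unique(as.character(inputs$label)))
    ytr <- match(as.character(tr$label), classes)
    yval <- match(as.character(va$label), classes)
    if (length(unique(ytr)) < 2) {
      abort("training labels contain a single class",
            class = "cytoniche_domain_error")
    }
  } else {
    classes <- NULL
    ytr <- as.numeric(tr$label)
    yval <- as.numeric(va$label)
    if (sd(ytr) == 0) {
      abort("regression labels have zero variance",
            class = "cytoniche_domain_error")
    }
  }
  Xtr <- .stack_features(tr)
  Xval <- .stack_features(va)
  n_classes <- length(classes)

  hp <- withr::with_seed(derive_seed(seed, "search"), {
    tibble::tibble(
      trial = seq_len(n_trials),
      n_filters = sample(search$n_filters, n_trials, replace = TRUE),
      learning_rate = 10^runif(n_trials,
                               log10(search$learning_rate[1]),
                               log10(search$learning_rate[2])),
      dropout = sample(search$dropout, n_trials, replace = TRUE)
    )
  })

  fits <- vector("list", n_trials)
  val_scores <- rep(NA_real_, n_trials)
  failed <- rep(FALSE, n_trials)
  for (t in seq_len(n_trials)) {
    res <- tryCatch(
      .fit_net(Xtr, ytr, Xval, yval, K, n_classes, task,
               hp$n_filters[t], hp$learning_rate[t], hp$dropout[t], pooling,
               epochs, batch_size, patience,
               seed = derive_seed(seed, paste0("trial", t))),
      error = function(e) NULL)
    if (is.null(res)) {
      failed[t] <- TRUE
      warn(paste0("trial ", t, " failed and was excluded from selection"))
      next
    }
    fits[[t]] <- res$par
    s <- .score_set(res$par, va, K, task, classes, pooling)
    val_scores[t] <- s$score
  }
  if (all(is.na(val_scores))) abort("every training trial failed")
  best_trial <- which.max(val_scores)

  par <- fits[[best_trial]]
  model <- structure(
    list(W = par$W, b = par$b, W_out = par$W_out, b_out = par$b_out,
         pooling = pooling, task = task, classes = classes,
         feature_markers = feature_markers, k = K,
         hyperparams = as.list(hp[best_trial,
                                  c("n_filters", "learning_rate", "dropout")]),
         val_score = val_scores[best_trial], seed = as.integer(seed)),
    class = "niche_model")

  test <- .score_set(par, te, K, task, classes, pooling)
  report <- hp
  report$val_score <- val_scores
  report$failed <- failed

  structure(list(model = model, report = report, best_trial = best_trial,
                 val_score = val_scores[best_trial],
                 test_score = test$score, test_rmse = test$rmse,
                 task = task, n_trials = n_trials),
            class = "niche_fit")
}

#' Forward pass of a trained model on one multi-cell input
#'
#' Evaluates the network on a single K x M feature matrix. The output is
#' invariant to any permutation of the rows (cells), because pooling is the
#' only interaction between cells.
#'
#' @param model A `niche_model`.
#' @param input A numeric matrix with one row per cell and one column per
#'   feature marker.
#' @return For classification, a named vector of class probabilities; for
#'   regression, a single numeric prediction.
#' @export
forward <- function(model, input) {
  stopifnot(inherits(model, "niche_model"))
  input <- as.matrix(input)
  if (ncol(input) != ncol(model$W)) {
    abort(paste0("input has ", ncol(input), " feature columns; model expects ",
                 ncol(model$W)))
  }
  fw <- .pool_forward(input, model$W, model$b, model$pooling,
                      K = nrow(input), n = 1L)
  Z <- sweep(fw$P %*% model$W_out, 2, model$b_out, "+")
  if (model$task == "classification") {
    p <- drop(.softmax(Z))
    names(p) <- model$classes
    p
  } else {
    unname(Z[1, 1])
  }
}

#' Predict labels for many multi-cell inputs
#'
#' @param object A `niche_model`.
#' @param inputs An `mc_inputs` tibble (feature dimensions must match).
#' @param ... Unused.
#' @return A tibble with `input_id` and, for classification, `.pred_class`
#'   plus one probability column per class; for regression, `.pred`.
#' @export
predict.niche_model <- function(object, inputs, ...) {
  X <- .stack_features(inputs)
  K <- attr(inputs, "k")
  fw <- .pool_forward(X, object$W, object$b, object$pooling,
                      K = K, n = nrow(inputs))
  Z <- sweep(fw$P %*% object$W_out, 2, object$b_out, "+")
  if (object$task == "classification") {
    S <- .softmax(Z)
    colnames(S) <- object$classes
    out <- tibble::tibble(
      input_id = inputs$input_id,
      .pred_class = object$classes[max.col(Z, ties.method = "first")])
    dplyr::bind_cols(out, tibble::as_tibble(S))
  } else {
    tibble::tibble(input_id = inputs$input_id, .pred = Z[, 1])
  }
}

#' Filter response of cells
#'
#' The selection statistic of the method: the scalar product of a cell's
#' marker vector with one trained filter's weights (no bias, no
#' activation). Cells with a positive response are the "selected" subset.
#'
#' @param model A `niche_model`.
#' @param cell_markers A numeric vector of length M (one cell) or a
#'   cells x M matrix.
#' @param filter_index Which filter's weights to use (1-based).
#' @return A numeric response per cell.
#' @export
filter_response <- function(model, cell_markers, filter_index = 1L) {
  stopifnot(inherits(model, "niche_model"))
  if (filter_index < 1 || filter_index > nrow(model$W)) {
    abort(paste0("filter_index out of range 1..", nrow(model$W)))
  }
  if (is.null(dim(cell_markers))) {
    cell_markers <- matrix(cell_markers, nrow = 1)
  }
  if (ncol(cell_markers) != ncol(model$W)) {
    abort("cell marker dimension does not match the model's filters")
  }
  drop(cell_markers %*% model$W[filter_index, ])
}

#' Regression fit quality: R-squared and RMSE
#'
#' R-squared is one minus the ratio of residual to total sum of squares
#' (total about the mean of `y`); RMSE is the root of the mean squared
#' prediction error.
#'
#' @param y Observed values.
#' @param yhat Predicted values (same length).
#' @return A one-row tibble with `r2` and `rmse`. If `y` is constant,
#'   `r2` is `NA` with a warning (RMSE is still returned).
#' @export
regression_metrics <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) > 0)
  rmse <- sqrt(mean((y - yhat)^2))
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    warn("y is constant; R-squared is undefined")
    r2 <- NA_real_
  } else {
    r2 <- 1 - sum((y - yhat)^2) / ss_tot
  }
  tibble::tibble(r2 = r2, rmse = rmse)
}

#' @export
print.niche_model <- function(x, ...) {
  cat("<niche_model> ", x$task, ", ", nrow(x$W), " filter(s) x ",
      ncol(x$W), " features, ", x$pooling, " pooling, val score ",
      signif(x$val_score, 4), "\n", sep = "")
  invisible(x)
}

#' @export
print.niche_fit <- function(x, ...) {
  cat("<niche_fit> ", x$n_trials, " trials (", sum(x$report$failed),
      " failed); best trial ", x$best_trial, " val score ",
      signif(x$val_score, 4),
      if (!is.na(x$test_score)) paste0(", test score ",
                                       signif(x$test_score, 4)),
      "\n", sep = "")
  invisible(x)
}

#' Tidy the filter weights of a trained model
#' @param x A `niche_model`.
#' @param ... Unused.
#' @return A tibble with one row per (filter, marker) weight.
#' @export
tidy.niche_model <- function(x, ...) {
  tibble::tibble(
    filter = rep(seq_len(nrow(x$W)), times = ncol(x$W)),
    marker = rep(x$feature_markers, each = nrow(x$W)),
    weight = as.vector(x$W))
}

#' One-row summary of a trained model
#' @param x A `niche_model`.
#' @param ... Unused.
#' @export
glance.niche_model <- function(x, ...) {
  tibble::tibble(task = x$task, n_filters = nrow(x$W),
                 pooling = x$pooling, k = x$k,
                 learning_rate = x$hyperparams$learning_rate,
                 dropout = x$hyperparams$dropout,
                 val_score = x$val_score)
}

#' Per-trial report of a hyperparameter search
#' @param x A `niche_fit`.
#' @param ... Unused.
#' @export
tidy.niche_fit <- function(x, ...) x$report

#' One-row summary of a hyperparameter search
#' @param x A `niche_fit`.
#' @param ... Unused.
#' @export
glance.niche_fit <- function(x, ...) {
  tibble::tibble(task = x$task, n_trials = x$n_trials,
                 n_failed = sum(x$report$failed),
                 best_trial = x$best_trial,
                 val_score = x$val_score, test_score = x$test_score,
                 test_rmse = x$test_rmse)
}
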