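#' Hyperparameters for penalized models
#'
#' Both model families maximize the penalized log-likelihood
#' `sum_i log p(y_i | x_i) - a1 * ||W||_1 - a2 * ||W||_2^2` by minibatch
#' stochastic gradient ascent, where `W` collects the weight matrices of all
#' layers (biases are unpenalized). An empty `hidden_layers` gives logistic
#' regression; otherwise each hidden layer applies a rectified-linear
#' activation `g(x) = max(0, x)` and, during training only, inverted dropout.
#' The L1 term is applied as a proximal (soft-threshold) update so that
#' weights reach exact zeros, performing implicit feature selection.
#'
#' @param a1 L1 penalty strength (>= 0).
#' @param a2 L2 penalty strength (>= 0).
#' @param hidden_layers integer vector of hidden-layer widths; `integer(0)`
#'   for logistic regression.
#' @param dropout_rate probability of eliding each hidden unit during
#'   training; only meaningful with hidden layers.
#' @param epochs passes over the training data.
#' @param learning_rate initial step size.
#' @param lr_decay multiplicative per-epoch decay of the step size.
#' @param minibatch minibatch size.
#' @param seed integer seed controlling initialisation, shuffling and dropout.
#' @param l2_squared if `TRUE` (default) the L2 term is the conventional
#'   squared elastic-net penalty `a2 * sum(W^2)`; if `FALSE` the unsquared
#'   norm `a2 * sqrt(sum(W^2))` is used.
#' @return a `ward_hp` list.
#' @export
model_hyperparams <- function(a1 = 0.001, a2 = 0.01,
                              hidden_layers = integer(0),
                              dropout_rate = 0,
                              epochs = 30, learning_rate = 0.05,
                              lr_decay = 0.9, minibatch = 32,
                              seed = 1L, l2_squared = TRUE) {
  stopifnot(a1 >= 0, a2 >= 0, dropout_rate >= 0, dropout_rate < 1,
            epochs >= 1, learning_rate > 0, minibatch >= 1)
  if (dropout_rate > 0 && length(hidden_layers) == 0) {
    warning("dropout has no effect without hidden layers")
  }
  structure(
    list(a1 = a1, a2 = a2, hidden_layers = as.integer(hidden_layers),
         dropout_rate = dropout_rate, epochs = as.integer(epochs),
         learning_rate = learning_rate, lr_decay = lr_decay,
         minibatch = as.integer(minibatch), seed = as.integer(seed),
         l2_squared = isTRUE(l2_squared)),
    class = "ward_hp"
  )
}

init_layers <- function(d_in, hidden, init_sd_scale = 1) {
  dims <- c(d_in, hidden, 1L)
  lapply(seq_len(length(dims) - 1L), function(i) {
    fan_in <- dims[i]
    sd0 <- if (i < length(dims) - 1L || length(hidden) > 0) {
      sqrt(2 / fan_in)
    } else {
      0  # logistic regression starts at the uninformative model
    }
    if (length(hidden) == 0) sd0 <- 0
    list(
      W = matrix(rnorm(dims[i] * dims[i + 1L], 0, sd0 * init_sd_scale),
                 dims[i], dims[i + 1L]),
      b = rep(0, dims[i + 1L])
    )
  })
}

# forward pass; returns list of layer inputs (Z[[l]] is the input to layer l)
# and the final linear score s. `masks` (training only) applies inverted
# dropout to hidden activations.
forward_pass <- function(layers, X, masks = NULL) {
  L <- length(layers)
  Z <- vector("list", L)
  A <- X
  for (l in seq_len(L)) {
    Z[[l]] <- A
    lin <- as.matrix(A %*% layers[[l]]$W)
    lin <- sweep(lin, 2, layers[[l]]$b, "+")
    if (l < L) {
      A <- pmax(lin, 0)
      if (!is.null(masks)) A <- A * masks[[l]]
    } else {
      A <- lin
    }
  }
  list(Z = Z, score = as.numeric(A))
}

penalty_value <- function(layers, hp) {
  w <- unlist(lapply(layers, function(l) l$W))
  l2 <- if (hp$l2_squared) sum(w^2) else sqrt(sum(w^2))
  hp$a1 * sum(abs(w)) + hp$a2 * l2
}

#' Penalized log-likelihood of a model on data
#'
#' Computes `sum_i log p(y_i | x_i) - a1 * ||W||_1 - a2 * ||W||_2^2` over all
#' layer weights (biases unpenalized).
#'
#' @param model a fitted `ward_model` (or a bare layer list with an `hp`
#'   attribute as used internally).
#' @param X design matrix (dense or sparse) aligned with the model
#'   vocabulary.
#' @param y binary labels in \{0, 1\}.
#' @return scalar penalized log-likelihood.
#' @export
penalized_log_likelihood <- function(model, X, y) {
  layers <- model$layers
  hp <- model$hp
  s <- forward_pass(layers, X)$score
  ll <- sum(ifelse(y == 1, stats::plogis(s, log.p = TRUE),
                   stats::plogis(-s, log.p = TRUE)))
  ll - penalty_value(layers, hp)
}

# analytic gradient of the penalized log-likelihood w.r.t. all weights and
# biases. L1 uses the sign subgradient (0 at 0); exact only away from zeros,
# which is how the numerical check applies it.
penalized_ll_grad <- function(model, X, y) {
  layers <- model$layers
  hp <- model$hp
  L <- length(layers)
  fw <- forward_pass(layers, X)
  p <- stats::plogis(fw$score)
  delta <- matrix(y - p, ncol = 1)            # d ll / d score
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    Zl <- fw$Z[[l]]
    gW <- as.matrix(Matrix::crossprod(Zl, delta))
    gb <- colSums(delta)
    grads[[l]] <- list(W = gW, b = gb)
    if (l > 1) {
      back <- delta %*% t(layers[[l]]$W)
      lin_prev <- as.matrix(fw$Z[[l]] )
      # relu derivative: activation of layer l-1 was max(0, lin); positive
      # activations identify positive pre-activations
      back[lin_prev <= 0] <- 0
      delta <- back
    }
  }
  # penalty gradients on weights only
  if (hp$l2_squared) {
    for (l in seq_len(L)) {
      grads[[l]]$W <- grads[[l]]$W - hp$a1 * sign(layers[[l]]$W) -
        2 * hp$a2 * layers[[l]]$W
    }
  } else {
    nrm <- sqrt(sum(unlist(lapply(layers, function(x) x$W))^2))
    for (l in seq_len(L)) {
      grads[[l]]$W <- grads[[l]]$W - hp$a1 * sign(layers[[l]]$W) -
        if (nrm > 0) hp$a2 * layers[[l]]$W / nrm else 0
    }
  }
  grads
}

flatten_params <- function(layers) {
  unlist(lapply(layers, function(l) c(as.numeric(l$W), l$b)))
}

unflatten_params <- function(theta, layers) {
  pos <- 1
  for (l in seq_along(layers)) {
    nw <- length(layers[[l]]$W)
    layers[[l]]$W[] <- theta[pos:(pos + nw - 1)]
    pos <- pos + nw
    nb <- length(layers[[l]]$b)
    layers[[l]]$b <- theta[pos:(pos + nb - 1)]
    pos <- pos + nb
  }
  layers
}

#' Train a penalized logistic regression or multilayer perceptron
#'
#' Maximizes the penalized log-likelihood by minibatch stochastic gradient
#' ascent with a step-decay learning rate. The L1 penalty is applied as a
#' proximal soft-threshold after each gradient step so that weights reach
#' exact zeros. Hidden layers use rectified-linear activations with inverted
#' dropout during training; prediction uses the full network unscaled.
#' Training is deterministic under a fixed `hp$seed`.
#'
#' @param instances instance tibble from [build_instances()], or any tibble
#'   with `y` and `features` columns.
#' @param hp a [model_hyperparams()] object.
#' @param vocab optional vocabulary; fit from `instances` when `NULL`.
#' @return a `ward_model` with elements `layers`, `hp`, `vocab`, and
#'   `training_log` (penalized log-likelihood per epoch).
#' @export
train_model <- function(instances, hp = model_hyperparams(), vocab = NULL) {
  stopifnot(all(instances$y %in% c(0L, 1L)))
  if (length(unique(instances$y)) < 2) {
    stop("training data must contain both classes", call. = FALSE)
  }
  vocab <- vocab %||% fit_vocabulary(instances)
  X <- as_instance_matrix(instances, vocab)
  y <- instances$y
  fit <- withr::with_seed(hp$seed, sgd_fit(X, y, hp))
  structure(
    list(layers = fit$layers, hp = hp, vocab = vocab,
         training_log = fit$log),
    class = "ward_model"
  )
}

sgd_fit <- function(X, y, hp) {
  n <- nrow(X)
  layers <- init_layers(ncol(X), hp$hidden_layers)
  L <- length(layers)
  keep <- 1 - hp$dropout_rate
  log_rows <- vector("list", hp$epochs)
  lr <- hp$learning_rate
  for (epoch in seq_len(hp$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = hp$minibatch)) {
      idx <- ord[start:min(start + hp$minibatch - 1, n)]
      Xb <- as.matrix(X[idx, , drop = FALSE])
      yb <- y[idx]
      masks <- NULL
      if (hp$dropout_rate > 0 && L > 1) {
        masks <- lapply(hp$hidden_layers, function(width) {
          matrix(
            (runif(length(idx) * width) < keep) / keep,
            length(idx), width
          )
        })
      }
      layers <- sgd_step(layers, Xb, yb, hp, lr, scale = length(idx) / n,
                         masks = masks)
    }
    model_now <- list(layers = layers, hp = hp)
    log_rows[[epoch]] <- tibble::tibble(
      epoch = epoch,
      penalized_ll = penalized_log_likelihood(model_now, X, y),
      learning_rate = lr
    )
    lr <- lr * hp$lr_decay
  }
  layers <- lapply(layers, function(l) {
    dimnames(l$W) <- NULL
    l
  })
  list(layers = layers, log = dplyr::bind_rows(log_rows))
}

sgd_step <- function(layers, Xb, yb, hp, lr, scale, masks = NULL) {
  L <- length(layers)
  fw <- forward_pass(layers, Xb, masks = masks)
  p <- stats::plogis(fw$score)
  delta <- matrix(yb - p, ncol = 1)
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(
      W = crossprod(fw$Z[[l]], delta),
      b = colSums(delta)
    )
    if (l > 1) {
      back <- delta %*% t(layers[[l]]$W)
      act_prev <- fw$Z[[l]]
      back[act_prev <= 0] <- 0
      if (!is.null(masks)) back <- back * masks[[l - 1]]
      delta <- back
    }
  }
  l2norm <- if (!hp$l2_squared) {
    sqrt(sum(unlist(lapply(layers, function(x) x$W))^2))
  } else {
    NA_real_
  }
  for (l in seq_len(L)) {
    l2grad <- if (hp$l2_squared) {
      2 * hp$a2 * layers[[l]]$W
    } else if (l2norm > 0) {
      hp$a2 * layers[[l]]$W / l2norm
    } else {
      0
    }
    Wnew <- layers[[l]]$W + lr * (as.matrix(grads[[l]]$W) - scale * l2grad)
    # proximal L1: soft threshold toward exact zeros
    thr <- lr * scale * hp$a1
    layers[[l]]$W <- sign(Wnew) * pmax(abs(Wnew) - thr, 0)
    layers[[l]]$b <- layers[[l]]$b + lr * grads[[l]]$b
  }
  layers
}

#' Predict case probabilities
#'
#' Forward pass through the fitted network (no dropout at prediction time).
#' Features absent from the model vocabulary are dropped.
#'
#' @param model a `ward_model`.
#' @param instances instance tibble.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_proba <- function(model, instances) {
  X <- as_instance_matrix(instances, model$vocab)
  stats::plogis(forward_pass(model$layers, X)$score)
}

#' @export
predict.ward_model <- function(object, newdata, ...) {
  dplyr::mutate(newdata, .pred = predict_proba(object, newdata))
}

#' @export
print.ward_model <- function(x, ...) {
  hidden <- if (length(x$hp$hidden_layers) == 0) {
    "logistic regression"
  } else {
    sprintf("MLP (%s hidden units)", paste(x$hp$hidden_layers, collapse = "-"))
  }
  w <- unlist(lapply(x$layers, function(l) l$W))
  cat(sprintf(
    "<ward_model> %s; %d features; a1=%g a2=%g; %.1f%% zero weights\n",
    hidden, nrow(x$vocab), x$hp$a1, x$hp$a2, 100 * mean(w == 0)))
  invisible(x)
}

#' Tidy a fitted model into a weight table
#'
#' For logistic regression, one row per feature plus the intercept
#' (`term`, `estimate`). For a multilayer perceptron, one row per weight with
#' `layer`, `from`, `to` indices; input-layer rows carry the feature name in
#' `term`.
#'
#' @param x a `ward_model`.
#' @param ... unused.
#' @return a tibble.
#' @exportS3Method generics::tidy
tidy.ward_model <- function(x, ...) {
  if (length(x$hp$hidden_layers) == 0) {
    tibble::tibble(
      term = c("(Intercept)", x$vocab$feature),
      estimate = c(x$layers[[1]]$b, as.numeric(x$layers[[1]]$W))
    )
  } else {
    rows <- lapply(seq_along(x$layers), function(l) {
      W <- x$layers[[l]]$W
      ij <- which(W != 0 | TRUE, arr.ind = TRUE)
      tibble::tibble(
        layer = l, from = ij[, 1], to = ij[, 2],
        term = if (l == 1) x$vocab$feature[ij[, 1]] else NA_character_,
        estimate = as.numeric(W)
      )
    })
    dplyr::bind_rows(rows)
  }
}

#' One-row model summary
#'
#' @param x a `ward_model`.
#' @param ... unused.
#' @return tibble with feature count, architecture, penalties, sparsity and
#'   final penalized log-likelihood.
#' @exportS3Method generics::glance
glance.ward_model <- function(x, ...) {
  w <- unlist(lapply(x$layers, function(l) l$W))
  tibble::tibble(
    n_features = nrow(x$vocab),
    n_hidden_layers = length(x$hp$hidden_layers),
    n_weights = length(w),
    a1 = x$hp$a1, a2 = x$hp$a2,
    prop_zero_weights = mean(w == 0),
    final_penalized_ll = utils::tail(x$training_log$penalized_ll, 1)
  )
}

#' Stratified k-fold cross-validation over a hyperparameter grid
#'
#' Selects the hyperparameter setting maximizing mean fold auROC; ties are
#' broken toward stronger regularization (larger `a1`, then larger `a2`).
#' Folds are stratified by class; if a fold ends up single-class the data are
#' refolded with a new seed (with a message).
#'
#' @param instances instance tibble.
#' @param hp_grid list of [model_hyperparams()] objects.
#' @param k number of folds (>= 2).
#' @param seed integer seed for fold assignment.
#' @return list with `best_hp` and a `metrics` tibble (one row per
#'   hp x fold).
#' @export
cross_validate <- function(instances, hp_grid, k = 5, seed = 1L) {
  stopifnot(k >= 2, length(hp_grid) >= 1)
  folds <- withr::with_seed(seed, make_folds(instances$y, k, seed))
  vocab_all <- NULL
  rows <- list()
  means <- numeric(length(hp_grid))
  for (g in seq_along(hp_grid)) {
    hp <- hp_grid[[g]]
    fold_auc <- vapply(seq_len(k), function(f) {
      tr <- instances[folds != f, , drop = FALSE]
      te <- instances[folds == f, , drop = FALSE]
      m <- train_model(tr, hp)
      sc <- predict_proba(m, te)
      auroc(sc[te$y == 1], sc[te$y == 0])
    }, numeric(1))
    means[g] <- mean(fold_auc)
    rows[[g]] <- tibble::tibble(
      hp_id = g, a1 = hp$a1, a2 = hp$a2, fold = seq_len(k), auroc = fold_auc
    )
  }
  a1s <- vapply(hp_grid, `[[`, numeric(1), "a1")
  a2s <- vapply(hp_grid, `[[`, numeric(1), "a2")
  best <- order(-means, -a1s, -a2s)[1]
  list(best_hp = hp_grid[[best]], metrics = dplyr::bind_rows(rows),
       mean_auroc = means)
}

make_folds <- function(y, k, seed, max_tries = 20) {
  for (try in seq_len(max_tries)) {
    folds <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(y[folds == f])) == length(unique(y))
    }, logical(1)))
    if (ok) return(folds)
    message("single-class fold encountered; refolding with a new seed")
  }
  stop("could not build stratified folds with both classes present",
       call. = FALSE)
}

#' Serialize a fitted model to JSON and back
#'
#' @param model a `ward_model`.
#' @param path file path.
#' @export
write_model <- function(model, path) {
  obj <- list(
    hp = unclass(model$hp),
    layer_dims = lapply(model$layers, function(l) dim(l$W)),
    weights = lapply(model$layers, function(l) as.numeric(l$W)),
    biases = lapply(model$layers, function(l) l$b),
    vocabulary = model$vocab
  )
  # 17 significant digits: doubles survive the text round-trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = FALSE)
  hp <- do.call(model_hyperparams, obj$hp[setdiff(names(obj$hp), NULL)])
  layers <- lapply(seq_along(obj$weights), function(l) {
    list(
      W = matrix(obj$weights[[l]], obj$layer_dims[[l]][1],
                 obj$layer_dims[[l]][2]),
      b = as.numeric(obj$biases[[l]])
    )
  })
  structure(
    list(layers = layers, hp = hp, vocab = tibble::as_tibble(obj$vocabulary),
         training_log = NULL),
    class = "ward_model"
  )
}
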