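# linearly separable two-feature toy set: the label is the sign of x1 + x2,
# with points near the boundary removed to leave a clear margin
toy_instances <- function(n = 60, seed = 5) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(3 * n * 2), 3 * n, 2)
    keep <- which(abs(X[, 1] + X[, 2]) > 0.4)[seq_len(n)]
    X <- X[keep, , drop = FALSE]
    y <- as.integer(X[, 1] + X[, 2] > 0)
    tibble::tibble(
      y = y,
      features = lapply(seq_len(n), function(i) c(f1 = X[i, 1], f2 = X[i, 2]))
    )
  })
}

test_that("the penalized log-likelihood matches closed forms and an oracle", {
  hp <- model_hyperparams(a1 = 0, a2 = 0)
  model <- list(layers = list(list(W = matrix(0, 3, 1), b = 0)), hp = hp)
  X <- matrix(rnorm(15), 5, 3)
  y <- c(1, 0, 1, 1, 0)
  # zero-weight logistic model: n * log(0.5), no penalty
  expect_equal(penalized_log_likelihood(model, X, y), 5 * log(0.5))

  # random weights against a naive transcription, with and without penalty
  set.seed(12)
  w <- rnorm(3); b <- rnorm(1)
  for (pen in list(c(0, 0), c(0.3, 0.7))) {
    hp2 <- model_hyperparams(a1 = pen[1], a2 = pen[2])
    m2 <- list(layers = list(list(W = matrix(w, 3, 1), b = b)), hp = hp2)
    expect_equal(
      penalized_log_likelihood(m2, X, y),
      naive_penalized_ll_logistic(w, b, X, y, pen[1], pen[2]),
      tolerance = 1e-10
    )
  }
})

test_that("the analytic gradient matches central differences to 1e-5", {
  set.seed(42)
  hp <- model_hyperparams(a1 = 0.01, a2 = 0.02, hidden_layers = 2L, seed = 5)
  X <- matrix(rnorm(16), 8, 2)
  y <- rbinom(8, 1, 0.5)
  layers <- withr::with_seed(5, init_layers(2, 2L))   # 2x2 + 2x1 weights
  # move all weights away from zero so the L1 subgradient is exact
  layers <- lapply(layers, function(l) {
    l$W <- l$W + 0.3 * sign(l$W + 1e-9); l
  })
  model <- list(layers = layers, hp = hp)
  theta <- flatten_params(layers)
  f <- function(t) {
    penalized_log_likelihood(
      list(layers = unflatten_params(t, layers), hp = hp), X, y)
  }
  numerical <- vapply(seq_along(theta), function(i) {
    e <- rep(0, length(theta)); e[i] <- 1e-6
    (f(theta + e) - f(theta - e)) / 2e-6
  }, numeric(1))
  g <- penalized_ll_grad(model, X, y)
  analytic <- unlist(lapply(g, function(l) c(as.numeric(l$W), l$b)))
  expect_lt(max(abs(numerical - analytic)), 1e-5)
})

test_that("training separates a separable toy problem and is deterministic", {
  inst <- toy_instances()
  hp <- model_hyperparams(a1 = 1e-5, a2 = 1e-5, epochs = 40, seed = 2)
  m1 <- train_model(inst, hp)
  m2 <- train_model(inst, hp)
  expect_identical(m1$layers, m2$layers)
  sc <- predict_proba(m1, inst)
  expect_gte(auroc(sc[inst$y == 1], sc[inst$y == 0]), 0.99)
  # the penalized likelihood improves over training
  expect_gt(
    tail(m1$training_log$penalized_ll, 1), head(m1$training_log$penalized_ll, 1)
  )
})

test_that("an overwhelming L1 penalty drives all weights to exact zero", {
  inst <- toy_instances()
  m <- train_model(inst, model_hyperparams(a1 = 1e6, a2 = 0, epochs = 10,
                                           seed = 3))
  w <- m$layers[[1]]$W
  expect_true(all(abs(w) < 1e-6))
  # with zero weights every prediction sits at the bias-only probability
  sc <- predict_proba(m, inst)
  expect_true(all(abs(sc - sc[1]) < 1e-12))
})

test_that("single-class training data are rejected", {
  inst <- toy_instances()
  expect_error(train_model(inst[inst$y == 1, ]), "both classes")
})

test_that("L1 shrinkage is monotone in a1", {
  inst <- toy_instances(n = 120, seed = 9)
  l1_norm <- vapply(c(0.001, 0.5, 5), function(a1) {
    m <- train_model(inst, model_hyperparams(a1 = a1, a2 = 0, epochs = 20,
                                             seed = 4))
    sum(abs(m$layers[[1]]$W))
  }, numeric(1))
  expect_true(all(diff(l1_norm) <= 1e-8))
})

test_that("the MLP forward pass matches a hand-computed relu composition", {
  # 2 -> 2 -> 1 network with hand-set weights
  layers <- list(
    list(W = matrix(c(1, -1, 0.5, 2), 2, 2), b = c(0.1, -0.2)),
    list(W = matrix(c(1, -2), 2, 1), b = 0.3)
  )
  hp <- model_hyperparams(hidden_layers = 2L)
  model <- structure(
    list(layers = layers, hp = hp,
         vocab = tibble::tibble(index = 1:2, feature = c("x1", "x2"))),
    class = "ward_model"
  )
  x <- c(x1 = 0.7, x2 = -0.4)
  h <- pmax(c(
    0.7 * 1 + (-0.4) * (-1) + 0.1,
    0.7 * 0.5 + (-0.4) * 2 + (-0.2)
  ), 0)
  expected <- 1 / (1 + exp(-(h[1] * 1 + h[2] * (-2) + 0.3)))
  inst <- tibble::tibble(y = 0L, features = list(x))
  expect_equal(predict_proba(model, inst), expected, tolerance = 1e-12)

  # all-zero input through a zero-bias model scores 0.5
  z <- structure(
    list(layers = list(list(W = matrix(0, 2, 1), b = 0)),
         hp = model_hyperparams(),
         vocab = tibble::tibble(index = 1:2, feature = c("x1", "x2"))),
    class = "ward_model"
  )
  expect_equal(
    predict_proba(z, tibble::tibble(y = 0L, features = list(c(x1 = 0, x2 = 0)))),
    0.5
  )
})

test_that("an MLP with no hidden layers reproduces logistic regression exactly", {
  inst <- toy_instances(n = 80, seed = 13)
  hp <- model_hyperparams(a1 = 0.01, a2 = 0.01, hidden_layers = integer(0),
                          epochs = 15, seed = 6)
  m <- train_model(inst, hp)
  # direct logistic forward with the fitted weights, bit for bit
  X <- as_instance_matrix(inst, m$vocab)
  manual <- plogis(as.numeric(as.matrix(X %*% m$layers[[1]]$W)) +
                     m$layers[[1]]$b)
  expect_identical(predict_proba(m, inst), manual)
  expect_length(m$layers, 1)
})

test_that("dropout regularizes training but never perturbs prediction", {
  inst <- toy_instances(n = 100, seed = 21)
  hp <- model_hyperparams(a1 = 0.001, a2 = 0.001, hidden_layers = c(8L),
                          dropout_rate = 0.5, epochs = 12, seed = 8)
  m <- train_model(inst, hp)
  s1 <- predict_proba(m, inst)
  s2 <- predict_proba(m, inst)
  expect_identical(s1, s2)
  expect_gt(auroc(s1[inst$y == 1], s1[inst$y == 0]), 0.9)
  expect_warning(model_hyperparams(dropout_rate = 0.5), "no effect")
})

test_that("elastic-net logistic agreement with glmnet on a shared problem", {
  set.seed(33)
  n <- 400; d <- 20
  X <- matrix(rnorm(n * d), n, d)
  w0 <- c(1.5, -1.5, 1, rep(0, d - 3))
  y <- rbinom(n, 1, plogis(X %*% w0))
  inst <- tibble::tibble(
    y = y,
    features = lapply(seq_len(n), function(i) {
      setNames(X[i, ], sprintf("f%02d", 1:d))
    })
  )
  m <- train_model(inst, model_hyperparams(a1 = 0.001, a2 = 0.01,
                                           epochs = 40, seed = 10))
  ours <- setNames(as.numeric(m$layers[[1]]$W), m$vocab$feature)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0.5,
                        lambda = 0.01 / n, standardize = FALSE)
  ref <- as.numeric(fit$beta)
  # both recover the informative structure: large weights agree in sign and
  # roughly in magnitude
  big <- which(abs(w0) > 0)
  expect_equal(sign(ours[sprintf("f%02d", big)]), sign(w0[big]),
               ignore_attr = TRUE)
  expect_lt(max(abs(ours[sprintf("f%02d", big)] - ref[big])), 0.35)
})

test_that("cross-validation partitions the data and prefers regularization on ties", {
  inst <- toy_instances(n = 90, seed = 17)
  folds <- withr::with_seed(1, make_folds(inst$y, 5, 1))
  expect_length(folds, 90)
  expect_setequal(unique(folds), 1:5)
  for (f in 1:5) expect_true(all(c(0, 1) %in% inst$y[folds == f]))

  hp1 <- model_hyperparams(a1 = 0.001, a2 = 0.01, epochs = 8, seed = 2)
  one <- cross_validate(inst, list(hp1), k = 3, seed = 4)
  expect_identical(one$best_hp, hp1)
  expect_equal(nrow(one$metrics), 3)

  # a degenerate grid of identical settings: tie broken toward larger a1
  hp_lo <- model_hyperparams(a1 = 0.001, a2 = 0.01, epochs = 1,
                             learning_rate = 1e-9, seed = 2)
  hp_hi <- model_hyperparams(a1 = 0.002, a2 = 0.01, epochs = 1,
                             learning_rate = 1e-9, seed = 2)
  cv <- cross_validate(inst, list(hp_lo, hp_hi), k = 3, seed = 4)
  expect_equal(cv$best_hp$a1, 0.002)
})

test_that("models round-trip through JSON", {
  inst <- toy_instances(n = 50, seed = 19)
  m <- train_model(inst, model_hyperparams(hidden_layers = c(4L), epochs = 5,
                                           seed = 7, dropout_rate = 0.2))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$layers, m$layers, tolerance = 1e-12)
  expect_equal(back$vocab, m$vocab)
  expect_equal(back$hp$hidden_layers, m$hp$hidden_layers)
  expect_identical(predict_proba(back, inst), predict_proba(m, inst))
})

test_that("tidy and glance summarise fitted models", {
  inst <- toy_instances(n = 50, seed = 23)
  m <- train_model(inst, model_hyperparams(epochs = 5, seed = 1))
  td <- tidy(m)
  expect_equal(td$term, c("(Intercept)", "f1", "f2"))
  gl <- glance(m)
  expect_equal(gl$n_features, 2L)
  expect_equal(gl$n_hidden_layers, 0L)

  mlp <- train_model(inst, model_hyperparams(hidden_layers = c(3L),
                                             epochs = 5, seed = 1))
  td2 <- tidy(mlp)
  expect_equal(nrow(td2), 2 * 3 + 3 * 1)
  expect_equal(glance(mlp)$n_weights, 9L)
})
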