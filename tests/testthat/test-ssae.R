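ns <- asNamespace("cfcdetect")

toy_clusters <- function(n_per = 20, d = 10, sep = 3, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * d), n_per),
             matrix(rnorm(n_per * d, mean = sep), n_per))
  X <- (X - min(X)) / (max(X) - min(X))
  list(X = X, labels = rep(c("background", "seizure"), each = n_per))
}

test_that("stratified splitting is exact, disjoint and reproducible", {
  labels <- rep(c("seizure", "background"), c(94, 94))
  sp <- split_dataset(labels, 0.5, seed = 1)
  expect_equal(sum(labels[sp$train] == "seizure"), 47)
  expect_equal(sum(labels[sp$train] == "background"), 47)
  expect_equal(sort(c(sp$train, sp$test)), seq_along(labels))
  expect_identical(sp, split_dataset(labels, 0.5, seed = 1))
  expect_false(identical(sp, split_dataset(labels, 0.5, seed = 2)))
  sp2 <- split_dataset(c("seizure", "seizure", "background", "background"),
                       0.5, seed = 3)
  expect_length(sp2$train, 2)
  expect_length(sp2$test, 2)
  # rounding half-up on odd classes
  sp3 <- split_dataset(rep(c("seizure", "background"), c(5, 5)), 0.5,
                       seed = 4)
  expect_length(sp3$train, 6)
  expect_error(split_dataset(c("seizure", "background", "background"), 0.5),
               class = "cfcdetect_split")
})

test_that("encoding is the logistic image of an affine map", {
  stage <- structure(list(W1 = matrix(0, 3, 4), b1 = numeric(3)),
                     class = "ae_stage")
  expect_equal(unname(encode(stage, matrix(rnorm(8), 2))),
               matrix(0.5, 2, 3))
  stage$b1 <- rep(-50, 3)
  expect_true(all(encode(stage, matrix(rnorm(8), 2)) < 1e-20))
  set.seed(2)
  stage2 <- structure(list(W1 = matrix(rnorm(12), 3), b1 = rnorm(3)),
                      class = "ae_stage")
  X <- matrix(rnorm(8), 2)
  oracle <- 1 / (1 + exp(-(X %*% t(stage2$W1) +
                             rep(1, 2) %o% stage2$b1)))
  expect_equal(unname(encode(stage2, X)), unname(oracle), tolerance = 1e-12)
  expect_error(encode(stage2, matrix(1, 1, 7)),
               class = "cfcdetect_dimension")
})

test_that("the sparsity penalty vanishes when mean activation hits target", {
  expect_equal(ns$kl_bernoulli(0.1, 0.1), 0)
  expect_gt(ns$kl_bernoulli(0.1, 0.5), 0)
  expect_gt(ns$kl_bernoulli(0.1, 0.01), 0)
})

test_that("analytic gradients match finite differences", {
  set.seed(3)
  eps <- 1e-6
  d <- 6; h <- 4; n <- 5
  X <- matrix(runif(n * d), n)
  par <- rnorm(2 * d * h + d + h, sd = 0.3)
  fn <- function(p) ns$stage_objective(p, X, d, h, 0.1, 4, 1e-3)
  num <- vapply(seq_along(par), function(i) {
    e <- numeric(length(par)); e[i] <- eps
    (fn(par + e) - fn(par - e)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(ns$stage_gradient(par, X, d, h, 0.1, 4, 1e-3) - num)),
            1e-6)

  H <- matrix(runif(8 * 3), 8)
  Y <- ns$label_onehot(rep(c("background", "seizure"), 4))
  ps <- rnorm(8, sd = 0.3)
  fns <- function(p) ns$softmax_objective(p, H, Y, 1e-3)
  nums <- vapply(seq_along(ps), function(i) {
    e <- numeric(length(ps)); e[i] <- eps
    (fns(ps + e) - fns(ps - e)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(ns$softmax_gradient(ps, H, Y, 1e-3) - nums)), 1e-6)

  pf <- rnorm(4 * 6 + 4 + 3 * 4 + 3 + 2 * 3 + 2, sd = 0.3)
  Yf <- Y[1:5, , drop = FALSE]
  fnf <- function(p) ns$ft_objective(p, X, Yf, 6, 4, 3, 1e-3)
  numf <- vapply(seq_along(pf), function(i) {
    e <- numeric(length(pf)); e[i] <- eps
    (fnf(pf + e) - fnf(pf - e)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(ns$ft_gradient(pf, X, Yf, 6, 4, 3, 1e-3) - numf)), 1e-6)
})

test_that("an unregularised overcomplete stage reconstructs almost exactly", {
  set.seed(4)
  X <- matrix(runif(50 * 8), 50)
  cfg <- train_config(sparsity_weight = 0, l2_weight = 0, max_iter = 400,
                      tol = 1e-12)
  st <- train_stage(X, hidden = 8, cfg, seed = 5)
  expect_lt(st$reconstruction_mse, 1e-3)
})

test_that("stage training is a pure function of (data, config, seed)", {
  set.seed(6)
  X <- matrix(runif(20 * 6), 20)
  cfg <- train_config(max_iter = 50)
  a <- train_stage(X, 4, cfg, seed = 9)
  b <- train_stage(X, 4, cfg, seed = 9)
  expect_identical(a$W1, b$W1)
  expect_identical(a$W2, b$W2)
  c <- train_stage(X, 4, cfg, seed = 10)
  expect_false(identical(a$W1, c$W1))
})

test_that("the best-so-far objective never increases during training", {
  set.seed(7)
  X <- matrix(runif(30 * 6), 30)
  for (opt in c("lbfgs", "gd")) {
    st <- train_stage(X, 4, train_config(max_iter = 60, optimizer = opt),
                      seed = 2)
    best <- cummin(st$curve)
    expect_true(all(diff(best) <= 0))
    if (opt == "gd") {
      # accepted gd steps are themselves monotone
      expect_true(all(diff(st$curve) <= 0))
    }
  }
})

test_that("the softmax head separates separable data with proper posteriors", {
  toy <- toy_clusters(n_per = 15, d = 2, sep = 4)
  head <- train_softmax(toy$X, toy$labels, seed = 1)
  Z <- sweep(toy$X %*% t(head$W), 2, head$b, `+`)
  P <- ns$softmax_rows(Z)
  expect_equal(unname(rowSums(P)), rep(1, 30), tolerance = 1e-12)
  pred <- ifelse(P[, 2] > P[, 1], "seizure", "background")
  expect_equal(mean(pred == toy$labels), 1)
  expect_error(train_softmax(toy$X, rep("seizure", 30)),
               class = "cfcdetect_split")
})

test_that("the stacked model learns a toy problem and composes as advertised", {
  toy <- toy_clusters(n_per = 20, d = 10, sep = 3)
  cfg <- train_config(hidden1 = 6, hidden2 = 3, max_iter = 200, seed = 5)
  model <- train_ssae(toy$X, toy$labels, cfg)
  pred <- predict(model, toy$X)
  expect_equal(mean(pred$label == toy$labels), 1)
  expect_equal(pred$p_background + pred$p_seizure, rep(1, 40),
               tolerance = 1e-12)
  # prediction equals the encode . encode . softmax composition
  Xs <- ns$apply_scaler(toy$X, model$scaler)
  A2 <- encode(model$stage2, encode(model$stage1, Xs))
  P <- ns$softmax_rows(sweep(A2 %*% t(model$softmax$W), 2,
                             model$softmax$b, `+`))
  expect_equal(pred$p_seizure, unname(P[, 2]), tolerance = 1e-12)
  expect_error(predict(model, toy$X[, 1:5]), class = "cfcdetect_dimension")
})

test_that("training is reproducible end to end", {
  toy <- toy_clusters(n_per = 10, d = 8, sep = 3)
  cfg <- train_config(hidden1 = 5, hidden2 = 3, max_iter = 60, seed = 21)
  m1 <- train_ssae(toy$X, toy$labels, cfg)
  m2 <- train_ssae(toy$X, toy$labels, cfg)
  expect_identical(m1$stage1$W1, m2$stage1$W1)
  expect_identical(m1$softmax$W, m2$softmax$W)
})

test_that("prediction ties resolve to background", {
  toy <- toy_clusters(n_per = 5, d = 4, sep = 3)
  cfg <- train_config(hidden1 = 3, hidden2 = 2, max_iter = 20,
                      fine_tune = FALSE, seed = 1)
  model <- train_ssae(toy$X, toy$labels, cfg)
  model$softmax$W[] <- 0
  model$softmax$b[] <- 0
  pred <- predict(model, toy$X)
  expect_equal(pred$p_seizure, rep(0.5, 10))
  expect_true(all(pred$label == "background"))
})

test_that("fine-tuning is optional, monotone and not harmful on train data", {
  toy <- toy_clusters(n_per = 15, d = 8, sep = 1.2, seed = 8)
  cfg <- train_config(hidden1 = 5, hidden2 = 3, max_iter = 150,
                      fine_tune = FALSE, seed = 3)
  model <- train_ssae(toy$X, toy$labels, cfg)
  expect_identical(fine_tune(model, toy$X, toy$labels, max_iter = 0), model)
  ft <- fine_tune(model, toy$X, toy$labels)
  expect_true(all(diff(cummin(ft$fine_tune_curve)) <= 0))
  acc <- function(m) mean(predict(m, toy$X)$label == toy$labels)
  expect_gte(acc(ft), acc(model))
})

test_that("models round-trip through JSON bit for bit", {
  toy <- toy_clusters(n_per = 6, d = 5, sep = 3)
  cfg <- train_config(hidden1 = 4, hidden2 = 2, max_iter = 30, seed = 2)
  model <- train_ssae(toy$X, toy$labels, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_ssae(model, path)
  back <- read_ssae(path)
  expect_identical(back$stage1$W1, model$stage1$W1)
  expect_identical(back$stage2$W2, model$stage2$W2)
  expect_identical(back$softmax$W, model$softmax$W)
  expect_identical(back$scaler$mins, unname(model$scaler$mins))
  expect_identical(predict(back, toy$X), predict(model, toy$X))
})

test_that("architecture constraints are enforced", {
  toy <- toy_clusters(n_per = 5, d = 4, sep = 3)
  expect_error(train_ssae(toy$X, toy$labels,
                          train_config(hidden1 = 3, hidden2 = 5)),
               class = "cfcdetect_config")
  expect_error(train_ssae(toy$X, toy$labels,
                          train_config(hidden1 = 10, hidden2 = 2)),
               class = "cfcdetect_config")
  expect_error(train_config(sparsity_target = 0), class = "cfcdetect_config")
})
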