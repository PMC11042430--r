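#' Training configuration for the stacked sparse autoencoder
#'
#' Two sparse autoencoder stages trained greedily on comodulogram features
#' mapped into (0, 1), then a 2-class softmax head, optionally fine-tuned
#' end-to-end. Each stage minimises
#' \deqn{J = \mathrm{MSE} + \lambda \sum w^2 + \beta \sum_j
#'       \mathrm{KL}(\rho \,\|\, \hat\rho_j)}
#' where \eqn{\hat\rho_j} is the mean logistic activation of hidden unit j
#' over the training set and
#' \eqn{\mathrm{KL}(\rho\|\hat\rho) = \rho\log(\rho/\hat\rho) +
#' (1-\rho)\log((1-\rho)/(1-\hat\rho))}.
#'
#' @param hidden1,hidden2 hidden-layer sizes of the two stages
#'   (`hidden2 <= hidden1 <= input dimension`).
#' @param sparsity_target target mean activation rho, in (0, 1).
#' @param sparsity_weight sparsity penalty weight beta (>= 0).
#' @param l2_weight L2 weight-decay lambda (>= 0), applied to weights (not
#'   biases) in every optimisation.
#' @param max_iter iteration cap per optimisation stage.
#' @param tol stop when one optimisation step improves the objective by less
#'   than this (the objective is on a per-element mean-squared-error scale,
#'   so this is an absolute tolerance on a quantity of order 1e-2 to 1).
#' @param fine_tune run end-to-end supervised fine-tuning after greedy
#'   training.
#' @param fine_tune_iter iteration cap for the fine-tuning pass (a short
#'   supervised polish of the greedily trained network).
#' @param optimizer `"lbfgs"` (default, deterministic quasi-Newton via
#'   [stats::optim()]) or `"gd"` (full-batch gradient descent with adaptive
#'   step).
#' @param scaling how [train_ssae()] maps features into the logistic
#'   decoder's (0, 1) range: `"fixed"` (default) applies the affine map
#'   (x + 1) / 2, exact for correlation-valued features in [-1, 1] and
#'   preserving the comodulogram's common scale across features;
#'   `"minmax"` rescales each feature by its min-max over the training set.
#' @param seed seed for all weight initialisations.
#' @return A `train_config` list.
#' @export
train_config <- function(hidden1 = 100, hidden2 = 50, sparsity_target = 0.10,
                         sparsity_weight = 1, l2_weight = 1e-5,
                         max_iter = 400, tol = 1e-8, fine_tune = TRUE,
                         fine_tune_iter = 100,
                         optimizer = c("lbfgs", "gd"),
                         scaling = c("fixed", "minmax"), seed = 1) {
  optimizer <- match.arg(optimizer)
  scaling <- match.arg(scaling)
  if (sparsity_target <= 0 || sparsity_target >= 1) {
    stop_with("cfcdetect_config", "sparsity_target must lie in (0, 1)")
  }
  if (sparsity_weight < 0 || l2_weight < 0) {
    stop_with("cfcdetect_config", "penalty weights must be >= 0")
  }
  structure(list(hidden1 = hidden1, hidden2 = hidden2,
                 sparsity_target = sparsity_target,
                 sparsity_weight = sparsity_weight, l2_weight = l2_weight,
                 max_iter = max_iter, tol = tol, fine_tune = fine_tune,
                 fine_tune_iter = fine_tune_iter, optimizer = optimizer,
                 scaling = scaling, seed = seed),
            class = "train_config")
}

# ---- parameter packing ------------------------------------------------------

pack <- function(...) unlist(list(...), use.names = FALSE)

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# Share one forward/backward pass between the objective and gradient
# callbacks: L-BFGS evaluates both at the same point almost every iteration.
make_cached <- function(compute) {
  last_par <- NULL
  last <- NULL
  refresh <- function(p) {
    if (is.null(last_par) || !identical(p, last_par)) {
      last <<- compute(p)
      last_par <<- p
    }
  }
  list(
    fn = function(p) { refresh(p); last$value },
    gr = function(p) { refresh(p); last$grad }
  )
}

# ---- deterministic minimiser ------------------------------------------------

# Minimise fn with analytic gradient gr; records the objective value at each
# accepted iteration. Both optimisers are deterministic full-batch methods.
minimize <- function(par, fn, gr, max_iter, tol, optimizer = "lbfgs") {
  if (max_iter <= 0) {
    return(list(par = par, value = fn(par), curve = numeric(0)))
  }
  curve <- numeric(0)
  if (optimizer == "lbfgs") {
    fn_rec <- function(p) {
      v <- fn(p)
      curve[length(curve) + 1L] <<- v
      v
    }
    res <- stats::optim(par, fn_rec, gr, method = "L-BFGS-B",
                        control = list(maxit = max_iter,
                                       factr = tol / .Machine$double.eps))
    out <- list(par = res$par, value = res$value, curve = curve)
  } else {
    step <- 0.5
    J <- fn(par)
    curve <- J
    for (it in seq_len(max_iter)) {
      g <- gr(par)
      cand <- par - step * g
      Jc <- fn(cand)
      while (!is.finite(Jc) || Jc > J) {
        step <- step / 2
        if (step < 1e-12) break
        cand <- par - step * g
        Jc <- fn(cand)
      }
      if (step < 1e-12) break
      improved <- J - Jc
      par <- cand
      J <- Jc
      step <- step * 1.2
      curve[length(curve) + 1L] <- J
      if (improved < tol * max(abs(J), 1)) break
    }
    out <- list(par = par, value = J, curve = curve)
  }
  if (!is.finite(out$value)) {
    stop_with("cfcdetect_divergence",
              "optimisation diverged (non-finite objective); try a smaller step or stronger regularisation")
  }
  out
}

# ---- sparse autoencoder stage ----------------------------------------------

stage_unpack <- function(par, d, h) {
  i <- 0L
  W1 <- matrix(par[i + seq_len(h * d)], h, d); i <- i + h * d
  b1 <- par[i + seq_len(h)]; i <- i + h
  W2 <- matrix(par[i + seq_len(d * h)], d, h); i <- i + d * h
  b2 <- par[i + seq_len(d)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

stage_forward <- function(X, p) {
  A <- logistic(sweep(X %*% t(p$W1), 2, p$b1, `+`))
  Xh <- logistic(sweep(A %*% t(p$W2), 2, p$b2, `+`))
  list(A = A, Xh = Xh)
}

kl_bernoulli <- function(rho, rhohat) {
  rhohat <- pmin(pmax(rhohat, 1e-10), 1 - 1e-10)
  rho * log(rho / rhohat) + (1 - rho) * log((1 - rho) / (1 - rhohat))
}

stage_objective <- function(par, X, d, h, rho, beta, lambda) {
  p <- stage_unpack(par, d, h)
  fw <- stage_forward(X, p)
  mse <- mean((fw$Xh - X)^2)
  kl <- sum(kl_bernoulli(rho, colMeans(fw$A)))
  mse + lambda * (sum(p$W1^2) + sum(p$W2^2)) + beta * kl
}

stage_gradient <- function(par, X, d, h, rho, beta, lambda) {
  stage_fngr(par, X, d, h, rho, beta, lambda)$grad
}

# Objective and gradient from one forward/backward pass.
stage_fngr <- function(par, X, d, h, rho, beta, lambda) {
  n <- nrow(X)
  p <- stage_unpack(par, d, h)
  fw <- stage_forward(X, p)
  A <- fw$A
  Xh <- fw$Xh
  rhohat <- pmin(pmax(colMeans(A), 1e-10), 1 - 1e-10)
  value <- mean((Xh - X)^2) +
    lambda * (sum(p$W1^2) + sum(p$W2^2)) +
    beta * sum(kl_bernoulli(rho, rhohat))
  D2 <- (2 * (Xh - X) / (n * d)) * Xh * (1 - Xh)
  gW2 <- t(D2) %*% A + 2 * lambda * p$W2
  gb2 <- colSums(D2)
  sparse_term <- beta * (-rho / rhohat + (1 - rho) / (1 - rhohat)) / n
  DA <- sweep(D2 %*% p$W2, 2, sparse_term, `+`)
  D1 <- DA * A * (1 - A)
  gW1 <- t(D1) %*% X + 2 * lambda * p$W1
  gb1 <- colSums(D1)
  list(value = value, grad = pack(gW1, gb1, gW2, gb2))
}

#' Train one sparse autoencoder stage
#'
#' Full-batch, deterministic minimisation of the sparse-autoencoder objective
#' (see [train_config()]) with logistic activations on both the encoder and
#' decoder layer. Inputs are expected on a [0, 1] scale (the pipeline maps
#' features into that range before training; see [train_ssae()]).
#'
#' @param X numeric matrix, observations in rows.
#' @param hidden hidden-layer size.
#' @param config a [train_config()]; `sparsity_target`, `sparsity_weight`,
#'   `l2_weight`, `max_iter`, `tol` and `optimizer` are used.
#' @param seed initialisation seed.
#' @return An `ae_stage` with encoder/decoder parameters, the training
#'   curve (objective per iteration), and the final reconstruction MSE.
#' @export
train_stage <- function(X, hidden, config = train_config(),
                        seed = config$seed) {
  X <- as.matrix(X)
  assert_finite(X, "stage inputs")
  if (nrow(X) < 1) stop_with("cfcdetect_config", "no training inputs")
  d <- ncol(X)
  h <- hidden
  par0 <- with_seed(seed, pack(glorot(h, d), numeric(h), glorot(d, h),
                               numeric(d)))
  cache <- make_cached(function(p) {
    stage_fngr(p, X, d, h, config$sparsity_target, config$sparsity_weight,
               config$l2_weight)
  })
  fit <- minimize(par0, fn = cache$fn, gr = cache$gr,
                  max_iter = config$max_iter, tol = config$tol,
                  optimizer = config$optimizer)
  p <- stage_unpack(fit$par, d, h)
  recon <- stage_forward(X, p)$Xh
  structure(list(W1 = p$W1, b1 = p$b1, W2 = p$W2, b2 = p$b2,
                 curve = fit$curve, objective = fit$value,
                 reconstruction_mse = mean((recon - X)^2)),
            class = "ae_stage")
}

#' Encode inputs through a trained stage
#'
#' `logistic(W %*% x + b)`; outputs lie in (0, 1).
#'
#' @param stage an `ae_stage` from [train_stage()].
#' @param X matrix of observations in rows (or a single vector).
#' @return Matrix of hidden activations, observations in rows.
#' @export
encode <- function(stage, X) {
  if (is.vector(X)) X <- matrix(X, 1)
  if (ncol(X) != ncol(stage$W1)) {
    stop_with("cfcdetect_dimension", "input has %d features, stage expects %d",
              ncol(X), ncol(stage$W1))
  }
  logistic(sweep(X %*% t(stage$W1), 2, stage$b1, `+`))
}

# ---- softmax head -----------------------------------------------------------

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

softmax_unpack <- function(par, h, k = 2L) {
  list(W = matrix(par[seq_len(k * h)], k, h), b = par[k * h + seq_len(k)])
}

softmax_objective <- function(par, H, Y, lambda) {
  p <- softmax_unpack(par, ncol(H))
  P <- softmax_rows(sweep(H %*% t(p$W), 2, p$b, `+`))
  -mean(log(pmax(rowSums(P * Y), 1e-300))) + lambda * sum(p$W^2)
}

softmax_gradient <- function(par, H, Y, lambda) {
  n <- nrow(H)
  p <- softmax_unpack(par, ncol(H))
  P <- softmax_rows(sweep(H %*% t(p$W), 2, p$b, `+`))
  dZ <- (P - Y) / n
  pack(t(dZ) %*% H + 2 * lambda * p$W, colSums(dZ))
}

label_onehot <- function(labels, classes = c("background", "seizure")) {
  labels <- as.character(labels)
  if (!all(labels %in% classes)) {
    stop_with("cfcdetect_validation", "labels must be in {%s}",
              paste(classes, collapse = ", "))
  }
  Y <- matrix(0, length(labels), length(classes))
  Y[cbind(seq_along(labels), match(labels, classes))] <- 1
  Y
}

#' Train the 2-class softmax head
#'
#' Multinomial logistic regression fitted by deterministic gradient-based
#' minimisation of cross-entropy with an L2 penalty on the weights.
#'
#' @param H feature matrix (observations in rows), e.g. second-stage codes.
#' @param labels per-row labels in `{background, seizure}`; both classes
#'   must be present.
#' @param l2_weight L2 penalty weight.
#' @param max_iter,tol,optimizer,seed as in [train_config()].
#' @return A `softmax_head` with `W` (2 x hidden), `b`, class order and the
#'   training curve.
#' @export
train_softmax <- function(H, labels, l2_weight = 1e-3, max_iter = 400,
                          tol = 1e-6, optimizer = "lbfgs", seed = 1) {
  H <- as.matrix(H)
  classes <- c("background", "seizure")
  Y <- label_onehot(labels, classes)
  if (any(colSums(Y) == 0)) {
    stop_with("cfcdetect_split", "softmax training needs both classes present")
  }
  h <- ncol(H)
  par0 <- with_seed(seed, pack(glorot(2L, h), numeric(2L)))
  fit <- minimize(
    par0,
    fn = function(p) softmax_objective(p, H, Y, l2_weight),
    gr = function(p) softmax_gradient(p, H, Y, l2_weight),
    max_iter = max_iter, tol = tol, optimizer = optimizer
  )
  p <- softmax_unpack(fit$par, h)
  structure(list(W = p$W, b = p$b, classes = classes, curve = fit$curve),
            class = "softmax_head")
}

# ---- feature scaling --------------------------------------------------------

fit_scaler <- function(X, method = "fixed") {
  if (method == "fixed") {
    # correlation-valued features: [-1, 1] -> [0, 1], identical across
    # features, so relative coupling strengths are preserved
    return(list(mins = rep(-1, ncol(X)), range = rep(2, ncol(X))))
  }
  mins <- apply(X, 2, min)
  rng <- apply(X, 2, max) - mins
  list(mins = mins, range = rng)
}

apply_scaler <- function(X, scaler) {
  rng <- ifelse(scaler$range > 0, scaler$range, 1)
  S <- sweep(sweep(X, 2, scaler$mins), 2, rng, `/`)
  S[, scaler$range == 0] <- 0.5   # constant feature: centre of decoder range
  S
}

# ---- stacked model ----------------------------------------------------------

#' Train the full stacked sparse autoencoder classifier
#'
#' Greedy layer-wise training: features are mapped into the logistic
#' decoder's (0, 1) range (see the `scaling` argument of [train_config()];
#' any data-dependent transform is fitted on the *training set only*, stored
#' and reused at prediction time); stage 1 is trained on the scaled
#' features; stage 2
#' on stage 1's codes; the softmax head on stage 2's codes; optionally the
#' whole encoder-encoder-softmax path is fine-tuned end-to-end on
#' cross-entropy + L2.
#'
#' @param X feature matrix, one flattened comodulogram per row (see
#'   [flatten_cfc()]).
#' @param labels per-row labels in `{background, seizure}`.
#' @param config a [train_config()].
#' @return An `ssae_model` with both stages, the softmax head, the scaling
#'   transform, class order and the config snapshot.
#' @export
train_ssae <- function(X, labels, config = train_config()) {
  X <- as.matrix(X)
  if (config$hidden2 > config$hidden1 || config$hidden1 > ncol(X)) {
    stop_with("cfcdetect_config",
              "need hidden2 <= hidden1 <= input dimension")
  }
  scaler <- fit_scaler(X, method = config$scaling)
  Xs <- apply_scaler(X, scaler)
  stage1 <- train_stage(Xs, config$hidden1, config,
                        seed = derive_seed(config$seed, 1))
  H1 <- encode(stage1, Xs)
  stage2 <- train_stage(H1, config$hidden2, config,
                        seed = derive_seed(config$seed, 2))
  H2 <- encode(stage2, H1)
  head <- train_softmax(H2, labels, l2_weight = config$l2_weight,
                        max_iter = config$max_iter, tol = config$tol,
                        optimizer = config$optimizer,
                        seed = derive_seed(config$seed, 3))
  model <- structure(
    list(stage1 = stage1, stage2 = stage2, softmax = head, scaler = scaler,
         classes = head$classes, config = config),
    class = "ssae_model"
  )
  if (isTRUE(config$fine_tune)) {
    model <- fine_tune(model, X, labels, config,
                       max_iter = config$fine_tune_iter)
  }
  model
}

ft_unpack <- function(par, d, h1, h2) {
  i <- 0L
  W1 <- matrix(par[i + seq_len(h1 * d)], h1, d); i <- i + h1 * d
  b1 <- par[i + seq_len(h1)]; i <- i + h1
  W2 <- matrix(par[i + seq_len(h2 * h1)], h2, h1); i <- i + h2 * h1
  b2 <- par[i + seq_len(h2)]; i <- i + h2
  Ws <- matrix(par[i + seq_len(2L * h2)], 2L, h2); i <- i + 2L * h2
  bs <- par[i + seq_len(2L)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, Ws = Ws, bs = bs)
}

ft_objective <- function(par, Xs, Y, d, h1, h2, lambda) {
  p <- ft_unpack(par, d, h1, h2)
  A1 <- logistic(sweep(Xs %*% t(p$W1), 2, p$b1, `+`))
  A2 <- logistic(sweep(A1 %*% t(p$W2), 2, p$b2, `+`))
  P <- softmax_rows(sweep(A2 %*% t(p$Ws), 2, p$bs, `+`))
  -mean(log(pmax(rowSums(P * Y), 1e-300))) +
    lambda * (sum(p$W1^2) + sum(p$W2^2) + sum(p$Ws^2))
}

ft_gradient <- function(par, Xs, Y, d, h1, h2, lambda) {
  ft_fngr(par, Xs, Y, d, h1, h2, lambda)$grad
}

ft_fngr <- function(par, Xs, Y, d, h1, h2, lambda) {
  n <- nrow(Xs)
  p <- ft_unpack(par, d, h1, h2)
  A1 <- logistic(sweep(Xs %*% t(p$W1), 2, p$b1, `+`))
  A2 <- logistic(sweep(A1 %*% t(p$W2), 2, p$b2, `+`))
  P <- softmax_rows(sweep(A2 %*% t(p$Ws), 2, p$bs, `+`))
  value <- -mean(log(pmax(rowSums(P * Y), 1e-300))) +
    lambda * (sum(p$W1^2) + sum(p$W2^2) + sum(p$Ws^2))
  dZ <- (P - Y) / n
  gWs <- t(dZ) %*% A2 + 2 * lambda * p$Ws
  gbs <- colSums(dZ)
  D2 <- (dZ %*% p$Ws) * A2 * (1 - A2)
  gW2 <- t(D2) %*% A1 + 2 * lambda * p$W2
  gb2 <- colSums(D2)
  D1 <- (D2 %*% p$W2) * A1 * (1 - A1)
  gW1 <- t(D1) %*% Xs + 2 * lambda * p$W1
  gb1 <- colSums(D1)
  list(value = value, grad = pack(gW1, gb1, gW2, gb2, gWs, gbs))
}

#' Supervised end-to-end fine-tuning
#'
#' Jointly minimises cross-entropy + L2 over both encoders and the softmax
#' head (the decoders are not on the prediction path and are left
#' untouched). With `max_iter = 0` the model is returned unchanged.
#'
#' @param model a trained `ssae_model`.
#' @param X raw (unscaled) training features; the model's stored scaling is
#'   applied internally.
#' @param labels training labels.
#' @param config a [train_config()]; `l2_weight`, `max_iter`, `tol` and
#'   `optimizer` are used.
#' @param max_iter iteration cap, overriding `config$max_iter`.
#' @return The fine-tuned `ssae_model` (same structure).
#' @export
fine_tune <- function(model, X, labels, config = model$config,
                      max_iter = config$max_iter) {
  if (max_iter <= 0) return(model)
  Xs <- apply_scaler(as.matrix(X), model$scaler)
  Y <- label_onehot(labels, model$classes)
  d <- ncol(Xs)
  h1 <- nrow(model$stage1$W1)
  h2 <- nrow(model$stage2$W1)
  par0 <- pack(model$stage1$W1, model$stage1$b1, model$stage2$W1,
               model$stage2$b1, model$softmax$W, model$softmax$b)
  cache <- make_cached(function(p) {
    ft_fngr(p, Xs, Y, d, h1, h2, config$l2_weight)
  })
  fit <- minimize(par0, fn = cache$fn, gr = cache$gr,
                  max_iter = max_iter, tol = config$tol,
                  optimizer = config$optimizer)
  p <- ft_unpack(fit$par, d, h1, h2)
  model$stage1$W1 <- p$W1
  model$stage1$b1 <- p$b1
  model$stage2$W1 <- p$W2
  model$stage2$b1 <- p$b2
  model$softmax$W <- p$Ws
  model$softmax$b <- p$bs
  model$fine_tune_curve <- fit$curve
  model
}

#' Classify comodulogram features
#'
#' Applies the stored train-set scaling, both encoder stages and the softmax
#' head. The hard label is the arg-max class; an exact tie at 0.5 is
#' resolved to `background` (favouring specificity).
#'
#' @param object an `ssae_model`.
#' @param X feature matrix, observations in rows (raw scale).
#' @param ... unused.
#' @return data.frame with `p_background`, `p_seizure` (summing to 1) and
#'   the hard `label`.
#' @export
predict.ssae_model <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != length(object$scaler$mins)) {
    stop_with("cfcdetect_dimension",
              "features have %d columns, model expects %d",
              ncol(X), length(object$scaler$mins))
  }
  Xs <- apply_scaler(X, object$scaler)
  A2 <- encode(object$stage2, encode(object$stage1, Xs))
  P <- softmax_rows(sweep(A2 %*% t(object$softmax$W), 2, object$softmax$b,
                          `+`))
  data.frame(
    p_background = P[, 1], p_seizure = P[, 2],
    label = ifelse(P[, 2] > P[, 1], "seizure", "background"),
    stringsAsFactors = FALSE
  )
}

# ---- splitting --------------------------------------------------------------

#' Stratified random train/test split
#'
#' Each class is split at the given fraction (train size rounded half-up);
#' train and test are disjoint and their union is the input. The same seed
#' always yields the same split.
#'
#' @param labels per-item class labels; every class needs >= 2 items.
#' @param fraction training fraction.
#' @param seed split seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_dataset <- function(labels, fraction = 0.5, seed = 1) {
  labels <- as.character(labels)
  idx_by_class <- split(seq_along(labels), labels)
  if (any(lengths(idx_by_class) < 2)) {
    stop_with("cfcdetect_split", "every class needs at least 2 items")
  }
  with_seed(seed, {
    train <- unlist(lapply(idx_by_class, function(idx) {
      n_tr <- floor(length(idx) * fraction + 0.5)
      sample(idx, n_tr)
    }), use.names = FALSE)
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

# ---- serialization ----------------------------------------------------------

ser_mat <- function(m) list(dim = dim(m), data = as.numeric(m))
deser_mat <- function(x) {
  matrix(as.numeric(x$data), as.integer(x$dim[1]), as.integer(x$dim[2]))
}

#' Serialize / restore a trained model as JSON
#'
#' Weights are written at full IEEE precision so that
#' `read_ssae(write_ssae(m, f))` reproduces the model bit for bit.
#'
#' @param model an `ssae_model`.
#' @param path JSON file path.
#' @export
write_ssae <- function(model, path) {
  obj <- list(
    classes = model$classes,
    scaler = list(mins = as.numeric(model$scaler$mins),
                  range = as.numeric(model$scaler$range)),
    stage1 = list(W1 = ser_mat(model$stage1$W1),
                  b1 = as.numeric(model$stage1$b1),
                  W2 = ser_mat(model$stage1$W2),
                  b2 = as.numeric(model$stage1$b2)),
    stage2 = list(W1 = ser_mat(model$stage2$W1),
                  b1 = as.numeric(model$stage2$b1),
                  W2 = ser_mat(model$stage2$W2),
                  b2 = as.numeric(model$stage2$b2)),
    softmax = list(W = ser_mat(model$softmax$W),
                   b = as.numeric(model$softmax$b)),
    config = unclass(model$config)
  )
  # I(17) = 17 *significant* digits: doubles survive the text round trip
  # bit for bit
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_ssae
#' @export
read_ssae <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stage <- function(s) {
    structure(list(W1 = deser_mat(s$W1), b1 = as.numeric(s$b1),
                   W2 = deser_mat(s$W2), b2 = as.numeric(s$b2)),
              class = "ae_stage")
  }
  cfg <- obj$config
  config <- train_config(hidden1 = cfg$hidden1, hidden2 = cfg$hidden2,
                         sparsity_target = cfg$sparsity_target,
                         sparsity_weight = cfg$sparsity_weight,
                         l2_weight = cfg$l2_weight, max_iter = cfg$max_iter,
                         tol = cfg$tol, fine_tune = cfg$fine_tune,
                         fine_tune_iter = cfg$fine_tune_iter,
                         optimizer = cfg$optimizer, scaling = cfg$scaling,
                         seed = cfg$seed)
  structure(
    list(stage1 = stage(obj$stage1), stage2 = stage(obj$stage2),
         softmax = structure(list(W = deser_mat(obj$softmax$W),
                                  b = as.numeric(obj$softmax$b),
                                  classes = obj$classes),
                             class = "softmax_head"),
         scaler = list(mins = as.numeric(obj$scaler$mins),
                       range = as.numeric(obj$scaler$range)),
         classes = obj$classes, config = config),
    class = "ssae_model"
  )
}
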