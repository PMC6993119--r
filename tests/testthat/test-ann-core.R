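test_that("min-max scalers map the training range to [-1, 1] and back", {
  X <- cbind(seq(0, 10, length.out = 11), seq(-4, 4, length.out = 11))
  sc <- fit_scalers(X)
  Xs <- apply_scaler(sc$input, X)
  expect_equal(range(Xs[, 1]), c(-1, 1))
  expect_equal(apply_scaler(sc$input, matrix(c(5, 0), 1))[1, 1], 0) # midpoint -> 0
  expect_equal(invert_scaler(sc$input, Xs), X, tolerance = 1e-12)
  # constant column flagged and mapped to 0
  expect_warning(scc <- fit_scalers(cbind(X[, 1], 7)), "constant")
  expect_equal(apply_scaler(scc$input, cbind(X[, 1], 7))[, 2], rep(0, 11))
  # values outside the fitted range pass through unclipped
  expect_gt(apply_scaler(sc$input, matrix(c(20, 0), 1))[1, 1], 1)
  expect_error(fit_scalers(X[0, , drop = FALSE]), class = "kneeload_scaler_error")
})

test_that("Nguyen-Widrow initialization has the prescribed row norms", {
  p <- nguyen_widrow_init(c(12, 100, 20, 2), seed = 11)
  norms1 <- sqrt(rowSums(p$W[[1]]^2))
  expect_equal(norms1, rep(0.7 * 100^(1 / 12), 100), tolerance = 1e-9)
  norms2 <- sqrt(rowSums(p$W[[2]]^2))
  expect_equal(norms2, rep(0.7 * 20^(1 / 100), 20), tolerance = 1e-9)
  # degenerate single-neuron hidden layer: norm 0.7 * 1^(1/1)
  p1 <- nguyen_widrow_init(c(1, 1, 1), seed = 2)
  expect_equal(sqrt(sum(p1$W[[1]]^2)), 0.7, tolerance = 1e-12)
  # output layer small uniform
  expect_lt(max(abs(p$W[[3]])), 0.5 / 20 + 1e-12)
  # determinism
  expect_identical(p, nguyen_widrow_init(c(12, 100, 20, 2), seed = 11))
  expect_false(identical(p, nguyen_widrow_init(c(12, 100, 20, 2), seed = 12)))
})

test_that("forward pass computes the tanh-linear composition", {
  # zero weights and biases: output is the unscaled image of 0
  p <- nguyen_widrow_init(c(3, 4, 2), seed = 1)
  p$W <- lapply(p$W, function(W) W * 0)
  p$b <- lapply(p$b, function(b) b * 0)
  X <- matrix(rnorm(15), ncol = 3)
  Y <- matrix(rnorm(10, mean = 5), ncol = 2)
  sc <- fit_scalers(X, Y)
  out <- mlp_forward(p, X, sc)
  mid <- (sc$target$max + sc$target$min) / 2
  expect_equal(out, matrix(mid, 5, 2, byrow = TRUE), tolerance = 1e-12)

  # 1-1-1 network, identity scaling: closed form 2*tanh(x) + 0.5
  p1 <- kneeload:::unpack_params(c(1, 0, 2, 0.5), c(1, 1, 1))
  expect_equal(mlp_forward(p1, matrix(0.5))[1, 1], 2 * tanh(0.5) + 0.5, tolerance = 1e-14)

  # rows are independent: duplicated input row gives duplicated output
  p2 <- nguyen_widrow_init(c(3, 5, 2), seed = 4)
  X2 <- X[c(1, 1, 2), ]
  out2 <- mlp_forward(p2, X2)
  expect_equal(out2[1, ], out2[2, ])
  expect_error(mlp_forward(p2, matrix(1, 2, 4)), class = "kneeload_dim_error")
})

test_that("analytic Jacobian agrees with central finite differences", {
  set.seed(21)
  p <- nguyen_widrow_init(c(2, 3, 1), seed = 5)
  Xs <- matrix(rnorm(10), ncol = 2)
  J <- mlp_jacobian(p, Xs)
  Jfd <- fd_jacobian(p, Xs)
  expect_lt(max(abs(J - Jfd)) / max(abs(Jfd)), 1e-5)
  # zero input rows with zero biases: first-layer weight derivatives vanish
  p0 <- nguyen_widrow_init(c(2, 3, 2), seed = 6)
  p0$b <- lapply(p0$b, function(b) b * 0)
  J0 <- mlp_jacobian(p0, matrix(0, 4, 2))
  w1_cols <- seq_len(3 * 2)
  expect_equal(max(abs(J0[, w1_cols])), 0)
})

test_that("a linear-only network's Jacobian is the design matrix", {
  # single linear (output) layer: residual = Wx + b, so d/d[W, b] = [x, 1]
  p <- kneeload:::unpack_params(c(0.3, -0.2, 0.1), c(2, 1))
  Xs <- matrix(rnorm(12), ncol = 2)
  J <- mlp_jacobian(p, Xs)
  expect_equal(J, cbind(Xs, 1), tolerance = 1e-14)
})

test_that("Levenberg-Marquardt fits a realizable linear target", {
  set.seed(2)
  X <- matrix(seq(-2, 2, length.out = 50), ncol = 1)
  Y <- 2 * X + 1
  model <- train_network(X, Y, hidden = 4, config = train_config(max_epochs = 200, seed = 3))
  expect_lt(tail(model$log$mse, 1), 1e-8)
  expect_lte(nrow(model$log), 200)
})

test_that("training log and stopping rules behave as specified", {
  set.seed(4)
  X <- matrix(rnorm(80), ncol = 2)
  Y <- matrix(X %*% c(1, -1) + 0.1 * rnorm(40), ncol = 1)
  sc <- fit_scalers(X, Y)
  p <- nguyen_widrow_init(c(2, 3, 1), seed = 9)
  fit <- train_lm(p, apply_scaler(sc$input, X), apply_scaler(sc$target, Y),
    config = train_config(max_epochs = 3, seed = 9)
  )
  expect_lte(nrow(fit$log), 3)
  expect_true(attr(fit$log, "stop_reason") %in%
    c("max_epochs", "grad_tol", "patience", "mu_max"))
  # accepted steps force a non-increasing per-epoch SSE (mse) sequence
  fit2 <- train_lm(p, apply_scaler(sc$input, X), apply_scaler(sc$target, Y),
    config = train_config(max_epochs = 30, seed = 9)
  )
  expect_true(all(diff(fit2$log$mse) <= 1e-15))
  # deterministic: identical log across repeated runs
  fit3 <- train_lm(p, apply_scaler(sc$input, X), apply_scaler(sc$target, Y),
    config = train_config(max_epochs = 30, seed = 9)
  )
  expect_identical(fit2$log, fit3$log)
})

test_that("blockwise normal equations equal direct Jacobian assembly", {
  set.seed(6)
  p <- nguyen_widrow_init(c(3, 6, 2), seed = 13)
  Xs <- matrix(rnorm(90), ncol = 3)
  Ts <- matrix(rnorm(60), ncol = 2)
  J <- mlp_jacobian(p, Xs)
  e <- as.vector(kneeload:::forward_scaled(p, Xs) - Ts)
  direct_JtJ <- crossprod(J)
  direct_Jte <- drop(crossprod(J, e))
  for (bs in c(4L, 7L, 30L)) {
    ne <- kneeload:::lm_normal_equations(p, Xs, Ts, block_size = bs)
    expect_lt(max(abs(ne$JtJ - direct_JtJ)), 1e-10)
    expect_lt(max(abs(ne$Jte - direct_Jte)), 1e-10)
    expect_equal(ne$sse, sum(e^2), tolerance = 1e-12)
  }
})

test_that("heavily damped LM steps point along the negative gradient", {
  set.seed(7)
  p <- nguyen_widrow_init(c(2, 4, 1), seed = 17)
  Xs <- matrix(rnorm(60), ncol = 2)
  Ts <- matrix(rnorm(30), ncol = 1)
  ne <- kneeload:::lm_normal_equations(p, Xs, Ts)
  mu <- 1e9 * max(diag(ne$JtJ))
  H <- ne$JtJ
  diag(H) <- diag(H) + mu
  delta <- solve(H, -ne$Jte)
  cosang <- sum(delta * -ne$Jte) / sqrt(sum(delta^2) * sum(ne$Jte^2))
  expect_gt(cosang, cos(1 * pi / 180))
})
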