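# Feed-forward network core: min-max scaling, Nguyen-Widrow initialization,
# forward pass, analytic Jacobian, full-batch Levenberg-Marquardt training.
#
# Architecture convention: layer_sizes = c(n_in, hidden..., n_out). All
# hidden layers use tanh, the output layer is linear. Inputs and targets are
# mapped to [-1, 1] by per-column training-set min/max before the network
# sees them; training therefore happens entirely in scaled space, matching
# the conventional default of neural-network regression tooling.

#' Fit per-column min-max scalers mapping to [-1, 1]
#'
#' Records column minima and maxima of the training matrices; [apply_scaler()]
#' then maps values linearly so the training range spans `[-1, 1]`. Columns
#' with zero range are flagged and mapped to 0 (with a warning). Values from
#' outside the training range - e.g. a held-out participant - map outside
#' `[-1, 1]` and are deliberately passed through unclipped.
#'
#' @param X numeric matrix (e.g. network inputs).
#' @param Y optional second matrix (targets); scaled independently.
#' @return list with `input` (and, if `Y` given, `target`) scaler objects.
#' @export
fit_scalers <- function(X, Y = NULL) {
  one <- function(M, what) {
    if (!is.matrix(M)) M <- as.matrix(M)
    if (nrow(M) == 0) {
      stop_kneeload("cannot fit scaler on empty ", what, " matrix",
        class = "kneeload_scaler_error"
      )
    }
    mins <- apply(M, 2, min)
    maxs <- apply(M, 2, max)
    const <- maxs <= mins
    if (any(const)) {
      warning("constant column(s) in ", what, " matrix mapped to 0: ",
        paste(which(const), collapse = ", "),
        call. = FALSE
      )
    }
    structure(list(min = mins, max = maxs, constant = const), class = "minmax_scaler")
  }
  out <- list(input = one(X, "input"))
  if (!is.null(Y)) out$target <- one(Y, "target")
  out
}

#' @rdname fit_scalers
#' @param scaler a `minmax_scaler`.
#' @param M matrix to scale (columns must match the fitted matrix).
#' @export
apply_scaler <- function(scaler, M) {
  if (!is.matrix(M)) M <- as.matrix(M)
  if (ncol(M) != length(scaler$min)) {
    stop_kneeload("column count does not match fitted scaler", class = "kneeload_scaler_error")
  }
  rng <- scaler$max - scaler$min
  rng[scaler$constant] <- 1 # constant columns map to 0 via centered offset
  ctr <- (scaler$max + scaler$min) / 2
  sweep(sweep(M, 2, ctr, "-"), 2, rng / 2, "/")
}

#' @rdname fit_scalers
#' @export
invert_scaler <- function(scaler, M) {
  if (!is.matrix(M)) M <- as.matrix(M)
  rng <- scaler$max - scaler$min
  rng[scaler$constant] <- 1
  ctr <- (scaler$max + scaler$min) / 2
  sweep(sweep(M, 2, rng / 2, "*"), 2, ctr, "+")
}

#' Nguyen-Widrow network initialization
#'
#' Initializes the tanh hidden layers so that the active (approximately
#' linear) regions of the neurons tile the input range: each hidden layer
#' with fan-in `f` and `n` neurons draws random weight-row directions and
#' rescales every row to norm `0.7 * n^(1/f)`, and spreads the biases evenly
#' across the active range. The linear output layer is initialized with
#' small uniform values in `[-0.5, 0.5] / fan-in`.
#'
#' @param layer_sizes integer vector `c(n_in, hidden..., n_out)`, length >= 2.
#' @param seed integer seed; the same seed gives identical parameters.
#' @return object of class `mlp_params`: `layer_sizes`, lists `W` and `b`.
#' @export
#' @examples
#' p <- nguyen_widrow_init(c(12, 100, 20, 2), seed = 1)
#' sqrt(sum(p$W[[1]][1, ]^2)) # 0.7 * 100^(1/12)
nguyen_widrow_init <- function(layer_sizes, seed = 1) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2 || any(layer_sizes < 1)) {
    stop_kneeload("layer_sizes must be >= 2 positive integers", class = "kneeload_config_error")
  }
  L <- length(layer_sizes) - 1L
  with_seed(seed, {
    W <- vector("list", L)
    b <- vector("list", L)
    for (l in seq_len(L)) {
      f <- layer_sizes[l]
      n <- layer_sizes[l + 1L]
      if (l < L) {
        beta <- 0.7 * n^(1 / f)
        Wl <- matrix(runif(n * f, -1, 1), nrow = n, ncol = f)
        norms <- sqrt(rowSums(Wl^2))
        norms[norms == 0] <- 1
        Wl <- Wl * (beta / norms)
        bl <- if (n == 1) 0 else beta * seq(-1, 1, length.out = n)
        # align each bias with its row direction so centers spread both ways
        bl <- bl * sign(Wl[, 1] + (Wl[, 1] == 0))
      } else {
        Wl <- matrix(runif(n * f, -0.5, 0.5) / f, nrow = n, ncol = f)
        bl <- runif(n, -0.5, 0.5) / f
      }
      W[[l]] <- Wl
      b[[l]] <- bl
    }
    structure(list(layer_sizes = layer_sizes, W = W, b = b), class = "mlp_params")
  })
}

# --- parameter packing -------------------------------------------------------
# Flat parameter order: for each layer, W row-major (neuron-major), then b.

n_params <- function(params) {
  s <- params$layer_sizes
  sum(s[-1] * s[-length(s)]) + sum(s[-1])
}

pack_params <- function(params) {
  unlist(lapply(seq_along(params$W), function(l) {
    c(as.vector(t(params$W[[l]])), params$b[[l]])
  }), use.names = FALSE)
}

unpack_params <- function(theta, layer_sizes) {
  W <- list()
  b <- list()
  pos <- 0L
  for (l in seq_len(length(layer_sizes) - 1L)) {
    f <- layer_sizes[l]
    n <- layer_sizes[l + 1L]
    W[[l]] <- matrix(theta[pos + seq_len(n * f)], nrow = n, ncol = f, byrow = TRUE)
    pos <- pos + n * f
    b[[l]] <- theta[pos + seq_len(n)]
    pos <- pos + n
  }
  structure(list(layer_sizes = layer_sizes, W = W, b = b), class = "mlp_params")
}

# Forward pass in scaled space; optionally keep activations for backprop.
forward_scaled <- function(params, Xs, keep = FALSE) {
  L <- length(params$W)
  A <- vector("list", L + 1L)
  A[[1]] <- Xs
  for (l in seq_len(L)) {
    Z <- tcrossprod(A[[l]], params$W[[l]])
    Z <- sweep(Z, 2, params$b[[l]], "+")
    A[[l + 1L]] <- if (l < L) tanh(Z) else Z
  }
  if (keep) A else A[[L + 1L]]
}

#' Forward pass of the multilayer perceptron
#'
#' Scales inputs to `[-1, 1]` with the fitted input scaler, applies the tanh
#' hidden layers and the linear output layer, and maps the result back to
#' physical units with the inverse target scaler. Rows are independent.
#'
#' @param params an `mlp_params` (see [nguyen_widrow_init()]).
#' @param X `R x n_in` input matrix (physical units).
#' @param scalers scalers from [fit_scalers()] with `input` and `target`;
#'   `NULL` means identity scaling (inputs/outputs already in `[-1, 1]`).
#' @return `R x n_out` output matrix.
#' @export
mlp_forward <- function(params, X, scalers = NULL) {
  if (!is.matrix(X)) X <- matrix(X, ncol = params$layer_sizes[1])
  if (ncol(X) != params$layer_sizes[1]) {
    stop_kneeload(
      "input has ", ncol(X), " columns; network expects ",
      params$layer_sizes[1],
      class = "kneeload_dim_error"
    )
  }
  Xs <- if (is.null(scalers)) X else apply_scaler(scalers$input, X)
  out <- forward_scaled(params, Xs)
  if (is.null(scalers)) out else invert_scaler(scalers$target, out)
}

# Backpropagated Jacobian blocks of the scaled outputs w.r.t. all parameters.
# Returns, for each output c, an n x P matrix (rows = samples); d out_c / d theta.
jacobian_blocks <- function(params, Xs) {
  L <- length(params$W)
  sizes <- params$layer_sizes
  A <- forward_scaled(params, Xs, keep = TRUE)
  n <- nrow(Xs)
  C <- sizes[length(sizes)]
  P <- n_params(params)
  # layer parameter offsets in the flat vector
  offW <- integer(L)
  offb <- integer(L)
  pos <- 0L
  for (l in seq_len(L)) {
    offW[l] <- pos
    pos <- pos + sizes[l + 1L] * sizes[l]
    offb[l] <- pos
    pos <- pos + sizes[l + 1L]
  }
  lapply(seq_len(C), function(cc) {
    J <- matrix(0, nrow = n, ncol = P)
    # seed: derivative of output cc w.r.t. linear output pre-activation
    G <- matrix(0, nrow = n, ncol = C)
    G[, cc] <- 1
    for (l in rev(seq_len(L))) {
      nl <- sizes[l + 1L]
      fl <- sizes[l]
      Aprev <- A[[l]]
      # d out / d W_l[j, k] = G[, j] * Aprev[, k]; row-major flat index (j-1)*fl + k
      J[, offW[l] + seq_len(nl * fl)] <-
        G[, rep(seq_len(nl), each = fl), drop = FALSE] *
          Aprev[, rep(seq_len(fl), times = nl), drop = FALSE]
      J[, offb[l] + seq_len(nl)] <- G
      if (l > 1L) {
        G <- (G %*% params$W[[l]]) * (1 - A[[l]]^2)
      }
    }
    J
  })
}

#' Jacobian of the network outputs with respect to all parameters
#'
#' Exact backpropagated derivatives of every scalar (scaled-space) output
#' with respect to every weight and bias - the workhorse of
#' Levenberg-Marquardt training. Residual rows are ordered output-major:
#' all samples of output 1, then all samples of output 2, etc. Parameter
#' columns follow the flat packing (per layer: weights row-major, then
#' biases).
#'
#' @param params an `mlp_params`.
#' @param Xs `R x n_in` matrix in scaled space.
#' @return `(R * n_out) x P` Jacobian matrix.
#' @export
mlp_jacobian <- function(params, Xs) {
  if (!is.matrix(Xs)) Xs <- matrix(Xs, ncol = params$layer_sizes[1])
  if (ncol(Xs) != params$layer_sizes[1]) {
    stop_kneeload("input column count mismatch", class = "kneeload_dim_error")
  }
  do.call(rbind, jacobian_blocks(params, Xs))
}

# Accumulate J'J, J'e and SSE over row blocks without materializing the full
# Jacobian. Identical (to numerical round-off of the summation order) to
# direct assembly; `block_size` only bounds memory.
lm_normal_equations <- function(params, Xs, Ts, block_size = 2000L) {
  n <- nrow(Xs)
  P <- n_params(params)
  JtJ <- matrix(0, P, P)
  Jte <- numeric(P)
  sse <- 0
  starts <- seq(1L, n, by = block_size)
  for (s in starts) {
    e_idx <- seq(s, min(s + block_size - 1L, n))
    Xb <- Xs[e_idx, , drop = FALSE]
    Tb <- Ts[e_idx, , drop = FALSE]
    Jb <- jacobian_blocks(params, Xb)
    Yb <- forward_scaled(params, Xb)
    for (cc in seq_along(Jb)) {
      err <- Yb[, cc] - Tb[, cc]
      JtJ <- JtJ + crossprod(Jb[[cc]])
      Jte <- Jte + drop(crossprod(Jb[[cc]], err))
      sse <- sse + sum(err^2)
    }
  }
  list(JtJ = JtJ, Jte = Jte, sse = sse)
}

#' Training configuration for Levenberg-Marquardt
#'
#' @param max_epochs maximum training epochs (default 1000).
#' @param grad_tol stop when the gradient infinity norm falls below this
#'   (default 1e-6).
#' @param patience stop after this many consecutive epochs without a new
#'   gradient-norm minimum (default 6).
#' @param mu0,mu_increase,mu_decrease,mu_max Levenberg-Marquardt damping
#'   schedule: start value, factor applied after a rejected step, factor
#'   applied after an accepted step, and the ceiling beyond which training
#'   aborts. Defaults 1e-3, 10, 0.1, 1e10 (standard practice).
#' @param seed seed used for weight initialization by [train_network()].
#' @param block_size rows per Jacobian block in the normal-equation
#'   accumulation (memory knob only; results are independent of it).
#' @return object of class `train_config`.
#' @export
train_config <- function(max_epochs = 1000, grad_tol = 1e-6, patience = 6,
                         mu0 = 1e-3, mu_increase = 10, mu_decrease = 0.1,
                         mu_max = 1e10, seed = 1, block_size = 2000L) {
  if (max_epochs < 1 || grad_tol <= 0 || patience < 1) {
    stop_kneeload("invalid stopping configuration", class = "kneeload_config_error")
  }
  if (!(mu_decrease > 0 && mu_decrease < 1 && mu_increase > 1 && mu0 > 0 && mu_max > mu0)) {
    stop_kneeload("invalid damping schedule", class = "kneeload_config_error")
  }
  structure(
    list(
      max_epochs = as.integer(max_epochs), grad_tol = grad_tol,
      patience = as.integer(patience), mu0 = mu0,
      mu_increase = mu_increase, mu_decrease = mu_decrease, mu_max = mu_max,
      seed = as.integer(seed), block_size = as.integer(block_size)
    ),
    class = "train_config"
  )
}

#' Train a network with full-batch Levenberg-Marquardt
#'
#' Damped Gauss-Newton in scaled space: each epoch solves
#' `(J'J + mu I) delta = -J'e` and accepts the step only if the sum of
#' squared errors decreases (then `mu` shrinks); otherwise `mu` grows and
#' the step is retried within the epoch, up to `mu_max`. The normal
#' equations are accumulated blockwise, so the full Jacobian of a large
#' dataset is never materialized. Training stops at `max_epochs`, when the
#' gradient infinity norm `max |J'e|` drops below `grad_tol`, or when it has
#' not reached a new minimum for `patience` consecutive epochs.
#'
#' @param params initial `mlp_params`.
#' @param X,Y training matrices in scaled space (rows = samples).
#' @param config a [train_config()].
#' @return list with `params` (trained) and `log` (a `train_log` data frame
#'   of per-epoch `mse`, `grad_norm`, `mu`, with attribute `stop_reason` in
#'   `max_epochs`, `grad_tol`, `patience`, `mu_max`).
#' @export
train_lm <- function(params, X, Y, config = train_config()) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!is.matrix(Y)) Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) {
    stop_kneeload("X and Y row counts differ", class = "kneeload_dim_error")
  }
  if (ncol(X) != params$layer_sizes[1] ||
    ncol(Y) != params$layer_sizes[length(params$layer_sizes)]) {
    stop_kneeload("matrix dimensions do not match the network architecture",
      class = "kneeload_dim_error"
    )
  }
  theta <- pack_params(params)
  sizes <- params$layer_sizes
  P <- length(theta)
  n_resid <- nrow(X) * ncol(Y)
  mu <- config$mu0
  best_grad <- Inf
  stall <- 0L
  log_rows <- vector("list", config$max_epochs)
  stop_reason <- "max_epochs"
  epochs_done <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    cur <- unpack_params(theta, sizes)
    ne <- lm_normal_equations(cur, X, Y, config$block_size)
    grad <- max(abs(ne$Jte))
    log_rows[[epoch]] <- data.frame(
      epoch = epoch, mse = ne$sse / n_resid, grad_norm = grad, mu = mu
    )
    epochs_done <- epoch
    if (grad < config$grad_tol) {
      stop_reason <- "grad_tol"
      break
    }
    if (grad < best_grad) {
      best_grad <- grad
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) {
        stop_reason <- "patience"
        break
      }
    }
    # inner damping loop: find an SSE-decreasing step
    accepted <- FALSE
    while (!accepted) {
      H <- ne$JtJ
      diag(H) <- diag(H) + mu
      delta <- tryCatch(
        {
          U <- chol(H)
          -backsolve(U, forwardsolve(t(U), ne$Jte))
        },
        error = function(e) NULL
      )
      if (!is.null(delta)) {
        cand <- theta + drop(delta)
        cand_params <- unpack_params(cand, sizes)
        res <- forward_scaled(cand_params, X) - Y
        sse_new <- sum(res^2)
        if (is.finite(sse_new) && sse_new < ne$sse) {
          theta <- cand
          mu <- max(mu * config$mu_decrease, 1e-20)
          accepted <- TRUE
        }
      }
      if (!accepted) {
        mu <- mu * config$mu_increase
        if (mu > config$mu_max) break
      }
    }
    if (!accepted) {
      # no decreasing step exists below mu_max: numerically converged
      stop_reason <- "mu_max"
      break
    }
  }
  log <- do.call(rbind, log_rows[seq_len(epochs_done)])
  attr(log, "stop_reason") <- stop_reason
  class(log) <- c("train_log", class(log))
  list(params = unpack_params(theta, sizes), log = log)
}

#' Train a knee-moment estimation network end to end
#'
#' Convenience wrapper: fits min-max scalers on the training matrices (only;
#' held-out data must be scaled with these same training-set scalers),
#' initializes with Nguyen-Widrow at `config$seed`, and runs [train_lm()].
#'
#' @param X `R x 12` input matrix (physical units).
#' @param Y `R x C` target matrix (Nm/kg), `C` 1 or 2.
#' @param hidden integer vector of hidden-layer sizes (default `c(100, 20)`,
#'   the reference architecture).
#' @param config a [train_config()].
#' @return object of class `kneeload_mlp`: `params`, `scalers`, `log`,
#'   `outputs` (target column names).
#' @export
train_network <- function(X, Y, hidden = c(100, 20), config = train_config()) {
  if (!is.matrix(Y)) Y <- as.matrix(Y)
  scalers <- fit_scalers(X, Y)
  layer_sizes <- c(ncol(X), hidden, ncol(Y))
  params <- nguyen_widrow_init(layer_sizes, seed = config$seed)
  fit <- train_lm(params, apply_scaler(scalers$input, X),
    apply_scaler(scalers$target, Y),
    config = config
  )
  structure(
    list(
      params = fit$params, scalers = scalers, log = fit$log,
      outputs = colnames(Y)
    ),
    class = "kneeload_mlp"
  )
}

#' @export
predict.kneeload_mlp <- function(object, newdata, ...) {
  out <- mlp_forward(object$params, newdata, object$scalers)
  colnames(out) <- object$outputs
  out
}

#' @export
print.kneeload_mlp <- function(x, ...) {
  cat(sprintf(
    "<kneeload_mlp> layers %s; trained %d epochs (stop: %s), final MSE %.3g\n",
    paste(x$params$layer_sizes, collapse = "-"),
    nrow(x$log), attr(x$log, "stop_reason"), tail(x$log$mse, 1)
  ))
  invisible(x)
}
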