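#' Hidden-layer size from the empirical node formula
#'
#' `M = round(sqrt(N + L) + a)` with the offset `a` restricted to `[1, 10]`.
#' With the package's 98 features, one output and `a = 2` this gives the
#' 12 hidden units of the default architecture.
#'
#' @param n_inputs Number of input features `N`.
#' @param n_outputs Number of outputs `L`.
#' @param a_offset Integer offset `a` in `[1, 10]`.
#' @return Integer hidden-layer size.
#' @examples
#' hidden_nodes(98, 1, 2) # 12
#' @export
hidden_nodes <- function(n_inputs, n_outputs = 1, a_offset = 2) {
  stopifnot(n_inputs >= 1, n_outputs >= 1)
  if (a_offset < 1 || a_offset > 10) {
    rlang::abort("a_offset must lie in [1, 10]", class = "mirboost_input_error")
  }
  as.integer(round(sqrt(n_inputs + n_outputs) + a_offset))
}

#' Weak-learner network configuration
#'
#' One hidden layer of `tansig` (hyperbolic tangent) units and a `purelin`
#' (identity) output; mean-squared-error objective. Defaults follow the
#' package's standard recipe: 50 epochs, learning rate 0.1 (used by the
#' gradient-descent trainer only), MSE error bound 0.01, hidden size from
#' [hidden_nodes()] with offset 2, Levenberg-Marquardt training.
#'
#' @param n_inputs Number of input features.
#' @param n_hidden Hidden-layer size; `NULL` derives it via [hidden_nodes()].
#' @param n_outputs Number of output units (1 for the binary classifier).
#' @param a_offset Offset for the hidden-node formula.
#' @param epochs Maximum training epochs.
#' @param learning_rate Step size for the gradient-descent trainer.
#' @param error_bound Stop training once the weighted MSE falls below this.
#' @param trainer `"levenberg_marquardt"` or `"gradient_descent"`.
#' @return A `network_config` list.
#' @export
network_config <- function(n_inputs = 98, n_hidden = NULL, n_outputs = 1,
                           a_offset = 2, epochs = 50, learning_rate = 0.1,
                           error_bound = 0.01,
                           trainer = c("levenberg_marquardt", "gradient_descent")) {
  trainer <- match.arg(trainer)
  stopifnot(epochs >= 1, learning_rate > 0, error_bound > 0)
  if (is.null(n_hidden)) n_hidden <- hidden_nodes(n_inputs, n_outputs, a_offset)
  structure(list(n_inputs = as.integer(n_inputs),
                 n_hidden = as.integer(n_hidden),
                 n_outputs = as.integer(n_outputs),
                 a_offset = as.integer(a_offset),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 error_bound = error_bound,
                 hidden_transfer = "tansig",
                 output_transfer = "purelin",
                 trainer = trainer),
            class = "network_config")
}

init_weak <- function(config) {
  M <- config$n_hidden; N <- config$n_inputs
  # uniform [-0.5, 0.5] initialization from the current RNG stream
  list(w1 = matrix(stats::runif(M * N, -0.5, 0.5), M, N),
       b1 = stats::runif(M, -0.5, 0.5),
       w2 = stats::runif(M, -0.5, 0.5),
       b2 = stats::runif(1, -0.5, 0.5))
}

scale_input <- function(x, center, scale) {
  sweep(sweep(x, 2, center, "-"), 2, scale, "/")
}

#' Forward pass of a weak learner
#'
#' `purelin(W2 . tansig(W1 . x_scaled + b1) + b2)`; input standardization
#' uses the center/scale stored in the learner at training time.
#'
#' @param learner A `bp_weak` object from [train_weak()].
#' @param x Numeric matrix (rows = samples) or a single feature vector.
#' @return Numeric vector of raw scores, one per row.
#' @export
nn_forward <- function(learner, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(learner$w1)) {
    rlang::abort(sprintf("input has %d columns, network expects %d",
                         ncol(x), ncol(learner$w1)),
                 class = "mirboost_input_error")
  }
  xs <- scale_input(x, learner$center, learner$scale)
  h <- tanh(sweep(xs %*% t(learner$w1), 2, learner$b1, "+"))
  drop(h %*% learner$w2 + learner$b2)
}

# analytic Jacobian of the scalar output w.r.t. the packed parameter vector
# theta = [vec(w1 by input column) | b1 | w2 | b2]; xs is pre-scaled
weak_jacobian <- function(par, xs) {
  M <- length(par$b1); N <- ncol(par$w1); n <- nrow(xs)
  h <- tanh(sweep(xs %*% t(par$w1), 2, par$b1, "+"))
  d <- (1 - h^2) * matrix(par$w2, n, M, byrow = TRUE)  # dy/d(pre-activation_j)
  J <- matrix(0, n, M * N + M + M + 1)
  for (k in seq_len(N)) {
    J[, ((k - 1) * M + 1):(k * M)] <- d * xs[, k]
  }
  J[, (M * N + 1):(M * N + M)] <- d
  J[, (M * N + M + 1):(M * N + 2 * M)] <- h
  J[, M * N + 2 * M + 1] <- 1
  list(J = J, yhat = drop(h %*% par$w2 + par$b2))
}

pack_par <- function(p) c(p$w1, p$b1, p$w2, p$b2)

unpack_par <- function(theta, M, N) {
  list(w1 = matrix(theta[seq_len(M * N)], M, N),
       b1 = theta[(M * N + 1):(M * N + M)],
       w2 = theta[(M * N + M + 1):(M * N + 2 * M)],
       b2 = theta[M * N + 2 * M + 1])
}

train_lm <- function(par, xs, y, w, config) {
  theta <- pack_par(par)
  M <- config$n_hidden; N <- config$n_inputs
  sw <- sqrt(w)
  mse_of <- function(yhat) sum(w * (yhat - y)^2)
  fj <- weak_jacobian(par, xs)
  mse <- mse_of(fj$yhat)
  mu <- 1e-3
  epoch <- 0L
  converged <- FALSE
  while (epoch < config$epochs && mse > config$error_bound) {
    epoch <- epoch + 1L
    r <- sw * (fj$yhat - y)
    Jw <- fj$J * sw
    g <- crossprod(Jw, r)
    if (max(abs(g)) < 1e-7) { converged <- TRUE; break }
    A <- crossprod(Jw)
    improved <- FALSE
    while (mu <= 1e10) {
      delta <- tryCatch(
        solve(A + diag(mu, nrow(A)), -g),
        error = function(e) NULL
      )
      if (!is.null(delta)) {
        cand <- unpack_par(theta + as.numeric(delta), M, N)
        fj_cand <- weak_jacobian(cand, xs)
        mse_cand <- mse_of(fj_cand$yhat)
        if (mse_cand < mse) {
          theta <- pack_par(cand); par <- cand
          fj <- fj_cand; mse <- mse_cand
          mu <- max(mu / 10, 1e-20)
          improved <- TRUE
          break
        }
      }
      mu <- mu * 10
    }
    if (!improved) { converged <- TRUE; break }  # damping exhausted
  }
  list(par = par, mse = mse, epochs_run = epoch,
       converged = converged || mse <= config$error_bound)
}

train_gd <- function(par, xs, y, w, config) {
  mse <- Inf
  epoch <- 0L
  n <- nrow(xs)
  while (epoch < config$epochs) {
    epoch <- epoch + 1L
    h <- tanh(sweep(xs %*% t(par$w1), 2, par$b1, "+"))
    yhat <- drop(h %*% par$w2 + par$b2)
    err <- yhat - y
    mse <- sum(w * err^2)
    if (mse <= config$error_bound) break
    # weighted batch gradients of sum_i w_i (yhat_i - y_i)^2
    dout <- 2 * w * err
    gw2 <- crossprod(h, dout)
    gb2 <- sum(dout)
    dh <- (dout %*% t(par$w2)) * (1 - h^2)
    gw1 <- t(dh) %*% xs
    gb1 <- colSums(dh)
    lr <- config$learning_rate
    par$w1 <- par$w1 - lr * gw1
    par$b1 <- par$b1 - lr * gb1
    par$w2 <- par$w2 - lr * as.numeric(gw2)
    par$b2 <- par$b2 - lr * gb2
  }
  list(par = par, mse = mse, epochs_run = epoch,
       converged = mse <= config$error_bound)
}

#' Train one backpropagation weak learner
#'
#' Fits the single-hidden-layer network to targets in `{-1, +1}` by
#' minimizing the weighted mean squared error
#' `sum_i w_i (f(x_i) - y_i)^2` (weights on the probability simplex).
#' Training stops at `config$epochs` epochs or as soon as the weighted MSE
#' drops to `config$error_bound`, whichever comes first; the
#' Levenberg-Marquardt trainer additionally stops on a vanishing gradient or
#' exhausted damping. Inputs are standardized per column (parameters stored
#' in the learner; zero-variance columns get unit scale).
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Numeric targets in `{-1, +1}`.
#' @param weights Sample weights summing to 1; `NULL` means uniform.
#' @param config A [network_config()]; `NULL` derives one from `ncol(x)`.
#' @param seed Optional integer seed for weight initialization; `NULL` draws
#'   from the current RNG stream.
#' @return A `bp_weak` object: weights, biases, scaling parameters and
#'   training diagnostics (`mse`, `epochs_run`, `converged`, `note`).
#' @export
train_weak <- function(x, y, weights = NULL, config = NULL, seed = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (length(y) != n) {
    rlang::abort("length(y) must equal nrow(x)", class = "mirboost_input_error")
  }
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n || any(weights < 0)) {
    rlang::abort("weights must be non-negative, one per sample",
                 class = "mirboost_input_error")
  }
  weights <- weights / sum(weights)
  if (is.null(config)) config <- network_config(n_inputs = ncol(x))
  if (config$n_inputs != ncol(x)) {
    rlang::abort("config$n_inputs does not match ncol(x)",
                 class = "mirboost_input_error")
  }
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  xs <- scale_input(x, center, scale)

  fit_one <- function() {
    if (length(unique(y)) < 2) {
      warning("single-class targets: returning a constant model",
              call. = FALSE)
      M <- config$n_hidden; N <- config$n_inputs
      par <- list(w1 = matrix(0, M, N), b1 = rep(0, M),
                  w2 = rep(0, M), b2 = y[1])
      return(list(par = par, mse = 0, epochs_run = 0L, converged = TRUE,
                  note = "constant model (degenerate single-class targets)"))
    }
    par <- init_weak(config)
    fit <- if (config$trainer == "levenberg_marquardt") {
      train_lm(par, xs, y, weights, config)
    } else {
      train_gd(par, xs, y, weights, config)
    }
    fit$note <- NA_character_
    fit
  }
  fit <- if (is.null(seed)) fit_one() else withr::with_seed(seed, fit_one())

  structure(c(fit$par,
              list(center = center, scale = scale, config = config,
                   diagnostics = list(mse = fit$mse,
                                      epochs_run = fit$epochs_run,
                                      converged = fit$converged,
                                      note = fit$note))),
            class = "bp_weak")
}

#' @export
print.bp_weak <- function(x, ...) {
  cat(sprintf("<bp_weak> %d-%d-%d network (%s), weighted MSE %.4g after %d epochs\n",
              ncol(x$w1), nrow(x$w1), 1L, x$config$trainer,
              x$diagnostics$mse, x$diagnostics$epochs_run))
  invisible(x)
}
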