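#' Levenberg-Marquardt training configuration
#'
#' Controls the damped least-squares training loop of [mlp_lm()]. The
#' damping factor `mu` interpolates between Gauss-Newton (`mu -> 0`) and
#' scaled gradient descent (`mu -> Inf`): a step is accepted only if it
#' strictly decreases the sum-of-squares loss, after which `mu` is relaxed
#' by `mu_down`; a rejected step escalates `mu` by `mu_up` and retries.
#'
#' @param mu_init initial damping factor.
#' @param mu_up multiplier applied to `mu` after a rejected step (> 1).
#' @param mu_down multiplier applied after an accepted step (in (0, 1)).
#' @param mu_max ceiling on `mu`; training stops when no acceptable step is
#'   found below it.
#' @param max_epochs maximum number of accepted update steps.
#' @param grad_tol stop when the infinity norm of the loss gradient falls
#'   below this.
#' @param loss_tol stop when the sum-of-squares loss falls below this.
#' @param standardize z-score inputs using training-set statistics before
#'   fitting (recommended: the entropy features span orders of magnitude).
#' @return A list of class `mlp_lm_control`.
#' @export
mlp_lm_control <- function(mu_init = 1e-3, mu_up = 10, mu_down = 0.1,
                           mu_max = 1e10, max_epochs = 200L,
                           grad_tol = 1e-7, loss_tol = 1e-10,
                           standardize = TRUE) {
  stopifnot(mu_init > 0, mu_up > 1, mu_down > 0, mu_down < 1,
            mu_max > mu_init, max_epochs >= 0, grad_tol >= 0, loss_tol >= 0)
  structure(list(mu_init = mu_init, mu_up = mu_up, mu_down = mu_down,
                 mu_max = mu_max, max_epochs = as.integer(max_epochs),
                 grad_tol = grad_tol, loss_tol = loss_tol,
                 standardize = isTRUE(standardize)),
            class = "mlp_lm_control")
}

# ---- parameter vector layout -------------------------------------------
# theta = (vec(W_in) [n_h x n_in, column-major], b_h [n_h],
#          w_out [n_h], b_out [1])

init_weights <- function(n_in, n_hidden, seed) {
  rs <- local_rng(seed)
  on.exit(restore_rng(rs))
  n_par <- n_hidden * n_in + n_hidden + n_hidden + 1L
  stats::runif(n_par, min = -0.5, max = 0.5)
}

# Preserve the caller's RNG stream around internal seeded draws.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

unpack_theta <- function(theta, n_in, n_h) {
  i <- n_h * n_in
  list(W = matrix(theta[seq_len(i)], n_h, n_in),
       b_h = theta[i + seq_len(n_h)],
       w_out = theta[i + n_h + seq_len(n_h)],
       b_out = theta[i + 2L * n_h + 1L])
}

# Forward pass for a row matrix X (n x n_in). Returns output vector and the
# hidden activations needed by the Jacobian.
mlp_forward <- function(theta, X, n_h) {
  p <- unpack_theta(theta, ncol(X), n_h)
  A <- tanh(sweep(X %*% t(p$W), 2L, p$b_h, "+"))   # n x n_h
  z <- drop(A %*% p$w_out) + p$b_out
  list(out = stats::plogis(z), A = A, w_out = p$w_out)
}

# Jacobian dO/dtheta (n x n_par), matching the theta layout above.
mlp_jacobian <- function(theta, X, n_h) {
  fw <- mlp_forward(theta, X, n_h)
  s <- fw$out * (1 - fw$out)                        # logistic derivative
  D <- s * (1 - fw$A^2) * matrix(fw$w_out, nrow(X), n_h, byrow = TRUE)
  p <- ncol(X)
  J_W <- D[, rep(seq_len(n_h), times = p), drop = FALSE] *
    X[, rep(seq_len(p), each = n_h), drop = FALSE]
  cbind(J_W, D, s * fw$A, s)
}

lm_fit_loop <- function(theta, X, y, n_h, control) {
  loss_of <- function(th) {
    e <- y - mlp_forward(th, X, n_h)$out
    sum(e^2)
  }
  mu <- control$mu_init
  loss <- loss_of(theta)
  history <- loss
  epoch <- 0L
  converged <- "max_epochs"
  while (epoch < control$max_epochs) {
    fw <- mlp_forward(theta, X, n_h)
    e <- y - fw$out
    J <- mlp_jacobian(theta, X, n_h)     # dO/dtheta
    g <- drop(crossprod(J, e))           # -grad of 0.5*SSE
    if (max(abs(g)) < control$grad_tol) { converged <- "grad_tol"; break }
    if (loss < control$loss_tol) { converged <- "loss_tol"; break }
    JtJ <- crossprod(J)
    accepted <- FALSE
    while (!accepted && mu <= control$mu_max) {
      delta <- tryCatch(
        solve(JtJ + diag(mu, ncol(J)), g),
        error = function(cond) NULL)     # singular: escalate damping
      if (!is.null(delta)) {
        cand <- theta + delta
        cand_loss <- loss_of(cand)
        if (is.finite(cand_loss) && cand_loss < loss) {
          theta <- cand
          loss <- cand_loss
          mu <- max(mu * control$mu_down, 1e-20)
          accepted <- TRUE
        }
      }
      if (!accepted) mu <- mu * control$mu_up
    }
    if (!accepted) { converged <- "mu_max"; break }
    epoch <- epoch + 1L
    history <- c(history, loss)
  }
  list(theta = theta, loss_history = history, epochs = epoch,
       converged = converged, mu_final = mu)
}

#' Fit a single-hidden-layer neural classifier by Levenberg-Marquardt
#'
#' Trains a feed-forward network — one tanh hidden layer (default 10 units,
#' the size used throughout the focal/non-focal EEG experiments) and one
#' logistic output unit — by Levenberg-Marquardt damped least squares on the
#' sum-of-squares residuals `y - p(x)`, the classic `trainlm`-style recipe.
#' The positive class is `"FC"`; labels may be given as a factor/character
#' vector with levels NFC/FC or as 0/1 numerics. Inputs are z-scored on
#' training statistics by default. Training is deterministic given `seed`.
#'
#' @param x numeric feature matrix (records in rows), or a formula.
#' @param y class labels (`"FC"`/`"NFC"`, factor, logical, or 0/1).
#' @param n_hidden hidden-layer width.
#' @param seed integer seed for the weight initialisation.
#' @param control an [mlp_lm_control()] configuration.
#' @param ... passed between methods.
#' @return An object of class `mlp_lm` with components `theta` (packed
#'   weights), `n_in`, `n_hidden`, `center`/`scale` (standardisation
#'   constants), `loss_history`, `epochs`, `converged`, `levels`, `seed` and
#'   `call`. Methods: `print`, `summary`, `coef`, `predict`, `residuals`,
#'   `plot`.
#' @examples
#' X <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 3), 30))
#' y <- rep(c("NFC", "FC"), each = 30)
#' fit <- mlp_lm(X, y, seed = 1)
#' mean(predict(fit, X, type = "class") == y)
#' @export
mlp_lm <- function(x, ...) UseMethod("mlp_lm")

#' @rdname mlp_lm
#' @export
mlp_lm.default <- function(x, y, n_hidden = 10L, seed = 1L,
                           control = mlp_lm_control(), ...) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("'x' must be finite", call. = FALSE)
  y01 <- encode_labels(y)
  if (nrow(X) != length(y01))
    stop("nrow(x) must match length(y)", call. = FALSE)
  if (min(table(y01)) < 2L)
    stop("need at least 2 examples per class", call. = FALSE)
  n_in <- ncol(X)
  n_h <- as.integer(n_hidden)
  stopifnot(n_in >= 1L, n_h >= 1L)

  if (control$standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, stats::sd)
    scl[scl == 0] <- 1
  } else {
    ctr <- numeric(n_in); scl <- rep(1, n_in)
  }
  Xs <- scale(X, center = ctr, scale = scl)

  theta0 <- init_weights(n_in, n_h, seed)
  fit <- lm_fit_loop(theta0, Xs, y01, n_h, control)

  structure(
    list(theta = fit$theta, n_in = n_in, n_hidden = n_h,
         center = ctr, scale = scl,
         loss_history = fit$loss_history, epochs = fit$epochs,
         converged = fit$converged, mu_final = fit$mu_final,
         levels = c("NFC", "FC"), seed = as.integer(seed),
         control = control, fitted_values = NULL, y = y01,
         feature_names = colnames(X), call = match.call()),
    class = "mlp_lm"
  ) -> obj
  obj$fitted_values <- predict(obj, X, type = "response")
  obj
}

#' @param formula model formula `label ~ feat1 + feat2` (or `label ~ .`).
#' @param data data.frame holding the formula variables.
#' @rdname mlp_lm
#' @export
mlp_lm.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  obj <- mlp_lm.default(X, y, ...)
  obj$call <- match.call()
  obj
}

encode_labels <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    bad <- setdiff(unique(y), c("NFC", "FC"))
    if (length(bad))
      stop("labels must be \"NFC\"/\"FC\" (or 0/1); got: ",
           paste(bad, collapse = ", "), call. = FALSE)
    return(as.numeric(y == "FC"))
  }
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1)))
    stop("numeric labels must be 0 (NFC) or 1 (FC)", call. = FALSE)
  y
}

#' Predict method for `mlp_lm` fits
#'
#' @param object an [mlp_lm()] fit.
#' @param newdata feature matrix or data.frame with the training columns.
#' @param type `"response"` for the posterior-like network output in (0, 1),
#'   `"class"` for hard NFC/FC labels.
#' @param threshold decision threshold on the response; the positive class
#'   FC is predicted when the response is `>= threshold` (ties go to FC).
#' @param ... unused.
#' @return Numeric vector (`type = "response"`) or character vector of
#'   `"NFC"`/`"FC"` labels.
#' @export
predict.mlp_lm <- function(object, newdata, type = c("response", "class"),
                           threshold = 0.5, ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(X)) &&
      all(object$feature_names %in% colnames(X)))
    X <- X[, object$feature_names, drop = FALSE]
  storage.mode(X) <- "double"
  if (ncol(X) != object$n_in)
    stop(sprintf("newdata has %d columns, model expects %d",
                 ncol(X), object$n_in), call. = FALSE)
  Xs <- scale(X, center = object$center, scale = object$scale)
  p <- mlp_forward(object$theta, Xs, object$n_hidden)$out
  if (type == "response") return(unname(p))
  ifelse(p >= threshold, "FC", "NFC")
}

#' @export
print.mlp_lm <- function(x, ...) {
  cat(sprintf("Levenberg-Marquardt MLP: %d-%d-1 (tanh/logistic), %d weights\n",
              x$n_in, x$n_hidden, length(x$theta)))
  cat(sprintf("  %d accepted epochs, stop: %s, final SSE %.4g\n",
              x$epochs, x$converged, utils::tail(x$loss_history, 1L)))
  invisible(x)
}

#' @export
summary.mlp_lm <- function(object, ...) {
  pred <- ifelse(object$fitted_values >= 0.5, 1, 0)
  acc <- mean(pred == object$y)
  out <- list(fit = object, train_accuracy = acc,
              final_loss = utils::tail(object$loss_history, 1L))
  class(out) <- "summary.mlp_lm"
  out
}

#' @export
print.summary.mlp_lm <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  training accuracy %.4f (threshold 0.5)\n", x$train_accuracy))
  invisible(x)
}

#' @export
coef.mlp_lm <- function(object, ...) {
  p <- unpack_theta(object$theta, object$n_in, object$n_hidden)
  if (!is.null(object$feature_names)) colnames(p$W) <- object$feature_names
  p
}

#' @export
residuals.mlp_lm <- function(object, ...) object$y - object$fitted_values

#' @export
plot.mlp_lm <- function(x, ...) {
  plot(seq_along(x$loss_history) - 1L, x$loss_history, type = "b",
       log = "y", xlab = "accepted epoch", ylab = "sum-of-squares loss",
       main = "Levenberg-Marquardt training curve", ...)
  invisible(x)
}
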