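make_gaussian_task <- function(n_per_class, delta = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n_per_class), ncol = 2),
             matrix(rnorm(2 * n_per_class, mean = delta), ncol = 2))
  colnames(X) <- c("f1", "f2")
  list(X = X, y = rep(c("NFC", "FC"), each = n_per_class))
}

test_that("weight initialisation is seeded and correctly sized", {
  w1 <- fwhteeg:::init_weights(10, 10, seed = 5)
  w2 <- fwhteeg:::init_weights(10, 10, seed = 5)
  w3 <- fwhteeg:::init_weights(10, 10, seed = 6)
  expect_identical(w1, w2)
  expect_false(identical(w1, w3))
  expect_length(w1, 10 * 10 + 10 + 10 + 1)  # 121 parameters
})

test_that("forward pass stays in (0, 1) and is 0.5 at zero weights", {
  X <- matrix(rnorm(20), 5, 4)
  theta0 <- numeric(4 * 3 + 3 + 3 + 1)
  expect_equal(fwhteeg:::mlp_forward(theta0, X, 3)$out, rep(0.5, 5))
  theta <- fwhteeg:::init_weights(4, 3, 1)
  out <- fwhteeg:::mlp_forward(theta, X * 100, 3)$out
  expect_true(all(out > 0 & out < 1))
})

test_that("analytic Jacobian matches central finite differences", {
  set.seed(21)
  X <- matrix(rnorm(5 * 3), 5, 3)
  n_h <- 4
  for (trial in 1:10) {
    theta <- rnorm(3 * n_h + n_h + n_h + 1, sd = 0.8)
    J <- fwhteeg:::mlp_jacobian(theta, X, n_h)
    h <- 1e-6
    J_num <- sapply(seq_along(theta), function(p) {
      tp <- tm <- theta
      tp[p] <- tp[p] + h
      tm[p] <- tm[p] - h
      (fwhteeg:::mlp_forward(tp, X, n_h)$out -
         fwhteeg:::mlp_forward(tm, X, n_h)$out) / (2 * h)
    })
    expect_lt(max(abs(J - J_num)) / max(abs(J)), 1e-6)
  }
})

test_that("training solves XOR exactly across seeds", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c(0, 1, 1, 0)
  for (seed in 1:5) {
    fit <- mlp_lm(X, y, n_hidden = 10, seed = seed)
    pred <- as.numeric(predict(fit, X) >= 0.5)
    expect_equal(pred, y)
  }
})

test_that("accepted steps strictly decrease the loss; training is seeded", {
  task <- make_gaussian_task(40, delta = 2, seed = 3)
  fit <- mlp_lm(task$X, task$y, seed = 9)
  expect_true(all(diff(fit$loss_history) < 0))
  fit2 <- mlp_lm(task$X, task$y, seed = 9)
  expect_identical(fit$loss_history, fit2$loss_history)
  expect_identical(fit$theta, fit2$theta)
})

test_that("a zero-epoch budget returns the initial network unchanged", {
  task <- make_gaussian_task(10, seed = 4)
  fit <- mlp_lm(task$X, task$y, seed = 2,
                control = mlp_lm_control(max_epochs = 0))
  expect_identical(fit$theta, fwhteeg:::init_weights(2, 10, 2))
  expect_equal(fit$epochs, 0L)
})

test_that("well-separated Gaussians are fit to near-perfect accuracy", {
  task <- make_gaussian_task(100, delta = 4, seed = 5)
  fit <- mlp_lm(task$X, task$y, seed = 1)
  acc <- mean(predict(fit, task$X, type = "class") == task$y)
  expect_gte(acc, 0.99)
})

test_that("large damping turns the LM step into a gradient step", {
  set.seed(22)
  X <- matrix(rnorm(30 * 3), 30, 3)
  y <- as.numeric(rnorm(30) > 0)
  n_h <- 4
  theta <- rnorm(3 * n_h + n_h + n_h + 1)
  J <- fwhteeg:::mlp_jacobian(theta, X, n_h)
  e <- y - fwhteeg:::mlp_forward(theta, X, n_h)$out
  g <- drop(crossprod(J, e))
  mu <- 1e8
  delta <- solve(crossprod(J) + diag(mu, length(theta)), g)
  angle <- acos(sum(delta * g) / sqrt(sum(delta^2) * sum(g^2))) * 180 / pi
  expect_lt(angle, 1)
})

test_that("prediction applies the documented decision rule", {
  task <- make_gaussian_task(20, seed = 6)
  fit <- mlp_lm(task$X, task$y, seed = 1)
  p <- predict(fit, task$X)
  cls <- predict(fit, task$X, type = "class")
  expect_identical(cls, ifelse(p >= 0.5, "FC", "NFC"))
  # threshold above 1 can never fire the positive class
  expect_true(all(predict(fit, task$X, type = "class",
                          threshold = 1.1) == "NFC"))
  expect_error(predict(fit, task$X[, 1, drop = FALSE]), "expects 2")
})

test_that("the formula interface and label checks work", {
  task <- make_gaussian_task(20, seed = 8)
  d <- data.frame(task$X, label = task$y)
  fit <- mlp_lm(label ~ f1 + f2, data = d, seed = 1)
  expect_s3_class(fit, "mlp_lm")
  expect_gte(mean(predict(fit, d[, 1:2], type = "class") == task$y), 0.9)
  expect_error(mlp_lm(task$X, rep("banana", 40)), "NFC")
  expect_error(mlp_lm(task$X, rep(2, 40)), "0 \\(NFC\\) or 1")
  expect_error(mlp_lm(task$X, c(rep(0, 39), 1)), "2 examples")
})
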