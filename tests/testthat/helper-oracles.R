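# Independent naive references for the nonlinear statistics, transcribed
# directly from their defining formulas (template matrices + explicit
# pairwise Chebyshev distances). Deliberately separate from the package's
# compiled kernels.

oracle_templates <- function(y, mm, nt) {
  vapply(seq_len(nt), function(i) y[i + 0:(mm - 1L)], numeric(mm))
}

# ApEn: N-mm+1 templates, self-matches included, phi = mean(log(match frac))
oracle_apen <- function(y, m, r) {
  phi <- function(mm) {
    nt <- length(y) - mm + 1L
    tmpl <- matrix(oracle_templates(y, mm, nt), nrow = mm)
    logc <- vapply(seq_len(nt), function(i) {
      d <- apply(abs(tmpl - tmpl[, i]), 2L, max)
      log(mean(d <= r))
    }, numeric(1L))
    mean(logc)
  }
  phi(m) - phi(m + 1L)
}

# SampEn pair counts over unordered pairs, self-matches excluded; both
# template lengths use the first N-m start points.
oracle_sampen_counts <- function(y, m, r) {
  nt <- length(y) - m
  count <- function(mm) {
    tmpl <- matrix(oracle_templates(y, mm, nt), nrow = mm)
    tot <- 0L
    for (i in seq_len(nt - 1L)) {
      d <- apply(abs(tmpl[, (i + 1L):nt, drop = FALSE] - tmpl[, i]), 2L, max)
      tot <- tot + sum(d <= r)
    }
    tot
  }
  c(A = count(m + 1L), B = count(m))
}

oracle_sampen <- function(y, m, r) {
  cnt <- oracle_sampen_counts(y, m, r)
  -log(cnt["A"] / cnt["B"])
}

# FuzzyEn: baseline-removed templates, exponential membership, mean over
# ordered pairs j != i.
oracle_fuzzyen <- function(y, m, n_exp, p) {
  nt <- length(y) - m
  phi <- function(mm) {
    tmpl <- matrix(oracle_templates(y, mm, nt), nrow = mm)
    tmpl <- sweep(tmpl, 2L, colMeans(tmpl))
    acc <- 0
    for (i in seq_len(nt)) {
      d <- apply(abs(tmpl[, -i, drop = FALSE] - tmpl[, i]), 2L, max)
      acc <- acc + mean(exp(-d^n_exp / p))
    }
    acc / nt
  }
  log(phi(m)) - log(phi(m + 1L))
}

# PermEn by exhaustive ordinal-pattern tabulation; ties ranked by time
# index (ties.method = "first").
oracle_permen <- function(y, k, tau = 1L, normalized = TRUE) {
  nt <- length(y) - (k - 1L) * tau
  pats <- vapply(seq_len(nt), function(t)
    paste(rank(y[t + (0:(k - 1L)) * tau], ties.method = "first"),
          collapse = "."), character(1L))
  p <- table(pats) / nt
  h <- -sum(p * log(p))
  if (normalized) h / log(factorial(k)) else h
}

# Pooled-variance two-sample t statistic and p-value in closed form.
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  c(t = t, p = 2 * pt(-abs(t), df = nx + ny - 2))
}

random_test_series <- function(n, kind = c("ar1", "white", "mixed")) {
  kind <- match.arg(kind)
  switch(kind,
    white = rnorm(n),
    ar1 = as.numeric(stats::filter(rnorm(n), 0.8, method = "recursive")),
    mixed = rnorm(n) + sin(seq_len(n) / 5))
}
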