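#' Entropy parameter set
#'
#' Bundles every tunable of the five entropy features. Tolerances are
#' expressed as fractions of the series standard deviation and resolved to
#' absolute values per channel inside [extract_feature_vector()], which makes
#' the pipeline invariant to an overall amplitude rescaling of the input.
#' Defaults are the community-standard choices for biomedical series:
#' embedding dimension 2, tolerance 0.2 SD, ordinal order 3 with delay 1,
#' fuzzy gradient exponent 2.
#'
#' @param embed_m embedding dimension for ApEn and SampEn.
#' @param tol_frac ApEn/SampEn tolerance as a fraction of the series SD.
#' @param perm_order ordinal pattern order (embedding dimension) for PermEn.
#' @param perm_delay embedding delay for PermEn.
#' @param fuzzy_m embedding dimension for FuzzyEn.
#' @param fuzzy_n gradient exponent of the exponential membership function.
#' @param fuzzy_tol_frac membership width as a fraction of the series SD.
#' @param logen_floor floor applied to squared samples before the log in
#'   LogEn, so exact zeros stay finite.
#' @param max_series_len optional cap: if set, coefficient vectors longer
#'   than this are decimated (every `ceiling(n/max)`th value) before the
#'   quadratic-time entropies. Default `Inf` (full vector).
#' @return A list of class `entropy_params`.
#' @export
entropy_params <- function(embed_m = 2L, tol_frac = 0.2,
                           perm_order = 3L, perm_delay = 1L,
                           fuzzy_m = 2L, fuzzy_n = 2, fuzzy_tol_frac = 0.2,
                           logen_floor = 1e-12, max_series_len = Inf) {
  p <- list(embed_m = as.integer(embed_m), tol_frac = tol_frac,
            perm_order = as.integer(perm_order),
            perm_delay = as.integer(perm_delay),
            fuzzy_m = as.integer(fuzzy_m), fuzzy_n = fuzzy_n,
            fuzzy_tol_frac = fuzzy_tol_frac,
            logen_floor = logen_floor, max_series_len = max_series_len)
  stopifnot(p$embed_m >= 1L, p$tol_frac > 0, p$perm_order >= 2L,
            p$perm_delay >= 1L, p$fuzzy_m >= 1L, p$fuzzy_n > 0,
            p$fuzzy_tol_frac > 0, p$logen_floor > 0, p$max_series_len >= 64)
  class(p) <- "entropy_params"
  p
}

check_series <- function(series, m) {
  series <- as.numeric(series)
  if (!all(is.finite(series))) stop("series must be finite", call. = FALSE)
  if (length(series) <= m + 1L)
    stop(sprintf("series length %d too short for embedding dimension %d",
                 length(series), m), call. = FALSE)
  series
}

#' Approximate entropy
#'
#' Template-matching regularity statistic of Pincus: the negative mean log
#' conditional probability that runs of `m` samples that match within
#' tolerance `r_abs` (Chebyshev distance) still match at length `m + 1`.
#' Self-matches are counted, so the statistic is biased but always defined.
#' Lower values indicate a more regular (self-similar) series.
#'
#' @param series numeric vector, length greater than `m + 1`.
#' @param m embedding dimension.
#' @param r_abs absolute match tolerance (same units as the series; the
#'   pipeline uses `tol_frac * sd(series)`).
#' @return A single non-negative number (up to floating-point error).
#' @examples
#' approximate_entropy(rep(1, 50), m = 2, r_abs = 0.1)  # exactly 0
#' @export
approximate_entropy <- function(series, m = 2L, r_abs) {
  series <- check_series(series, m)
  if (!is.numeric(r_abs) || r_abs <= 0)
    stop("'r_abs' must be positive", call. = FALSE)
  .apen_cpp(series, as.integer(m), r_abs)
}

#' Sample entropy
#'
#' Richman-Moorman revision of approximate entropy: `-log(A/B)` where `B`
#' counts pairs of length-`m` templates within `r_abs` (Chebyshev) and `A`
#' the subset still within tolerance at length `m + 1`, self-matches
#' excluded. Larger values mean a less predictable series. When no template
#' pairs match at all (`B = 0`), or none continue to match (`A = 0`), the
#' statistic is undefined/infinite; a documented finite cap
#' `log(N - m) + log(N - m - 1)` (the value had exactly one pair matched) is
#' returned instead, carrying attribute `degenerate = TRUE`, so feature
#' tables stay finite.
#'
#' @inheritParams approximate_entropy
#' @return A single non-negative number; degenerate inputs yield the cap
#'   value with attribute `degenerate`.
#' @export
sample_entropy <- function(series, m = 2L, r_abs) {
  series <- check_series(series, m)
  if (!is.numeric(r_abs) || r_abs <= 0)
    stop("'r_abs' must be positive", call. = FALSE)
  cnt <- .sampen_counts_cpp(series, as.integer(m), r_abs)
  a <- cnt[1L]; b <- cnt[2L]
  nt <- length(series) - m
  cap <- log(nt) + log(nt - 1)
  if (b == 0 || a == 0)
    return(structure(cap, degenerate = TRUE))
  min(-log(a / b), cap)
}

# Lehmer pattern codes of ordinal (rank) patterns, ties broken by time
# index. Vectorised over all embedded windows: for each pair (l, j), l < j,
# count windows where the later element sorts before the earlier one.
ordinal_pattern_codes <- function(series, k, tau) {
  n_vec <- length(series) - (k - 1L) * tau
  idx <- seq_len(n_vec)
  cols <- lapply(0:(k - 1L), function(d) series[idx + d * tau])
  # code = sum over positions j of (#{l > j : y_l < y_j}) * (k - j)!
  code <- integer(n_vec)
  fact <- factorial(k - seq_len(k))
  for (j in seq_len(k - 1L)) {
    smaller_later <- integer(n_vec)
    for (l in (j + 1L):k)
      smaller_later <- smaller_later + (cols[[l]] < cols[[j]])
    code <- code + smaller_later * fact[j]
  }
  code
}

#' Permutation entropy
#'
#' Shannon entropy of the distribution of ordinal (rank-order) patterns in
#' delay-embedded windows of `k` consecutive values (Bandt-Pompe). Ties are
#' broken by time index, the standard stable-ranking convention. With
#' `normalized = TRUE` (the default, and what the feature pipeline uses) the
#' entropy is divided by `log(k!)` so the result lies in `[0, 1]`: 0 for a
#' monotone series (one pattern), 1 when all `k!` patterns are equally
#' frequent.
#'
#' @param series numeric vector of length at least `(k - 1) * tau + 2`.
#' @param k ordinal pattern order (number of values per window).
#' @param tau embedding delay between window elements.
#' @param normalized divide by `log(k!)`?
#' @return A single number in `[0, log(k!)]`, or `[0, 1]` if normalized.
#' @examples
#' permutation_entropy(1:100, k = 3)  # ramp: single pattern -> 0
#' @export
permutation_entropy <- function(series, k = 3L, tau = 1L, normalized = TRUE) {
  k <- as.integer(k); tau <- as.integer(tau)
  stopifnot(k >= 2L, tau >= 1L)
  series <- as.numeric(series)
  if (!all(is.finite(series))) stop("series must be finite", call. = FALSE)
  if (length(series) < (k - 1L) * tau + 2L)
    stop(sprintf("series length %d too short for order %d, delay %d",
                 length(series), k, tau), call. = FALSE)
  codes <- ordinal_pattern_codes(series, k, tau)
  p <- tabulate(codes + 1L, nbins = factorial(k))
  p <- p[p > 0] / length(codes)
  h <- -sum(p * log(p))
  if (normalized) h / log(factorial(k)) else h
}

#' Fuzzy entropy
#'
#' Sample-entropy variant that replaces the hard tolerance threshold with a
#' smooth exponential membership `exp(-d^n / p)` evaluated on
#' baseline-removed templates (each window has its own mean subtracted), so
#' the statistic varies continuously with the data and discounts local
#' offsets. `fuzzy_entropy = log(phi_m) - log(phi_{m+1})` with `phi` the
#' mean pairwise membership over distinct template pairs.
#'
#' @inheritParams approximate_entropy
#' @param n_exp gradient exponent of the membership function.
#' @param p_width membership width (same units as the series to the power
#'   `n_exp`; the pipeline uses `fuzzy_tol_frac * sd(series)`).
#' @return A single non-negative number (up to floating-point error).
#' @export
fuzzy_entropy <- function(series, m = 2L, n_exp = 2, p_width) {
  series <- check_series(series, m)
  if (!is.numeric(p_width) || p_width <= 0)
    stop("'p_width' must be positive", call. = FALSE)
  if (n_exp <= 0) stop("'n_exp' must be positive", call. = FALSE)
  .fuzzyen_cpp(series, as.integer(m), n_exp, p_width)
}

#' Log-energy entropy
#'
#' Sum of the natural logs of the squared samples,
#' `sum(log(pmax(y^2, floor_eps)))` — a measure of how the signal energy is
#' spread across samples. The floor keeps exact zeros (e.g. from zero
#' padding) finite; an all-zero series of length N returns
#' `N * log(floor_eps)` by construction.
#'
#' @param series numeric vector.
#' @param floor_eps positive floor applied to each squared sample.
#' @return A single number (unbounded in sign).
#' @examples
#' log_energy_entropy(c(1, -1, 1))    # 0
#' log_energy_entropy(c(exp(1), exp(1)))  # 4
#' @export
log_energy_entropy <- function(series, floor_eps = 1e-12) {
  series <- as.numeric(series)
  if (!all(is.finite(series))) stop("series must be finite", call. = FALSE)
  if (!is.numeric(floor_eps) || floor_eps <= 0)
    stop("'floor_eps' must be positive", call. = FALSE)
  sum(log(pmax(series^2, floor_eps)))
}

entropy_names <- c("ApEn", "SampEn", "PermEn", "FuzzyEn", "LogEn")

channel_entropies <- function(samples, params) {
  co <- as.numeric(fwht(samples))
  if (is.finite(params$max_series_len) && length(co) > params$max_series_len)
    co <- co[seq(1L, length(co), by = ceiling(length(co) / params$max_series_len))]
  s <- stats::sd(co)
  if (s == 0) s <- .Machine$double.eps  # flat channel: any tolerance works
  c(ApEn = approximate_entropy(co, params$embed_m, params$tol_frac * s),
    SampEn = as.numeric(sample_entropy(co, params$embed_m,
                                       params$tol_frac * s)),
    PermEn = permutation_entropy(co, params$perm_order, params$perm_delay),
    FuzzyEn = fuzzy_entropy(co, params$fuzzy_m, params$fuzzy_n,
                            params$fuzzy_tol_frac * s),
    LogEn = log_energy_entropy(co, params$logen_floor))
}

#' Extract the entropy feature vector of one record
#'
#' Runs the full per-record feature path: each channel is decomposed by the
#' fast Walsh-Hadamard transform ([fwht()]) and the five entropies are
#' computed on its Hadamard coefficients, in the fixed order ApEn, SampEn,
#' PermEn, FuzzyEn, LogEn. A paired record yields 10 values (the x-channel
#' block then the y-channel block, names suffixed `_x` / `_y`); a
#' single-channel record yields 5. Tolerances are resolved per channel as
#' `tol_frac * sd(coefficients)`, so features are invariant to amplitude
#' rescaling of the record.
#'
#' @param record an [eeg_signal()] or [paired_signal()].
#' @param params an [entropy_params()] set.
#' @return Named numeric vector of length 5 or 10 with attributes
#'   `source_id`, `label` and `params`.
#' @export
extract_feature_vector <- function(record, params = entropy_params()) {
  stopifnot(inherits(params, "entropy_params"))
  if (inherits(record, "eeg_signal")) {
    vals <- channel_entropies(record$samples, params)
  } else if (inherits(record, "eeg_paired")) {
    vx <- channel_entropies(record$x$samples, params)
    vy <- channel_entropies(record$y$samples, params)
    vals <- c(stats::setNames(vx, paste0(entropy_names, "_x")),
              stats::setNames(vy, paste0(entropy_names, "_y")))
  } else {
    stop("'record' must be an eeg_signal or eeg_paired object", call. = FALSE)
  }
  structure(vals, source_id = record$source_id, label = record$label,
            params = params)
}

#' Extract features for a collection of records
#'
#' @param records list of [eeg_signal()] / [paired_signal()] objects.
#' @param params an [entropy_params()] set shared by all records.
#' @return A data.frame in feature-table layout (see
#'   [write_feature_table()]).
#' @export
extract_feature_table <- function(records, params = entropy_params()) {
  feature_rows_to_df(lapply(records, extract_feature_vector, params = params))
}
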