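#' Zero-pad a sample vector to the next power of two
#'
#' The Walsh-Hadamard transform is defined for lengths 2^n; shorter records
#' are padded with trailing zeros to the next greater power of two before
#' decomposition. A 10,240-sample intracranial record therefore yields
#' 16,384 coefficients, while a 4096-sample record is transformed unchanged.
#' Padding is applied only here (inside the transform path), never by the
#' file readers, so raw record lengths are preserved for provenance.
#'
#' @param samples non-empty numeric vector.
#' @return The input, followed by zeros up to length `2^ceiling(log2(n))`.
#' @examples
#' length(pad_to_next_pow2(numeric(10240)))  # 16384
#' @export
pad_to_next_pow2 <- function(samples) {
  n <- length(samples)
  if (n == 0L) stop("'samples' must be non-empty", call. = FALSE)
  n2 <- 2L^ceiling(log2(n))
  if (n2 == n) return(samples)
  c(samples, numeric(n2 - n))
}

#' Orthonormal Walsh (Hadamard) matrix
#'
#' Builds the order-`2^n` Walsh matrix by the doubling recursion
#' \deqn{W_n = \frac{1}{\sqrt 2}\begin{pmatrix}W_{n-1} & W_{n-1}\\
#'       W_{n-1} & -W_{n-1}\end{pmatrix}, \qquad W_0 = (1),}
#' i.e. entries \eqn{\pm 2^{-n/2}} in natural (Hadamard) ordering. The matrix
#' is symmetric and orthonormal, so it is its own inverse; this makes the
#' transform an involution and preserves signal energy (Parseval).
#'
#' @param order_n integer in `0:12` (side length `2^order_n`; the cap guards
#'   against accidental multi-gigabyte allocations — the fast transform in
#'   [fwht()] never materialises the matrix).
#' @return A `2^order_n` square numeric matrix.
#' @examples
#' walsh_matrix(1)  # (1/sqrt(2)) * [1 1; 1 -1]
#' @export
walsh_matrix <- function(order_n) {
  if (!is.numeric(order_n) || length(order_n) != 1L ||
      order_n != round(order_n) || order_n < 0 || order_n > 12)
    stop("'order_n' must be an integer in 0:12", call. = FALSE)
  w <- matrix(1, 1L, 1L)
  if (order_n > 0) {
    for (i in seq_len(order_n))
      w <- rbind(cbind(w, w), cbind(w, -w)) / sqrt(2)
  }
  w
}

#' Fast Walsh-Hadamard transform of an EEG signal
#'
#' Decomposes a signal onto the orthogonal +-1-valued rectangular (Walsh)
#' basis. The input is zero-padded to the next power of two
#' ([pad_to_next_pow2()]) and transformed by the in-place butterfly
#' (additions and subtractions only, O(N log N)), then scaled by
#' \eqn{1/\sqrt N} so the result equals multiplication by the orthonormal
#' [walsh_matrix()]. Coefficients are returned in natural (Hadamard)
#' ordering; use [to_sequency_order()] for the sequency-ordered view.
#'
#' @param signal an [eeg_signal()] or a plain numeric vector.
#' @return Numeric vector of Hadamard coefficients, length a power of two,
#'   with attributes `order_n`, `ordering = "natural"` and
#'   `scaling = "orthonormal"`.
#' @examples
#' fwht(c(1, 0, 0, 0))  # impulse -> constant 0.5
#' fwht(c(1, 1, 1, 1))  # constant -> (2, 0, 0, 0)
#' @export
fwht <- function(signal) {
  v <- if (inherits(signal, "eeg_signal")) signal$samples else as.numeric(signal)
  if (length(v) == 0L) stop("'signal' must be non-empty", call. = FALSE)
  if (!all(is.finite(v))) stop("'signal' must be finite", call. = FALSE)
  v <- pad_to_next_pow2(v)
  n <- length(v)
  h <- 1L
  while (h < n) {
    dim(v) <- c(h, 2L, n / (2L * h))
    a <- v[, 1L, , drop = FALSE]
    b <- v[, 2L, , drop = FALSE]
    v[, 1L, ] <- a + b
    v[, 2L, ] <- a - b
    h <- 2L * h
  }
  v <- as.numeric(v) / sqrt(n)
  structure(v, order_n = as.integer(log2(n)),
            ordering = "natural", scaling = "orthonormal")
}

# natural (Hadamard) index of sequency index k (both 0-based):
# bit-reverse the Gray code of k over `bits` bits.
seq_to_nat_index <- function(bits) {
  k <- 0:(2L^bits - 1L)
  g <- bitwXor(k, bitwShiftR(k, 1L))        # binary -> Gray
  r <- integer(length(g))                    # bit reversal
  for (b in seq_len(bits) - 1L)
    r <- bitwOr(bitwShiftL(r, 1L), bitwAnd(bitwShiftR(g, b), 1L))
  r + 1L
}

#' Reorder Hadamard coefficients between natural and sequency ordering
#'
#' Sequency — the number of sign changes of a Walsh function — is the
#' Walsh-domain analogue of frequency. Both orderings index the same basis;
#' the pipeline computes entropies on the natural-ordered coefficients, and
#' these utilities expose the sequency view (e.g. for plotting a
#' "Walsh spectrum"). `to_sequency_order(to_natural_order(v))` is the
#' identity.
#'
#' @param coeffs coefficient vector of power-of-two length, as from [fwht()].
#' @return The permuted coefficient vector with its `ordering` attribute set.
#' @export
to_sequency_order <- function(coeffs) {
  n <- length(coeffs)
  bits <- as.integer(round(log2(n)))
  if (2L^bits != n) stop("length must be a power of two", call. = FALSE)
  out <- coeffs[seq_to_nat_index(bits)]
  attributes(out) <- attributes(coeffs)[setdiff(names(attributes(coeffs)), "names")]
  attr(out, "ordering") <- "sequency"
  out
}

#' @rdname to_sequency_order
#' @export
to_natural_order <- function(coeffs) {
  n <- length(coeffs)
  bits <- as.integer(round(log2(n)))
  if (2L^bits != n) stop("length must be a power of two", call. = FALSE)
  out <- numeric(n)
  out[seq_to_nat_index(bits)] <- coeffs
  attributes(out) <- attributes(coeffs)[setdiff(names(attributes(coeffs)), "names")]
  attr(out, "ordering") <- "natural"
  out
}
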