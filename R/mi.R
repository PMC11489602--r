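#' Binary (Bernoulli) entropy in bits
#'
#' H(p) = -p log2 p - (1-p) log2 (1-p), with the 0 log 0 = 0 convention.
#'
#' @param p probability (vectorized), each in \[0, 1\].
#' @return entropy in bits, in \[0, 1\].
#' @examples
#' binary_entropy(0.5)  # 1 bit
#' binary_entropy(c(0, 1, 0.25))
#' @export
binary_entropy <- function(p) {
  if (any(p < 0 | p > 1, na.rm = FALSE)) stop("`p` must lie in [0, 1]")
  term <- function(q) ifelse(q == 0, 0, -q * log2(q))
  term(p) + term(1 - p)
}

#' 2x2 joint counts of two binary series
#'
#' @param x,y equal-length binary (0/1) vectors.
#' @return a list of class `binary_joint` with integer cells `n00`, `n01`,
#'   `n10`, `n11` (first index = x, second = y) and `n_total`.
#' @export
joint_counts <- function(x, y) {
  if (length(x) != length(y)) {
    stop("series length mismatch: ", length(x), " vs ", length(y))
  }
  if (length(x) < 1) stop("series must have length >= 1")
  x <- as.integer(x); y <- as.integer(y)
  if (any(x != 0L & x != 1L) || any(y != 0L & y != 1L)) {
    stop("series must be binary 0/1")
  }
  n11 <- sum(x == 1L & y == 1L)
  n10 <- sum(x == 1L) - n11
  n01 <- sum(y == 1L) - n11
  n00 <- length(x) - n11 - n10 - n01
  structure(list(n00 = n00, n01 = n01, n10 = n10, n11 = n11,
                 n_total = length(x)),
            class = "binary_joint")
}

# Vectorized plug-in MI (bits) from 2x2 cell counts. Arguments may be
# vectors (used heavily by the surrogate null, where only n11 varies).
# Exact integer counts go into the log terms directly: no intermediate
# normalization, so results are bit-for-bit reproducible.
mi_from_counts <- function(n00, n01, n10, n11, n) {
  # doubles throughout: products like nij * n overflow 32-bit integers
  n00 <- as.double(n00); n01 <- as.double(n01)
  n10 <- as.double(n10); n11 <- as.double(n11)
  n <- as.double(n)
  if (length(n) == 1) n <- rep(n, length(n11))
  cell <- function(nij, ni, nj) {
    out <- numeric(length(nij))
    pos <- nij > 0
    out[pos] <- (nij[pos] / n[pos]) *
      log2((nij[pos] * n[pos]) / (ni[pos] * nj[pos]))
    out
  }
  nx0 <- n00 + n01; nx1 <- n10 + n11   # x margins
  ny0 <- n00 + n10; ny1 <- n01 + n11   # y margins
  # grouping (diagonal) + (off-diagonal): swapping x and y swaps only the
  # commutative inner additions, so MI is exactly symmetric in its arguments
  mi <- (cell(n00, nx0, ny0) + cell(n11, nx1, ny1)) +
    (cell(n01, nx0, ny1) + cell(n10, nx1, ny0))
  pmax(mi, 0)  # clamp float negatives of order -1e-16
}

#' Plug-in mutual information of two binary series
#'
#' Estimates I(X;Y) = H(X) - H(X|Y) = sum over cells of
#' p(x,y) log2\[p(x,y) / (p(x) p(y))\], substituting empirical 2x2 cell
#' frequencies for the probabilities (the maximum-likelihood plug-in
#' estimator, no bias correction). MI is measured in bits, is symmetric in
#' its arguments, nonnegative, and bounded above by each marginal entropy.
#' The conditional entropy is computed independently via
#' H(X|Y) = sum_y p(y) H(X | Y = y), so the entropy identity can be used
#' as an internal cross-check.
#'
#' @param x,y equal-length binary (0/1) vectors, length >= 2. Constant
#'   series are allowed and yield `mi_bits = 0` (zero-entropy bound).
#' @return a list of class `mi_result` with `mi_bits`,
#'   `entropy_x_bits`, `entropy_y_bits`, and `cond_entropy_bits` (H(X|Y)).
#' @examples
#' mutual_information(c(0, 1, 0, 1), c(0, 1, 0, 1))  # I(X;X) = H(X) = 1
#' @export
mutual_information <- function(x, y) {
  if (length(x) < 2) stop("series must have length >= 2")
  jc <- joint_counts(x, y)
  n <- jc$n_total
  mi <- mi_from_counts(jc$n00, jc$n01, jc$n10, jc$n11, n)
  hx <- binary_entropy((jc$n10 + jc$n11) / n)
  hy <- binary_entropy((jc$n01 + jc$n11) / n)
  # H(X|Y) directly from the columns of the 2x2 table
  py0 <- (jc$n00 + jc$n10) / n
  py1 <- 1 - py0
  h_given_y0 <- if (py0 > 0) binary_entropy(jc$n10 / (jc$n00 + jc$n10)) else 0
  h_given_y1 <- if (py1 > 0) binary_entropy(jc$n11 / (jc$n01 + jc$n11)) else 0
  structure(list(mi_bits = mi,
                 entropy_x_bits = hx,
                 entropy_y_bits = hy,
                 cond_entropy_bits = py0 * h_given_y0 + py1 * h_given_y1),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf("MI = %.4f bits  [H(X) = %.4f, H(Y) = %.4f, H(X|Y) = %.4f]\n",
              x$mi_bits, x$entropy_x_bits, x$entropy_y_bits,
              x$cond_entropy_bits))
  invisible(x)
}

#' Pairwise mutual-information matrix
#'
#' Computes plug-in MI (bits) for every pair of variables in a symptom
#' matrix. The diagonal is set to 0 by convention: self-links are never
#' network edges, and the matrix doubles as an adjacency candidate for the
#' downstream graph stages.
#'
#' @param m a [symptom_matrix].
#' @return symmetric numeric matrix (bits) with variable names as
#'   dimnames and zero diagonal.
#' @export
pairwise_mi <- function(m) {
  stopifnot(inherits(m, "symptom_matrix"))
  k <- ncol(m)
  out <- matrix(0, k, k, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      mi <- mutual_information(m[, i], m[, j])$mi_bits
      out[i, j] <- mi
      out[j, i] <- mi
    }
  }
  out
}
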