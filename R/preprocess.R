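#' Conditionally log-transform an expression matrix
#'
#' Applies `log2(x + 1)` to every entry when the global range of the matrix
#' (`max - min`) exceeds 100, and leaves it untouched otherwise. Raw counts
#' and other wide-range inputs are thereby brought onto a scale where no
#' single highly expressed gene dominates, while data that are already
#' log-like pass through unchanged. The pseudocount of 1 maps zeros to zero.
#'
#' @param m numeric matrix, rows = cells, columns = genes; finite,
#'   non-negative entries.
#' @param threshold range above which the log transform triggers (default 100).
#' @return the (possibly transformed) matrix with attribute `log_applied`
#'   (logical) recording whether the transform ran.
#' @examples
#' m <- matrix(c(0, 1023, 2, 3), 2, 2)
#' lt <- maybe_log_transform(m)
#' attr(lt, "log_applied")  # TRUE: range > 100
#' @export
maybe_log_transform <- function(m, threshold = 100) {
  validate_expression_matrix(m)
  rng <- max(m) - min(m)
  applied <- rng > threshold
  if (applied) {
    dn <- dimnames(m)
    m <- log2(m + 1)
    dimnames(m) <- dn
  }
  attr(m, "log_applied") <- applied
  m
}

#' Min-max rescale each cell to the unit interval
#'
#' Rescales every row (cell) of the matrix to `[0, 1]`:
#' `X_ij = (M_ij - min(M_i.)) / (max(M_i.) - min(M_i.))`.
#' Per-cell scaling removes library-size and calibration differences between
#' cells and suppresses outliers before autoencoder training. Constant rows
#' (max = min) are mapped to all zeros instead of failing, so degenerate
#' cells do not abort a run; their count is reported via a message.
#'
#' @param m numeric matrix, rows = cells, columns = genes.
#' @return matrix of the same shape with every non-constant row spanning
#'   exactly `[0, 1]`; attribute `constant_rows` holds the indices of
#'   degenerate rows.
#' @examples
#' minmax_rows(matrix(c(0, 5, 10, 3, 3, 3), 2, 3, byrow = TRUE))
#' @export
minmax_rows <- function(m) {
  validate_expression_matrix(m)
  lo <- apply(m, 1L, min)
  hi <- apply(m, 1L, max)
  span <- hi - lo
  const <- which(span == 0)
  span[const] <- 1  # arbitrary: numerator is zero for these rows
  x <- (m - lo) / span
  if (length(const)) {
    x[const, ] <- 0
    message(length(const), " constant cell(s) rescaled to all-zero rows")
  }
  attr(x, "constant_rows") <- const
  x
}

#' Preprocess an expression matrix for autoencoder training
#'
#' Convenience wrapper chaining [maybe_log_transform()] (once, on the global
#' range, before anything else) and [minmax_rows()].
#'
#' @inheritParams maybe_log_transform
#' @return scaled matrix in `[0, 1]` with attribute `log_applied`.
#' @export
preprocess_matrix <- function(m, threshold = 100) {
  lt <- maybe_log_transform(m, threshold = threshold)
  x <- minmax_rows(lt)
  attr(x, "log_applied") <- attr(lt, "log_applied")
  x
}
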