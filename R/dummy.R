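#' Dummy-code a score pattern relative to a reference pattern
#'
#' Each item score `y[i]` is expanded to indicator scores `x[i,s] = 1` if
#' `y[i] = s` (`s = 1..m[i]`), and the coding is taken relative to an arbitrary
#' reference pattern `y0`: `x_tilde[i,s] = x[i,s] - x0[i,s]` (entries in
#' -1/0/1) and `y_tilde[i] = y[i] - y0[i]`.  These shifted scores are the
#' sufficient statistics of the marginal model; the reference pattern carries
#' zero coding by construction.
#'
#' @param y Integer score pattern (vector of length `k`).
#' @param y0 Reference score pattern.
#' @param design A [test_design()].
#' @return A list of class `"dummy_coding"` with `x_tilde` (length `sum(m)`),
#'   `y_tilde` (length `k`) and `y0`.
#' @examples
#' d <- test_design(c(2))
#' dummy_code(0, 2, d)  # x_tilde = (0, -1), y_tilde = -2
#' @export
dummy_code <- function(y, y0, design) {
  y <- drop(check_patterns(rbind(y), design))
  y0 <- drop(check_patterns(rbind(y0), design))
  structure(
    list(x_tilde = drop(dummy_matrix(rbind(y), y0, design)),
         y_tilde = as.integer(y - y0), y0 = y0),
    class = "dummy_coding"
  )
}

#' Recover a score pattern from its dummy coding
#'
#' Inverts [dummy_code()]: `y[i] = y0[i] + sum_s s * x_tilde[i,s]`.
#'
#' @param coding A `"dummy_coding"` object.
#' @param design A [test_design()].
#' @return Integer score pattern.
#' @export
decode_dummy <- function(coding, design) {
  off <- c(0L, cumsum(design$m))
  y <- vapply(seq_len(design$k), function(i) {
    s <- seq_len(design$m[i])
    coding$y0[i] + sum(s * coding$x_tilde[off[i] + s])
  }, numeric(1))
  as.integer(y)
}

# Dummy-score matrix for patterns in rows of Y, coded relative to y0.
# Returns an nrow(Y) x sum(m) matrix with entries in {-1, 0, 1}.
dummy_matrix <- function(Y, y0, design) {
  n <- nrow(Y)
  p <- sum(design$m)
  off <- c(0L, cumsum(design$m))
  X <- matrix(0, n, p)
  for (i in seq_len(design$k)) {
    yi <- Y[, i]
    pos <- yi > 0L
    X[cbind(which(pos), off[i] + yi[pos])] <- 1
    if (y0[i] > 0L) X[, off[i] + y0[i]] <- X[, off[i] + y0[i]] - 1
  }
  X
}

# Names "beta[i,s]"-style for the sum(m) dummy slots.
slot_names <- function(design, prefix = "beta") {
  unlist(lapply(seq_len(design$k), function(i)
    sprintf("%s[%d,%d]", prefix, i, seq_len(design$m[i]))))
}
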