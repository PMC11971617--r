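#' Randomly partition observed score patterns into two parts
#'
#' Assigns the distinct score patterns (not persons) to two disjoint,
#' exhaustive parts, each pattern independently with equal probability,
#' re-drawing until both parts hold at least two patterns.  When the data
#' already carry partition labels those are used verbatim.
#'
#' @param data A [pattern_counts()] object with at least 2 patterns.
#' @param labels Optional explicit labels in `{1, 2}` per pattern (in the
#'   data's pattern order); defaults to `data$partition` when present.
#' @param seed Integer seed for the random assignment (required when no
#'   labels are available).
#' @return List of two [pattern_counts()] objects (`part1`, `part2`).
#' @export
split_patterns <- function(data, labels = NULL, seed = NULL) {
  stopifnot(inherits(data, "pattern_counts"))
  npat <- nrow(data$y)
  if (npat < 2L) stop("need at least 2 distinct patterns to split")
  if (is.null(labels)) labels <- data$partition
  if (is.null(labels)) {
    if (is.null(seed)) stop("supply 'seed' (or explicit labels) for a random split")
    set.seed(seed)
    repeat {
      labels <- sample(c(1L, 2L), npat, replace = TRUE)
      if (min(tabulate(labels, 2L)) >= min(2L, npat %/% 2L)) break
    }
  }
  labels <- as.integer(labels)
  if (length(labels) != npat || !all(labels %in% c(1L, 2L)))
    stop("'labels' must assign every pattern to part 1 or 2")
  if (length(unique(labels)) < 2L) stop("one part of the split is empty")
  lapply(1:2, function(g) {
    keep <- labels == g
    pattern_counts(data$y[keep, , drop = FALSE], data$counts[keep],
                   design = data$design)
  })
}

#' Split-sample likelihood-ratio goodness-of-fit test
#'
#' Fits the model to the full observed pattern set `O` and, independently, to
#' a two-part partition `O1, O2` (each sub-fit using its own observed support
#' and its own most frequent pattern as reference), and forms
#' `LR = 2 * ((l1 + n1 log(n1/n)) + (l2 + n2 log(n2/n)) - l)`,
#' referred to a chi-squared distribution with degrees of freedom equal to the
#' model's free-parameter count plus one.  Under a well-fitting model the two
#' half-fits reproduce the full fit up to the multinomial split factor, so
#' large `LR` signals misfit.
#'
#' @param data A [pattern_counts()] object.
#' @param labels,seed Passed to [split_patterns()].
#' @param v,deg2,eps_fixed,y0,control Model configuration, as in [gpcm()]
#'   (`y0` applies to the full-data fit).
#' @return Object of class `"split_lr"`: list with `lr`, `df`, `pvalue`,
#'   `loglik_full`, `loglik_1`, `loglik_2`, `n1`, `n2`, `converged`, and the
#'   three underlying fits in `fits`.  `pvalue` is `NA` if any sub-fit failed
#'   to converge.
#' @examples
#' \donttest{
#' split_lr_test(antisocial_patterns())  # uses the bundled partition labels
#' }
#' @export
split_lr_test <- function(data, labels = NULL, seed = NULL, v = 6L,
                          deg2 = NULL, eps_fixed = c(3 / 5, 4 / 5), y0 = NULL,
                          control = list()) {
  parts <- split_patterns(data, labels, seed)
  fit_full <- gpcm(data, v, deg2, eps_fixed, y0 = y0, control = control,
                   vcov = FALSE)
  fit1 <- gpcm(parts[[1L]], v, deg2, eps_fixed, control = control, vcov = FALSE)
  fit2 <- gpcm(parts[[2L]], v, deg2, eps_fixed, control = control, vcov = FALSE)
  n <- data$n; n1 <- parts[[1L]]$n; n2 <- parts[[2L]]$n
  lr <- 2 * ((fit1$loglik + n1 * log(n1 / n)) +
               (fit2$loglik + n2 * log(n2 / n)) - fit_full$loglik)
  df <- fit_full$np + 1L
  ok <- fit_full$converged && fit1$converged && fit2$converged
  structure(
    list(lr = lr, df = df,
         pvalue = if (ok) stats::pchisq(lr, df, lower.tail = FALSE) else NA_real_,
         loglik_full = fit_full$loglik, loglik_1 = fit1$loglik,
         loglik_2 = fit2$loglik, n1 = n1, n2 = n2, converged = ok,
         fits = list(full = fit_full, part1 = fit1, part2 = fit2)),
    class = "split_lr")
}

#' @export
print.split_lr <- function(x, ...) {
  cat(sprintf("Split-sample LR goodness-of-fit test\n"))
  cat(sprintf("  l = %.3f, l1 = %.3f (n1 = %d), l2 = %.3f (n2 = %d)\n",
              x$loglik_full, x$loglik_1, x$n1, x$loglik_2, x$n2))
  cat(sprintf("  LR = %.3f on %d df, p = %.3f%s\n", x$lr, x$df, x$pvalue,
              if (!x$converged) " [non-convergence: p unreliable]" else ""))
  invisible(x)
}

#' Likelihood-ratio test of nested fits
#'
#' Compares a null fit nested inside an alternative (e.g. the GPCM inside the
#' nominal response model on the same data and support):
#' `LR = 2 (l_alt - l_null)` on `df = np_alt - np_null` degrees of freedom.
#'
#' @param fit_null,fit_alt Two [gpcm()] / [nominal_gpcm()] fits of the same
#'   data with the null model nested in the alternative.
#' @param tol Numerical slack allowed on `l_alt >= l_null` before the nesting
#'   check errors.
#' @return List with `lr`, `df`, `pvalue`.
#' @export
lr_test <- function(fit_null, fit_alt, tol = 1e-6) {
  stopifnot(inherits(fit_null, "gpcm_fit"), inherits(fit_alt, "gpcm_fit"))
  if (fit_null$data$n != fit_alt$data$n ||
      nrow(fit_null$data$y) != nrow(fit_alt$data$y))
    stop("the two fits are not based on the same data")
  lr <- 2 * (fit_alt$loglik - fit_null$loglik)
  if (lr < -tol)
    stop("alternative fits worse than null beyond tolerance: ",
         "models not nested, or a fit did not converge")
  lr <- max(lr, 0)
  df <- fit_alt$np - fit_null$np
  list(lr = lr, df = df,
       pvalue = if (df > 0L) stats::pchisq(lr, df, lower.tail = FALSE)
                else NA_real_)
}
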