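#' Define a polytomous test design
#'
#' A test design records the number of items `k` and, for each item `i`, the
#' highest category score `m[i]`, so that item `i` has `m[i] + 1` ordered
#' response categories scored `0, 1, ..., m[i]`.  The category counts need not
#' be equal across items.  The design fixes the space of theoretically possible
#' score patterns, of size `prod(m + 1)`.
#'
#' @param m Integer vector of per-item maximum scores; `m[i] >= 1`.
#' @return An object of class `"test_design"` with elements `k`, `m` and
#'   `n_patterns` (the size of the full pattern space).
#' @examples
#' d <- test_design(rep(4, 5))
#' d$n_patterns  # 3125
#' @export
test_design <- function(m) {
  m <- as.integer(m)
  if (length(m) < 1L || anyNA(m) || any(m < 1L))
    stop("'m' must be a vector of integers >= 1, one per item")
  structure(
    list(k = length(m), m = m, n_patterns = prod(m + 1)),
    class = "test_design"
  )
}

#' @export
print.test_design <- function(x, ...) {
  cat("Test design:", x$k, "items, categories per item:",
      paste(x$m + 1L, collapse = ", "),
      sprintf("(%g possible score patterns)\n", x$n_patterns))
  invisible(x)
}

# Validate a matrix of score patterns (rows) against a design.
check_patterns <- function(y, design, what = "pattern") {
  y <- as.matrix(y)
  dimnames(y) <- NULL
  storage.mode(y) <- "integer"
  if (ncol(y) != design$k)
    stop(sprintf("%s has %d columns; design has %d items", what, ncol(y), design$k))
  if (anyNA(y))
    stop(sprintf("missing values in %s are not supported", what))
  bad <- which(t(y) < 0L | t(y) > design$m, arr.ind = TRUE)
  if (length(bad)) {
    stop(sprintf("score out of range 0..m in %s: row %d, item %d",
                 what, bad[1L, 2L], bad[1L, 1L]))
  }
  y
}

#' Format and parse score-pattern strings
#'
#' Patterns are written as comma-separated category scores in parentheses,
#' e.g. `"(0,1,0,2,0)"`.
#'
#' @param y Integer vector (one pattern) or matrix (patterns in rows).
#' @return `pattern_string()` returns a character vector; `parse_pattern()`
#'   returns an integer matrix with one row per pattern string.
#' @export
pattern_string <- function(y) {
  y <- if (is.matrix(y)) y else matrix(y, nrow = 1L)
  apply(y, 1L, function(r) paste0("(", paste(r, collapse = ","), ")"))
}

#' @rdname pattern_string
#' @param s Character vector of pattern strings.
#' @export
parse_pattern <- function(s) {
  parts <- strsplit(gsub("[()\\s]", "", s, perl = TRUE), ",", fixed = TRUE)
  len <- lengths(parts)
  if (length(unique(len)) != 1L)
    stop("pattern strings have unequal numbers of items")
  out <- matrix(as.integer(unlist(parts)), nrow = length(s), byrow = TRUE)
  if (anyNA(out)) stop("malformed pattern string")
  out
}

#' Construct a pattern-frequency table
#'
#' The sufficient data for the marginal model: the set of distinct observed
#' score patterns together with their sample frequencies, and optionally a
#' two-part partition label per pattern (used by [split_lr_test()]).  Patterns
#' are stored in ascending lexicographic order.
#'
#' @param patterns Integer matrix (one pattern per row) or character vector of
#'   pattern strings.
#' @param counts Positive integer vector of pattern frequencies.
#' @param design A [test_design()]; inferred (`m[i]` = maximum observed score,
#'   at least 1) when omitted.
#' @param partition Optional vector of labels in `{1, 2}`, one per pattern.
#' @return An object of class `"pattern_counts"`: list with `design`, `y`
#'   (integer matrix), `counts`, `partition` (or `NULL`) and total count `n`.
#' @export
pattern_counts <- function(patterns, counts, design = NULL, partition = NULL) {
  if (is.character(patterns)) patterns <- parse_pattern(patterns)
  patterns <- as.matrix(patterns)
  if (is.null(design)) design <- test_design(pmax(apply(patterns, 2L, max), 1L))
  y <- check_patterns(patterns, design)
  counts <- as.integer(counts)
  if (length(counts) != nrow(y) || anyNA(counts) || any(counts < 1L))
    stop("'counts' must be positive integers, one per pattern")
  if (anyDuplicated(pattern_string(y)))
    stop("duplicate score patterns; aggregate counts first")
  if (!is.null(partition)) {
    partition <- as.integer(partition)
    if (length(partition) != nrow(y) || anyNA(partition) ||
        !all(partition %in% c(1L, 2L)))
      stop("'partition' must label every pattern with 1 or 2")
  }
  ord <- do.call(order, as.data.frame(y))
  structure(
    list(design = design, y = y[ord, , drop = FALSE], counts = counts[ord],
         partition = if (!is.null(partition)) partition[ord],
         n = sum(counts)),
    class = "pattern_counts"
  )
}

#' @export
print.pattern_counts <- function(x, ...) {
  cat(sprintf("Pattern counts: %d distinct patterns, n = %d (%d items)\n",
              nrow(x$y), x$n, x$design$k))
  if (!is.null(x$partition))
    cat(sprintf("  partition: n1 = %d, n2 = %d\n",
                sum(x$counts[x$partition == 1L]),
                sum(x$counts[x$partition == 2L])))
  df <- as.data.frame(x)
  print(utils::head(df, 10L), row.names = FALSE)
  if (nrow(df) > 10L) cat("  ...", nrow(df) - 10L, "more patterns\n")
  invisible(x)
}

#' @export
as.data.frame.pattern_counts <- function(x, ...) {
  df <- data.frame(pattern = pattern_string(x$y), count = x$counts,
                   stringsAsFactors = FALSE)
  if (!is.null(x$partition)) df$partition <- x$partition
  df
}

#' Tabulate person-by-item responses into pattern counts
#'
#' Collapses a wide table of individual responses (one row per person, one
#' integer score column per item) to the distinct-pattern frequency table the
#' likelihood needs.  Missing values are rejected: the model assumes complete
#' score patterns.
#'
#' @param responses Data frame or integer matrix, persons in rows.
#' @param design Optional [test_design()]; inferred from the data if omitted.
#' @return A [pattern_counts()] object.
#' @examples
#' resp <- rbind(c(0, 0), c(1, 1), c(1, 1))
#' as_pattern_counts(resp, test_design(c(1, 1)))
#' @export
as_pattern_counts <- function(responses, design = NULL) {
  y <- as.matrix(responses)
  if (!is.numeric(y)) stop("responses must be integer scores")
  if (is.null(design)) design <- test_design(pmax(apply(y, 2L, max), 1L))
  y <- check_patterns(y, design, what = "responses")
  key <- pattern_string(y)
  tab <- table(key)
  uy <- parse_pattern(names(tab))
  pattern_counts(uy, as.integer(tab), design)
}

#' Read and write pattern-frequency tables
#'
#' The pattern CSV format has a `pattern` column (strings like `"(0,1,0,2,0)"`),
#' a `count` column, and an optional `partition` column of labels in `{1, 2}`.
#' `read_responses()` reads a wide person-by-item CSV instead and collapses it
#' with [as_pattern_counts()].
#'
#' @param path File path.
#' @param design Optional [test_design()]; inferred when omitted.
#' @return A [pattern_counts()] object; `write_pattern_counts()` returns the
#'   path invisibly.
#' @export
read_pattern_counts <- function(path, design = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("pattern", "count") %in% names(df)))
    stop("pattern CSV needs 'pattern' and 'count' columns")
  pattern_counts(df$pattern, df$count, design = design,
                 partition = if ("partition" %in% names(df)) df$partition)
}

#' @rdname read_pattern_counts
#' @export
read_responses <- function(path, design = NULL) {
  df <- utils::read.csv(path)
  as_pattern_counts(df, design)
}

#' @rdname read_pattern_counts
#' @param data A [pattern_counts()] object to write.
#' @export
write_pattern_counts <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = 1L)
  invisible(path)
}

#' Aggressive antisocial behaviour data
#'
#' Responses of 493 adolescents to five polytomously scored items asking how
#' often they committed an aggressive antisocial act in the last 12 months
#' (0 = never, 1 = once, 2 = two or three times, 3 = four to ten times,
#' 4 = more than ten times; Dekovic data).  The sample contains 85 distinct
#' score patterns out of 5^5 = 3125 possible ones.  The bundled table also
#' carries the random two-part pattern partition used in the reference
#' analysis of these data (`partition`), and that analysis' published EAP
#' estimates and conditional latent variances (`eap`, `var`), retained for
#' cross-checking.
#'
#' @param reference If `TRUE`, return the full transcription as a data frame
#'   (columns `pattern`, `count`, `partition`, `eap`, `var`) instead of a
#'   [pattern_counts()] object.
#' @return A [pattern_counts()] with partition labels, or a data frame.
#' @examples
#' d <- antisocial_patterns()
#' d$n          # 493
#' nrow(d$y)    # 85
#' @export
antisocial_patterns <- function(reference = FALSE) {
  path <- system.file("extdata", "dekovic_antisocial.csv", package = "cgpcm",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (reference) return(df)
  pattern_counts(df$pattern, df$count, design = test_design(rep(4L, 5L)),
                 partition = df$partition)
}
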