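## Outlier removal by interquartile range and decomposition of score
## ranges into domains (histogram bins of Scott's-rule width).

#' Remove outliers by the interquartile-range rule
#'
#' Keeps values `v` with `Q1 - k*IQR <= v <= Q3 + k*IQR`, quartiles by
#' linear interpolation between order statistics (quantile type 7). The
#' median is never removed; with zero spread all values are kept.
#'
#' @param values Numeric vector, at least 4 values.
#' @param k IQR multiplier, default 1.5 (Tukey).
#' @return The retained values, input order preserved.
#' @export
remove_outliers_iqr <- function(values, k = 1.5) {
  if (length(values) < 4) stop("too few observations (need >= 4)")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  values[values >= q[1] - k * iqr & values <= q[2] + k * iqr]
}

#' Scott's-rule histogram bin width
#'
#' `width = 3.49 * s * n^(-1/3)` with `s` the sample standard deviation
#' and `n` the number of values.
#'
#' @param values Numeric vector with at least 2 values and nonzero spread.
#' @return Bin width (same units as `values`).
#' @examples
#' scott_bin_width(rnorm(1000))  # ~ 3.49 * s * 0.1
#' @export
scott_bin_width <- function(values) {
  if (length(values) < 2) stop("degenerate distribution (need >= 2 values)")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("degenerate distribution (zero variance)")
  3.49 * s * length(values)^(-1 / 3)
}

#' Decompose a score range into domains
#'
#' Bins of Scott's-rule width spanning `[min, max]` of the (already
#' outlier-filtered) values. Bins are half-open `[lo, hi)`; the last bin is
#' closed at the top and extended to include the maximum, so the bins tile
#' the full range with no gaps.
#'
#' @param values Outlier-filtered numeric scores.
#' @param scale_name Label carried into the result.
#' @return Object of class `domain_set`: list with `scale_name`,
#'   `edges` (strictly increasing numeric vector of bin bounds) and
#'   `n_bins`.
#' @export
make_domains <- function(values, scale_name = "") {
  width <- scott_bin_width(values)
  lo <- min(values); hi <- max(values)
  n_bins <- max(1L, ceiling((hi - lo) / width - 1e-9))
  edges <- lo + width * seq(0, n_bins)
  edges[n_bins + 1] <- max(edges[n_bins + 1], hi)
  structure(list(scale_name = scale_name, edges = edges,
                 n_bins = as.integer(n_bins)),
            class = "domain_set")
}

#' Bin (domain) membership of scores
#'
#' @param domains A `domain_set`.
#' @param x Numeric scores.
#' @return Integer bin index in `1..n_bins` per score; `NA` for scores
#'   outside `[min, max]`. Bins are `[lo, hi)`, the last bin `[lo, hi]`.
#' @export
domain_index <- function(domains, x) {
  idx <- findInterval(x, domains$edges, rightmost.closed = TRUE)
  idx[idx < 1 | idx > domains$n_bins] <- NA_integer_
  idx
}

#' Bin intervals of a domain set
#'
#' @param domains A `domain_set`.
#' @return Data frame with columns `bin`, `lo`, `hi`.
#' @export
domain_bins <- function(domains) {
  data.frame(bin = seq_len(domains$n_bins),
             lo = domains$edges[-(domains$n_bins + 1)],
             hi = domains$edges[-1])
}

#' Serialize / restore domain sets as JSON
#'
#' @param domains A `domain_set` (or named list of them) for writing.
#' @param file Path.
#' @return `write_domains` returns `file` invisibly; `read_domains` the
#'   restored `domain_set` or list.
#' @export
write_domains <- function(domains, file) {
  payload <- if (inherits(domains, "domain_set")) {
    unclass(domains)
  } else {
    lapply(domains, unclass)
  }
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' @rdname write_domains
#' @export
read_domains <- function(file) {
  raw <- jsonlite::read_json(file, simplifyVector = TRUE)
  revive <- function(r) {
    structure(list(scale_name = r$scale_name, edges = as.numeric(r$edges),
                   n_bins = as.integer(r$n_bins)), class = "domain_set")
  }
  if (!is.null(raw$edges)) revive(raw) else lapply(raw, revive)
}

#' @export
print.domain_set <- function(x, ...) {
  cat("domain_set '", x$scale_name, "': ", x$n_bins, " bins over [",
      signif(x$edges[1], 5), ", ", signif(x$edges[length(x$edges)], 5),
      "]\n", sep = "")
  invisible(x)
}
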