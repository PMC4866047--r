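#' @importFrom rlang abort %||% .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join bind_rows bind_cols n row_number across
#'   if_else distinct pull rename count
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dbl map_int map_lgl map_chr map2 pmap imap
#' @importFrom stats median mad setNames rbinom rnorm runif rexp rnbinom
#'   fisher.test p.adjust chisq.test glm binomial coef vcov pchisq qnorm
#'   quantile complete.cases as.formula sd
#' @importFrom utils head modifyList
NULL

stop_format <- function(msg) {
  abort(msg, class = "mutlandscape_format_error")
}

stop_validation <- function(msg) {
  abort(msg, class = "mutlandscape_validation_error")
}

stop_config <- function(msg) {
  abort(msg, class = "mutlandscape_config_error")
}

stop_degenerate <- function(msg) {
  abort(msg, class = "mutlandscape_degenerate_error")
}

# Interval arithmetic. External tables are 1-based inclusive; internally we
# convert to half-open [start, end + 1) so that abutting intervals do not
# overlap and overlap length is a plain difference.
intervals_overlap <- function(start1, end1, start2, end2) {
  # inputs 1-based inclusive; vectorized over the first pair
  pmax(start1, start2) <= pmin(end1, end2)
}

overlap_length <- function(start1, end1, start2, end2) {
  pmax(0, pmin(end1, end2) + 1 - pmax(start1, start2))
}

# TRUE for each (chrom, pos) (or interval) hitting any interval in `ivl`
# (tibble with chrom, start, end, 1-based inclusive).
hits_intervals <- function(chrom, start, end = start, ivl) {
  if (is.null(ivl) || nrow(ivl) == 0) {
    return(rep(FALSE, length(chrom)))
  }
  vapply(seq_along(chrom), function(i) {
    j <- ivl$chrom == chrom[i]
    any(intervals_overlap(start[i], end[i], ivl$start[j], ivl$end[j]))
  }, logical(1))
}

# Wilson score interval for a binomial proportion; vectorized.
# Cross-checked against stats::prop.test(correct = FALSE) in the test suite.
wilson_interval <- function(x, n, conf = 0.95) {
  stopifnot(all(n >= 1), all(x >= 0), all(x <= n))
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  tibble(
    estimate = p,
    lower = pmax(0, centre - half),
    upper = pmin(1, centre + half)
  )
}

# split a semicolon-joined reason string into a character vector
split_reasons <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

join_reasons <- function(x) {
  if (length(x) == 0) "" else paste(x, collapse = ";")
}

has_flag <- function(flags, flag) {
  vapply(
    strsplit(ifelse(is.na(flags), "", flags), ",", fixed = TRUE),
    function(f) flag %in% trimws(f),
    logical(1)
  )
}
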