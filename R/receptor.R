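#' Assign receptor status from expression and IHC
#'
#' Reconciles immunohistochemistry (IHC) receptor calls with a two-component
#' Gaussian mixture fitted to the marker gene's expression values (ESR1 for
#' ER, ERBB2 for HER2 — the same operation serves both). Each sample with
#' expression is assigned the mixture component with the higher posterior
#' probability; the component with the higher mean is labelled `pos`. The
#' final call is:
#'
#' * IHC absent: the mixture call;
#' * IHC and mixture agree: the IHC call;
#' * they disagree: the mixture call only if the posterior probability of the
#'   opposite-of-IHC component is at least `override_ratio` (default 5) times
#'   that of the IHC component — otherwise IHC is retained as the clinical
#'   gold standard.
#'
#' Samples without expression fall back to IHC alone.
#'
#' @param data Data frame with one row per sample containing `sample`,
#'   `expression` (may be `NA`) and `ihc` (`"pos"`, `"neg"` or `NA`).
#' @param override_ratio Posterior ratio required for expression to overturn
#'   a discordant IHC call (default 5).
#' @param min_samples Minimum number of samples with expression required to
#'   attempt a mixture fit (default 20).
#' @return The input tibble with added columns `mixture_call`,
#'   `posterior_pos`, `posterior_neg` and `final_call`.
#' @examples
#' d <- tibble::tibble(
#'   sample = sprintf("S%03d", 1:200),
#'   expression = c(rnorm(120, -2, 0.5), rnorm(80, 2, 0.5)),
#'   ihc = NA_character_
#' )
#' table(assign_receptor_status(d)$final_call)
#' @export
assign_receptor_status <- function(data, override_ratio = 5,
                                   min_samples = 20) {
  data <- as_tibble(data)
  missing <- setdiff(c("sample", "expression", "ihc"), names(data))
  if (length(missing) > 0) {
    stop_format(paste0("receptor input is missing column(s): ",
                       paste(missing, collapse = ", ")))
  }
  bad_ihc <- setdiff(unique(data$ihc[!is.na(data$ihc)]), c("pos", "neg"))
  if (length(bad_ihc) > 0) {
    stop_validation(paste0("IHC calls must be 'pos', 'neg' or NA, got: ",
                           paste(bad_ihc, collapse = ", ")))
  }
  expr <- data$expression
  obs <- which(!is.na(expr))
  if (length(obs) < min_samples) {
    stop_validation(paste0("need at least ", min_samples,
                           " samples with expression for a mixture fit"))
  }
  if (sd(expr[obs]) == 0) {
    stop_degenerate("all expression values identical; mixture fit is degenerate")
  }

  # Mclust resolves helper functions in the caller's frame, so evaluate the
  # call with the mclust namespace on the search path of a scratch env
  fit_env <- list2env(list(.expr = expr[obs]),
                      parent = asNamespace("mclust"))
  fit <- eval(quote(mclust::Mclust(.expr, G = 2, modelNames = "V",
                                   verbose = FALSE)),
              envir = fit_env)
  if (is.null(fit)) {
    stop_degenerate("two-component Gaussian mixture fit failed")
  }
  pos_comp <- which.max(fit$parameters$mean)
  post_pos <- fit$z[, pos_comp]
  post_neg <- fit$z[, 3 - pos_comp]

  data$posterior_pos <- NA_real_
  data$posterior_neg <- NA_real_
  data$posterior_pos[obs] <- post_pos
  data$posterior_neg[obs] <- post_neg
  # ties (posterior exactly 0.5) go to the higher-mean (pos) component
  data$mixture_call <- if_else(data$posterior_pos >= data$posterior_neg,
                               "pos", "neg")

  data$final_call <- purrr::pmap_chr(
    list(data$mixture_call, data$ihc, data$posterior_pos, data$posterior_neg),
    function(mix, ihc, ppos, pneg) {
      if (is.na(mix)) return(ihc)            # no expression: IHC or NA
      if (is.na(ihc)) return(mix)            # no IHC: expression call
      if (mix == ihc) return(ihc)
      post_ihc <- if (ihc == "pos") ppos else pneg
      post_opp <- if (ihc == "pos") pneg else ppos
      if (post_opp >= override_ratio * post_ihc) mix else ihc
    }
  )
  data
}

#' Per-sample coverage quality control
#'
#' Flags samples for exclusion when less than `min_fraction` of targeted
#' bases reach the minimum coverage (the study design uses 25% of bases at
#' 50x). The boundary is strict: a fraction exactly at the threshold is
#' included.
#'
#' @param data Data frame with columns `sample` and `coverage_fraction`
#'   (fraction of targeted bases at or above the coverage floor, in \[0, 1\]).
#' @param min_fraction Exclusion threshold (default 0.25).
#' @return The input tibble with a logical `include` column.
#' @export
sample_qc <- function(data, min_fraction = 0.25) {
  data <- as_tibble(data)
  missing <- setdiff(c("sample", "coverage_fraction"), names(data))
  if (length(missing) > 0) {
    stop_format(paste0("QC input is missing column(s): ",
                       paste(missing, collapse = ", ")))
  }
  cf <- data$coverage_fraction
  if (any(is.na(cf)) || any(cf < 0 | cf > 1)) {
    stop_validation("coverage fractions must lie in [0, 1]")
  }
  mutate(data, include = cf >= min_fraction)
}
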