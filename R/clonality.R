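#' Estimate cancer cell fractions with confidence intervals
#'
#' The VAF and its 95% Wilson score interval are computed from the alt read
#' count and depth, then converted to a cancer cell fraction with the
#' purity/copy-number correction
#'
#' \deqn{CCF = VAF \cdot (p \cdot CN_{tum} + (1-p) \cdot CN_{norm}) / p}
#'
#' applied to the point estimate and both interval endpoints (mutation
#' multiplicity is taken as 1). CCF values are capped at 1. A mutation is
#' labelled `subclonal` when its CCF interval lies entirely below 1,
#' `clonal` otherwise.
#'
#' @param data Tibble with columns `alt_count` (or `alt_fwd` + `alt_rev`),
#'   `depth`, `purity` and `cn_tum` (optionally `cn_norm`, default 2).
#' @param conf Confidence level for the VAF interval (default 0.95).
#' @param ci_method `"wilson"` (default) or `"clopper-pearson"`.
#' @return The input with added columns `vaf_hat`, `vaf_lower`, `vaf_upper`,
#'   `ccf`, `ccf_lower`, `ccf_upper`, `clonality`.
#' @examples
#' estimate_ccf(tibble::tibble(
#'   alt_count = 50, depth = 100, purity = 1, cn_tum = 2
#' ))$ccf  # 1
#' @export
estimate_ccf <- function(data, conf = 0.95,
                         ci_method = c("wilson", "clopper-pearson")) {
  ci_method <- match.arg(ci_method)
  data <- as_tibble(data)
  if (!"alt_count" %in% names(data) &&
      all(c("alt_fwd", "alt_rev") %in% names(data))) {
    data$alt_count <- data$alt_fwd + data$alt_rev
  }
  missing <- setdiff(c("alt_count", "depth", "purity", "cn_tum"),
                     names(data))
  if (length(missing) > 0) {
    stop_format(paste0("CCF input is missing column(s): ",
                       paste(missing, collapse = ", ")))
  }
  if (nrow(data) == 0) {
    return(mutate(data, vaf_hat = double(0), vaf_lower = double(0),
                  vaf_upper = double(0), ccf = double(0),
                  ccf_lower = double(0), ccf_upper = double(0),
                  clonality = character(0)))
  }
  if (!"cn_norm" %in% names(data)) data$cn_norm <- 2
  if (any(data$depth < 1)) stop_validation("depth must be >= 1")
  if (any(data$purity <= 0 | data$purity > 1)) {
    stop_validation("purity must be in (0, 1]")
  }
  if (any(data$cn_tum == 0)) {
    stop_validation(
      "cn_tum is 0: a mutation inside a homozygous deletion is inconsistent"
    )
  }
  if (any(data$cn_tum < 1)) stop_validation("cn_tum must be >= 1")

  ci <- if (ci_method == "wilson") {
    wilson_interval(data$alt_count, data$depth, conf)
  } else {
    alpha <- 1 - conf
    tibble(
      estimate = data$alt_count / data$depth,
      lower = stats::qbeta(alpha / 2, data$alt_count,
                           data$depth - data$alt_count + 1),
      upper = stats::qbeta(1 - alpha / 2, data$alt_count + 1,
                           data$depth - data$alt_count)
    )
  }
  scale <- (data$purity * data$cn_tum +
              (1 - data$purity) * data$cn_norm) / data$purity
  data$vaf_hat <- ci$estimate
  data$vaf_lower <- ci$lower
  data$vaf_upper <- ci$upper
  data$ccf <- pmin(1, ci$estimate * scale)
  data$ccf_lower <- pmin(1, ci$lower * scale)
  data$ccf_upper <- pmin(1, ci$upper * scale)
  data$clonality <- label_clonality(data$ccf_lower, data$ccf_upper)
  data
}

#' Label mutations clonal or subclonal from a CCF interval
#'
#' Subclonal means the interval does not reach 1 (`upper < 1`); an interval
#' touching 1 is clonal.
#'
#' @param lower,upper CCF confidence bounds (vectorized).
#' @return Character vector of `"clonal"` / `"subclonal"`.
#' @export
label_clonality <- function(lower, upper) {
  if (any(lower > upper)) stop_validation("CI lower bound exceeds upper")
  if_else(upper < 1, "subclonal", "clonal")
}

#' Mutant-allele tumour heterogeneity (MATH) score
#'
#' The scaled median absolute deviation of a tumour's mutation VAFs
#' (coding and noncoding) divided by their median:
#' `mad_constant * median(|vaf - median(vaf)|) / median(vaf)`. Tumours with
#' fewer than `min_mutations` mutations are excluded (returned as `NA`).
#' The score is on the unit scale by default; `times_100 = TRUE` gives the
#' percentage convention of the original heterogeneity literature.
#'
#' @param vafs Numeric VAFs in (0, 1].
#' @param min_mutations Minimum mutation count to score (default 5).
#' @param mad_constant Consistency constant of the scaled MAD (default
#'   1.4826).
#' @param times_100 Multiply by 100 (default `FALSE`).
#' @return A single score, or `NA_real_` when the tumour is excluded.
#' @examples
#' math_score(c(0.1, 0.2, 0.3, 0.4, 0.5))  # 0.4942
#' @export
math_score <- function(vafs, min_mutations = 5, mad_constant = 1.4826,
                       times_100 = FALSE) {
  vafs <- vafs[!is.na(vafs)]
  if (any(vafs < 0 | vafs > 1)) stop_validation("VAFs must be in [0, 1]")
  if (length(vafs) > 0 && all(vafs == 0)) {
    stop_validation("all VAFs are zero; MATH is undefined")
  }
  if (length(vafs) < min_mutations) return(NA_real_)
  score <- mad_constant * median(abs(vafs - median(vafs))) / median(vafs)
  if (times_100) 100 * score else score
}

#' Per-sample MATH scores for a cohort
#'
#' @param mutations Mutation tibble with `sample` and `vaf` columns
#'   (pass-filter calls, coding and noncoding).
#' @inheritParams math_score
#' @return Tibble `sample`, `n_mutations`, `math` (`NA` when excluded).
#' @export
cohort_math_scores <- function(mutations, min_mutations = 5,
                               mad_constant = 1.4826, times_100 = FALSE) {
  mutations |>
    group_by(.data$sample) |>
    summarise(
      n_mutations = dplyr::n(),
      math = math_score(.data$vaf, min_mutations, mad_constant, times_100),
      .groups = "drop"
    )
}

#' Gene-level copy-number calls
#'
#' Looks up the segment covering each gene (longest overlap when several)
#' in each sample and derives: amplification (total copies >= `amp_min`,
#' default 5), homozygous deletion (total copies 0) and LOH (minor copy
#' number 0 with at least one copy left, irrespective of total). Genes not
#' covered by any segment are reported with `covered = FALSE` rather than
#' erroring.
#'
#' @param segments Validated segment tibble.
#' @param gene_coords Tibble `gene`, `chrom`, `start`, `end`.
#' @param amp_min Amplification threshold in total copies (default 5).
#' @return Tibble `sample`, `gene`, `covered`, `total_copies`,
#'   `minor_copies`, `amplification`, `homozygous_deletion`, `loh`.
#' @export
gene_cna_calls <- function(segments, gene_coords, amp_min = 5) {
  segments <- validate_segments(segments)
  gene_coords <- as_tibble(gene_coords)
  missing <- setdiff(c("gene", "chrom", "start", "end"), names(gene_coords))
  if (length(missing) > 0) {
    stop_format(paste0("gene_coords is missing column(s): ",
                       paste(missing, collapse = ", ")))
  }
  grid <- tidyr::crossing(sample = unique(segments$sample), gene_coords)
  hits <- grid |>
    left_join(segments, by = c("sample", "chrom"),
              suffix = c("", "_seg"), relationship = "many-to-many") |>
    mutate(ov = overlap_length(.data$start, .data$end,
                               .data$start_seg, .data$end_seg)) |>
    filter(.data$ov > 0) |>
    group_by(.data$sample, .data$gene) |>
    dplyr::slice_max(.data$ov, n = 1, with_ties = FALSE) |>
    ungroup() |>
    mutate(total_copies = .data$n_major + .data$n_minor) |>
    select("sample", "gene", "total_copies", minor_copies = "n_minor")
  grid |>
    select("sample", "gene") |>
    left_join(hits, by = c("sample", "gene")) |>
    mutate(
      covered = !is.na(.data$total_copies),
      amplification = .data$covered & .data$total_copies >= amp_min,
      homozygous_deletion = .data$covered & .data$total_copies == 0,
      loh = .data$covered & .data$minor_copies == 0 & .data$total_copies >= 1
    )
}

#' Annotate mutations with local tumour copy number
#'
#' Joins each mutation to the copy-number segment covering its position in
#' its sample and adds `cn_tum` (total copies). Mutations not covered by any
#' segment get `NA`; mutations falling in homozygously deleted segments get
#' `cn_tum = 0` and should be excluded before CCF estimation.
#'
#' @param mutations Mutation tibble with `sample`, `chrom`, `pos`.
#' @param segments Validated segment tibble.
#' @return `mutations` with a `cn_tum` column.
#' @export
annotate_copy_number <- function(mutations, segments) {
  segments <- validate_segments(segments)
  mutations <- as_tibble(mutations)
  if (nrow(mutations) == 0) {
    mutations$cn_tum <- integer(0)
    return(mutations)
  }
  seg <- segments |>
    mutate(total = .data$n_major + .data$n_minor) |>
    select("sample", "chrom", seg_start = "start", seg_end = "end", "total")
  mutations$.row <- seq_len(nrow(mutations))
  hit <- mutations |>
    select(".row", "sample", "chrom", "pos") |>
    inner_join(seg, by = c("sample", "chrom"),
               relationship = "many-to-many") |>
    filter(.data$seg_start <= .data$pos, .data$seg_end >= .data$pos) |>
    distinct(.data$.row, .keep_all = TRUE)
  mutations$cn_tum <- hit$total[match(mutations$.row, hit$.row)]
  mutations$.row <- NULL
  mutations
}

#' Chromosomal instability: ploidy-corrected fraction of genome altered
#'
#' Each segment's log2 ratio is `log2(total_copies / ploidy)`; segments with
#' ratio at or above `gain_threshold` (default 0.4) or at or below
#' `loss_threshold` (default -0.5) are altered (total copies of 0 always
#' fall in the loss class), and the score is the altered length divided by
#' the total covered length.
#'
#' @param segments Validated segment tibble for one or more samples.
#' @param purity_tbl Tibble `sample`, `purity`, `ploidy`.
#' @param gain_threshold,loss_threshold Log2-ratio thresholds (defaults 0.4
#'   and -0.5).
#' @return Tibble `sample`, `covered_bases`, `altered_bases`, `cin`.
#' @export
cin_score <- function(segments, purity_tbl, gain_threshold = 0.4,
                      loss_threshold = -0.5) {
  segments <- validate_segments(segments)
  purity_tbl <- validate_purity(purity_tbl)
  if (nrow(segments) == 0) stop_validation("no segments; CIN undefined")
  joined <- segments |>
    inner_join(select(purity_tbl, "sample", "ploidy"), by = "sample") |>
    mutate(
      len = .data$end - .data$start + 1,
      total = .data$n_major + .data$n_minor,
      log2r = if_else(.data$total == 0, -Inf,
                      log2(.data$total / .data$ploidy)),
      altered = .data$log2r >= gain_threshold | .data$log2r <= loss_threshold
    )
  out <- joined |>
    group_by(.data$sample) |>
    summarise(
      covered_bases = sum(.data$len),
      altered_bases = sum(.data$len[.data$altered]),
      .groups = "drop"
    ) |>
    mutate(cin = .data$altered_bases / .data$covered_bases)
  if (any(out$covered_bases == 0)) {
    stop_validation("zero covered length; CIN undefined")
  }
  out
}
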