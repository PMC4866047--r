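#' Domain vocabularies
#'
#' Closed vocabularies used throughout the package: variant classes,
#' functional consequences, receptor states and cause-of-death codes.
#' Readers reject values outside these sets so that downstream rules never
#' meet an unknown category.
#'
#' @name vocabularies
#' @keywords internal
NULL

variant_classes <- c("SNV", "insertion", "deletion")

consequence_levels <- c(
  "missense", "nonsense", "readthrough", "frameshift",
  "inframe_indel", "splice_site", "silent", "noncoding"
)

# consequences that enter driver-score denominators (coding + splice;
# silent and noncoding excluded)
scoreable_consequences <- c(
  "missense", "nonsense", "readthrough", "frameshift",
  "inframe_indel", "splice_site"
)

inactivating_consequences <- c("nonsense", "frameshift", "splice_site")
recurrent_eligible_consequences <- c("missense", "inframe_indel")

death_causes <- c("breast", "other", "unknown", "alive")

intclust_levels <- c("1", "2", "3", "4+", "4-", "5", "6", "7", "8", "9", "10")

histology_levels <- c("ductal/NST", "lobular", "mixed", "mucinous",
                      "medullary", "other")

#' Validate a mutation table
#'
#' Checks the invariants of the per-variant record: known variant classes and
#' consequences, non-negative strand counts, `depth` equal to the sum of the
#' four strand counts, `vaf` consistent with the alt counts, and a filter
#' audit trail in which `removal_reasons` is non-empty exactly when
#' `filter_status == "removed"`.
#'
#' @param calls A data frame of variant calls (see [read_mutations()] for the
#'   column contract).
#' @return The input as a tibble, invisibly validated; errors of class
#'   `mutlandscape_validation_error` describe the first violated invariant.
#' @export
validate_mutations <- function(calls) {
  calls <- as_tibble(calls)
  required <- c("sample", "gene", "chrom", "pos", "ref", "alt",
                "variant_class", "consequence", "codon",
                "alt_fwd", "alt_rev", "ref_fwd", "ref_rev", "quality")
  missing <- setdiff(required, names(calls))
  if (length(missing) > 0) {
    stop_format(paste0("mutation table is missing required column(s): ",
                       paste(missing, collapse = ", ")))
  }
  if (nrow(calls) == 0) {
    return(normalise_mutations(calls))
  }
  bad_class <- setdiff(unique(calls$variant_class), variant_classes)
  if (length(bad_class) > 0) {
    stop_validation(paste0("unknown variant class: ",
                           paste(bad_class, collapse = ", ")))
  }
  bad_csq <- setdiff(unique(calls$consequence), consequence_levels)
  if (length(bad_csq) > 0) {
    stop_validation(paste0("unknown consequence: ",
                           paste(bad_csq, collapse = ", ")))
  }
  counts <- calls[, c("alt_fwd", "alt_rev", "ref_fwd", "ref_rev")]
  if (any(as.matrix(counts) < 0, na.rm = TRUE)) {
    stop_validation("negative read counts")
  }
  if (any(is.na(as.matrix(counts)))) {
    stop_validation("missing strand read counts")
  }
  if (any(calls$pos < 1)) {
    stop_validation("positions must be 1-based (>= 1)")
  }
  if (!is.na(pos <- match(TRUE, !is.na(calls$codon) & calls$codon < 1))) {
    stop_validation("codon index must be >= 1")
  }
  calls <- normalise_mutations(calls)
  if (any(calls$depth < 1)) {
    stop_validation("every variant needs at least one supporting read")
  }
  if (any(calls$alt_fwd + calls$alt_rev > calls$depth)) {
    stop_validation("alt read count exceeds depth")
  }
  ok_audit <- (calls$filter_status == "pass") ==
    (!nzchar(calls$removal_reasons))
  if (!all(ok_audit)) {
    stop_validation(
      "removal_reasons must be empty exactly when filter_status is 'pass'"
    )
  }
  calls
}

# fill derived / audit columns with canonical values
normalise_mutations <- function(calls) {
  calls <- as_tibble(calls)
  if (nrow(calls) == 0) {
    calls$depth <- integer(0)
    calls$vaf <- double(0)
    if (!"flags" %in% names(calls)) calls$flags <- character(0)
    if (!"strand_bias_phred" %in% names(calls)) {
      calls$strand_bias_phred <- double(0)
    }
    if (!"filter_status" %in% names(calls)) {
      calls$filter_status <- character(0)
    }
    if (!"removal_reasons" %in% names(calls)) {
      calls$removal_reasons <- character(0)
    }
    return(calls)
  }
  calls$depth <- calls$alt_fwd + calls$alt_rev + calls$ref_fwd + calls$ref_rev
  calls$vaf <- (calls$alt_fwd + calls$alt_rev) / calls$depth
  if (!"flags" %in% names(calls)) calls$flags <- ""
  calls$flags[is.na(calls$flags)] <- ""
  if (!"strand_bias_phred" %in% names(calls)) {
    calls$strand_bias_phred <- NA_real_
  }
  if (!"filter_status" %in% names(calls)) calls$filter_status <- "pass"
  calls$filter_status[is.na(calls$filter_status)] <- "pass"
  if (!"removal_reasons" %in% names(calls)) calls$removal_reasons <- ""
  calls$removal_reasons[is.na(calls$removal_reasons)] <- ""
  calls
}

#' Validate copy-number segments
#'
#' Allele-specific segments must satisfy `n_major >= n_minor >= 0`, have
#' `start <= end` (1-based inclusive), and be non-overlapping within each
#' sample and chromosome.
#'
#' @param segments Data frame with columns `sample`, `chrom`, `start`, `end`,
#'   `n_major`, `n_minor`.
#' @return The segments as a tibble, sorted by sample, chromosome, start.
#' @export
validate_segments <- function(segments) {
  segments <- as_tibble(segments)
  required <- c("sample", "chrom", "start", "end", "n_major", "n_minor")
  missing <- setdiff(required, names(segments))
  if (length(missing) > 0) {
    stop_format(paste0("segment table is missing required column(s): ",
                       paste(missing, collapse = ", ")))
  }
  if (nrow(segments) == 0) return(segments)
  if (any(segments$n_minor < 0) || any(segments$n_major < segments$n_minor)) {
    stop_validation("segments require n_major >= n_minor >= 0")
  }
  if (any(segments$start > segments$end) || any(segments$start < 1)) {
    stop_validation("segments require 1 <= start <= end")
  }
  segments <- arrange(segments, .data$sample, .data$chrom, .data$start)
  overlap <- segments |>
    group_by(.data$sample, .data$chrom) |>
    summarise(
      bad = any(.data$start[-1] <= .data$end[-length(.data$end)]),
      .groups = "drop"
    )
  if (any(overlap$bad, na.rm = TRUE)) {
    stop_validation("overlapping segments within a sample chromosome")
  }
  segments
}

#' Validate the purity/ploidy table
#'
#' @param purity Data frame with columns `sample`, `purity`, `ploidy`.
#' @return The input as a tibble.
#' @export
validate_purity <- function(purity) {
  purity <- as_tibble(purity)
  required <- c("sample", "purity", "ploidy")
  missing <- setdiff(required, names(purity))
  if (length(missing) > 0) {
    stop_format(paste0("purity table is missing required column(s): ",
                       paste(missing, collapse = ", ")))
  }
  if (nrow(purity) > 0) {
    if (any(purity$purity <= 0 | purity$purity > 1)) {
      stop_validation("purity must lie in (0, 1]")
    }
    if (any(purity$ploidy <= 0)) {
      stop_validation("ploidy must be positive")
    }
  }
  purity
}

#' Validate a clinical table
#'
#' @param clinical Data frame with one row per sample; see [read_clinical()].
#' @return The input as a tibble.
#' @export
validate_clinical <- function(clinical) {
  clinical <- as_tibble(clinical)
  required <- c("sample", "age_years", "grade", "size_mm",
                "lymph_node_positive", "er_ihc", "her2_ihc", "intclust",
                "histology", "followup_months", "death_cause")
  missing <- setdiff(required, names(clinical))
  if (length(missing) > 0) {
    stop_format(paste0("clinical table is missing required column(s): ",
                       paste(missing, collapse = ", ")))
  }
  if (nrow(clinical) == 0) return(clinical)
  if (any(clinical$followup_months < 0, na.rm = TRUE)) {
    stop_validation("followup_months must be >= 0")
  }
  bad_grade <- setdiff(unique(clinical$grade[!is.na(clinical$grade)]),
                       c(1L, 2L, 3L))
  if (length(bad_grade) > 0) {
    stop_validation("grade must be 1, 2 or 3")
  }
  bad_cause <- setdiff(unique(clinical$death_cause[!is.na(clinical$death_cause)]),
                       death_causes)
  if (length(bad_cause) > 0) {
    stop_validation(paste0("unknown death cause: ",
                           paste(bad_cause, collapse = ", ")))
  }
  bad_ic <- setdiff(unique(clinical$intclust[!is.na(clinical$intclust)]),
                    intclust_levels)
  if (length(bad_ic) > 0) {
    stop_validation(paste0("unknown IntClust label: ",
                           paste(bad_ic, collapse = ", ")))
  }
  clinical
}
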