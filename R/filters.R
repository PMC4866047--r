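#' Filtering thresholds
#'
#' All thresholds of the two-level (generic + somatic) filtering scheme, with
#' defaults from the replicate-calibrated study design. Boundary semantics
#' follow the rules as stated: caller quality below 6.95 is removed
#' (strict), indel strand-bias Phred scores at or above 40 are removed
#' (inclusive), VAF below 0.1 and depth below 10 are removed (strict),
#' population allele frequency at or above 1% removes SNVs (inclusive) but
#' only strictly above 1% removes indels, and the COSMIC hotspot rescue uses
#' "more than two" breast samples with strict >5% normal-breast and >1%
#' blood overrides.
#'
#' @param snv_quality_min Minimum caller quality for SNVs (default 6.95).
#' @param strand_bias_fdr_snv Cohort-wide FDR level for the read-direction
#'   bias test (default 1e-4).
#' @param indel_strand_bias_phred_max Indels with caller strand-bias Phred
#'   scores at or above this are removed (default 40).
#' @param vaf_min,depth_min VAF and depth floors (defaults 0.1 and 10).
#' @param kg_af_max Population allele-frequency ceiling (default 0.01).
#' @param normal_pool_vaf_min Pool VAF at which a normal-pool observation
#'   counts (default 0.1).
#' @param cosmic_breast_min_count Breast-sample count in COSMIC required for
#'   the stringent normal-pool rescue ("more than two" = 3; default 3).
#' @param cosmic_rescue_normal_breast_max,cosmic_rescue_blood_max Fractions
#'   above which a COSMIC-rescued variant is removed anyway (defaults 0.05
#'   and 0.01, strict).
#' @param cosmic_somatic_min_count Breast count treated as "present and
#'   confirmed somatic" for the low-VAF/low-depth rescue (default 1).
#' @param homopolymer_min_run Minimum homopolymer run length that removes an
#'   overlapping indel (default 6).
#' @param muc16_region The MUC16 tandem-repeat window (chr19:
#'   8,955,441-9,044,530).
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(snv_quality_min = 6.95,
                              strand_bias_fdr_snv = 1e-4,
                              indel_strand_bias_phred_max = 40,
                              vaf_min = 0.1,
                              depth_min = 10,
                              kg_af_max = 0.01,
                              normal_pool_vaf_min = 0.1,
                              cosmic_breast_min_count = 3,
                              cosmic_rescue_normal_breast_max = 0.05,
                              cosmic_rescue_blood_max = 0.01,
                              cosmic_somatic_min_count = 1,
                              homopolymer_min_run = 6,
                              muc16_region = list(chrom = "chr19",
                                                  start = 8955441,
                                                  end = 9044530)) {
  vals <- c(snv_quality_min, strand_bias_fdr_snv, indel_strand_bias_phred_max,
            vaf_min, depth_min, kg_af_max, normal_pool_vaf_min,
            cosmic_breast_min_count, cosmic_rescue_normal_breast_max,
            cosmic_rescue_blood_max, cosmic_somatic_min_count,
            homopolymer_min_run)
  if (any(vals <= 0)) stop_config("all thresholds must be positive")
  if (muc16_region$start >= muc16_region$end) {
    stop_config("muc16 region start must be < end")
  }
  structure(
    list(
      snv_quality_min = snv_quality_min,
      strand_bias_fdr_snv = strand_bias_fdr_snv,
      indel_strand_bias_phred_max = indel_strand_bias_phred_max,
      vaf_min = vaf_min, depth_min = depth_min, kg_af_max = kg_af_max,
      normal_pool_vaf_min = normal_pool_vaf_min,
      cosmic_breast_min_count = cosmic_breast_min_count,
      cosmic_rescue_normal_breast_max = cosmic_rescue_normal_breast_max,
      cosmic_rescue_blood_max = cosmic_rescue_blood_max,
      cosmic_somatic_min_count = cosmic_somatic_min_count,
      homopolymer_min_run = homopolymer_min_run,
      muc16_region = muc16_region
    ),
    class = "filter_thresholds"
  )
}

snv_reason_codes <- c("low_quality", "muc16_repeat_region", "caller_flag",
                      "strand_bias", "low_vaf_or_depth",
                      "population_frequency", "normal_pool")

indel_reason_codes <- c("muc16_repeat_region", "lowqual_flag", "strand_bias",
                        "repeat_region", "microsatellite", "homopolymer",
                        "population_frequency", "low_vaf_or_depth",
                        "normal_pool")

#' All removal reason codes emitted by the filters
#' @return Character vector of the enumerated audit codes.
#' @export
filter_reason_codes <- function() {
  unique(c(snv_reason_codes, indel_reason_codes))
}

#' Exact test for read-direction (strand) bias
#'
#' Two-sided Fisher exact p-value on the 2x2 table
#' \[\[alt_fwd, alt_rev\], \[ref_fwd, ref_rev\]\]: a variant whose supporting
#' reads fall significantly more often on one strand than its reference
#' reads do is a likely alignment artefact.
#'
#' @param alt_fwd,alt_rev,ref_fwd,ref_rev Non-negative read counts;
#'   vectorized. At least one alt read per variant is required (there is no
#'   variant to test otherwise).
#' @return Numeric vector of two-sided p-values.
#' @export
strand_bias_test <- function(alt_fwd, alt_rev, ref_fwd, ref_rev) {
  counts <- cbind(alt_fwd, alt_rev, ref_fwd, ref_rev)
  if (any(counts < 0)) stop_validation("read counts must be non-negative")
  if (any(alt_fwd + alt_rev < 1)) {
    stop_validation("strand bias test requires at least one alt read")
  }
  vapply(seq_len(nrow(counts)), function(i) {
    fisher.test(matrix(counts[i, ], nrow = 2, byrow = TRUE))$p.value
  }, double(1))
}

resource_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

require_resources <- function(resources, tables) {
  missing <- setdiff(tables, names(resources))
  if (length(missing) > 0) {
    stop_config(paste0("resources are missing table(s): ",
                       paste(missing, collapse = ", ")))
  }
}

# shared somatic rules: population frequency, VAF/depth with COSMIC rescue,
# normal pool with stringent COSMIC rescue
somatic_rules <- function(calls, resources, th, kg_inclusive) {
  key <- resource_key(calls$chrom, calls$pos)

  cosmic <- resources$cosmic
  cidx <- match(key, resource_key(cosmic$chrom, cosmic$pos))
  cosmic_count <- if_else(is.na(cidx), 0L, as.integer(cosmic$breast_count[cidx]))
  cosmic_somatic <- !is.na(cidx) & cosmic$somatic[cidx] &
    cosmic_count >= th$cosmic_somatic_min_count

  kg <- resources$kg_af
  kidx <- match(key, resource_key(kg$chrom, kg$pos))
  kg_af <- if_else(is.na(kidx), 0, kg$af[kidx])

  np <- resources$normal_pool
  nidx <- match(key, resource_key(np$chrom, np$pos))
  in_pool <- !is.na(nidx) & np$pool_vaf[nidx] >= th$normal_pool_vaf_min
  frac_breast <- if_else(is.na(nidx), 0, np$fraction_breast[nidx])
  frac_blood <- if_else(is.na(nidx), 0, np$fraction_blood[nidx])

  low_vaf_or_depth <- (calls$vaf < th$vaf_min | calls$depth < th$depth_min) &
    !cosmic_somatic

  population_frequency <- if (kg_inclusive) kg_af >= th$kg_af_max else
    kg_af > th$kg_af_max

  cosmic_recurrent <- cosmic_count >= th$cosmic_breast_min_count
  normal_pool <- in_pool & (
    !cosmic_recurrent |
      frac_breast > th$cosmic_rescue_normal_breast_max |
      frac_blood > th$cosmic_rescue_blood_max
  )

  list(low_vaf_or_depth = low_vaf_or_depth,
       population_frequency = population_frequency,
       normal_pool = normal_pool)
}

in_muc16 <- function(calls, th) {
  calls$chrom == th$muc16_region$chrom &
    calls$pos >= th$muc16_region$start &
    calls$pos <= th$muc16_region$end
}

finalise_filters <- function(calls, fired, rule_order = NULL) {
  if (!is.null(rule_order)) fired <- fired[rule_order]
  reason_mat <- do.call(cbind, fired)
  reasons <- apply(reason_mat, 1, function(r) {
    join_reasons(names(fired)[r])
  })
  calls$removal_reasons <- unname(reasons)
  calls$filter_status <- if_else(nzchar(calls$removal_reasons),
                                 "removed", "pass")
  calls
}

#' Apply the SNV filtering rules
#'
#' Applies the seven SNV rules with reasons accumulated, never
#' short-circuited, so the audit trail lists every rule a variant violates
#' and the pass/remove partition is independent of rule order:
#' caller quality below the floor; MUC16 tandem-repeat window; caller
#' `nearby_gap_events` / `poor_mapping_regional_alternate_allele_mapq`
#' flags; cohort-wide Benjamini-Hochberg-significant strand bias; VAF/depth
#' floor unless the variant is a confirmed-somatic COSMIC mutation;
#' population allele frequency at or above 1%; and presence in the normal
#' pool at VAF >= 0.1 unless rescued by recurrence in COSMIC breast samples
#' (in which case only gross normal-tissue or blood prevalence removes it).
#'
#' @param calls Validated mutation tibble containing only SNVs.
#' @param resources Named list of resource tables (`cosmic`, `kg_af`,
#'   `normal_pool`); see [simulate_cohort()] for the layout.
#' @param thresholds A [filter_thresholds()].
#' @param rule_order Optional permutation of the rule indices; because
#'   reasons accumulate, the pass/remove partition is invariant to it (a
#'   property the test suite asserts).
#' @return `calls` with `filter_status` and semicolon-joined
#'   `removal_reasons` filled in.
#' @export
apply_snv_filters <- function(calls, resources,
                              thresholds = filter_thresholds(),
                              rule_order = NULL) {
  calls <- validate_mutations(calls)
  th <- thresholds
  if (nrow(calls) == 0) return(calls)
  if (any(calls$variant_class != "SNV")) {
    stop_validation("apply_snv_filters expects SNV calls only")
  }
  require_resources(resources, c("cosmic", "kg_af", "normal_pool"))

  p_strand <- strand_bias_test(calls$alt_fwd, calls$alt_rev,
                               calls$ref_fwd, calls$ref_rev)
  q_strand <- p.adjust(p_strand, method = "BH")

  som <- somatic_rules(calls, resources, th, kg_inclusive = TRUE)
  fired <- list(
    low_quality = calls$quality < th$snv_quality_min,
    muc16_repeat_region = in_muc16(calls, th),
    caller_flag = has_flag(calls$flags, "nearby_gap_events") |
      has_flag(calls$flags, "poor_mapping_regional_alternate_allele_mapq"),
    strand_bias = q_strand <= th$strand_bias_fdr_snv,
    low_vaf_or_depth = som$low_vaf_or_depth,
    population_frequency = som$population_frequency,
    normal_pool = som$normal_pool
  )
  finalise_filters(calls, fired, rule_order)
}

#' Apply the indel filtering rules
#'
#' Indels are removed when they fall in the MUC16 tandem-repeat window,
#' carry the caller's `LowQual` flag, have a strand-bias Phred score at or
#' above 40, overlap a simple-repeat or microsatellite interval, overlap a
#' homopolymer run of six or more bases, are present in the population
#' reference above 1% (strict), or fail the same VAF/depth and normal-pool
#' rules as SNVs (including the COSMIC rescues). Reasons accumulate as for
#' [apply_snv_filters()].
#'
#' @inheritParams apply_snv_filters
#' @param rule_order Optional permutation of the rule indices (see
#'   [apply_snv_filters()]).
#' @param resources Must also contain `repeat_intervals`,
#'   `microsatellite_intervals` and `homopolymers` interval tables.
#' @return `calls` with the filter audit columns filled in.
#' @export
apply_indel_filters <- function(calls, resources,
                                thresholds = filter_thresholds(),
                                rule_order = NULL) {
  calls <- validate_mutations(calls)
  th <- thresholds
  if (nrow(calls) == 0) return(calls)
  if (any(!calls$variant_class %in% c("insertion", "deletion"))) {
    stop_validation("apply_indel_filters expects indel calls only")
  }
  require_resources(resources, c("cosmic", "kg_af", "normal_pool",
                                 "repeat_intervals",
                                 "microsatellite_intervals", "homopolymers"))

  hp <- resources$homopolymers
  hp <- hp[hp$run_length >= th$homopolymer_min_run, , drop = FALSE]
  sb_phred <- calls$strand_bias_phred
  sb_phred[is.na(sb_phred)] <- 0

  som <- somatic_rules(calls, resources, th, kg_inclusive = FALSE)
  fired <- list(
    muc16_repeat_region = in_muc16(calls, th),
    lowqual_flag = has_flag(calls$flags, "LowQual"),
    strand_bias = sb_phred >= th$indel_strand_bias_phred_max,
    repeat_region = hits_intervals(calls$chrom, calls$pos,
                                   ivl = resources$repeat_intervals),
    microsatellite = hits_intervals(calls$chrom, calls$pos,
                                    ivl = resources$microsatellite_intervals),
    homopolymer = hits_intervals(calls$chrom, calls$pos, ivl = hp),
    population_frequency = som$population_frequency,
    low_vaf_or_depth = som$low_vaf_or_depth,
    normal_pool = som$normal_pool
  )
  finalise_filters(calls, fired, rule_order)
}

#' Classify germline variants as pathogenic
#'
#' Applies the two-route germline pathogenicity rule: (1) the variant is
#' recorded in ClinVar as pathogenic or probable-pathogenic with a germline
#' origin (germline, inherited, paternal, maternal, biparental or
#' uniparental) and is not a common polymorphism (population allele
#' frequency above 1% disqualifies); or (2) the variant is absent from
#' ClinVar, observed in one to six normal samples, and is inactivating —
#' truncating or splice-disrupting, or Provean-deleterious for missense
#' SNVs; frame-disrupting or splice-disrupting for indels.
#'
#' @param variants Tibble with columns `chrom`, `pos`, `variant_class`,
#'   `consequence`.
#' @param resources List with `clinvar` (columns `chrom`, `pos`,
#'   `significance`, `origin`), `provean` (columns `chrom`, `pos`, `call`),
#'   `kg_af` and `normal_pool` (column `n_normals`).
#' @return The input with a `germline_class` column (`"pathogenic"` /
#'   `"not_pathogenic"`).
#' @export
classify_germline_pathogenic <- function(variants, resources) {
  variants <- as_tibble(variants)
  require_resources(resources, c("clinvar", "provean", "kg_af",
                                 "normal_pool"))
  if (nrow(variants) == 0) {
    variants$germline_class <- character(0)
    return(variants)
  }
  key <- resource_key(variants$chrom, variants$pos)

  cv <- resources$clinvar
  cvidx <- match(key, resource_key(cv$chrom, cv$pos))
  in_clinvar <- !is.na(cvidx)
  patho_sig <- in_clinvar &
    cv$significance[cvidx] %in% c("pathogenic", "probable-pathogenic")
  germline_origin <- in_clinvar &
    cv$origin[cvidx] %in% c("germline", "inherited", "paternal", "maternal",
                            "biparental", "uniparental")

  kg <- resources$kg_af
  kidx <- match(key, resource_key(kg$chrom, kg$pos))
  kg_af <- if_else(is.na(kidx), 0, kg$af[kidx])

  np <- resources$normal_pool
  nidx <- match(key, resource_key(np$chrom, np$pos))
  n_normals <- if_else(is.na(nidx), 0L, as.integer(np$n_normals[nidx]))

  pv <- resources$provean
  pidx <- match(key, resource_key(pv$chrom, pv$pos))
  provean_del <- !is.na(pidx) & pv$call[pidx] %in% c("deleterious", "damaging")

  is_snv <- variants$variant_class == "SNV"
  inactivating_snv <- is_snv &
    variants$consequence %in% c("nonsense", "splice_site")
  disruptive_indel <- !is_snv &
    variants$consequence %in% c("frameshift", "splice_site")

  route1 <- patho_sig & germline_origin & kg_af <= 0.01
  route2 <- !in_clinvar & n_normals >= 1 & n_normals <= 6 &
    (inactivating_snv | (is_snv & provean_del) | disruptive_indel)

  variants$germline_class <- if_else(route1 | route2,
                                     "pathogenic", "not_pathogenic")
  variants
}
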