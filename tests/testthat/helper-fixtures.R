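# Hand-built 50-variant fixture exercising every removal rule at least once,
# with the expected pass/remove partition and reason sets written alongside
# each variant.

fx_variant <- function(id, class = "SNV", chrom = "chr1", pos = 1e6 + id,
                       quality = 50, alt_fwd = 15L, alt_rev = 15L,
                       ref_fwd = 60L, ref_rev = 60L, flags = "",
                       sb_phred = if (class == "SNV") NA_real_ else 10,
                       consequence = if (class == "SNV") "missense"
                       else "frameshift",
                       codon = 10L,
                       expect = "pass", reasons = "") {
  tibble::tibble(
    sample = sprintf("S%02d", id), gene = "G1", chrom = chrom, pos = pos,
    ref = "A", alt = if (class == "SNV") "T" else "AT",
    variant_class = class, consequence = consequence, codon = codon,
    alt_fwd = as.integer(alt_fwd), alt_rev = as.integer(alt_rev),
    ref_fwd = as.integer(ref_fwd), ref_rev = as.integer(ref_rev),
    quality = quality, flags = flags, strand_bias_phred = sb_phred,
    expected_status = expect, expected_reasons = reasons
  )
}

filter_fixture <- function() {
  v <- list(
    # --- SNVs (30) ---------------------------------------------------------
    fx_variant(1), fx_variant(2), fx_variant(3),
    fx_variant(4, alt_fwd = 35, alt_rev = 35, ref_fwd = 35, ref_rev = 35),
    fx_variant(5, alt_fwd = 60, alt_rev = 60, ref_fwd = 140, ref_rev = 140),
    fx_variant(6, quality = 5.0, expect = "removed", reasons = "low_quality"),
    fx_variant(7, quality = 6.94, expect = "removed",
               reasons = "low_quality"),
    fx_variant(8, quality = 6.95),                      # boundary: strict <
    fx_variant(9, chrom = "chr19", pos = 9e6, expect = "removed",
               reasons = "muc16_repeat_region"),
    fx_variant(10, chrom = "chr19", pos = 8955441, expect = "removed",
               reasons = "muc16_repeat_region"),        # window start
    fx_variant(11, chrom = "chr19", pos = 8955440),     # just outside
    fx_variant(12, flags = "nearby_gap_events", expect = "removed",
               reasons = "caller_flag"),
    fx_variant(13, flags = "poor_mapping_regional_alternate_allele_mapq",
               expect = "removed", reasons = "caller_flag"),
    fx_variant(14, flags = "clustered_events"),         # unrelated flag
    fx_variant(15, alt_fwd = 40, alt_rev = 0, expect = "removed",
               reasons = "strand_bias"),
    fx_variant(16, alt_fwd = 18, alt_rev = 12),         # mild imbalance
    fx_variant(17, alt_fwd = 5, alt_rev = 5, ref_fwd = 95, ref_rev = 95,
               expect = "removed", reasons = "low_vaf_or_depth"),
    fx_variant(18, chrom = "chr2", pos = 1000, alt_fwd = 5, alt_rev = 5,
               ref_fwd = 95, ref_rev = 95),             # COSMIC rescue
    fx_variant(19, alt_fwd = 2, alt_rev = 2, ref_fwd = 2, ref_rev = 2,
               expect = "removed", reasons = "low_vaf_or_depth"),
    fx_variant(20, alt_fwd = 5, alt_rev = 5, ref_fwd = 45, ref_rev = 45),
    fx_variant(21, chrom = "chr2", pos = 2000, expect = "removed",
               reasons = "population_frequency"),       # AF 0.01 inclusive
    fx_variant(22, chrom = "chr2", pos = 2001),         # AF 0.009
    fx_variant(23, chrom = "chr2", pos = 3000, expect = "removed",
               reasons = "normal_pool"),
    fx_variant(24, chrom = "chr2", pos = 3001),         # COSMIC >2 rescue
    fx_variant(25, chrom = "chr2", pos = 3002, expect = "removed",
               reasons = "normal_pool"),                # breast frac > 5%
    fx_variant(26, chrom = "chr2", pos = 3003, expect = "removed",
               reasons = "normal_pool"),                # blood frac > 1%
    fx_variant(27, chrom = "chr2", pos = 3004, expect = "removed",
               reasons = "normal_pool"),                # COSMIC count 2 only
    fx_variant(28, chrom = "chr2", pos = 3005),         # pool VAF < 0.1
    fx_variant(29, chrom = "chr19", pos = 9000001, quality = 5.0,
               expect = "removed",
               reasons = "low_quality;muc16_repeat_region"),
    fx_variant(30),
    # --- indels (20) -------------------------------------------------------
    fx_variant(31, class = "deletion", chrom = "chr3"),
    fx_variant(32, class = "insertion", chrom = "chr3"),
    fx_variant(33, class = "deletion", chrom = "chr3"),
    fx_variant(34, class = "deletion", chrom = "chr19", pos = 9000100,
               expect = "removed", reasons = "muc16_repeat_region"),
    fx_variant(35, class = "deletion", chrom = "chr3", flags = "LowQual",
               expect = "removed", reasons = "lowqual_flag"),
    fx_variant(36, class = "deletion", chrom = "chr3", sb_phred = 40,
               expect = "removed", reasons = "strand_bias"),
    fx_variant(37, class = "deletion", chrom = "chr3", sb_phred = 39.9),
    fx_variant(38, class = "deletion", chrom = "chr4", pos = 5500,
               expect = "removed", reasons = "repeat_region"),
    fx_variant(39, class = "insertion", chrom = "chr4", pos = 7100,
               expect = "removed", reasons = "microsatellite"),
    fx_variant(40, class = "deletion", chrom = "chr4", pos = 8005,
               expect = "removed", reasons = "homopolymer"),
    fx_variant(41, class = "deletion", chrom = "chr4", pos = 9005),
    fx_variant(42, class = "deletion", chrom = "chr2", pos = 4000),
    fx_variant(43, class = "deletion", chrom = "chr2", pos = 4001,
               expect = "removed", reasons = "population_frequency"),
    fx_variant(44, class = "deletion", chrom = "chr3", alt_fwd = 5,
               alt_rev = 5, ref_fwd = 95, ref_rev = 95,
               expect = "removed", reasons = "low_vaf_or_depth"),
    fx_variant(45, class = "deletion", chrom = "chr2", pos = 1001,
               alt_fwd = 5, alt_rev = 5, ref_fwd = 95, ref_rev = 95),
    fx_variant(46, class = "insertion", chrom = "chr3", alt_fwd = 2,
               alt_rev = 2, ref_fwd = 2, ref_rev = 2,
               expect = "removed", reasons = "low_vaf_or_depth"),
    fx_variant(47, class = "deletion", chrom = "chr2", pos = 3006,
               expect = "removed", reasons = "normal_pool"),
    fx_variant(48, class = "deletion", chrom = "chr3"),
    fx_variant(49, class = "insertion", chrom = "chr3"),
    fx_variant(50, class = "deletion", chrom = "chr2", pos = 3007)
  )
  calls <- dplyr::bind_rows(v)
  resources <- list(
    cosmic = tibble::tibble(
      chrom = "chr2",
      pos = c(1000, 1001, 3001, 3002, 3003, 3004, 3007),
      breast_count = c(10L, 10L, 10L, 10L, 10L, 2L, 10L),
      somatic = TRUE
    ),
    kg_af = tibble::tibble(
      chrom = "chr2",
      pos = c(2000, 2001, 4000, 4001),
      af = c(0.01, 0.009, 0.01, 0.011)
    ),
    normal_pool = tibble::tibble(
      chrom = "chr2",
      pos = c(3000, 3001, 3002, 3003, 3004, 3005, 3006, 3007),
      pool_vaf = c(0.2, 0.2, 0.2, 0.2, 0.2, 0.05, 0.3, 0.2),
      n_normals = c(50L, 30L, 30L, 30L, 30L, 30L, 40L, 30L),
      fraction_breast = c(0.2, 0.01, 0.06, 0.01, 0.01, 0.2, 0.2, 0.01),
      fraction_blood = c(0.1, 0.005, 0.005, 0.02, 0.005, 0.1, 0.05, 0.002)
    ),
    clinvar = tibble::tibble(chrom = character(0), pos = double(0),
                             significance = character(0),
                             origin = character(0)),
    provean = tibble::tibble(chrom = character(0), pos = double(0),
                             call = character(0)),
    repeat_intervals = tibble::tibble(chrom = "chr4", start = 5000,
                                      end = 6000),
    microsatellite_intervals = tibble::tibble(chrom = "chr4", start = 7000,
                                              end = 7500),
    homopolymers = tibble::tibble(chrom = "chr4",
                                  start = c(8000, 9000),
                                  end = c(8010, 9010),
                                  run_length = c(6L, 5L))
  )
  list(calls = calls, resources = resources)
}

run_filter_fixture <- function(fx = filter_fixture(), ...) {
  snv <- dplyr::filter(fx$calls, variant_class == "SNV")
  ind <- dplyr::filter(fx$calls, variant_class != "SNV")
  dplyr::bind_rows(
    apply_snv_filters(snv, fx$resources, ...),
    apply_indel_filters(ind, fx$resources, ...)
  )
}

# panel for the driver-recovery experiments: 5 hotspot oncogenes, 5 tumour
# suppressors, 40 passengers; driver rate 0.10 per stratum (>= 20 mutations
# per gene in the smaller stratum), passenger rate 0.01
recovery_panel <- function(n_onc = 5, n_tsg = 5, n_passenger = 40,
                           driver_rate = 0.10, passenger_rate = 0.01) {
  mk <- function(gene, role, rate, hotspots) {
    tibble::tibble(gene = gene, role = role, length_codons = 500L,
                   hotspot_codons = list(hotspots), rate_erpos = rate,
                   rate_erneg = rate, log_hr = 0, use_both = FALSE)
  }
  dplyr::bind_rows(
    purrr::map_dfr(seq_len(n_onc), function(i) {
      mk(sprintf("ONC%d", i), "oncogene", driver_rate, c(100L, 200L, 300L))
    }),
    purrr::map_dfr(seq_len(n_tsg), function(i) {
      mk(sprintf("TSG%d", i), "tsg", driver_rate, integer(0))
    }),
    purrr::map_dfr(seq_len(n_passenger), function(i) {
      mk(sprintf("P%02d", i), "passenger", passenger_rate, integer(0))
    })
  )
}

run_driver_recovery <- function(seed, n_tumours = 1000) {
  ch <- simulate_cohort(cohort_config(
    n_tumours = n_tumours, seed = seed, gene_panel = recovery_panel(),
    hotspot_share = 0.6, background_rate = 0
  ))
  pass <- run_cohort_filters(ch)
  er <- tibble::tibble(sample = ch$truth$samples$sample,
                       er = ch$truth$samples$true_er)
  drivers <- identify_mut_drivers(
    dplyr::filter(pass, filter_status == "pass", !is.na(consequence)), er
  )
  called <- unique(drivers$gene[drivers$driver_gene])
  list(
    called = called,
    truth = ch$truth$drivers$gene,
    passengers = grep("^P", unique(ch$mutations$gene), value = TRUE)
  )
}

run_cohort_filters <- function(cohort) {
  snv <- dplyr::filter(cohort$mutations, variant_class == "SNV")
  ind <- dplyr::filter(cohort$mutations, variant_class != "SNV")
  out <- apply_snv_filters(snv, cohort$resources)
  if (nrow(ind) > 0) {
    out <- dplyr::bind_rows(out,
                            apply_indel_filters(ind, cohort$resources))
  }
  out
}

# minimal valid clinical row builder
fx_clinical <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    sample = sprintf("S%04d", seq_len(n)),
    age_years = round(runif(n, 30, 90)),
    grade = sample(1:3, n, replace = TRUE),
    size_mm = round(runif(n, 5, 90), 1),
    lymph_node_positive = runif(n) < 0.5,
    er_ihc = sample(c("pos", "neg", NA), n, replace = TRUE,
                    prob = c(0.6, 0.3, 0.1)),
    her2_ihc = sample(c("pos", "neg", NA), n, replace = TRUE,
                      prob = c(0.15, 0.75, 0.1)),
    intclust = sample(c("1", "3", "5", "10"), n, replace = TRUE),
    histology = sample(c("ductal/NST", "lobular"), n, replace = TRUE),
    followup_months = round(runif(n, 1, 250), 1),
    death_cause = sample(c("breast", "other", "unknown", "alive"), n,
                         replace = TRUE, prob = c(0.3, 0.1, 0.05, 0.55))
  )
}
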