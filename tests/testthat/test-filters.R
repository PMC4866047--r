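test_that("strand bias test matches hand cases and the enumeration oracle", {
  expect_equal(strand_bias_test(5, 5, 50, 50), 1)
  expect_equal(strand_bias_test(1, 0, 0, 0), 1)
  expect_equal(strand_bias_test(10, 0, 50, 50),
               fisher_p_enumerated(10, 0, 50, 50), tolerance = 1e-10)
  expect_error(strand_bias_test(0, 0, 5, 5),
               class = "mutlandscape_validation_error")
  expect_error(strand_bias_test(-1, 2, 5, 5),
               class = "mutlandscape_validation_error")

  # random spot-checks against the brute-force oracle
  set.seed(15)
  for (i in 1:40) {
    cells <- as.integer(rmultinom(1, sample(4:30, 1), rep(1 / 4, 4)))
    if (cells[1] + cells[2] == 0) cells[1] <- 1L
    expect_equal(strand_bias_test(cells[1], cells[2], cells[3], cells[4]),
                 fisher_p_enumerated(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
  }
})

test_that("the 50-variant fixture partitions exactly as expected", {
  fx <- filter_fixture()
  expect_equal(nrow(fx$calls), 50)
  out <- run_filter_fixture(fx)
  out <- out[match(fx$calls$sample, out$sample), ]
  expect_equal(out$filter_status, fx$calls$expected_status)
  # reason sets match exactly (order-free comparison)
  got <- lapply(out$removal_reasons,
                function(r) sort(strsplit(r, ";")[[1]]))
  want <- lapply(fx$calls$expected_reasons,
                 function(r) sort(strsplit(r, ";")[[1]]))
  expect_equal(got, want)
})

test_that("filter audit is complete and uses only enumerated codes", {
  ch <- simulate_cohort(cohort_config(n_tumours = 150, seed = 21))
  out <- run_cohort_filters(ch)
  removed <- out[out$filter_status == "removed", ]
  reasons <- strsplit(removed$removal_reasons, ";")
  expect_true(all(lengths(reasons) >= 1))
  expect_true(all(unlist(reasons) %in% filter_reason_codes()))
  passed <- out[out$filter_status == "pass", ]
  expect_true(all(passed$removal_reasons == ""))
})

test_that("the pass/remove partition is invariant to rule order", {
  fx <- filter_fixture()
  set.seed(33)
  snv <- dplyr::filter(fx$calls, variant_class == "SNV")
  ind <- dplyr::filter(fx$calls, variant_class != "SNV")
  base_snv <- apply_snv_filters(snv, fx$resources)
  base_ind <- apply_indel_filters(ind, fx$resources)
  for (i in 1:5) {
    perm_snv <- apply_snv_filters(snv, fx$resources,
                                  rule_order = sample(7))
    perm_ind <- apply_indel_filters(ind, fx$resources,
                                    rule_order = sample(9))
    expect_equal(perm_snv$filter_status, base_snv$filter_status)
    expect_equal(perm_ind$filter_status, base_ind$filter_status)
    expect_equal(
      lapply(perm_snv$removal_reasons, function(r) sort(strsplit(r, ";")[[1]])),
      lapply(base_snv$removal_reasons, function(r) sort(strsplit(r, ";")[[1]]))
    )
  }
  # row order is equally irrelevant (the BH step is cohort-wide but
  # permutation-equivariant)
  shuffle <- sample(nrow(snv))
  perm <- apply_snv_filters(snv[shuffle, ], fx$resources)
  expect_equal(perm$filter_status[order(shuffle)], base_snv$filter_status)
})

test_that("filters demand SNV/indel inputs and complete resources", {
  fx <- filter_fixture()
  snv <- dplyr::filter(fx$calls, variant_class == "SNV")
  ind <- dplyr::filter(fx$calls, variant_class != "SNV")
  expect_error(apply_snv_filters(ind, fx$resources),
               class = "mutlandscape_validation_error")
  expect_error(apply_indel_filters(snv, fx$resources),
               class = "mutlandscape_validation_error")
  broken <- fx$resources
  broken$cosmic <- NULL
  expect_error(apply_snv_filters(snv, broken),
               class = "mutlandscape_config_error")
})

test_that("germline pathogenicity rules fire as specified", {
  resources <- list(
    clinvar = tibble::tibble(
      chrom = "chr1", pos = c(100, 400),
      significance = c("pathogenic", "pathogenic"),
      origin = c("germline", "germline")
    ),
    provean = tibble::tibble(chrom = "chr1", pos = 300,
                             call = "deleterious"),
    kg_af = tibble::tibble(chrom = "chr1", pos = 400, af = 0.02),
    normal_pool = tibble::tibble(
      chrom = "chr1", pos = c(200, 300, 500, 600),
      pool_vaf = 0.5, n_normals = c(3L, 3L, 3L, 10L),
      fraction_breast = 0, fraction_blood = 0
    )
  )
  variants <- tibble::tibble(
    chrom = "chr1",
    pos = c(100, 200, 300, 400, 500, 600, 700),
    variant_class = c("SNV", "SNV", "SNV", "SNV", "SNV", "deletion",
                      "deletion"),
    consequence = c("missense", "nonsense", "missense", "missense",
                    "missense", "frameshift", "frameshift")
  )
  out <- classify_germline_pathogenic(variants, resources)
  expect_equal(out$germline_class, c(
    "pathogenic",      # ClinVar pathogenic + germline, AF 0
    "pathogenic",      # absent from ClinVar, nonsense in 3 normals
    "pathogenic",      # absent from ClinVar, Provean-deleterious in 3
    "not_pathogenic",  # ClinVar pathogenic but 1000G AF 0.02 > 1%
    "not_pathogenic",  # missense, Provean-neutral, in 3 normals
    "not_pathogenic",  # frameshift indel but in 10 normals (> 6)
    "not_pathogenic"   # not seen anywhere
  ))
})

test_that("filter sensitivity and artefact removal meet the calibrated targets", {
  ch <- simulate_cohort(cohort_config(n_tumours = 300, seed = 42))
  out <- run_cohort_filters(ch)
  tr <- dplyr::left_join(out, ch$truth$mutations, by = "mut_id")
  sens <- mean(tr$filter_status[!tr$is_artefact] == "pass")
  removal <- mean(tr$filter_status[tr$is_artefact] == "removed")
  expect_gte(sens, 0.95)
  expect_gte(removal, 0.95)
})
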