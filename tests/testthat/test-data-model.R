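test_that("mutation table round-trips through the TSV dialect", {
  fx <- filter_fixture()
  calls <- validate_mutations(fx$calls)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mutations(calls, path)
  back <- read_mutations(path)
  expect_equal(as.data.frame(back[, names(back)]),
               as.data.frame(calls[, names(back)]))

  # empty table with a valid header
  write_mutations(calls[0, ], path)
  expect_equal(nrow(read_mutations(path)), 0)
})

test_that("mutation readers reject malformed input", {
  fx <- filter_fixture()
  calls <- fx$calls
  path <- withr::local_tempfile(fileext = ".tsv")

  # missing required column named in the error
  bad <- dplyr::rename(calls, class = variant_class)
  readr::write_tsv(dplyr::select(bad, -pos), path)
  expect_error(read_mutations(path), "pos",
               class = "mutlandscape_format_error")

  # alt count exceeding depth is impossible by construction (depth is the
  # sum), but negative counts and unknown categories must be rejected
  bad <- calls
  bad$alt_fwd[1] <- -1L
  expect_error(validate_mutations(bad),
               class = "mutlandscape_validation_error")
  bad <- calls
  bad$consequence[1] <- "stop_gain"
  expect_error(validate_mutations(bad),
               class = "mutlandscape_validation_error")
  bad <- calls
  bad$variant_class[1] <- "SNP"
  expect_error(validate_mutations(bad),
               class = "mutlandscape_validation_error")

  # audit invariant: removal reasons exactly when removed
  bad <- validate_mutations(calls)
  bad$filter_status[1] <- "removed"
  expect_error(validate_mutations(bad),
               class = "mutlandscape_validation_error")
})

test_that("VCF dialect maps onto the same variant records", {
  vcf_lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"sample\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"gene\">",
    "##INFO=<ID=VC,Number=1,Type=String,Description=\"class\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"consequence\">",
    "##INFO=<ID=CODON,Number=1,Type=Integer,Description=\"codon\">",
    "##INFO=<ID=ALTF,Number=1,Type=Integer,Description=\"alt fwd\">",
    "##INFO=<ID=ALTR,Number=1,Type=Integer,Description=\"alt rev\">",
    "##INFO=<ID=REFF,Number=1,Type=Integer,Description=\"ref fwd\">",
    "##INFO=<ID=REFR,Number=1,Type=Integer,Description=\"ref rev\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    paste0("chr1\t12345\t.\tA\tG\t88.2\t.\t",
           "SAMPLE=S01;GENE=PIK3CA;VC=SNV;CSQ=missense;CODON=545;",
           "ALTF=20;ALTR=18;REFF=55;REFR=57")
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_lines, path)
  x <- read_mutations(path, dialect = "vcf")
  expect_equal(nrow(x), 1)
  expect_equal(x$sample, "S01")
  expect_equal(x$gene, "PIK3CA")
  expect_equal(x$pos, 12345)
  expect_equal(x$codon, 545L)
  expect_equal(x$depth, 150L)
  expect_equal(x$vaf, 38 / 150)
  expect_equal(x$quality, 88.2)
})

test_that("segment and purity tables validate and round-trip", {
  segs <- tibble::tibble(sample = "T1", chrom = "chr1", start = 1,
                         end = 1000, n_major = 1L, n_minor = 1L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_segments(segs, path)
  expect_equal(as.data.frame(read_segments(path)), as.data.frame(segs))

  overlapping <- dplyr::bind_rows(
    segs, tibble::tibble(sample = "T1", chrom = "chr1", start = 900,
                         end = 2000, n_major = 2L, n_minor = 0L)
  )
  expect_error(validate_segments(overlapping),
               class = "mutlandscape_validation_error")
  # abutting segments under the half-open convention do not overlap
  abutting <- dplyr::bind_rows(
    segs, tibble::tibble(sample = "T1", chrom = "chr1", start = 1001,
                         end = 2000, n_major = 2L, n_minor = 0L)
  )
  expect_silent(validate_segments(abutting))

  bad <- segs
  bad$n_minor <- 2L
  expect_error(validate_segments(bad),
               class = "mutlandscape_validation_error")

  pur <- tibble::tibble(sample = "T1", purity = 0.7, ploidy = 2.1)
  write_purity(pur, path)
  expect_equal(as.data.frame(read_purity(path)), as.data.frame(pur))
  expect_error(validate_purity(dplyr::mutate(pur, purity = 1.2)),
               class = "mutlandscape_validation_error")
  expect_error(validate_purity(dplyr::mutate(pur, purity = 0)),
               class = "mutlandscape_validation_error")
})

test_that("clinical table validates and round-trips", {
  clin <- fx_clinical(25)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clinical(clin, path)
  expect_equal(as.data.frame(read_clinical(path)), as.data.frame(clin))
  expect_error(validate_clinical(dplyr::mutate(clin, followup_months = -1)),
               class = "mutlandscape_validation_error")
  expect_error(validate_clinical(dplyr::mutate(clin, grade = 4L)),
               class = "mutlandscape_validation_error")
  expect_error(
    validate_clinical(dplyr::mutate(clin, death_cause = "cardiac")),
    class = "mutlandscape_validation_error"
  )
})

test_that("receptor assignment recovers well-separated components and is deterministic", {
  set.seed(101)
  n <- 200
  truth <- rep(c("neg", "pos"), each = n / 2)
  d <- tibble::tibble(
    sample = sprintf("S%03d", seq_len(n)),
    expression = c(rnorm(n / 2, -2, 0.5), rnorm(n / 2, 2, 0.5)),
    ihc = NA_character_
  )
  out <- assign_receptor_status(d)
  expect_gte(mean(out$final_call == truth), 0.99)
  out2 <- assign_receptor_status(d)
  expect_identical(out$final_call, out2$final_call)
})

test_that("mixture recovery holds at 6-sd separation with n = 500", {
  set.seed(202)
  n <- 500
  truth <- rep(c("neg", "pos"), times = c(300, 200))
  d <- tibble::tibble(
    sample = sprintf("S%03d", seq_len(n)),
    expression = c(rnorm(300, 0, 1), rnorm(200, 6, 1)),
    ihc = NA_character_
  )
  out <- assign_receptor_status(d)
  expect_gte(mean(out$final_call == truth), 0.99)
})

test_that("the 5x posterior rule arbitrates IHC/expression disagreement", {
  # engineered posteriors: place one IHC-pos sample deep inside the negative
  # component (ratio >> 5: overridden) and one near the boundary (retained)
  set.seed(303)
  d <- tibble::tibble(
    sample = sprintf("S%03d", 1:102),
    expression = c(rnorm(50, -2, 0.5), rnorm(50, 2, 0.5), -2, 0),
    ihc = c(rep(NA_character_, 100), "pos", "pos")
  )
  out <- assign_receptor_status(d)
  deep <- out[out$sample == "S101", ]
  boundary <- out[out$sample == "S102", ]
  expect_gte(deep$posterior_neg / deep$posterior_pos, 5)
  expect_equal(deep$final_call, "neg")
  # the boundary sample's ratio must be below 5 for the complement case
  expect_lt(boundary$posterior_neg / boundary$posterior_pos, 5)
  expect_equal(boundary$final_call, "pos")
})

test_that("degenerate receptor inputs are rejected", {
  d <- tibble::tibble(sample = sprintf("S%02d", 1:30),
                      expression = rep(1.5, 30), ihc = NA_character_)
  expect_error(assign_receptor_status(d),
               class = "mutlandscape_degenerate_error")
  expect_error(assign_receptor_status(d[1:10, ]),
               class = "mutlandscape_validation_error")
})

test_that("coverage QC applies the strict 25% rule", {
  d <- tibble::tibble(sample = c("A", "B", "C"),
                      coverage_fraction = c(0.24, 0.25, 1.0))
  out <- sample_qc(d)
  expect_equal(out$include, c(FALSE, TRUE, TRUE))
  expect_error(
    sample_qc(tibble::tibble(sample = "A", coverage_fraction = 1.2)),
    class = "mutlandscape_validation_error"
  )
})
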