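test_that("CCF estimation reproduces the arithmetic worked examples", {
  out <- estimate_ccf(tibble::tibble(
    alt_count = 50, depth = 100, purity = 1, cn_tum = 2
  ))
  expect_equal(out$ccf, 1)        # 0.5 x 2 / 1, capped at 1

  # vaf = 0.25 exactly, purity 0.5, cn 2: CCF = 0.25 * 3 / 0.5 -> capped 1
  out <- estimate_ccf(tibble::tibble(
    alt_count = 25, depth = 100, purity = 0.5, cn_tum = 2
  ))
  expect_equal(out$ccf, 1)

  # vaf 0.2, purity 0.8, cn 4: CCF = 0.2 * (3.2 + 0.4) / 0.8 = 0.9
  out <- estimate_ccf(tibble::tibble(
    alt_count = 20, depth = 100, purity = 0.8, cn_tum = 4
  ))
  expect_equal(out$ccf, 0.9)

  expect_error(
    estimate_ccf(tibble::tibble(alt_count = 5, depth = 10, purity = 0.5,
                                cn_tum = 0)),
    class = "mutlandscape_validation_error"
  )
})

wilson_interval_ref <- function(x, n) {
  # independent route: prop.test without continuity correction
  as.numeric(suppressWarnings(
    stats::prop.test(x, n, correct = FALSE)$conf.int
  ))
}

test_that("the Wilson interval matches the standard score interval", {
  set.seed(64)
  for (i in 1:25) {
    n <- sample(10:500, 1)
    x <- sample(0:n, 1)
    w <- wilson_interval_ref(x, n)
    got <- mutlandscape:::wilson_interval(x, n)
    expect_equal(c(got$lower, got$upper), w, tolerance = 1e-9)
  }
})

test_that("clonality labels follow the CI-reaches-1 rule", {
  expect_equal(label_clonality(0.53, 0.88), "subclonal")
  expect_equal(label_clonality(0.39, 1.0), "clonal")
  expect_equal(label_clonality(1, 1), "clonal")
  expect_error(label_clonality(0.9, 0.5),
               class = "mutlandscape_validation_error")
})

test_that("CCF point estimates recover truth at high depth", {
  # depth 1000, purity 0.7, cn 2; 200 mutations per true CCF level.
  # The recovery criterion is on the error of the mean estimate: the
  # per-mutation absolute deviation has a binomial noise floor (~0.033 at
  # CCF 0.8) that no unbiased estimator can beat.
  set.seed(55)
  for (ccf in seq(0.2, 1, by = 0.2)) {
    ev <- expected_vaf(ccf, 0.7, 2, 1)
    alt <- rbinom(200, 1000, ev)
    out <- estimate_ccf(tibble::tibble(
      alt_count = alt, depth = 1000, purity = 0.7, cn_tum = 2
    ))
    expect_lt(abs(mean(out$ccf - ccf)), 0.03)
  }
})

test_that("clonality operating characteristics hold at depth 150", {
  set.seed(56)
  # true CCF 1: at most ~5% called subclonal (95% CI construction)
  ev <- expected_vaf(1, 0.7, 2, 1)
  alt <- rbinom(400, 150, ev)
  out <- estimate_ccf(tibble::tibble(
    alt_count = alt, depth = 150, purity = 0.7, cn_tum = 2
  ))
  expect_lte(mean(out$clonality == "subclonal"), 0.05)
  # true CCF 0.4: mostly subclonal
  ev <- expected_vaf(0.4, 0.7, 2, 1)
  alt <- rbinom(400, 150, ev)
  out <- estimate_ccf(tibble::tibble(
    alt_count = alt, depth = 150, purity = 0.7, cn_tum = 2
  ))
  expect_gte(mean(out$clonality == "subclonal"), 0.80)
})

test_that("MATH score matches the worked example and its edge rules", {
  expect_equal(math_score(rep(0.3, 5)), 0)
  expect_equal(math_score(c(0.1, 0.2, 0.3, 0.4, 0.5)), 0.4942)
  expect_true(is.na(math_score(c(0.1, 0.2, 0.3, 0.4))))  # fewer than five
  expect_error(math_score(rep(0, 6)),
               class = "mutlandscape_validation_error")
  # scale invariance
  set.seed(90)
  for (i in 1:10) {
    v <- runif(sample(5:30, 1), 0.05, 0.5)
    k <- runif(1, 0.1, 2)
    expect_equal(math_score(pmin(1, k * v)), math_score(v),
                 tolerance = 1e-12)
  }
  # the x100 convention is a pure rescaling
  expect_equal(math_score(c(0.1, 0.2, 0.3, 0.4, 0.5), times_100 = TRUE),
               49.42)
})

test_that("gene-level CNA calls use the longest-overlap segment", {
  coords <- tibble::tibble(gene = c("A", "B", "C"), chrom = "chr1",
                           start = c(100, 5000, 99000),
                           end = c(200, 5100, 99100))
  segs <- tibble::tibble(
    sample = "T1", chrom = "chr1",
    start = c(1, 1000, 90000), end = c(999, 89999, 95000),
    n_major = c(4L, 2L, 2L), n_minor = c(2L, 0L, 2L)
  )
  out <- gene_cna_calls(segs, coords)
  a <- out[out$gene == "A", ]
  expect_true(a$amplification)           # total 6 >= 5
  b <- out[out$gene == "B", ]
  expect_true(b$loh)                     # (2, 0)
  expect_false(b$amplification)
  cc <- out[out$gene == "C", ]
  expect_false(cc$covered)               # no covering segment: absent call

  hd <- gene_cna_calls(
    tibble::tibble(sample = "T1", chrom = "chr1", start = 1, end = 999,
                   n_major = 0L, n_minor = 0L),
    coords[1, ]
  )
  expect_true(hd$homozygous_deletion)
  expect_false(hd$loh)                   # HD is not LOH (total must be >= 1)
})

test_that("CIN score applies the asymmetric log-ratio thresholds", {
  pur <- tibble::tibble(sample = "T1", purity = 0.7, ploidy = 2)
  # all segments at the ploidy: zero
  segs <- tibble::tibble(sample = "T1", chrom = c("chr1", "chr2"),
                         start = 1, end = 1000,
                         n_major = 1L, n_minor = 1L)
  expect_equal(cin_score(segs, pur)$cin, 0)

  # half the covered genome at twice the ploidy: 0.5
  segs <- tibble::tibble(sample = "T1", chrom = c("chr1", "chr2"),
                         start = 1, end = 1000,
                         n_major = c(1L, 3L), n_minor = c(1L, 1L))
  expect_equal(cin_score(segs, pur)$cin, 0.5)

  # log2 ratio just below the gain threshold is not counted:
  # total 5 at ploidy 3.8 gives log2(5/3.8) = 0.396
  pur2 <- tibble::tibble(sample = "T1", purity = 0.7, ploidy = 3.8)
  segs <- tibble::tibble(sample = "T1", chrom = "chr1", start = 1,
                         end = 1000, n_major = 3L, n_minor = 2L)
  expect_equal(cin_score(segs, pur2)$cin, 0)

  # total copies 0 always falls in the loss class
  segs <- tibble::tibble(sample = "T1", chrom = "chr1", start = 1,
                         end = 1000, n_major = 0L, n_minor = 0L)
  expect_equal(cin_score(segs, pur)$cin, 1)

  # adding a neutral segment never increases the score
  segs <- tibble::tibble(sample = "T1", chrom = c("chr1", "chr2"),
                         start = 1, end = 1000,
                         n_major = c(3L, 1L), n_minor = c(1L, 1L))
  with_neutral <- dplyr::bind_rows(
    segs, tibble::tibble(sample = "T1", chrom = "chr3", start = 1,
                         end = 1000, n_major = 1L, n_minor = 1L)
  )
  expect_lte(cin_score(with_neutral, pur)$cin, cin_score(segs, pur)$cin)
})

test_that("copy-number annotation joins the covering segment", {
  segs <- tibble::tibble(
    sample = c("T1", "T1"), chrom = "chr1",
    start = c(1, 1000), end = c(999, 2000),
    n_major = c(1L, 3L), n_minor = c(1L, 2L)
  )
  muts <- tibble::tibble(sample = "T1", chrom = "chr1",
                         pos = c(500, 1500, 5000))
  out <- annotate_copy_number(muts, segs)
  expect_equal(out$cn_tum, c(2L, 5L, NA_integer_))
})
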