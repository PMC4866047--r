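test_that("fisher_exact_2x2 matches hand cases and handles zeros", {
  r <- fisher_exact_2x2(5, 5, 5, 5)
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p_value, 1)
  expect_error(fisher_exact_2x2(0, 0, 0, 0),
               class = "mutlandscape_validation_error")
  expect_error(fisher_exact_2x2(-1, 2, 3, 4),
               class = "mutlandscape_validation_error")
  expect_equal(fisher_exact_2x2(0, 5, 5, 5)$odds_ratio, 0)
  expect_equal(fisher_exact_2x2(5, 0, 0, 5)$odds_ratio, Inf)
})

test_that("fisher_exact_2x2 equals the enumeration oracle on random tables", {
  set.seed(24)
  for (i in 1:50) {
    cells <- as.integer(rmultinom(1, sample(1:25, 1), rep(1 / 4, 4)))
    if (sum(cells) == 0) cells[1] <- 1L
    expect_equal(
      fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])$p_value,
      fisher_p_enumerated(cells[1], cells[2], cells[3], cells[4]),
      tolerance = 1e-9
    )
  }
})

test_that("bh_fdr performs the step-up adjustment", {
  expect_equal(bh_fdr(0.01), 0.01)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "mutlandscape_validation_error")
  # order invariance and q >= p
  set.seed(77)
  p <- runif(60)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  perm <- sample(60)
  expect_equal(bh_fdr(p[perm]), q[perm])
})

test_that("pairwise screen flags engineered exclusivity and respects the floor", {
  set.seed(100)
  n <- 2000
  x <- c(rep(TRUE, 300), rep(FALSE, n - 300))
  y <- c(rep(FALSE, 300), rep(TRUE, 300), rep(FALSE, n - 600))
  fm <- tibble::tibble(
    sample = sprintf("S%04d", 1:n),
    X = x, Y = y,
    RARE = c(rep(TRUE, 8), rep(FALSE, n - 8)),        # 0.4%: below floor
    Z = runif(n) < 0.1
  )
  out <- pairwise_comutation(fm)
  xy <- dplyr::filter(out, gene_a == "X", gene_b == "Y")
  expect_equal(xy$direction, "mutual_exclusivity")
  expect_true(xy$significant)
  expect_false(any(out$gene_a == "RARE" | out$gene_b == "RARE"))
  # symmetry: permuting columns gives the same pair set
  out2 <- pairwise_comutation(fm[, c("sample", "Z", "Y", "X", "RARE")])
  expect_equal(dplyr::arrange(out, gene_a, gene_b)[, c("gene_a", "gene_b", "p_value")],
               dplyr::arrange(out2, gene_a, gene_b)[, c("gene_a", "gene_b", "p_value")])
  # fewer than two eligible genes: empty result
  expect_equal(nrow(pairwise_comutation(fm[, c("sample", "RARE")])), 0)
})

test_that("mutation-CNA screen applies the effect-size floor", {
  set.seed(101)
  n <- 2000
  del <- runif(n) < 0.3
  mut <- ifelse(del, runif(n) < 0.25, runif(n) < 0.09)  # OR ~ 3.4
  fm <- tibble::tibble(sample = sprintf("S%04d", 1:n), TSG = mut)
  cna <- tibble::tibble(sample = sprintf("S%04d", 1:n), DEL_8p = del)
  out <- mutation_cna_association(fm, cna)
  expect_equal(out$direction, "co_occurrence")
  expect_true(out$significant)

  # a strong p-value with |log OR| < log 2 is suppressed
  base <- runif(n) < 0.4
  weak <- ifelse(base, runif(n) < 0.46, runif(n) < 0.40)  # OR ~ 1.28
  fm2 <- tibble::tibble(sample = fm$sample, G = weak)
  cna2 <- tibble::tibble(sample = fm$sample, R = base)
  out2 <- mutation_cna_association(fm2, cna2)
  if (abs(out2$log_odds) < log(2)) expect_false(out2$significant)

  empty <- mutation_cna_association(fm, cna[, "sample", drop = FALSE])
  expect_equal(nrow(empty), 0)
})

test_that("clinical screen and logistic model detect an engineered grade effect", {
  set.seed(102)
  n <- 2000
  clin <- fx_clinical(n, seed = 102)
  grade3 <- clin$grade == 3
  p_mut <- ifelse(grade3, 0.24, 0.1)  # OR ~ 2.9 for grade 3
  fm <- tibble::tibble(sample = clin$sample, GENE = runif(n) < p_mut,
                       NULLGENE = runif(n) < 0.1)
  out <- clinical_association_screen(fm, clin)
  hit <- dplyr::filter(out, gene == "GENE", variable == "grade")
  expect_true(hit$significant)

  lg <- clinical_logistic(fm, clin, "GENE")
  g3 <- dplyr::filter(lg, term == "grade3TRUE")
  expect_gt(g3$odds_ratio, 1.5)
  expect_true(g3$ci_lower < 2.9 && 2.9 < g3$ci_upper)

  # constant covariate: flagged degenerate, not a crash
  clin2 <- dplyr::mutate(clin, grade = 2L)
  lg2 <- clinical_logistic(fm, clin2, "GENE")
  expect_true(all(lg2$flagged))
})

test_that("IntClust enrichment detects an engineered cluster signal", {
  set.seed(103)
  n <- 2000
  labels <- tibble::tibble(
    sample = sprintf("S%04d", 1:n),
    intclust = sample(c("1", "2", "3", "4+", "5"), n, replace = TRUE)
  )
  in2 <- labels$intclust == "2"
  fm <- tibble::tibble(
    sample = labels$sample,
    HOT = ifelse(in2, runif(n) < 0.2, runif(n) < 0.02),
    FLAT = runif(n) < 0.05
  )
  out <- intclust_enrichment(fm, labels)
  hit <- dplyr::filter(out, gene == "HOT", intclust == "2")
  expect_true(hit$significant)
  expect_equal(hit$direction, "enriched")

  # single-cluster cohort: empty result
  one <- dplyr::mutate(labels, intclust = "1")
  expect_equal(nrow(intclust_enrichment(fm, one)), 0)
})

test_that("concordance arithmetic matches the definition", {
  expect_equal(confusion_concordance(10, 10, 0, 0), 100)
  expect_equal(confusion_concordance(0, 0, 5, 5), 0)
  expect_error(confusion_concordance(0, 0, 0, 0),
               class = "mutlandscape_validation_error")
})

test_that("false discoveries under a global null stay at the nominal rate", {
  # independent Bernoulli mutation matrix: every pairwise discovery is false
  set.seed(104)
  fdp <- replicate(30, {
    n <- 300
    fm <- tibble::tibble(sample = sprintf("S%03d", 1:n))
    for (g in sprintf("G%02d", 1:12)) fm[[g]] <- runif(n) < 0.15
    out <- pairwise_comutation(fm, fdr = 0.1)
    if (nrow(out) == 0) 0 else sum(out$significant) / max(1, sum(out$significant))
  })
  # mean proportion of replicates with any (false) discovery must be small
  expect_lte(mean(fdp), 2 * 0.1)
})
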