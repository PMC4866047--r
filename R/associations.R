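#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional exact two-sided p-value (the sum of probabilities of all
#' tables, with the observed margins, no more likely than the observed one)
#' together with the sample odds ratio `(a*d)/(b*c)` (0 or `Inf` when a
#' margin cell is empty).
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise:
#'   \[\[a, b\], \[c, d\]\].
#' @return A tibble with columns `odds_ratio`, `log_odds` and `p_value`.
#' @examples
#' fisher_exact_2x2(13, 40, 1, 21)$p_value  # 0.05331
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop_validation("cell counts must be non-negative integers")
  }
  if (sum(cells) == 0) stop_validation("all four cells are zero")
  p <- fisher.test(matrix(cells, nrow = 2, byrow = TRUE))$p.value
  or <- sample_odds_ratio(a, b, c, d)
  tibble(odds_ratio = or, log_odds = log(or), p_value = p)
}

sample_odds_ratio <- function(a, b, c, d) {
  if (b == 0 || c == 0) {
    if (a == 0 || d == 0) return(NaN) # degenerate: a zero margin
    return(Inf)
  }
  (a * d) / (b * c)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; a thin, named wrapper around the standard
#' procedure so every screen in the package adjusts identically.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop_validation("p-values must be in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

# run Fisher tests over a tibble of (a, b, c, d) rows and attach q-values
screen_fisher <- function(tab) {
  if (nrow(tab) == 0) {
    return(mutate(tab, odds_ratio = double(0), log_odds = double(0),
                  p_value = double(0), q_value = double(0),
                  direction = character(0)))
  }
  res <- purrr::pmap_dfr(tab[, c("a", "b", "c", "d")], fisher_exact_2x2)
  tab <- bind_cols(tab, res)
  tab$q_value <- bh_fdr(tab$p_value)
  tab$direction <- if_else(tab$odds_ratio < 1,
                           "mutual_exclusivity", "co_occurrence")
  tab
}

#' Pairwise co-mutation / mutual-exclusivity screen
#'
#' Tests every pair of genes mutated in at least `min_mutant_fraction` of
#' the cohort with a two-sided Fisher exact test on the 2x2 carrier table,
#' adjusts across all tested pairs by Benjamini-Hochberg, and labels each
#' pair `co_occurrence` (odds ratio > 1) or `mutual_exclusivity` (odds
#' ratio < 1).
#'
#' @param functional Wide logical tibble (`sample` column plus one logical
#'   column per gene), e.g. from [functional_mutation_matrix()].
#' @param min_mutant_fraction Frequency floor for a gene to enter the screen
#'   (default 0.005).
#' @param fdr FDR level defining the `significant` flag (default 0.1).
#' @return Tibble with one row per tested pair: `gene_a`, `gene_b`, the 2x2
#'   counts `a`, `b`, `c`, `d` (a = both mutated), `odds_ratio`, `log_odds`,
#'   `p_value`, `q_value`, `direction`, `significant`. Fewer than two
#'   eligible genes yields an empty result.
#' @export
pairwise_comutation <- function(functional, min_mutant_fraction = 0.005,
                                fdr = 0.1) {
  mat <- as.matrix(functional[, setdiff(names(functional), "sample"),
                              drop = FALSE])
  storage.mode(mat) <- "logical"
  n <- nrow(mat)
  eligible <- colnames(mat)[colMeans(mat) >= min_mutant_fraction]
  empty <- tibble(gene_a = character(0), gene_b = character(0),
                  a = integer(0), b = integer(0), c = integer(0),
                  d = integer(0), odds_ratio = double(0),
                  log_odds = double(0), p_value = double(0),
                  q_value = double(0), direction = character(0),
                  significant = logical(0))
  if (length(eligible) < 2) return(empty)
  pairs <- utils::combn(sort(eligible), 2)
  tab <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    x <- mat[, pairs[1, k]]
    y <- mat[, pairs[2, k]]
    tibble(
      gene_a = pairs[1, k], gene_b = pairs[2, k],
      a = sum(x & y), b = sum(x & !y), c = sum(!x & y), d = sum(!x & !y)
    )
  })
  tab <- screen_fisher(tab)
  tab$significant <- tab$q_value <= fdr
  tab
}

#' Mutation vs copy-number-region association screen
#'
#' Fisher screen of every driver gene against every recurrent-CNA region,
#' with Benjamini-Hochberg control and an absolute log-odds effect-size
#' floor: associations with `|log OR| < min_abs_log_odds` are never flagged
#' significant regardless of p-value.
#'
#' @param functional Wide logical mutation tibble (`sample` + gene columns).
#' @param cna_regions Wide logical tibble (`sample` + region columns) on the
#'   same samples.
#' @param fdr FDR level (default 0.01).
#' @param min_abs_log_odds Effect-size floor (default `log(2)`).
#' @return Tibble with one row per gene x region: counts, `odds_ratio`,
#'   `log_odds`, `p_value`, `q_value`, `direction`, `significant`.
#' @export
mutation_cna_association <- function(functional, cna_regions, fdr = 0.01,
                                     min_abs_log_odds = log(2)) {
  shared <- intersect(functional$sample, cna_regions$sample)
  genes <- setdiff(names(functional), "sample")
  regions <- setdiff(names(cna_regions), "sample")
  empty <- tibble(gene = character(0), region = character(0),
                  a = integer(0), b = integer(0), c = integer(0),
                  d = integer(0), odds_ratio = double(0),
                  log_odds = double(0), p_value = double(0),
                  q_value = double(0), direction = character(0),
                  significant = logical(0))
  if (length(genes) == 0 || length(regions) == 0 || length(shared) == 0) {
    return(empty)
  }
  f <- functional[match(shared, functional$sample), , drop = FALSE]
  r <- cna_regions[match(shared, cna_regions$sample), , drop = FALSE]
  tab <- tidyr::crossing(gene = genes, region = regions) |>
    mutate(purrr::map2_dfr(.data$gene, .data$region, function(g, rg) {
      x <- f[[g]]
      y <- r[[rg]]
      tibble(a = sum(x & y), b = sum(x & !y), c = sum(!x & y),
             d = sum(!x & !y))
    }))
  tab <- screen_fisher(tab)
  tab$significant <- tab$q_value <= fdr &
    is.finite(tab$log_odds) & abs(tab$log_odds) >= min_abs_log_odds
  tab
}

#' Chi-square screen of mutations against clinical variables
#'
#' For each gene and each categorical clinical variable, tests whether the
#' variable's distribution differs between mutant and wild-type samples
#' (chi-square test across categories), with Benjamini-Hochberg control
#' over all gene x variable tests. Variables are coded per the survival
#' scheme: age >= 55, size >= 50 mm, lymph-node positivity and grade as a
#' categorical.
#'
#' @param functional Wide logical mutation tibble.
#' @param clinical Clinical tibble (see [read_clinical()]).
#' @param fdr FDR level (default 0.05).
#' @return Tibble `gene`, `variable`, `p_value`, `q_value`, `significant`,
#'   `degenerate` (constant variable or constant gene; such rows carry `NA`
#'   p-values and are flagged rather than crashing).
#' @export
clinical_association_screen <- function(functional, clinical, fdr = 0.05) {
  clin <- clinical_codes(clinical)
  genes <- setdiff(names(functional), "sample")
  vars <- c("age_ge_55", "size_ge_50", "node_positive", "grade")
  joined <- left_join(functional, clin, by = "sample")
  tab <- tidyr::crossing(gene = genes, variable = vars) |>
    mutate(purrr::map2_dfr(.data$gene, .data$variable, function(g, v) {
      keep <- !is.na(joined[[v]])
      x <- factor(joined[[g]][keep], levels = c(FALSE, TRUE))
      y <- factor(joined[[v]][keep])
      if (nlevels(droplevels(x)) < 2 || nlevels(droplevels(y)) < 2) {
        return(tibble(p_value = NA_real_, degenerate = TRUE))
      }
      p <- suppressWarnings(chisq.test(table(x, y))$p.value)
      tibble(p_value = p, degenerate = FALSE)
    }))
  ok <- !is.na(tab$p_value)
  tab$q_value <- NA_real_
  tab$q_value[ok] <- bh_fdr(tab$p_value[ok])
  tab$significant <- !is.na(tab$q_value) & tab$q_value <= fdr
  tab
}

# covariate coding shared by the association and survival modules
clinical_codes <- function(clinical) {
  clinical <- as_tibble(clinical)
  tibble(
    sample = clinical$sample,
    age_ge_55 = clinical$age_years >= 55,
    size_ge_50 = clinical$size_mm >= 50,
    node_positive = clinical$lymph_node_positive,
    grade = clinical$grade,
    grade3 = clinical$grade == 3
  )
}

#' Logistic model of mutation presence on clinical covariates
#'
#' Maximum-likelihood logistic regression of a gene's mutation indicator on
#' the coded clinical covariates (age >= 55, size >= 50 mm, node status,
#' grade 3 vs 1-2), returning per-covariate odds ratios with Wald 95%
#' confidence intervals. Complete separation or non-convergence is flagged,
#' not fatal.
#'
#' @param functional Wide logical mutation tibble.
#' @param clinical Clinical tibble.
#' @param gene Gene column to model.
#' @return Tibble `term`, `odds_ratio`, `ci_lower`, `ci_upper`, `p_value`,
#'   `n`, `flagged` (plus a `note` for degenerate fits).
#' @export
clinical_logistic <- function(functional, clinical, gene) {
  if (!gene %in% names(functional)) {
    stop_validation(paste0("gene not in functional matrix: ", gene))
  }
  d <- functional |>
    select("sample", mut = dplyr::all_of(gene)) |>
    left_join(clinical_codes(clinical), by = "sample") |>
    filter(complete.cases(.data$mut, .data$age_ge_55, .data$size_ge_50,
                          .data$node_positive, .data$grade3))
  flag_row <- function(note) {
    tibble(term = NA_character_, odds_ratio = NA_real_,
           ci_lower = NA_real_, ci_upper = NA_real_, p_value = NA_real_,
           n = nrow(d), flagged = TRUE, note = note)
  }
  if (nrow(d) < 10 || length(unique(d$mut)) < 2) {
    return(flag_row("constant outcome or too few samples"))
  }
  const_cov <- vapply(d[, c("age_ge_55", "size_ge_50", "node_positive",
                            "grade3")], function(x) length(unique(x)) < 2,
                      logical(1))
  if (any(const_cov)) {
    return(flag_row(paste0("constant covariate: ",
                           paste(names(const_cov)[const_cov],
                                 collapse = ", "))))
  }
  fit <- suppressWarnings(
    glm(mut ~ age_ge_55 + size_ge_50 + node_positive + grade3,
        data = d, family = binomial())
  )
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  separation <- !fit$converged || any(abs(est[-1]) > 10)
  z <- est / se
  tibble(
    term = names(est),
    odds_ratio = exp(est),
    ci_lower = exp(est - 1.96 * se),
    ci_upper = exp(est + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(z)),
    n = nrow(d),
    flagged = separation,
    note = if_else(separation, "possible separation or non-convergence",
                   NA_character_)
  )
}

#' IntClust enrichment/depletion of driver mutations
#'
#' For each gene and each cluster, Fisher exact test of mutation prevalence
#' in the cluster against the rest of the cohort, Benjamini-Hochberg
#' adjusted across all gene x cluster tests, with the direction of the
#' deviation reported. Clusters with fewer than `min_cluster_size` samples
#' are excluded.
#'
#' @param functional Wide logical mutation tibble.
#' @param intclust Tibble `sample`, `intclust`; every sample must be
#'   labelled.
#' @param fdr FDR level (default 0.01).
#' @param min_cluster_size Minimum samples per cluster (default 2).
#' @return Tibble `gene`, `intclust`, counts, `odds_ratio`, `log_odds`,
#'   `p_value`, `q_value`, `direction` (`enriched`/`depleted`),
#'   `significant`. A single-cluster cohort yields an empty result.
#' @export
intclust_enrichment <- function(functional, intclust, fdr = 0.01,
                                min_cluster_size = 2) {
  intclust <- as_tibble(intclust)
  if (any(is.na(intclust$intclust))) {
    stop_validation("every sample must carry an IntClust label")
  }
  joined <- inner_join(functional, intclust, by = "sample")
  sizes <- count(joined, .data$intclust)
  clusters <- sizes$intclust[sizes$n >= min_cluster_size]
  genes <- setdiff(names(functional), "sample")
  empty <- tibble(gene = character(0), intclust = character(0),
                  a = integer(0), b = integer(0), c = integer(0),
                  d = integer(0), odds_ratio = double(0),
                  log_odds = double(0), p_value = double(0),
                  q_value = double(0), direction = character(0),
                  significant = logical(0))
  if (length(clusters) < 2 || length(genes) == 0) return(empty)
  tab <- tidyr::crossing(gene = genes, intclust = clusters) |>
    mutate(purrr::map2_dfr(.data$gene, .data$intclust, function(g, cl) {
      inc <- joined$intclust == cl
      mut <- joined[[g]]
      tibble(a = sum(mut & inc), b = sum(mut & !inc),
             c = sum(!mut & inc), d = sum(!mut & !inc))
    }))
  tab <- screen_fisher(tab)
  tab$direction <- if_else(tab$odds_ratio > 1, "enriched", "depleted")
  tab$significant <- tab$q_value <= fdr
  tab
}

#' Concordance from a confusion table
#'
#' Percent agreement between two assays:
#' `100 * (both_negative + both_positive) / total`.
#'
#' @param both_negative,both_positive,only_ref,only_test Non-negative
#'   counts; the total must be positive.
#' @return Percent concordance (scalar).
#' @examples
#' confusion_concordance(988, 429, 40, 66)  # 93.04
#' @export
confusion_concordance <- function(both_negative, both_positive, only_ref,
                                  only_test) {
  cells <- c(both_negative, both_positive, only_ref, only_test)
  if (any(cells < 0)) stop_validation("counts must be non-negative")
  total <- sum(cells)
  if (total == 0) stop_validation("zero total; concordance undefined")
  100 * (both_negative + both_positive) / total
}
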