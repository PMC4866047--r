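#' Construct the breast-cancer-specific survival endpoint
#'
#' BCSS: the event is death from breast cancer; deaths from other or unknown
#' causes are censored at the date of death, and everyone else is censored
#' at last contact. Covariates are coded per the minimum-common-data scheme:
#' age >= 55 years, tumour size >= 50 mm, lymph-node positivity, and grade 3
#' versus 1-2 (grade kept as a categorical too).
#'
#' @param clinical Clinical tibble (see [read_clinical()]); rows with
#'   missing follow-up are dropped.
#' @return Tibble `sample`, `time_months`, `event` (1 = breast-cancer
#'   death), plus coded covariates `age_ge_55`, `size_ge_50`,
#'   `node_positive`, `grade`, `grade3`.
#' @export
prepare_bcss <- function(clinical) {
  clinical <- validate_clinical(clinical)
  clinical <- filter(clinical, !is.na(.data$followup_months))
  if (any(clinical$followup_months < 0)) {
    stop_validation("negative follow-up time")
  }
  codes <- clinical_codes(clinical)
  tibble(
    sample = clinical$sample,
    time_months = clinical$followup_months,
    event = as.integer(clinical$death_cause == "breast")
  ) |>
    left_join(codes, by = "sample")
}

#' Multivariable Cox model for a driver-gene mutation
#'
#' Cox proportional-hazards model of BCSS on the mutation indicator with the
#' standard covariates (age >= 55, grade 3 vs 1-2 by default, size >= 50 mm,
#' node status), Efron tie handling, Wald confidence interval and p-value.
#' Complete-case analysis; degenerate inputs (constant indicator, too few
#' events) raise a validation error, while non-convergence or a monotone
#' likelihood is returned flagged with diagnostics rather than thrown.
#'
#' @param records Output of [prepare_bcss()].
#' @param mutation Tibble `sample`, `mutated` (logical), or the name of a
#'   logical column already present in `records`.
#' @param covariates Covariate columns to adjust for (default the coded
#'   four; `grade` may replace `grade3` for three-level coding).
#' @param min_events Minimum number of observed events (default 10).
#' @param ties Tie-handling method passed to the Cox fit (default
#'   `"efron"`).
#' @return An object of class `driver_cox`: a list with `terms` (tibble of
#'   per-term hazard ratios, Wald CIs and p-values), `n`, `n_events`,
#'   `flagged`, `note`, `model_type` and the underlying `fit`. Use `tidy()`
#'   / `glance()` for tabular access.
#' @export
cox_multivariable <- function(records, mutation,
                              covariates = c("age_ge_55", "grade3",
                                             "size_ge_50", "node_positive"),
                              min_events = 10, ties = "efron") {
  d <- join_mutation(records, mutation)
  d <- d[complete.cases(d[, c("time_months", "event", "mutated",
                              covariates)]), , drop = FALSE]
  if (sum(d$event) < min_events) {
    stop_validation(paste0("fewer than ", min_events, " events"))
  }
  if (length(unique(d$mutated)) < 2) {
    stop_validation("mutation indicator is constant")
  }
  fml <- as.formula(paste("survival::Surv(time_months, event) ~ mutated +",
                          paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = d, ties = ties)
  new_driver_cox(fit, d, model_type = "multivariable")
}

#' Per-cluster interaction Cox model
#'
#' A single Cox model with terms mutation, cluster membership and their
#' interaction, reporting (i) the hazard ratio of the mutation outside the
#' cluster, (ii) the hazard ratio of membership among wild-type tumours,
#' (iii) the hazard ratio of mutated-and-member tumours versus neither, and
#' the Wald p-value of the interaction term — the design used to ask
#' whether a mutation's prognostic effect is specific to a molecular
#' subtype.
#'
#' @param records Output of [prepare_bcss()].
#' @param mutation Tibble `sample`, `mutated` or a column name in `records`.
#' @param membership Tibble `sample`, `member` (logical) or a column name.
#' @param min_stratum Minimum mutant and wild-type samples inside the
#'   cluster (default 5); smaller strata return a flagged, unfitted result.
#' @param ties Tie handling (default `"efron"`).
#' @return A `driver_cox` object (`model_type = "interaction"`) whose
#'   `terms` tibble has rows `mutation_outside_cluster`,
#'   `membership_wildtype`, `mutation_and_membership` and `interaction`,
#'   with `interaction_p` also stored at the top level.
#' @export
intclust_interaction_model <- function(records, mutation, membership,
                                       min_stratum = 5, ties = "efron") {
  d <- join_mutation(records, mutation)
  d <- join_membership(d, membership)
  d <- d[complete.cases(d[, c("time_months", "event", "mutated",
                              "member")]), , drop = FALSE]
  n_mut_in <- sum(d$mutated & d$member)
  n_wt_in <- sum(!d$mutated & d$member)
  if (n_mut_in < min_stratum || n_wt_in < min_stratum) {
    return(structure(
      list(terms = tibble(term = character(0), hazard_ratio = double(0),
                          ci_lower = double(0), ci_upper = double(0),
                          p_value = double(0)),
           n = nrow(d), n_events = sum(d$event), flagged = TRUE,
           note = paste0("insufficient stratum counts (", n_mut_in,
                         " mutant, ", n_wt_in, " wild-type in cluster)"),
           interaction_p = NA_real_, model_type = "interaction",
           fit = NULL),
      class = "driver_cox"
    ))
  }
  fit <- survival::coxph(
    survival::Surv(time_months, event) ~ mutated * member,
    data = d, ties = ties
  )
  est <- coef(fit)
  V <- vcov(fit)
  # linear combinations: mutation|outside = b_mut; membership|wt = b_mem;
  # mutation-and-membership vs neither = b_mut + b_mem + b_int
  combo <- rbind(
    mutation_outside_cluster = c(1, 0, 0),
    membership_wildtype = c(0, 1, 0),
    mutation_and_membership = c(1, 1, 1),
    interaction = c(0, 0, 1)
  )
  lp <- drop(combo %*% est)
  se <- sqrt(diag(combo %*% V %*% t(combo)))
  terms <- tibble(
    term = rownames(combo),
    hazard_ratio = exp(lp),
    ci_lower = exp(lp - 1.96 * se),
    ci_upper = exp(lp + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(lp / se))
  )
  structure(
    list(terms = terms, n = nrow(d), n_events = sum(d$event),
         flagged = FALSE, note = NA_character_,
         interaction_p = terms$p_value[terms$term == "interaction"],
         model_type = "interaction", fit = fit),
    class = "driver_cox"
  )
}

#' Kaplan-Meier comparison of MATH-score quartiles
#'
#' Splits scored tumours at the lower and upper quartiles of the MATH
#' distribution, estimates Kaplan-Meier BCSS curves for the two extreme
#' groups and compares them with a log-rank test.
#'
#' @param records Output of [prepare_bcss()].
#' @param math_scores Tibble `sample`, `math` (`NA` scores are dropped).
#' @param min_samples Minimum scored samples (default 20).
#' @return A list of class `km_math`: `fit` (a `survfit` object for the two
#'   groups), `logrank_p`, `groups` (per-sample group assignment tibble) and
#'   `quartiles`.
#' @export
km_math_quartiles <- function(records, math_scores, min_samples = 20) {
  d <- inner_join(records, as_tibble(math_scores), by = "sample")
  d <- filter(d, !is.na(.data$math))
  if (nrow(d) < min_samples) {
    stop_validation(paste0("fewer than ", min_samples, " scored samples"))
  }
  qs <- quantile(d$math, c(0.25, 0.75))
  if (qs[1] == qs[2]) {
    stop_degenerate("MATH quartiles coincide; groups undefined")
  }
  d$group <- dplyr::case_when(
    d$math <= qs[1] ~ "lower_quartile",
    d$math >= qs[2] ~ "upper_quartile",
    TRUE ~ NA_character_
  )
  d <- filter(d, !is.na(.data$group))
  fit <- survival::survfit(
    survival::Surv(time_months, event) ~ group, data = d
  )
  lr <- survival::survdiff(
    survival::Surv(time_months, event) ~ group, data = d
  )
  p <- pchisq(lr$chisq, df = length(lr$n) - 1, lower.tail = FALSE)
  structure(
    list(fit = fit, logrank_p = unname(p),
         groups = select(d, "sample", "math", "group"),
         quartiles = qs),
    class = "km_math"
  )
}

# internal: driver_cox construction and input joining ------------------------

new_driver_cox <- function(fit, data, model_type) {
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  flagged <- !is.null(fit$info) || any(!is.finite(se)) ||
    any(abs(est) > 15)
  note <- if (any(abs(est) > 15)) {
    "possible monotone likelihood (extreme coefficient)"
  } else if (any(!is.finite(se))) {
    "non-finite standard error"
  } else {
    NA_character_
  }
  terms <- tibble(
    term = names(est),
    hazard_ratio = exp(est),
    ci_lower = exp(est - 1.96 * se),
    ci_upper = exp(est + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(est / se))
  )
  structure(
    list(terms = terms, n = nrow(data), n_events = sum(data$event),
         flagged = flagged, note = note, model_type = model_type,
         fit = fit),
    class = "driver_cox"
  )
}

join_mutation <- function(records, mutation) {
  records <- as_tibble(records)
  if (is.character(mutation) && length(mutation) == 1) {
    if (!mutation %in% names(records)) {
      stop_format(paste0("no column '", mutation, "' in records"))
    }
    records$mutated <- records[[mutation]]
    return(records)
  }
  mutation <- as_tibble(mutation)
  if (!all(c("sample", "mutated") %in% names(mutation))) {
    stop_format("mutation needs columns 'sample' and 'mutated'")
  }
  left_join(records, select(mutation, "sample", "mutated"), by = "sample")
}

join_membership <- function(records, membership) {
  if (is.character(membership) && length(membership) == 1) {
    if (!membership %in% names(records)) {
      stop_format(paste0("no column '", membership, "' in records"))
    }
    records$member <- records[[membership]]
    return(records)
  }
  membership <- as_tibble(membership)
  if (!all(c("sample", "member") %in% names(membership))) {
    stop_format("membership needs columns 'sample' and 'member'")
  }
  left_join(records, select(membership, "sample", "member"), by = "sample")
}

#' @export
print.driver_cox <- function(x, ...) {
  cat("<driver_cox> ", x$model_type, " model: ", x$n, " samples, ",
      x$n_events, " events", if (x$flagged) " [flagged]", "\n", sep = "")
  if (!is.na(x$note %||% NA)) cat("note: ", x$note, "\n", sep = "")
  print(x$terms)
  invisible(x)
}
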