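#' Categorise mutations as recurrent, inactivating or other
#'
#' Recurrent mutations are missense SNVs and in-frame substitutions hitting
#' a codon that at least `min_recurrent` mutations of the same gene hit
#' across the supplied cohort (indels are referenced by the first codon
#' affected, irrespective of length, so insertions of different sizes at one
#' codon class together). Inactivating mutations are nonsense, frameshift
#' and splice-site variants. Everything else with a coding/splice
#' consequence is `other`; silent and noncoding mutations get `NA` and do
#' not enter score denominators. The categories are disjoint by
#' construction.
#'
#' @param calls Mutation tibble (typically one ER stratum); must carry
#'   `gene`, `consequence` and `codon`.
#' @param min_recurrent Minimum number of same-codon events for recurrence
#'   (default 2).
#' @return `calls` with a `category` column.
#' @export
classify_mutation_category <- function(calls, min_recurrent = 2) {
  calls <- as_tibble(calls)
  missing <- setdiff(c("gene", "consequence", "codon"), names(calls))
  if (length(missing) > 0) {
    stop_format(paste0("mutation input is missing column(s): ",
                       paste(missing, collapse = ", ")))
  }
  if (nrow(calls) == 0) {
    calls$category <- character(0)
    return(calls)
  }
  eligible <- calls$consequence %in% recurrent_eligible_consequences
  if (any(eligible & is.na(calls$codon))) {
    stop_validation(
      "recurrent-eligible mutation without a codon index"
    )
  }
  codon_n <- calls |>
    filter(.data$consequence %in% recurrent_eligible_consequences) |>
    count(.data$gene, .data$codon, name = "n_at_codon")
  calls <- left_join(calls, codon_n, by = c("gene", "codon"))
  calls$category <- dplyr::case_when(
    calls$consequence %in% inactivating_consequences ~ "inactivating",
    calls$consequence %in% recurrent_eligible_consequences &
      calls$n_at_codon >= min_recurrent ~ "recurrent",
    calls$consequence %in% scoreable_consequences ~ "other",
    TRUE ~ NA_character_
  )
  select(calls, -"n_at_codon")
}

#' Ratiometric per-gene driver scores (20/20 rule)
#'
#' For each gene, the ONC score is the fraction of its mutations that are
#' recurrent and the TSG score the fraction that are inactivating, out of
#' all coding/splice mutations (silent and noncoding excluded). A gene is
#' classified:
#'
#' * `oncogene` — ONC score >= `onc_threshold`, TSG score <
#'   `tsg_secondary`, and at least `min_events` recurrent mutations;
#' * `tumour_suppressor` — TSG score >= `tsg_threshold` with at least
#'   `min_events` inactivating mutations, or ONC score >= `onc_threshold`
#'   with TSG score >= `tsg_secondary` (the TP53-like pattern of high ONC
#'   and high TSG scores) and at least `min_events` recurrent plus
#'   inactivating mutations;
#' * `none` otherwise.
#'
#' @param categorized Output of [classify_mutation_category()].
#' @param min_events Minimum recurrent or inactivating mutations for a
#'   driver call (default 5).
#' @param onc_threshold,tsg_threshold Score thresholds (default 0.2, the
#'   20/20 rule, inclusive).
#' @param tsg_secondary TSG score above which a high-ONC gene is classed a
#'   tumour suppressor rather than an oncogene (default 0.05).
#' @return A tibble with one row per gene: `gene`, `n_total`, `n_recurrent`,
#'   `n_inactivating`, `onc_score`, `tsg_score`, `driver_class`.
#' @export
compute_gene_scores <- function(categorized, min_events = 5,
                                onc_threshold = 0.2, tsg_threshold = 0.2,
                                tsg_secondary = 0.05) {
  categorized <- as_tibble(categorized)
  if (!"category" %in% names(categorized)) {
    stop_format("input must carry a 'category' column; run classify_mutation_category()")
  }
  scored <- filter(categorized, !is.na(.data$category))
  if (nrow(scored) == 0) {
    stop_validation("no scoreable (coding/splice) mutations to score")
  }
  scores <- scored |>
    group_by(.data$gene) |>
    summarise(
      n_total = dplyr::n(),
      n_recurrent = sum(.data$category == "recurrent"),
      n_inactivating = sum(.data$category == "inactivating"),
      .groups = "drop"
    ) |>
    mutate(
      onc_score = .data$n_recurrent / .data$n_total,
      tsg_score = .data$n_inactivating / .data$n_total,
      driver_class = dplyr::case_when(
        .data$tsg_score >= tsg_threshold &
          .data$n_inactivating >= min_events ~ "tumour_suppressor",
        .data$onc_score >= onc_threshold &
          .data$tsg_score >= tsg_secondary &
          .data$n_recurrent + .data$n_inactivating >= min_events ~
          "tumour_suppressor",
        .data$onc_score >= onc_threshold &
          .data$tsg_score < tsg_secondary &
          .data$n_recurrent >= min_events ~ "oncogene",
        TRUE ~ "none"
      )
    )
  scores
}

#' Identify Mut-driver genes per ER stratum
#'
#' Categorises mutations and computes ratiometric scores independently
#' within the ER+ and ER- strata (recurrence is counted within a stratum),
#' then calls a gene a Mut-driver if it qualifies in either stratum.
#'
#' @param mutations Mutation tibble (pass-filter calls).
#' @param er_status Tibble with columns `sample` and `er` (`"pos"` /
#'   `"neg"`); every mutated sample must be present.
#' @param ... Passed to [compute_gene_scores()] (thresholds, `min_events`)
#'   and [classify_mutation_category()] is always run with its default
#'   recurrence rule.
#' @return A tibble of class `driver_scores`: one row per (gene, stratum)
#'   with the score columns of [compute_gene_scores()] plus `stratum`,
#'   `qualifies` (driver in that stratum) and `driver_gene` (driver in
#'   either stratum).
#' @export
identify_mut_drivers <- function(mutations, er_status, ...) {
  mutations <- as_tibble(mutations)
  er_status <- as_tibble(er_status)
  if (!all(c("sample", "er") %in% names(er_status))) {
    stop_format("er_status needs columns 'sample' and 'er'")
  }
  if (nrow(mutations) == 0) {
    out <- tibble(gene = character(0), stratum = character(0),
                  n_total = integer(0), n_recurrent = integer(0),
                  n_inactivating = integer(0), onc_score = double(0),
                  tsg_score = double(0), driver_class = character(0),
                  qualifies = logical(0), driver_gene = logical(0))
    class(out) <- c("driver_scores", class(out))
    return(out)
  }
  unmatched <- setdiff(unique(mutations$sample), er_status$sample)
  if (length(unmatched) > 0) {
    stop_validation(paste0("samples without ER status: ",
                           paste(head(unmatched, 5), collapse = ", ")))
  }
  joined <- left_join(mutations, select(er_status, "sample", "er"),
                      by = "sample")
  strata <- list(`ER+` = "pos", `ER-` = "neg")
  out <- purrr::imap(strata, function(er_lab, stratum_name) {
    sub <- filter(joined, .data$er == er_lab)
    sub <- filter(sub, !is.na(.data$consequence))
    if (nrow(sub) == 0) return(NULL)
    cat <- classify_mutation_category(sub)
    if (all(is.na(cat$category))) return(NULL)
    compute_gene_scores(cat, ...) |>
      mutate(stratum = stratum_name, .after = "gene")
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    out <- tibble(gene = character(0), stratum = character(0),
                  n_total = integer(0), n_recurrent = integer(0),
                  n_inactivating = integer(0), onc_score = double(0),
                  tsg_score = double(0), driver_class = character(0))
  }
  out$qualifies <- out$driver_class != "none"
  driver_genes <- unique(out$gene[out$qualifies])
  out$driver_gene <- out$gene %in% driver_genes
  class(out) <- c("driver_scores", class(out))
  out
}

# resolve a single class per driver gene: tumour suppressor and oncogene
# calls in different strata mean both mutation classes are functional
resolve_driver_classes <- function(drivers, use_both = "TP53") {
  drivers |>
    filter(.data$driver_gene) |>
    group_by(.data$gene) |>
    summarise(
      classes = list(unique(.data$driver_class[.data$qualifies])),
      .groups = "drop"
    ) |>
    mutate(
      class = purrr::map_chr(.data$classes, function(cl) {
        if (length(cl) > 1) "both"
        else if (cl == "oncogene") "oncogene"
        else "tumour_suppressor"
      }),
      class = if_else(.data$gene %in% use_both, "both", .data$class)
    ) |>
    select("gene", "class")
}

#' Per-sample functional-mutation matrix
#'
#' A sample carries a functional mutation in a driver gene when it has a
#' recurrent mutation (oncogenes), an inactivating mutation (tumour
#' suppressors), or either (genes in `use_both`, by default TP53, whose high
#' ONC and TSG scores make both classes functional).
#'
#' @param mutations Pass-filter mutation tibble.
#' @param drivers A `driver_scores` result from [identify_mut_drivers()].
#' @param er_status Tibble `sample`, `er`; defines the sample universe and
#'   the stratum in which recurrence is assessed.
#' @param use_both Genes for which both mutation classes count (default
#'   `"TP53"`).
#' @param genes Optional subset of driver genes; requesting a gene that is
#'   not a driver is an error.
#' @return A wide logical tibble: one row per sample in `er_status`, one
#'   column per driver gene.
#' @export
functional_mutation_matrix <- function(mutations, drivers, er_status,
                                       use_both = "TP53", genes = NULL) {
  if (!inherits(drivers, "driver_scores")) {
    stop_format("drivers must come from identify_mut_drivers()")
  }
  classes <- resolve_driver_classes(drivers, use_both = use_both)
  if (!is.null(genes)) {
    missing <- setdiff(genes, classes$gene)
    if (length(missing) > 0) {
      stop_validation(paste0("not in the driver list: ",
                             paste(missing, collapse = ", ")))
    }
    classes <- filter(classes, .data$gene %in% genes)
  }
  samples <- unique(er_status$sample)
  base <- tibble(sample = samples)
  if (nrow(classes) == 0 || nrow(mutations) == 0) {
    for (g in classes$gene) base[[g]] <- FALSE
    return(base)
  }
  joined <- mutations |>
    filter(.data$gene %in% classes$gene) |>
    left_join(select(as_tibble(er_status), "sample", "er"), by = "sample")
  carriers <- joined |>
    dplyr::group_split(.data$er) |>
    purrr::map(classify_mutation_category) |>
    bind_rows() |>
    left_join(classes, by = "gene") |>
    filter(
      (.data$class %in% c("oncogene", "both") &
         .data$category %in% "recurrent") |
        (.data$class %in% c("tumour_suppressor", "both") &
           .data$category %in% "inactivating")
    ) |>
    distinct(.data$sample, .data$gene)
  for (g in classes$gene) {
    base[[g]] <- base$sample %in% carriers$sample[carriers$gene == g]
  }
  base
}

#' Per-sample pathway alteration matrix
#'
#' A tumour is pathway-altered when at least one member gene is affected by
#' a functional mutation or a qualifying copy-number aberration:
#' amplification for oncogenes; homozygous deletion, or LOH coinciding with
#' a mutation, for tumour suppressors.
#'
#' @param functional Wide functional-mutation tibble from
#'   [functional_mutation_matrix()].
#' @param cna_calls Gene-level CNA tibble from [gene_cna_calls()] (columns
#'   `sample`, `gene`, `amplification`, `homozygous_deletion`, `loh`).
#' @param pathway_map Tibble `gene`, `pathway` (a gene may map to several
#'   pathways or none).
#' @param drivers `driver_scores` used to resolve gene classes.
#' @param use_both As in [functional_mutation_matrix()].
#' @return A wide logical tibble: one row per sample, one column per
#'   pathway.
#' @export
pathway_alteration_matrix <- function(functional, cna_calls, pathway_map,
                                      drivers, use_both = "TP53") {
  classes <- resolve_driver_classes(drivers, use_both = use_both)
  long_func <- functional |>
    tidyr::pivot_longer(-"sample", names_to = "gene",
                        values_to = "func_mut")
  cna <- as_tibble(cna_calls)
  if (nrow(cna) == 0) {
    cna <- tibble(sample = character(0), gene = character(0),
                  amplification = logical(0),
                  homozygous_deletion = logical(0), loh = logical(0))
  }
  events <- long_func |>
    left_join(select(cna, "sample", "gene", "amplification",
                     "homozygous_deletion", "loh"),
              by = c("sample", "gene")) |>
    left_join(classes, by = "gene") |>
    mutate(
      across(c("amplification", "homozygous_deletion", "loh"),
             ~ tidyr::replace_na(.x, FALSE)),
      qual_cna = (
        .data$class %in% c("oncogene", "both") & .data$amplification
      ) | (
        .data$class %in% c("tumour_suppressor", "both") &
          (.data$homozygous_deletion | (.data$loh & .data$func_mut))
      ),
      altered = .data$func_mut | .data$qual_cna
    )
  out <- tibble(sample = unique(functional$sample))
  pathways <- unique(pathway_map$pathway)
  for (pw in pathways) {
    pw_genes <- pathway_map$gene[pathway_map$pathway == pw]
    hit <- events |>
      filter(.data$gene %in% pw_genes, .data$altered) |>
      pull("sample")
    out[[pw]] <- out$sample %in% hit
  }
  out
}
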