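#' Pipeline configuration
#'
#' Collects stage toggles, input paths (when stages consume pre-existing
#' tables instead of the simulator), all stage thresholds and the global
#' seed. Defaults reproduce the study's thresholds end-to-end on a small
#' synthetic cohort.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Global seed; recorded in the manifest and passed to the
#'   simulator.
#' @param stages Stages to run, in dependency order, among `"simulate"`,
#'   `"filter"`, `"drivers"`, `"clonality"`, `"associations"`, `"survival"`.
#' @param cohort A [cohort_config()] for the simulate stage; its seed is
#'   overridden by `seed`.
#' @param thresholds A [filter_thresholds()].
#' @param inputs Named list of paths (`mutations`, `segments`, `purity`,
#'   `clinical`, `expression`) used when `"simulate"` is not among the
#'   stages.
#' @param comutation_fdr,intclust_fdr,clinical_fdr FDR levels for the
#'   association screens (defaults 0.1, 0.01, 0.05).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            seed = 1L,
                            stages = c("simulate", "filter", "drivers",
                                       "clonality", "associations",
                                       "survival"),
                            cohort = cohort_config(n_tumours = 200,
                                                   seed = seed),
                            thresholds = filter_thresholds(),
                            inputs = list(),
                            comutation_fdr = 0.1,
                            intclust_fdr = 0.01,
                            clinical_fdr = 0.05) {
  known <- c("simulate", "filter", "drivers", "clonality", "associations",
             "survival")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) {
    stop_config(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  }
  cohort$seed <- as.integer(seed)
  structure(
    list(outdir = outdir, seed = as.integer(seed),
         stages = stages, cohort = cohort, thresholds = thresholds,
         inputs = inputs, comutation_fdr = comutation_fdr,
         intclust_fdr = intclust_fdr, clinical_fdr = clinical_fdr),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; `cohort:`
#' and `thresholds:` blocks map onto [cohort_config()] and
#' [filter_thresholds()] arguments.
#'
#' @param path YAML file.
#' @param outdir Output directory (overrides any value in the file).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, outdir = NULL) {
  y <- yaml::read_yaml(path)
  cohort <- do.call(cohort_config, y$cohort %||% list())
  thresholds <- do.call(filter_thresholds, y$thresholds %||% list())
  pipeline_config(
    outdir = outdir %||% y$outdir %||% stop_config("outdir required"),
    seed = y$seed %||% 1L,
    stages = y$stages %||% c("simulate", "filter", "drivers", "clonality",
                             "associations", "survival"),
    cohort = cohort,
    thresholds = thresholds,
    inputs = y$inputs %||% list(),
    comutation_fdr = y$comutation_fdr %||% 0.1,
    intclust_fdr = y$intclust_fdr %||% 0.01,
    clinical_fdr = y$clinical_fdr %||% 0.05
  )
}

#' Run the analysis pipeline end-to-end
#'
#' Runs the requested stages in dependency order — simulate (or load),
#' filter, driver discovery, clonality/heterogeneity, association screens,
#' survival — writing every stage's outputs as TSV under `outdir` together
#' with a JSON manifest recording the seed, thresholds, per-file MD5
#' checksums and row counts. A stage whose prerequisites are missing raises
#' a dependency error naming the stage; a failure in one of the independent
#' terminal stages (associations, survival) is recorded in the manifest
#' without aborting the others.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop_config("config must be created with pipeline_config()")
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  state <- list()
  outputs <- list()
  errors <- list()

  emit <- function(name, data, writer = readr::write_tsv) {
    path <- file.path(config$outdir, paste0(name, ".tsv"))
    writer(data, path)
    outputs[[name]] <<- list(path = path, rows = nrow(data))
    path
  }
  require_state <- function(stage, what) {
    missing <- setdiff(what, names(state))
    if (length(missing) > 0) {
      stop_config(paste0("stage '", stage, "' requires upstream output(s): ",
                         paste(missing, collapse = ", ")))
    }
  }

  # --- simulate / load ------------------------------------------------------
  if ("simulate" %in% config$stages) {
    cohort <- simulate_cohort(config$cohort)
    state$mutations <- cohort$mutations
    state$segments <- cohort$segments
    state$purity <- cohort$purity
    state$clinical <- cohort$clinical
    state$expression <- cohort$expression
    state$resources <- cohort$resources
    state$truth <- cohort$truth
    emit("mutations", select(state$mutations, -"mut_id"),
         function(d, p) write_mutations(d, p))
    emit("segments", state$segments, function(d, p) write_segments(d, p))
    emit("purity", state$purity, function(d, p) write_purity(d, p))
    emit("clinical", state$clinical, function(d, p) write_clinical(d, p))
    emit("expression", state$expression)
    emit("truth_mutations", state$truth$mutations)
    emit("truth_drivers", state$truth$drivers)
    emit("truth_samples", state$truth$samples)
  } else {
    for (nm in names(config$inputs)) {
      path <- config$inputs[[nm]]
      if (!file.exists(path)) {
        stop_config(paste0("input file for '", nm, "' not found: ", path))
      }
      state[[nm]] <- switch(
        nm,
        mutations = read_mutations(path),
        segments = read_segments(path),
        purity = read_purity(path),
        clinical = read_clinical(path),
        expression = readr::read_tsv(path, show_col_types = FALSE),
        readr::read_tsv(path, show_col_types = FALSE)
      )
    }
  }

  # --- filter ---------------------------------------------------------------
  if ("filter" %in% config$stages) {
    require_state("filter", c("mutations", "resources"))
    snv <- filter(state$mutations, .data$variant_class == "SNV")
    ind <- filter(state$mutations, .data$variant_class != "SNV")
    snv <- apply_snv_filters(snv, state$resources, config$thresholds)
    ind <- if (nrow(ind) > 0) {
      apply_indel_filters(ind, state$resources, config$thresholds)
    } else {
      ind
    }
    audited <- bind_rows(snv, ind)
    state$audited <- audited
    state$pass <- filter(audited, .data$filter_status == "pass")
    emit("filter_audit",
         select(audited, "sample", "gene", "chrom", "pos", "ref", "alt",
                "filter_status", "removal_reasons"))
  }

  # --- receptor status (prerequisite of drivers/associations/survival) -----
  if (any(c("drivers", "associations", "survival") %in% config$stages)) {
    require_state("drivers", c("clinical"))
    er_in <- tibble(
      sample = state$clinical$sample,
      expression = if (!is.null(state$expression))
        state$expression$esr1[match(state$clinical$sample,
                                    state$expression$sample)]
      else NA_real_,
      ihc = state$clinical$er_ihc
    )
    er_assigned <- tryCatch(
      assign_receptor_status(er_in),
      error = function(e) mutate(er_in, final_call = .data$ihc)
    )
    state$er_status <- tibble(sample = er_assigned$sample,
                              er = er_assigned$final_call)
    state$er_status <- filter(state$er_status, !is.na(.data$er))
  }

  # --- drivers --------------------------------------------------------------
  if ("drivers" %in% config$stages) {
    require_state("drivers", c("pass", "er_status"))
    coding <- filter(state$pass,
                     .data$consequence %in% scoreable_consequences,
                     .data$sample %in% state$er_status$sample)
    drivers <- identify_mut_drivers(coding, state$er_status)
    state$drivers <- drivers
    state$functional <- functional_mutation_matrix(coding, drivers,
                                                   state$er_status)
    emit("driver_scores", as_tibble(drivers))
    emit("functional_matrix", state$functional)
  }

  # --- clonality / heterogeneity -------------------------------------------
  if ("clonality" %in% config$stages) {
    require_state("clonality", c("pass", "segments", "purity"))
    ann <- annotate_copy_number(state$pass, state$segments) |>
      left_join(select(state$purity, "sample", "purity"), by = "sample") |>
      filter(!is.na(.data$cn_tum), .data$cn_tum >= 1, !is.na(.data$purity))
    ccf <- estimate_ccf(ann)
    state$ccf <- ccf
    emit("ccf", select(ccf, "sample", "gene", "chrom", "pos", "vaf_hat",
                       "vaf_lower", "vaf_upper", "ccf", "ccf_lower",
                       "ccf_upper", "clonality"))
    state$math <- cohort_math_scores(state$pass)
    emit("math_scores", state$math)
    state$cin <- cin_score(state$segments, state$purity)
    emit("cin_scores", state$cin)
  }

  # --- associations ---------------------------------------------------------
  if ("associations" %in% config$stages) {
    res <- tryCatch({
      require_state("associations", c("functional", "clinical"))
      pw <- pairwise_comutation(state$functional,
                                fdr = config$comutation_fdr)
      emit("pairwise_associations", pw)
      labels <- tibble(sample = state$clinical$sample,
                       intclust = state$clinical$intclust)
      labels <- filter(labels, !is.na(.data$intclust))
      ic <- intclust_enrichment(
        semi_join_functional(state$functional, labels$sample),
        labels, fdr = config$intclust_fdr
      )
      emit("intclust_enrichment", ic)
      cl <- clinical_association_screen(state$functional, state$clinical,
                                        fdr = config$clinical_fdr)
      emit("clinical_associations", cl)
      list(pairwise = pw, intclust = ic, clinical = cl)
    }, error = function(e) {
      errors$associations <<- conditionMessage(e)
      NULL
    })
    state$associations <- res
  }

  # --- survival -------------------------------------------------------------
  if ("survival" %in% config$stages) {
    res <- tryCatch({
      require_state("survival", c("clinical", "functional"))
      records <- prepare_bcss(state$clinical)
      genes <- setdiff(names(state$functional), "sample")
      cox_rows <- purrr::map_dfr(genes, function(g) {
        mut <- tibble(sample = state$functional$sample,
                      mutated = state$functional[[g]])
        fit <- tryCatch(suppressWarnings(cox_multivariable(records, mut)),
                        error = function(e) NULL)
        if (is.null(fit)) return(tibble())
        tidy(fit) |>
          filter(.data$term == "mutatedTRUE") |>
          mutate(gene = g, n = fit$n, n_events = fit$n_events,
                 flagged = fit$flagged, .before = 1)
      })
      emit("cox_mutations", cox_rows)
      km <- NULL
      if (!is.null(state$math)) {
        km <- tryCatch(km_math_quartiles(records, state$math),
                       error = function(e) NULL)
        if (!is.null(km)) emit("km_math", glance(km))
      }
      list(cox = cox_rows, km = km)
    }, error = function(e) {
      errors$survival <<- conditionMessage(e)
      NULL
    })
    state$survival <- res
  }

  # --- manifest -------------------------------------------------------------
  manifest <- list(
    seed = config$seed,
    stages = config$stages,
    thresholds = unclass(config$thresholds),
    outputs = purrr::imap(outputs, function(o, nm) {
      list(file = basename(o$path),
           rows = o$rows,
           md5 = unname(tools::md5sum(o$path)))
    }),
    errors = errors
  )
  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(state = state, manifest = manifest,
                 manifest_path = manifest_path))
}

# restrict a wide functional matrix to a sample subset
semi_join_functional <- function(functional, samples) {
  functional[functional$sample %in% samples, , drop = FALSE]
}
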