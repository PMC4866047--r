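#' Expected variant allele fraction under purity and copy number
#'
#' Inverts the cancer-cell-fraction relation: a mutation present on
#' `multiplicity` copies in a fraction `ccf` of tumour cells, in a sample of
#' purity `purity` where the tumour carries `cn_tum` copies at the locus
#' (normal cells carry `cn_norm`, i.e. 2), is expected at allele fraction
#'
#' \deqn{VAF = m \cdot CCF \cdot p / (p \cdot CN_{tum} + (1-p) \cdot CN_{norm})}
#'
#' @param ccf Cancer cell fraction in (0, 1].
#' @param purity Tumour purity in (0, 1].
#' @param cn_tum Tumour total copy number at the locus (integer >= 1).
#' @param multiplicity Number of mutated copies, `1 <= multiplicity <= cn_tum`.
#' @param cn_norm Normal copy number (default 2).
#' @return Expected VAF, vectorized over the inputs.
#' @examples
#' expected_vaf(1, 1, 2, 1)        # 0.5: heterozygous in a pure diploid
#' expected_vaf(0.5, 0.8, 4, 1)    # 0.111...
#' @export
expected_vaf <- function(ccf, purity, cn_tum, multiplicity = 1, cn_norm = 2) {
  if (any(purity <= 0 | purity > 1)) stop_validation("purity must be in (0, 1]")
  if (any(ccf < 0 | ccf > 1)) stop_validation("ccf must be in [0, 1]")
  if (any(cn_tum < 1)) stop_validation("cn_tum must be >= 1")
  if (any(multiplicity < 1 | multiplicity > cn_tum)) {
    stop_validation("multiplicity must satisfy 1 <= multiplicity <= cn_tum")
  }
  multiplicity * ccf * purity / (purity * cn_tum + (1 - purity) * cn_norm)
}

#' Simulate strand-resolved read counts for a variant
#'
#' Draws sequencing depth from a negative binomial (mean `depth_mean`,
#' dispersion `depth_dispersion`; the targeted-panel design this emulates has
#' median depth near 150x), the alt-read count as binomial(depth, vaf), and
#' splits alt and ref reads across strands as binomial with probability
#' `strand_prob` (0.5 unless a strand-bias artefact is being injected).
#'
#' @param vaf Expected variant allele fraction(s) in \[0, 1\].
#' @param depth_mean,depth_dispersion Negative-binomial depth parameters.
#' @param strand_prob Probability that a read maps to the forward strand.
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   in isolation, otherwise the surrounding RNG stream is used.
#' @return A tibble with columns `alt_fwd`, `alt_rev`, `ref_fwd`, `ref_rev`.
#' @export
simulate_read_counts <- function(vaf, depth_mean = 150, depth_dispersion = 10,
                                 strand_prob = 0.5, seed = NULL) {
  if (any(vaf < 0 | vaf > 1)) stop_validation("vaf must be in [0, 1]")
  if (depth_mean <= 0 || depth_dispersion <= 0) {
    stop_validation("depth parameters must be positive")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(vaf)
  depth <- pmax(2L, rnbinom(n, size = depth_dispersion, mu = depth_mean))
  alt <- rbinom(n, depth, vaf)
  ref <- depth - alt
  alt_fwd <- rbinom(n, alt, strand_prob)
  ref_fwd <- rbinom(n, ref, 0.5)
  tibble(
    alt_fwd = alt_fwd,
    alt_rev = alt - alt_fwd,
    ref_fwd = ref_fwd,
    ref_rev = ref - ref_fwd
  )
}

#' Simulate survival times under a proportional-hazards model
#'
#' Event times are exponential with rate
#' `baseline_hazard * exp(X %*% log_hazard_ratios)`; censoring is an
#' independent exponential with rate `censor_rate` (plus an optional
#' administrative horizon), so the generated data satisfy the proportional
#' hazards assumption the downstream Cox models make.
#'
#' @param covariates Numeric matrix or data frame (n x p).
#' @param log_hazard_ratios Numeric vector of length p.
#' @param baseline_hazard Positive baseline event rate (per month).
#' @param censor_rate Non-negative censoring rate; 0 means no random
#'   censoring.
#' @param admin_censor_months Administrative censoring horizon (default
#'   `Inf`).
#' @param seed Optional integer seed.
#' @return A tibble with columns `time` (months) and `event` (1 = event
#'   observed, 0 = censored).
#' @export
simulate_survival <- function(covariates, log_hazard_ratios, baseline_hazard,
                              censor_rate = 0, admin_censor_months = Inf,
                              seed = NULL) {
  x <- as.matrix(covariates)
  if (ncol(x) != length(log_hazard_ratios)) {
    stop_validation("covariate columns and log_hazard_ratios lengths differ")
  }
  if (baseline_hazard <= 0) stop_validation("baseline hazard must be positive")
  if (censor_rate < 0) stop_validation("censor rate must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x)
  rate <- baseline_hazard * exp(drop(x %*% log_hazard_ratios))
  t_event <- rexp(n, rate)
  t_cens <- if (censor_rate > 0) rexp(n, censor_rate) else rep(Inf, n)
  t_cens <- pmin(t_cens, admin_censor_months)
  tibble(
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens)
  )
}

#' Default driver/passenger gene panel for the synthetic cohort
#'
#' A targeted panel emulating the mutation landscape of a large breast-cancer
#' cohort: hotspot-driven oncogenes (PIK3CA-like, AKT1-like, ERBB2-like),
#' tumour suppressors dominated by truncating mutations (TP53-like, GATA3,
#' MAP3K1, CDH1, ...), and scattered passengers. Per-stratum mutation rates
#' and per-gene log hazard ratios approximate the frequencies and prognostic
#' effects reported for such cohorts; all values are configurable.
#'
#' @param n_passengers Number of passenger genes (default 25).
#' @return A tibble with columns `gene`, `role`, `length_codons`,
#'   `hotspot_codons` (list column), `rate_erpos`, `rate_erneg`, `log_hr`,
#'   `use_both`.
#' @export
default_gene_panel <- function(n_passengers = 25) {
  drivers <- tibble(
    gene = c("PIK3CA", "TP53", "GATA3", "MAP3K1", "CDH1", "KMT2C",
             "ARID1A", "AKT1", "ERBB2", "SMAD4", "NF1", "USP9X"),
    role = c("oncogene", "tsg", "tsg", "tsg", "tsg", "tsg",
             "tsg", "oncogene", "oncogene", "tsg", "tsg", "tsg"),
    length_codons = c(1068, 393, 444, 1512, 882, 4911,
                      2285, 480, 1255, 552, 2839, 2570),
    hotspot_codons = list(
      c(345L, 420L, 542L, 545L, 1047L), integer(0), integer(0), integer(0),
      integer(0), integer(0), integer(0), c(17L), c(755L, 777L),
      integer(0), integer(0), integer(0)
    ),
    rate_erpos = c(0.45, 0.25, 0.14, 0.18, 0.14, 0.10,
                   0.06, 0.04, 0.028, 0.012, 0.03, 0.02),
    rate_erneg = c(0.30, 0.65, 0.02, 0.04, 0.03, 0.08,
                   0.05, 0.01, 0.032, 0.010, 0.06, 0.01),
    log_hr = c(0, 0.30, -0.55, -0.58, 0, 0,
               0, 0, 0, 1.22, 1.0, 1.1),
    use_both = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                 FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
  if (n_passengers > 0) {
    passengers <- tibble(
      gene = sprintf("PSG%02d", seq_len(n_passengers)),
      role = "passenger",
      length_codons = 500L,
      hotspot_codons = list(integer(0)),
      rate_erpos = rep(c(0.01, 0.02, 0.03), length.out = n_passengers),
      rate_erneg = rep(c(0.02, 0.01, 0.03), length.out = n_passengers),
      log_hr = 0,
      use_both = FALSE
    )
    drivers <- bind_rows(drivers, passengers)
  }
  drivers
}

#' Configuration for the synthetic cohort generator
#'
#' Collects every knob of the generator with defaults mirroring the cohort
#' the analysis was designed for: 2,433 tumours, a ~650-sample normal pool,
#' negative-binomial depth with mean 150 (median near 152x), 76% ER+, mostly
#' clonal mutations with a Uniform(0.1, 0.9) subclonal tail, and
#' proportional-hazards survival. Artefact rates are expected counts per
#' tumour for each injected artefact class, chosen so every filtering rule
#' sees positive and negative cases.
#'
#' @param n_tumours,n_normals Cohort sizes.
#' @param seed Integer seed (mandatory; the generator is deterministic given
#'   the seed).
#' @param gene_panel See [default_gene_panel()].
#' @param er_positive_fraction Fraction of tumours that are truly ER+.
#' @param hotspot_share Probability that an oncogene mutation hits one of its
#'   hotspot codons.
#' @param tsg_inactivating_share Probability that a tumour-suppressor
#'   mutation is truncating/splice-disrupting.
#' @param purity_shape1,purity_shape2 Beta parameters for tumour purity.
#' @param depth_mean,depth_dispersion Negative-binomial depth parameters.
#' @param clonal_fraction Probability a mutation is clonal (CCF = 1); the
#'   remainder take one of the tumour's subclone CCFs, drawn
#'   Uniform(0.1, 0.9).
#' @param n_subclones Subclones per tumour.
#' @param multiplicity Mutated copies per mutation (default 1).
#' @param background_rate Poisson mean of additional passenger/noncoding
#'   mutations per tumour (drives heterogeneity scores).
#' @param artefact_rates Named list of expected per-tumour artefact counts;
#'   see Details.
#' @param baseline_hazard,censor_rate,admin_censor_months Survival model.
#' @param covariate_log_hrs Log hazard ratios for (age >= 55, size >= 50mm,
#'   node positive, grade 3).
#' @details Artefact classes: `low_quality`, `muc16`, `caller_flag`,
#' `strand_bias`, `low_vaf` (non-hotspot low-VAF noise), `kg_common`
#' (population polymorphism), `normal_pool` (panel-of-normals hit);
#' `rescued_low_vaf` and `rescued_normal_pool` are *true* mutations engineered
#' to exercise the COSMIC rescue paths; indel classes `lowqual_flag`,
#' `indel_strand_bias`, `repeat_region`, `homopolymer`.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_tumours = 2433,
                          n_normals = 650,
                          seed = 1L,
                          gene_panel = default_gene_panel(),
                          er_positive_fraction = 0.76,
                          hotspot_share = 0.6,
                          tsg_inactivating_share = 0.8,
                          purity_shape1 = 8,
                          purity_shape2 = 2.5,
                          depth_mean = 150,
                          depth_dispersion = 10,
                          clonal_fraction = 0.90,
                          n_subclones = 2,
                          multiplicity = 1,
                          background_rate = 8,
                          artefact_rates = list(
                            low_quality = 0.20, muc16 = 0.10,
                            caller_flag = 0.10, strand_bias = 0.10,
                            low_vaf = 0.15, kg_common = 0.25,
                            normal_pool = 0.25, rescued_low_vaf = 0.05,
                            rescued_normal_pool = 0.05, lowqual_flag = 0.10,
                            indel_strand_bias = 0.05, repeat_region = 0.10,
                            homopolymer = 0.10
                          ),
                          baseline_hazard = 0.004,
                          censor_rate = 0.003,
                          admin_censor_months = 300,
                          covariate_log_hrs = c(age = 0.3, size = 0.3,
                                                node = 0.4, grade = 0.4)) {
  if (is.null(seed) || is.na(seed)) stop_config("a seed is mandatory")
  if (n_tumours < 0 || n_normals < 0) stop_config("cohort sizes must be >= 0")
  if (er_positive_fraction < 0 || er_positive_fraction > 1) {
    stop_config("er_positive_fraction must be in [0, 1]")
  }
  if (any(unlist(artefact_rates) < 0) || background_rate < 0) {
    stop_config("rates must be >= 0")
  }
  if (clonal_fraction < 0 || clonal_fraction > 1) {
    stop_config("clonal_fraction must be in [0, 1]")
  }
  if (baseline_hazard <= 0) stop_config("baseline hazard must be positive")
  panel <- as_tibble(gene_panel)
  bad_hotspot <- purrr::map2_lgl(panel$hotspot_codons, panel$length_codons,
                                 function(h, l) length(h) > 0 && any(h > l))
  if (any(bad_hotspot)) {
    stop_config(paste0("hotspot codon outside gene length for: ",
                       paste(panel$gene[bad_hotspot], collapse = ", ")))
  }
  structure(
    list(
      n_tumours = as.integer(n_tumours), n_normals = as.integer(n_normals),
      seed = as.integer(seed), gene_panel = panel,
      er_positive_fraction = er_positive_fraction,
      hotspot_share = hotspot_share,
      tsg_inactivating_share = tsg_inactivating_share,
      purity_shape1 = purity_shape1, purity_shape2 = purity_shape2,
      depth_mean = depth_mean, depth_dispersion = depth_dispersion,
      clonal_fraction = clonal_fraction, n_subclones = n_subclones,
      multiplicity = multiplicity, background_rate = background_rate,
      artefact_rates = artefact_rates, baseline_hazard = baseline_hazard,
      censor_rate = censor_rate, admin_censor_months = admin_censor_months,
      covariate_log_hrs = covariate_log_hrs
    ),
    class = "cohort_config"
  )
}

# genome layout used by the generator ---------------------------------------

sim_chrom_length <- 1.2e8
muc16_window <- list(chrom = "chr19", start = 8955441, end = 9044530)

# deterministic gene coordinates: genes tiled across chr1..chr22 starting at
# 30 Mb, clear of the MUC16 window and of the artefact-interval region
# (1-5 Mb) used for repeat/homopolymer tracks
sim_gene_coords <- function(panel) {
  n <- nrow(panel)
  chrom_idx <- ((seq_len(n) - 1) %% 22) + 1
  slot <- ((seq_len(n) - 1) %/% 22)
  tibble(
    gene = panel$gene,
    chrom = paste0("chr", chrom_idx),
    start = 3e7 + slot * 2e6,
    end = 3e7 + slot * 2e6 + 3 * panel$length_codons + 2
  )
}

random_bases <- function(n) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

random_snv_alleles <- function(n) {
  ref <- random_bases(n)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  list(ref = ref, alt = unname(alt))
}

#' Simulate a full synthetic cohort with recorded ground truth
#'
#' Generates every input the downstream analysis consumes — a mutation table
#' with strand-resolved read counts, allele-specific copy-number segments
#' with purity and ploidy, a clinical table with proportional-hazards
#' survival, marker-gene expression, and resource tables standing in for
#' COSMIC, population allele frequencies, ClinVar, Provean and repeat
#' tracks — together with a `truth` record of every latent quantity
#' (driver labels, per-mutation CCFs and artefact labels, per-gene hazard
#' ratios, true ER components).
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `mutations`,
#'   `segments`, `purity`, `clinical`, `expression`, `resources`, `truth`
#'   and `config`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop_config("config must be created with cohort_config()")
  }
  set.seed(config$seed)
  panel <- config$gene_panel
  coords <- sim_gene_coords(panel)
  empty <- simulate_cohort_empty(panel, coords, config)
  if (config$n_tumours == 0) return(empty)

  n <- config$n_tumours
  samples <- tibble(
    sample = sprintf("T%04d", seq_len(n)),
    true_er = if_else(runif(n) < config$er_positive_fraction, "pos", "neg"),
    purity = round(rbeta(n, config$purity_shape1, config$purity_shape2), 3)
  )
  samples$purity <- pmin(pmax(samples$purity, 0.05), 1)

  # chromosome-scale allele-specific copy-number states
  cn_states <- tibble(
    n_major = c(1L, 2L, 2L, 2L, 3L, 5L, 0L),
    n_minor = c(1L, 1L, 0L, 2L, 2L, 1L, 0L),
    prob = c(0.58, 0.15, 0.10, 0.09, 0.04, 0.03, 0.01)
  )
  seg_state <- sample(nrow(cn_states), n * 22, replace = TRUE,
                      prob = cn_states$prob)
  segments <- tibble(
    sample = rep(samples$sample, each = 22),
    chrom = rep(paste0("chr", 1:22), times = n),
    start = 1,
    end = sim_chrom_length,
    n_major = cn_states$n_major[seg_state],
    n_minor = cn_states$n_minor[seg_state]
  )
  ploidy <- segments |>
    group_by(sample = .data$sample) |>
    summarise(ploidy = mean(.data$n_major + .data$n_minor), .groups = "drop")
  purity_tbl <- samples |>
    select("sample", "purity") |>
    left_join(ploidy, by = "sample") |>
    mutate(ploidy = round(pmax(.data$ploidy, 0.5), 3))

  # subclone CCFs available in each tumour
  subclones <- matrix(runif(n * config$n_subclones, 0.1, 0.9), nrow = n)

  # --- true somatic mutations in panel genes -------------------------------
  rate_mat <- outer(
    seq_len(n), seq_len(nrow(panel)),
    function(i, j) if_else(samples$true_er[i] == "pos",
                           panel$rate_erpos[j], panel$rate_erneg[j])
  )
  hits <- which(matrix(runif(length(rate_mat)), nrow = n) < rate_mat,
                arr.ind = TRUE)
  true_mut <- tibble(
    sample_idx = hits[, 1],
    gene_idx = hits[, 2]
  )
  true_mut <- true_mut[sample.int(nrow(true_mut)), ] # shuffle row order

  true_rows <- sim_consequences(true_mut, panel, config)

  # --- background passenger / noncoding mutations --------------------------
  bg <- sim_background(samples, panel, config)
  body <- bind_rows(true_rows, bg)

  # positions, copy number, CCFs, read counts for all real mutations
  body$sample <- samples$sample[body$sample_idx]
  body$purity <- samples$purity[body$sample_idx]
  g <- match(body$gene, coords$gene)
  body$chrom <- if_else(is.na(g), body$chrom, coords$chrom[g])
  body$pos <- if_else(is.na(g), body$pos,
                      coords$start[g] + 3 * (pmax(body$codon, 1,
                                                  na.rm = TRUE) - 1))
  seg_key <- paste(body$sample, body$chrom)
  seg_lut <- segments |>
    mutate(key = paste(.data$sample, .data$chrom), total = .data$n_major + .data$n_minor)
  body$cn_tum <- seg_lut$total[match(seg_key, seg_lut$key)]
  # a mutation cannot live on a homozygously deleted segment
  body <- filter(body, .data$cn_tum >= 1)

  is_clonal <- runif(nrow(body)) < config$clonal_fraction
  pick <- cbind(body$sample_idx,
                sample.int(config$n_subclones, nrow(body), replace = TRUE))
  body$true_ccf <- if_else(is_clonal, 1, round(subclones[pick], 4))
  mult <- pmin(config$multiplicity, body$cn_tum)
  body$true_vaf <- expected_vaf(body$true_ccf, body$purity, body$cn_tum,
                                mult)
  counts <- simulate_read_counts(body$true_vaf, config$depth_mean,
                                 config$depth_dispersion)
  body <- bind_cols(body, counts)
  body$quality <- round(runif(nrow(body), 20, 250), 2)
  body$flags <- ""
  body$strand_bias_phred <- if_else(
    body$variant_class == "SNV", NA_real_, round(runif(nrow(body), 0, 20), 1)
  )
  body$is_artefact <- FALSE
  body$artefact_type <- NA_character_

  # --- injected artefacts ---------------------------------------------------
  art <- sim_artefacts(samples, panel, coords, config)
  all_rows <- bind_rows(body, art$rows)
  # drop zero-alt rows (a binomial draw can produce no alt reads; no call)
  all_rows <- filter(all_rows, .data$alt_fwd + .data$alt_rev >= 1)
  all_rows$mut_id <- sprintf("M%06d", seq_len(nrow(all_rows)))

  alleles <- random_snv_alleles(nrow(all_rows))
  all_rows$ref <- if_else(all_rows$variant_class == "SNV", alleles$ref, "A")
  all_rows$alt <- dplyr::case_when(
    all_rows$variant_class == "SNV" ~ alleles$alt,
    all_rows$variant_class == "insertion" ~ "AT",
    TRUE ~ "-"
  )

  mutations <- all_rows |>
    mutate(codon = as.integer(.data$codon)) |>
    select("sample", "gene", "chrom", "pos", "ref", "alt",
           variant_class = "variant_class", "consequence", "codon",
           "alt_fwd", "alt_rev", "ref_fwd", "ref_rev", "quality", "flags",
           "strand_bias_phred", mut_id = "mut_id") |>
    normalise_mutations() |>
    validate_mutations()

  resources <- sim_resources(all_rows, panel, coords, config)

  clin <- sim_clinical(samples, all_rows, panel, config)

  truth <- list(
    mutations = all_rows |>
      select("mut_id", "sample", "gene", "true_ccf", "true_vaf",
             "is_artefact", "artefact_type") |>
      mutate(true_clonal = !is.na(.data$true_ccf) & .data$true_ccf >= 1),
    drivers = panel |>
      filter(.data$role != "passenger") |>
      select("gene", "role", "log_hr"),
    samples = samples |>
      left_join(ploidy, by = "sample") |>
      select("sample", "true_er", "purity", "ploidy")
  )

  structure(
    list(
      mutations = mutations,
      segments = validate_segments(segments),
      purity = validate_purity(purity_tbl),
      clinical = clin$clinical,
      expression = clin$expression,
      resources = resources,
      truth = truth,
      config = config
    ),
    class = "synthetic_cohort"
  )
}

simulate_cohort_empty <- function(panel, coords, config) {
  structure(
    list(
      mutations = validate_mutations(tibble(
        sample = character(0), gene = character(0), chrom = character(0),
        pos = double(0), ref = character(0), alt = character(0),
        variant_class = character(0), consequence = character(0),
        codon = integer(0), alt_fwd = integer(0), alt_rev = integer(0),
        ref_fwd = integer(0), ref_rev = integer(0), quality = double(0),
        mut_id = character(0)
      )),
      segments = tibble(sample = character(0), chrom = character(0),
                        start = double(0), end = double(0),
                        n_major = integer(0), n_minor = integer(0)),
      purity = tibble(sample = character(0), purity = double(0),
                      ploidy = double(0)),
      clinical = tibble(),
      expression = tibble(sample = character(0), esr1 = double(0),
                          erbb2 = double(0)),
      resources = sim_resources(tibble(), panel, coords, config),
      truth = list(
        mutations = tibble(mut_id = character(0), sample = character(0),
                           gene = character(0), true_ccf = double(0),
                           true_vaf = double(0), is_artefact = logical(0),
                           artefact_type = character(0),
                           true_clonal = logical(0)),
        drivers = panel |>
          filter(.data$role != "passenger") |>
          select("gene", "role", "log_hr"),
        samples = tibble(sample = character(0), true_er = character(0),
                         purity = double(0), ploidy = double(0))
      ),
      config = config
    ),
    class = "synthetic_cohort"
  )
}

# consequence and codon draw for true panel-gene mutations
sim_consequences <- function(true_mut, panel, config) {
  if (nrow(true_mut) == 0) {
    return(tibble(sample_idx = integer(0), gene_idx = integer(0),
                  gene = character(0), chrom = character(0), pos = double(0),
                  variant_class = character(0), consequence = character(0),
                  codon = double(0)))
  }
  role <- panel$role[true_mut$gene_idx]
  len <- panel$length_codons[true_mut$gene_idx]
  n <- nrow(true_mut)
  u <- runif(n)
  consequence <- character(n)
  codon <- double(n)

  onc <- role == "oncogene"
  tsg <- role == "tsg"
  pas <- role == "passenger"

  # oncogenes: hotspot missense with prob hotspot_share, else mostly missense
  hot <- onc & u < config$hotspot_share
  consequence[hot] <- "missense"
  codon[hot] <- vapply(true_mut$gene_idx[hot], function(j) {
    h <- panel$hotspot_codons[[j]]
    if (length(h) == 0) sample.int(panel$length_codons[j], 1)
    else h[sample.int(length(h), 1)]
  }, double(1))
  rest_onc <- onc & !hot
  consequence[rest_onc] <- sample(
    c("missense", "silent", "nonsense", "frameshift", "inframe_indel"),
    sum(rest_onc), replace = TRUE, prob = c(0.80, 0.10, 0.02, 0.03, 0.05)
  )

  # tumour suppressors: truncating with prob tsg_inactivating_share
  inact <- tsg & u < config$tsg_inactivating_share
  consequence[inact] <- sample(c("nonsense", "frameshift", "splice_site"),
                               sum(inact), replace = TRUE,
                               prob = c(0.4, 0.4, 0.2))
  rest_tsg <- tsg & !inact
  consequence[rest_tsg] <- sample(c("missense", "silent"), sum(rest_tsg),
                                  replace = TRUE, prob = c(0.8, 0.2))

  consequence[pas] <- sample(
    c("missense", "silent", "nonsense", "frameshift"),
    sum(pas), replace = TRUE, prob = c(0.70, 0.20, 0.06, 0.04)
  )

  need_codon <- codon == 0
  codon[need_codon] <- vapply(len[need_codon],
                              function(l) sample.int(l, 1), double(1))
  tibble(
    sample_idx = true_mut$sample_idx,
    gene_idx = true_mut$gene_idx,
    gene = panel$gene[true_mut$gene_idx],
    chrom = NA_character_,
    pos = NA_real_,
    variant_class = if_else(
      consequence %in% c("frameshift", "inframe_indel"),
      sample(c("insertion", "deletion"), n, replace = TRUE),
      "SNV"
    ),
    consequence = consequence,
    codon = codon
  )
}

# background noncoding/passenger mutations feeding heterogeneity scores
sim_background <- function(samples, panel, config) {
  n <- nrow(samples)
  counts <- stats::rpois(n, config$background_rate)
  total <- sum(counts)
  if (total == 0) {
    return(tibble(sample_idx = integer(0), gene_idx = integer(0),
                  gene = character(0), chrom = character(0), pos = double(0),
                  variant_class = character(0), consequence = character(0),
                  codon = double(0)))
  }
  sample_idx <- rep(seq_len(n), counts)
  passenger_idx <- which(panel$role == "passenger")
  in_gene <- runif(total) < (if (length(passenger_idx) > 0) 0.3 else 0)
  gene_idx <- rep(NA_integer_, total)
  gene_idx[in_gene] <- passenger_idx[sample.int(length(passenger_idx),
                                                sum(in_gene), replace = TRUE)]
  consequence <- if_else(
    in_gene,
    sample(c("missense", "silent"), total, replace = TRUE,
           prob = c(0.6, 0.4)),
    "noncoding"
  )
  codon <- rep(NA_real_, total)
  codon[in_gene] <- vapply(panel$length_codons[gene_idx[in_gene]],
                           function(l) sample.int(l, 1), double(1))
  tibble(
    sample_idx = sample_idx,
    gene_idx = gene_idx,
    gene = if_else(in_gene, panel$gene[gene_idx], "intergenic"),
    chrom = if_else(in_gene, NA_character_,
                    paste0("chr", sample.int(22, total, replace = TRUE))),
    pos = if_else(in_gene, NA_real_,
                  floor(runif(total, 1e7, 2e7))),
    variant_class = "SNV",
    consequence = consequence,
    codon = codon
  )
}

# artefact rows exercising every filtering rule
sim_artefacts <- function(samples, panel, coords, config) {
  n <- nrow(samples)
  rates <- config$artefact_rates
  mk_base <- function(type, n_rows, class = "SNV", consequence = "missense") {
    if (n_rows == 0) {
      return(tibble())
    }
    idx <- sample.int(n, n_rows, replace = TRUE)
    pas <- which(panel$role == "passenger")
    if (length(pas) == 0) pas <- seq_len(nrow(panel))
    gi <- pas[sample.int(length(pas), n_rows, replace = TRUE)]
    codon <- vapply(panel$length_codons[gi], function(l) sample.int(l, 1),
                    double(1))
    tibble(
      sample_idx = idx,
      gene_idx = gi,
      gene = panel$gene[gi],
      chrom = coords$chrom[gi],
      pos = coords$start[gi] + 3 * (codon - 1) + 1,
      variant_class = class,
      consequence = consequence,
      codon = codon,
      sample = samples$sample[idx],
      purity = samples$purity[idx],
      cn_tum = 2L,
      true_ccf = NA_real_,
      true_vaf = NA_real_,
      is_artefact = TRUE,
      artefact_type = type
    )
  }
  draw <- function(type) stats::rpois(1, n * (rates[[type]] %||% 0))

  pieces <- list()

  add_counts <- function(x, vaf_lo = 0.2, vaf_hi = 0.6) {
    if (nrow(x) == 0) return(x)
    v <- runif(nrow(x), vaf_lo, vaf_hi)
    bind_cols(x, simulate_read_counts(v, config$depth_mean,
                                      config$depth_dispersion))
  }

  # (1) sub-threshold caller quality
  x <- add_counts(mk_base("low_quality", draw("low_quality")))
  if (nrow(x) > 0) {
    x$quality <- round(runif(nrow(x), 0, 6.5), 2)
    x$flags <- ""
    x$strand_bias_phred <- NA_real_
    pieces <- c(pieces, list(x))
  }

  # (2) MUC16 tandem-repeat window
  x <- add_counts(mk_base("muc16", draw("muc16")))
  if (nrow(x) > 0) {
    x$gene <- "MUC16"
    x$chrom <- muc16_window$chrom
    x$pos <- floor(runif(nrow(x), muc16_window$start, muc16_window$end))
    x$quality <- round(runif(nrow(x), 20, 250), 2)
    x$flags <- ""
    x$strand_bias_phred <- NA_real_
    pieces <- c(pieces, list(x))
  }

  # (3) caller-internal filter flags
  x <- add_counts(mk_base("caller_flag", draw("caller_flag")))
  if (nrow(x) > 0) {
    x$quality <- round(runif(nrow(x), 20, 250), 2)
    x$flags <- sample(c("nearby_gap_events",
                        "poor_mapping_regional_alternate_allele_mapq"),
                      nrow(x), replace = TRUE)
    x$strand_bias_phred <- NA_real_
    pieces <- c(pieces, list(x))
  }

  # (4) extreme read-direction bias
  x <- mk_base("strand_bias", draw("strand_bias"))
  if (nrow(x) > 0) {
    depth <- pmax(60L, rnbinom(nrow(x), size = config$depth_dispersion,
                               mu = config$depth_mean))
    alt <- pmax(20L, rbinom(nrow(x), depth, 0.3))
    alt <- pmin(alt, depth - 2L)
    ref <- depth - alt
    fwd <- runif(nrow(x)) < 0.5
    x$alt_fwd <- if_else(fwd, alt, 0L)
    x$alt_rev <- if_else(fwd, 0L, alt)
    x$ref_fwd <- floor(ref / 2)
    x$ref_rev <- ref - floor(ref / 2)
    x$quality <- round(runif(nrow(x), 20, 250), 2)
    x$flags <- ""
    x$strand_bias_phred <- NA_real_
    pieces <- c(pieces, list(x))
  }

  # (5a) low-VAF noise, not in COSMIC
  x <- add_counts(mk_base("low_vaf", draw("low_vaf")), 0.02, 0.055)
  if (nrow(x) > 0) {
    x$quality <- round(runif(nrow(x), 20, 250), 2)
    x$flags <- ""
    x$strand_bias_phred <- NA_real_
    pieces <- c(pieces, list(x))
  }

  # (5b) TRUE low-VAF hotspot mutations rescued via COSMIC
  x <- mk_base("rescued_low_vaf", draw("rescued_low_vaf"))
  if (nrow(x) > 0) {
    onc <- which(purrr::map_int(panel$hotspot_codons, length) > 0)
    gi <- onc[sample.int(length(onc), nrow(x), replace = TRUE)]
    x$gene_idx <- gi
    x$gene <- panel$gene[gi]
    x$chrom <- coords$chrom[gi]
    hs <- vapply(gi, function(j) {
      h <- panel$hotspot_codons[[j]]
      h[sample.int(length(h), 1)]
    }, integer(1))
    x$codon <- as.double(hs)
    x$pos <- coords$start[gi] + 3 * (hs - 1)
    x$true_ccf <- round(runif(nrow(x), 0.1, 0.25), 4)
    x$true_vaf <- expected_vaf(x$true_ccf, x$purity, x$cn_tum, 1)
    x <- bind_cols(x, simulate_read_counts(x$true_vaf, config$depth_mean,
                                           config$depth_dispersion))
    x$is_artefact <- FALSE
    x$artefact_type <- NA_character_
    x$quality <- round(runif(nrow(x), 20, 250), 2)
    x$flags <- ""
    x$strand_bias_phred <- NA_real_
    pieces <- c(pieces, list(x))
  }

  # (6) common population polymorphisms
  x <- add_counts(mk_base("kg_common", draw("kg_common")), 0.35, 0.65)
  if (nrow(x) > 0) {
    x$quality <- round(runif(nrow(x), 20, 250), 2)
    x$flags <- ""
    x$strand_bias_phred <- NA_real_
    pieces <- c(pieces, list(x))
  }

  # (7a) panel-of-normals hits (germline/noise), not rescued
  x <- add_counts(mk_base("normal_pool", draw("normal_pool")), 0.35, 0.65)
  if (nrow(x) > 0) {
    x$quality <- round(runif(nrow(x), 20, 250), 2)
    x$flags <- ""
    x$strand_bias_phred <- NA_real_
    pieces <- c(pieces, list(x))
  }

  # (7b) TRUE hotspot mutations present in the pool but COSMIC-rescued
  x <- mk_base("rescued_normal_pool", draw("rescued_normal_pool"))
  if (nrow(x) > 0) {
    onc <- which(purrr::map_int(panel$hotspot_codons, length) > 0)
    gi <- onc[sample.int(length(onc), nrow(x), replace = TRUE)]
    x$gene_idx <- gi
    x$gene <- panel$gene[gi]
    x$chrom <- coords$chrom[gi]
    hs <- vapply(gi, function(j) {
      h <- panel$hotspot_codons[[j]]
      h[sample.int(length(h), 1)]
    }, integer(1))
    x$codon <- as.double(hs)
    x$pos <- coords$start[gi] + 3 * (hs - 1)
    x$true_ccf <- 1
    x$true_vaf <- expected_vaf(1, x$purity, x$cn_tum, 1)
    x <- bind_cols(x, simulate_read_counts(x$true_vaf, config$depth_mean,
                                           config$depth_dispersion))
    x$is_artefact <- FALSE
    x$artefact_type <- "rescued_normal_pool"
    x$quality <- round(runif(nrow(x), 20, 250), 2)
    x$flags <- ""
    x$strand_bias_phred <- NA_real_
    pieces <- c(pieces, list(x))
  }

  # indel artefacts ---------------------------------------------------------
  mk_indel <- function(type, n_rows) {
    mk_base(type, n_rows, class = "deletion", consequence = "frameshift")
  }

  # LowQual caller flag
  x <- add_counts(mk_indel("lowqual_flag", draw("lowqual_flag")))
  if (nrow(x) > 0) {
    x$quality <- round(runif(nrow(x), 20, 250), 2)
    x$flags <- "LowQual"
    x$strand_bias_phred <- round(runif(nrow(x), 0, 20), 1)
    pieces <- c(pieces, list(x))
  }

  # strand-bias Phred score at/above 40
  x <- add_counts(mk_indel("indel_strand_bias", draw("indel_strand_bias")))
  if (nrow(x) > 0) {
    x$quality <- round(runif(nrow(x), 20, 250), 2)
    x$flags <- ""
    x$strand_bias_phred <- round(runif(nrow(x), 40, 90), 1)
    pieces <- c(pieces, list(x))
  }

  # simple-repeat / microsatellite overlap: placed in the 1-5 Mb artefact
  # region of each chromosome, matching the emitted repeat tracks
  x <- add_counts(mk_indel("repeat_region", draw("repeat_region")))
  if (nrow(x) > 0) {
    x$chrom <- paste0("chr", sample.int(22, nrow(x), replace = TRUE))
    x$pos <- floor(runif(nrow(x), 1e6, 2e6))
    x$gene <- "intergenic"
    x$codon <- NA_real_
    x$consequence <- "noncoding"
    x$quality <- round(runif(nrow(x), 20, 250), 2)
    x$flags <- ""
    x$strand_bias_phred <- round(runif(nrow(x), 0, 20), 1)
    pieces <- c(pieces, list(x))
  }

  # homopolymer runs of >= 6 bases
  x <- add_counts(mk_indel("homopolymer", draw("homopolymer")))
  if (nrow(x) > 0) {
    x$chrom <- paste0("chr", sample.int(22, nrow(x), replace = TRUE))
    x$pos <- floor(runif(nrow(x), 3e6, 4e6))
    x$gene <- "intergenic"
    x$codon <- NA_real_
    x$consequence <- "noncoding"
    x$quality <- round(runif(nrow(x), 20, 250), 2)
    x$flags <- ""
    x$strand_bias_phred <- round(runif(nrow(x), 0, 20), 1)
    pieces <- c(pieces, list(x))
  }

  rows <- if (length(pieces) > 0) bind_rows(pieces) else tibble()
  list(rows = rows)
}

# resource tables consistent with the injected artefacts and hotspots
sim_resources <- function(all_rows, panel, coords, config) {
  # COSMIC: hotspot loci of oncogenes, with breast counts comfortably > 2
  onc <- which(purrr::map_int(panel$hotspot_codons, length) > 0)
  cosmic <- purrr::map_dfr(onc, function(j) {
    h <- panel$hotspot_codons[[j]]
    tibble(
      chrom = coords$chrom[j],
      pos = coords$start[j] + 3 * (h - 1),
      breast_count = sample(10:400, length(h), replace = TRUE),
      somatic = TRUE
    )
  })

  pick_type <- function(type) {
    if (nrow(all_rows) == 0) return(all_rows[0, ])
    filter(all_rows, !is.na(.data$artefact_type),
           .data$artefact_type == type)
  }

  kg_rows <- pick_type("kg_common")
  kg_af <- if (nrow(kg_rows) > 0) {
    kg_rows |>
      distinct(.data$chrom, .data$pos) |>
      mutate(af = round(runif(dplyr::n(), 0.01, 0.3), 4))
  } else {
    tibble(chrom = character(0), pos = double(0), af = double(0))
  }

  np_rows <- pick_type("normal_pool")
  np1 <- if (nrow(np_rows) > 0) {
    np_rows |>
      distinct(.data$chrom, .data$pos) |>
      mutate(
        pool_vaf = round(runif(dplyr::n(), 0.1, 0.5), 3),
        n_normals = sample(7:120, dplyr::n(), replace = TRUE),
        fraction_breast = round(runif(dplyr::n(), 0.06, 0.5), 3),
        fraction_blood = round(runif(dplyr::n(), 0.02, 0.3), 3)
      )
  } else {
    tibble(chrom = character(0), pos = double(0), pool_vaf = double(0),
           n_normals = integer(0), fraction_breast = double(0),
           fraction_blood = double(0))
  }
  res_rows <- pick_type("rescued_normal_pool")
  np2 <- if (nrow(res_rows) > 0) {
    res_rows |>
      distinct(.data$chrom, .data$pos) |>
      mutate(
        pool_vaf = round(runif(dplyr::n(), 0.1, 0.3), 3),
        n_normals = sample(1:6, dplyr::n(), replace = TRUE),
        fraction_breast = round(runif(dplyr::n(), 0.001, 0.04), 3),
        fraction_blood = round(runif(dplyr::n(), 0.0, 0.009), 4)
      )
  } else {
    np1[0, ]
  }
  normal_pool <- bind_rows(np1, np2)

  repeat_intervals <- tibble(
    chrom = paste0("chr", 1:22),
    start = 1e6, end = 2.5e6
  )
  microsat_intervals <- tibble(
    chrom = paste0("chr", 1:22),
    start = 2.5e6 + 1, end = 3e6
  )
  homopolymers <- tibble(
    chrom = paste0("chr", 1:22),
    start = 3e6 + 1, end = 4e6, run_length = 6L
  )

  list(
    cosmic = cosmic,
    kg_af = kg_af,
    normal_pool = normal_pool,
    clinvar = tibble(chrom = character(0), pos = double(0),
                     significance = character(0), origin = character(0)),
    provean = tibble(chrom = character(0), pos = double(0),
                     call = character(0)),
    repeat_intervals = repeat_intervals,
    microsatellite_intervals = microsat_intervals,
    homopolymers = homopolymers
  )
}

# clinical covariates, marker expression and survival outcomes
sim_clinical <- function(samples, all_rows, panel, config) {
  n <- nrow(samples)
  age <- pmin(95, pmax(25, round(rnorm(n, 61, 13))))
  grade <- sample(1:3, n, replace = TRUE, prob = c(0.2, 0.45, 0.35))
  size <- round(stats::rlnorm(n, log(24), 0.5), 1)
  node <- runif(n) < 0.45

  # per-sample functional-mutation indicators for genes with survival effects
  hr_genes <- panel$gene[panel$log_hr != 0]
  mut_mat <- matrix(0, nrow = n, ncol = length(hr_genes),
                    dimnames = list(samples$sample, hr_genes))
  if (nrow(all_rows) > 0 && length(hr_genes) > 0) {
    carriers <- all_rows |>
      filter(!.data$is_artefact, .data$gene %in% hr_genes,
             .data$consequence %in% scoreable_consequences) |>
      distinct(.data$sample, .data$gene)
    if (nrow(carriers) > 0) {
      mut_mat[cbind(match(carriers$sample, samples$sample),
                    match(carriers$gene, hr_genes))] <- 1
    }
  }
  covs <- cbind(
    age = as.numeric(age >= 55),
    size = as.numeric(size >= 50),
    node = as.numeric(node),
    grade = as.numeric(grade == 3),
    mut_mat
  )
  betas <- c(config$covariate_log_hrs,
             setNames(panel$log_hr[match(hr_genes, panel$gene)], hr_genes))
  surv <- simulate_survival(covs, betas, config$baseline_hazard,
                            config$censor_rate, config$admin_censor_months)

  censored_cause <- sample(c("alive", "other", "unknown"), n, replace = TRUE,
                           prob = c(0.80, 0.15, 0.05))
  death_cause <- if_else(surv$event == 1, "breast", censored_cause)

  er_pos <- samples$true_er == "pos"
  flip <- runif(n) < 0.03
  er_ihc <- if_else(xor(er_pos, flip), "pos", "neg")
  er_ihc[runif(n) < 0.08] <- NA_character_
  her2_pos <- runif(n) < 0.15
  her2_flip <- runif(n) < 0.03
  her2_ihc <- if_else(xor(her2_pos, her2_flip), "pos", "neg")
  her2_ihc[runif(n) < 0.08] <- NA_character_

  intclust <- character(n)
  intclust[er_pos] <- sample(c("1", "2", "3", "4+", "6", "7", "8", "9"),
                             sum(er_pos), replace = TRUE,
                             prob = c(0.1, 0.06, 0.18, 0.12, 0.06, 0.14,
                                      0.18, 0.16))
  intclust[!er_pos] <- sample(c("4-", "5", "10"), sum(!er_pos),
                              replace = TRUE, prob = c(0.3, 0.3, 0.4))

  histology <- sample(histology_levels, n, replace = TRUE,
                      prob = c(0.72, 0.12, 0.05, 0.04, 0.02, 0.05))

  clinical <- tibble(
    sample = samples$sample,
    age_years = as.numeric(age),
    grade = as.integer(grade),
    size_mm = size,
    lymph_node_positive = node,
    er_ihc = er_ihc,
    her2_ihc = her2_ihc,
    intclust = intclust,
    histology = histology,
    followup_months = round(surv$time, 2),
    death_cause = death_cause
  )
  expression <- tibble(
    sample = samples$sample,
    esr1 = round(if_else(er_pos, rnorm(n, 2, 0.8), rnorm(n, -2, 0.8)), 4),
    erbb2 = round(if_else(her2_pos, rnorm(n, 2.5, 0.7),
                          rnorm(n, -1, 0.9)), 4)
  )
  list(clinical = validate_clinical(clinical), expression = expression)
}
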