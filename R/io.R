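#' Read a mutation table
#'
#' Reads per-sample somatic variant candidates from a MAF-like TSV (the
#' package's native dialect) or from a VCF annotated with the same fields in
#' its INFO column. Positions are 1-based. All rows are validated against the
#' variant-record invariants before being returned.
#'
#' The TSV dialect requires columns `sample`, `gene`, `chrom`, `pos`, `ref`,
#' `alt`, `class`, `consequence`, `codon`, `alt_fwd`, `alt_rev`, `ref_fwd`,
#' `ref_rev`, `quality`; optional columns `flags` (comma-separated caller
#' flags), `strand_bias_phred`, `filter_status` and `removal_reasons`
#' (semicolon-separated audit codes) are carried through.
#'
#' The VCF dialect expects one variant per record with INFO keys `SAMPLE`,
#' `GENE`, `VC`, `CSQ`, `CODON`, `ALTF`, `ALTR`, `REFF`, `REFR` and optional
#' `SB` (caller strand-bias Phred score) and `FLAGS`; the QUAL column is the
#' caller quality.
#'
#' @param path Path to the file.
#' @param dialect `"maf_tsv"` (default) or `"vcf"`.
#' @return A tibble with one validated row per candidate variant, including
#'   derived `depth` and `vaf` columns and the `filter_status` /
#'   `removal_reasons` audit columns.
#' @seealso [write_mutations()], [validate_mutations()]
#' @export
read_mutations <- function(path, dialect = c("maf_tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_format(paste0("file not found: ", path))
  }
  raw <- if (dialect == "maf_tsv") read_mutations_tsv(path) else
    read_mutations_vcf(path)
  validate_mutations(raw)
}

read_mutations_tsv <- function(path) {
  x <- suppressWarnings(readr::read_tsv(
    path,
    col_types = readr::cols(
      sample = readr::col_character(),
      gene = readr::col_character(),
      chrom = readr::col_character(),
      pos = readr::col_double(),
      ref = readr::col_character(),
      alt = readr::col_character(),
      class = readr::col_character(),
      consequence = readr::col_character(),
      codon = readr::col_integer(),
      alt_fwd = readr::col_integer(),
      alt_rev = readr::col_integer(),
      ref_fwd = readr::col_integer(),
      ref_rev = readr::col_integer(),
      quality = readr::col_double(),
      .default = readr::col_character()
    ),
    na = "NA",
    progress = FALSE
  ))
  required <- c("sample", "gene", "chrom", "pos", "ref", "alt", "class",
                "consequence", "codon", "alt_fwd", "alt_rev", "ref_fwd",
                "ref_rev", "quality")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop_format(paste0("mutation table is missing required column(s): ",
                       paste(missing, collapse = ", ")))
  }
  x <- rename(x, variant_class = "class")
  if ("strand_bias_phred" %in% names(x)) {
    x$strand_bias_phred <- as.numeric(x$strand_bias_phred)
  }
  x
}

read_mutations_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(
      sample = character(0), gene = character(0), chrom = character(0),
      pos = double(0), ref = character(0), alt = character(0),
      variant_class = character(0), consequence = character(0),
      codon = integer(0), alt_fwd = integer(0), alt_rev = integer(0),
      ref_fwd = integer(0), ref_rev = integer(0), quality = double(0)
    ))
  }
  info_chr <- function(key) unname(vcfR::extract.info(vcf, element = key))
  info_int <- function(key) as.integer(info_chr(key))
  tibble(
    sample = info_chr("SAMPLE"),
    gene = info_chr("GENE"),
    chrom = fix$CHROM,
    pos = as.numeric(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    variant_class = info_chr("VC"),
    consequence = info_chr("CSQ"),
    codon = info_int("CODON"),
    alt_fwd = info_int("ALTF"),
    alt_rev = info_int("ALTR"),
    ref_fwd = info_int("REFF"),
    ref_rev = info_int("REFR"),
    quality = as.numeric(fix$QUAL),
    strand_bias_phred = suppressWarnings(as.numeric(info_chr("SB"))),
    flags = {
      f <- info_chr("FLAGS")
      ifelse(is.na(f), "", f)
    }
  )
}

#' Write a mutation table
#'
#' Writes the package's MAF-like TSV dialect; [read_mutations()] on the
#' result reproduces the input exactly.
#'
#' @param calls A validated mutation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutations <- function(calls, path) {
  calls <- validate_mutations(calls)
  out <- calls |>
    rename(class = "variant_class") |>
    select(
      "sample", "gene", "chrom", "pos", "ref", "alt", "class", "consequence",
      "codon", "alt_fwd", "alt_rev", "ref_fwd", "ref_rev", "quality",
      "flags", "strand_bias_phred", "filter_status", "removal_reasons"
    )
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read allele-specific copy-number segments
#'
#' Reads an ASCAT-style segment TSV (`sample`, `chrom`, `start`, `end`,
#' `nMajor`, `nMinor`; 1-based inclusive coordinates) and enforces the
#' segment invariants, including non-overlap within each sample chromosome.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `sample`, `chrom`, `start`, `end`,
#'   `n_major`, `n_minor`.
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop_format(paste0("file not found: ", path))
  x <- readr::read_tsv(
    path,
    col_types = readr::cols(
      sample = readr::col_character(),
      chrom = readr::col_character(),
      start = readr::col_double(),
      end = readr::col_double(),
      nMajor = readr::col_integer(),
      nMinor = readr::col_integer()
    ),
    na = "NA",
    progress = FALSE
  )
  missing <- setdiff(c("sample", "chrom", "start", "end", "nMajor", "nMinor"),
                     names(x))
  if (length(missing) > 0) {
    stop_format(paste0("segment table is missing required column(s): ",
                       paste(missing, collapse = ", ")))
  }
  validate_segments(rename(x, n_major = "nMajor", n_minor = "nMinor"))
}

#' @rdname read_segments
#' @param segments A validated segment tibble.
#' @export
write_segments <- function(segments, path) {
  segments <- validate_segments(segments)
  out <- rename(segments, nMajor = "n_major", nMinor = "n_minor")
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read per-sample purity and ploidy
#'
#' @param path TSV with columns `sample`, `purity`, `ploidy`.
#' @return A validated tibble; purity outside (0, 1] is rejected.
#' @export
read_purity <- function(path) {
  if (!file.exists(path)) stop_format(paste0("file not found: ", path))
  x <- readr::read_tsv(
    path,
    col_types = readr::cols(
      sample = readr::col_character(),
      purity = readr::col_double(),
      ploidy = readr::col_double()
    ),
    na = "NA",
    progress = FALSE
  )
  validate_purity(x)
}

#' @rdname read_purity
#' @param purity A validated purity tibble.
#' @export
write_purity <- function(purity, path) {
  purity <- validate_purity(purity)
  readr::write_tsv(purity, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' One row per sample with demographics, pathology, receptor IHC calls,
#' IntClust label and follow-up. Missing values are permitted for grade,
#' size, nodes, IHC and IntClust and are carried as `NA`.
#'
#' @param path TSV with columns `sample`, `age_years`, `grade`, `size_mm`,
#'   `lymph_node_positive`, `er_ihc`, `her2_ihc`, `intclust`, `histology`,
#'   `followup_months`, `death_cause` (plus optional `er_final`,
#'   `her2_final`).
#' @return A validated tibble.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop_format(paste0("file not found: ", path))
  x <- readr::read_tsv(
    path,
    col_types = readr::cols(
      sample = readr::col_character(),
      age_years = readr::col_double(),
      grade = readr::col_integer(),
      size_mm = readr::col_double(),
      lymph_node_positive = readr::col_logical(),
      er_ihc = readr::col_character(),
      her2_ihc = readr::col_character(),
      intclust = readr::col_character(),
      histology = readr::col_character(),
      followup_months = readr::col_double(),
      death_cause = readr::col_character(),
      .default = readr::col_character()
    ),
    na = "NA",
    progress = FALSE
  )
  validate_clinical(x)
}

#' @rdname read_clinical
#' @param clinical A validated clinical tibble.
#' @export
write_clinical <- function(clinical, path) {
  clinical <- validate_clinical(clinical)
  readr::write_tsv(clinical, path, na = "NA", progress = FALSE)
  invisible(path)
}
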