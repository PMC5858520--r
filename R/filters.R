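# The somatic filter cascade: coverage, germline, population-variant and
# RNA-editing-site filters, plus functional-class partitioning and the
# per-stage ledger.

#' Filter configuration
#'
#' Thresholds of the consensus/filter cascade. Defaults follow the study
#' design: SNVs must be reported by at least 3 callers, INDELs by at least
#' 2; variants need at least 10x coverage in tumor RNA and 5x coverage in
#' the matched normal.
#'
#' @param min_snv_callers,min_indel_callers caller-agreement minima
#' @param min_tumor_depth,min_normal_depth coverage thresholds (reads)
#' @param population_sites,editing_sites optional paths to BED-like site
#'   lists (see [read_bed_sites])
#' @param population_rescue_depth normal coverage required for the
#'   population-site rescue clause (see [apply_population_filter])
#' @return object of class `filter_config`
#' @export
filter_config <- function(min_snv_callers = 3, min_indel_callers = 2,
                          min_tumor_depth = 10, min_normal_depth = 5,
                          population_sites = NULL, editing_sites = NULL,
                          population_rescue_depth = 10) {
  thr <- c(min_snv_callers, min_indel_callers, min_tumor_depth,
           min_normal_depth, population_rescue_depth)
  if (any(thr < 1)) stop("all filter thresholds must be >= 1")
  structure(list(
    min_snv_callers = as.integer(min_snv_callers),
    min_indel_callers = as.integer(min_indel_callers),
    min_tumor_depth = as.integer(min_tumor_depth),
    min_normal_depth = as.integer(min_normal_depth),
    population_sites = population_sites,
    editing_sites = editing_sites,
    population_rescue_depth = as.integer(population_rescue_depth)
  ), class = "filter_config")
}

#' Start an empty filter ledger
#'
#' The ledger records, per named stage, how many variants entered and left;
#' counts are non-increasing down the cascade.
#' @return zero-row data.frame with columns `stage`, `n_in`, `n_out`
#' @export
new_filter_ledger <- function() {
  data.frame(stage = character(), n_in = integer(), n_out = integer(),
             stringsAsFactors = FALSE)
}

#' Append a stage row to a filter ledger
#' @param ledger existing ledger
#' @param stage stage name
#' @param n_in,n_out variant counts before/after
#' @export
ledger_add <- function(ledger, stage, n_in, n_out) {
  if (n_out > n_in) stop("filter stage '", stage, "' increased the variant count")
  rbind(ledger, data.frame(stage = stage, n_in = as.integer(n_in),
                           n_out = as.integer(n_out),
                           stringsAsFactors = FALSE))
}

filter_result <- function(variants, stage, n_in) {
  list(variants = variants,
       ledger = data.frame(stage = stage, n_in = as.integer(n_in),
                           n_out = nrow(variants), stringsAsFactors = FALSE))
}

#' Coverage filter
#'
#' Retains a variant iff tumor depth meets `cfg$min_tumor_depth` in the
#' required tumor samples AND normal depth meets `cfg$min_normal_depth`.
#' With `mode = "all-samples"` every tumor sample of the patient must pass
#' (the joint constraint used for heterogeneity assessment); with
#' `mode = "per-sample"` only the calling sample must. Positions absent
#' from the depth table count as depth 0 (conservative).
#'
#' @param variants variant table
#' @param depth_table long-format depth table (see [read_depth_table])
#' @param cfg [filter_config]
#' @param tumor_samples character vector of tumor sample ids to require
#'   (for `"per-sample"`, the single sample the calls came from)
#' @param normal_sample sample id of the matched normal in `depth_table`
#' @param mode `"all-samples"` or `"per-sample"`
#' @return list with `variants` (filtered) and `ledger` (one-row data.frame)
#' @export
apply_coverage_filter <- function(variants, depth_table, cfg,
                                  tumor_samples,
                                  normal_sample = "normal",
                                  mode = c("all-samples", "per-sample")) {
  mode <- match.arg(mode)
  stopifnot_variant_table(variants)
  n_in <- nrow(variants)
  if (n_in == 0) return(filter_result(variants, "coverage", 0L))
  pk <- position_key(variants)
  ok <- depth_lookup(depth_table, pk, normal_sample) >= cfg$min_normal_depth
  for (s in tumor_samples) {
    ok <- ok & (depth_lookup(depth_table, pk, s) >= cfg$min_tumor_depth)
  }
  filter_result(variants[ok, , drop = FALSE], "coverage", n_in)
}

#' Germline filter
#'
#' Removes any variant whose `(chrom, pos, ref, alt)` key appears in the
#' matched-normal (germline) call set.
#'
#' @param variants variant table
#' @param normal_vcf path to the germline VCF, or a variant table already
#'   read from it
#' @return list with `variants` and `ledger`
#' @export
apply_germline_filter <- function(variants, normal_vcf) {
  stopifnot_variant_table(variants)
  n_in <- nrow(variants)
  germ <- if (is.character(normal_vcf)) {
    read_caller_vcf(normal_vcf, "normal")
  } else normal_vcf
  keep <- !(variant_key(variants) %in% variant_key(germ))
  filter_result(variants[keep, , drop = FALSE], "germline", n_in)
}

#' Population-variant filter
#'
#' A variant at a known population-polymorphism site is removed, unless the
#' matched normal has at least `cfg$population_rescue_depth` coverage at the
#' position and no variant call there — adequate normal coverage with no
#' germline call is evidence the site is genuinely somatic in this patient,
#' which rescues it. When normal depth at a population site is missing the
#' variant is removed (no rescue without evidence).
#'
#' Matching is allele-aware when the site list carries `ref`/`alt` columns,
#' otherwise by position.
#'
#' @param variants variant table
#' @param population_sites data.frame from [read_bed_sites], or a path
#' @param depth_table long-format depth table covering the normal sample
#' @param germline_calls variant table of normal-sample calls (used for the
#'   "no variant detected" clause); `NULL` means no calls
#' @param cfg [filter_config]
#' @param normal_sample sample id of the normal in `depth_table`
#' @return list with `variants` and `ledger`
#' @export
apply_population_filter <- function(variants, population_sites, depth_table,
                                    germline_calls = NULL,
                                    cfg = filter_config(),
                                    normal_sample = "normal") {
  stopifnot_variant_table(variants)
  n_in <- nrow(variants)
  if (is.character(population_sites)) {
    population_sites <- read_bed_sites(population_sites)
  }
  if (n_in == 0 || is.null(population_sites) || nrow(population_sites) == 0) {
    return(filter_result(variants, "population", n_in))
  }
  allele_aware <- all(c("ref", "alt") %in% names(population_sites))
  at_site <- if (allele_aware) {
    variant_key(variants) %in% variant_key(population_sites)
  } else {
    position_key(variants) %in% position_key(population_sites)
  }
  pk <- position_key(variants)
  nd <- depth_lookup(depth_table, pk, normal_sample)
  germ_pos <- if (is.null(germline_calls)) character() else
    position_key(germline_calls)
  rescued <- (nd >= cfg$population_rescue_depth) & !(pk %in% germ_pos)
  keep <- !at_site | rescued
  filter_result(variants[keep, , drop = FALSE], "population", n_in)
}

#' RNA-editing-site filter
#'
#' Removes variants located at known RNA-editing positions. Matching is by
#' position only, irrespective of alleles or strand.
#'
#' @param variants variant table
#' @param editing_sites data.frame from [read_bed_sites], or a path
#' @return list with `variants` and `ledger`
#' @export
apply_editing_filter <- function(variants, editing_sites) {
  stopifnot_variant_table(variants)
  n_in <- nrow(variants)
  if (is.character(editing_sites)) editing_sites <- read_bed_sites(editing_sites)
  if (n_in == 0 || is.null(editing_sites) || nrow(editing_sites) == 0) {
    return(filter_result(variants, "editing", n_in))
  }
  keep <- !(position_key(variants) %in% position_key(editing_sites))
  filter_result(variants[keep, , drop = FALSE], "editing", n_in)
}

#' Partition variants by functional class
#'
#' Routes INDELs to their own bin regardless of annotation; SNVs are split
#' into non-synonymous vs synonymous according to the (externally produced)
#' annotation table; unannotated SNVs land in `unknown`.
#'
#' @param variants variant table
#' @param annotation_table data.frame with `chrom`, `pos`, `ref`, `alt` and
#'   a `class` column (`"synonymous"` vs anything else counted as
#'   non-synonymous)
#' @return list of variant tables: `nonsynonymous`, `synonymous`, `indel`,
#'   `unknown`
#' @export
classify_and_split <- function(variants, annotation_table) {
  stopifnot_variant_table(variants)
  is_indel <- variants$kind == "INDEL"
  snv <- variants[!is_indel, , drop = FALSE]
  cls <- annotation_table$class[match(variant_key(snv),
                                      variant_key(annotation_table))]
  list(
    nonsynonymous = snv[!is.na(cls) & cls != "synonymous", , drop = FALSE],
    synonymous = snv[!is.na(cls) & cls == "synonymous", , drop = FALSE],
    indel = variants[is_indel, , drop = FALSE],
    unknown = snv[is.na(cls), , drop = FALSE]
  )
}

#' Run the full post-consensus filter cascade
#'
#' Germline, coverage, population and editing filters in order, with a
#' ledger row per stage (the cascade commutes for the key-match filters, so
#' the order only affects attribution of removals, not the result).
#'
#' @param variants consensus variant table for one sample
#' @param depth_table long-format depth table
#' @param cfg [filter_config]
#' @param tumor_samples see [apply_coverage_filter]
#' @param normal_vcf germline VCF path or variant table
#' @param population_sites,editing_sites site lists (data.frame or path),
#'   `NULL` to use `cfg` paths, stage skipped if absent
#' @param normal_sample normal sample id in `depth_table`
#' @param mode coverage mode, see [apply_coverage_filter]
#' @return list with `variants` and `ledger` (multi-row)
#' @export
apply_filter_cascade <- function(variants, depth_table, cfg, tumor_samples,
                                 normal_vcf = NULL,
                                 population_sites = cfg$population_sites,
                                 editing_sites = cfg$editing_sites,
                                 normal_sample = "normal",
                                 mode = "all-samples") {
  ledger <- new_filter_ledger()
  germ <- NULL
  if (!is.null(normal_vcf)) {
    germ <- if (is.character(normal_vcf)) read_caller_vcf(normal_vcf, "normal")
            else normal_vcf
    st <- apply_germline_filter(variants, germ)
    variants <- st$variants
    ledger <- rbind(ledger, st$ledger)
  }
  st <- apply_coverage_filter(variants, depth_table, cfg, tumor_samples,
                              normal_sample, mode)
  variants <- st$variants
  ledger <- rbind(ledger, st$ledger)
  if (!is.null(population_sites)) {
    st <- apply_population_filter(variants, population_sites, depth_table,
                                  germ, cfg, normal_sample)
    variants <- st$variants
    ledger <- rbind(ledger, st$ledger)
  }
  if (!is.null(editing_sites)) {
    st <- apply_editing_filter(variants, editing_sites)
    variants <- st$variants
    ledger <- rbind(ledger, st$ledger)
  }
  list(variants = variants, ledger = ledger)
}
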