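#' @keywords internal
#' @useDynLib clonalspread, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

#' Variant keys
#'
#' A variant is identified throughout the package by the string
#' `chrom:pos:ref:alt` (1-based position, left-normalized alleles).
#'
#' @param x data frame with columns `chrom`, `pos`, `ref`, `alt`
#' @return character vector of keys
#' @export
variant_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

#' Position keys (`chrom:pos`), used for allele-agnostic site matching
#' @param x data frame with columns `chrom`, `pos`
#' @return character vector
#' @export
position_key <- function(x) {
  paste(x$chrom, x$pos, sep = ":")
}

#' Round half away from zero
#'
#' `base::round` rounds half to even; published percentage tables use
#' conventional half-up rounding, so sharing percents go through this.
#'
#' @param x numeric
#' @param digits decimal places
#' @return numeric
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Empty variant table with the canonical column set
#' @return zero-row data.frame
#' @keywords internal
empty_variant_table <- function() {
  data.frame(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), kind = character(), callers = character(),
    tumor_depth = integer(), tumor_alt_depth = integer(),
    normal_depth = integer(), vaf = numeric(),
    stringsAsFactors = FALSE
  )
}

stopifnot_variant_table <- function(x, arg = "variants") {
  need <- c("chrom", "pos", "ref", "alt")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stop(sprintf("`%s` must be a data frame with columns %s", arg,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Read a BED-like site list
#'
#' Three-column BED (chrom, start, end; 0-based half-open), optionally with
#' `ref`/`alt` columns 4-5 for allele-aware matching. Returns one row per
#' covered 1-based position.
#'
#' @param path TSV file, no header; lines starting with `#` ignored
#' @return data.frame with `chrom`, `pos` and, when present, `ref`, `alt`
#' @export
read_bed_sites <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(raw) < 3) stop("site list must have at least 3 BED columns")
  n_per <- raw[[3]] - raw[[2]]
  if (any(n_per < 1)) stop("BED intervals must have end > start")
  out <- data.frame(
    chrom = rep(as.character(raw[[1]]), n_per),
    pos = unlist(Map(function(s, e) seq.int(s + 1L, e), raw[[2]], raw[[3]])),
    stringsAsFactors = FALSE
  )
  if (ncol(raw) >= 5) {
    out$ref <- rep(as.character(raw[[4]]), n_per)
    out$alt <- rep(as.character(raw[[5]]), n_per)
  }
  out
}

#' Write a BED-like site list (one interval per 1-based position)
#' @param sites data.frame with `chrom`, `pos` (+ optional `ref`, `alt`)
#' @param path output file
#' @keywords internal
write_bed_sites <- function(sites, path) {
  bed <- data.frame(sites$chrom, sites$pos - 1L, sites$pos)
  if (!is.null(sites$ref)) {
    bed$ref <- sites$ref
    bed$alt <- sites$alt
  }
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a long-format depth table
#'
#' Expected columns: `chrom`, `pos` (1-based), `sample`, `depth`.
#'
#' @param path TSV with header
#' @return data.frame
#' @export
read_depth_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "sample", "depth")
  if (!all(need %in% names(d))) {
    stop("depth table needs columns: ", paste(need, collapse = ", "))
  }
  d
}

#' Depth lookup: depth for (position key, sample), 0 when absent
#' @keywords internal
depth_lookup <- function(depth_table, pos_keys, sample) {
  sub <- depth_table[depth_table$sample == sample, , drop = FALSE]
  idx <- match(pos_keys, position_key(sub))
  out <- sub$depth[idx]
  out[is.na(out)] <- 0L
  out
}
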