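# Concatenated-SNV pseudo-alignments: construction from a mutation matrix
# and FASTA/relaxed-PHYLIP IO.

#' Build a concatenated-SNV pseudo-alignment
#'
#' One column per retained SNV: a tumor sample carries the alternate base
#' where the variant was called in it and the reference base otherwise; the
#' normal taxon carries the reference base at every column. Variants with
#' multi-character alleles (INDELs) are excluded — the alignment is
#' strictly over \{A,C,G,T\}.
#'
#' @param matrix a [build_mutation_matrix] result (restricted to fully
#'   covered positions by construction)
#' @param normal_label taxon name for the all-reference normal row
#' @return object of class `pseudo_alignment`: list with `taxa`, `chars`
#'   (taxa-by-columns character matrix) and `variants` (column metadata)
#' @export
build_pseudoalignment <- function(matrix, normal_label = "normal") {
  snv <- matrix$variants$kind == "SNV" &
    nchar(matrix$variants$ref) == 1 & nchar(matrix$variants$alt) == 1
  n_dropped <- sum(!snv)
  if (n_dropped > 0) {
    message(n_dropped, " non-SNV variant(s) excluded from the pseudo-alignment")
  }
  vars <- matrix$variants[snv, , drop = FALSE]
  if (nrow(vars) == 0) stop("no SNVs available: empty alignment")
  pres <- matrix$presence[snv, , drop = FALSE]

  taxa <- c(normal_label, matrix$samples)
  chars <- base::matrix(rep(vars$ref, each = length(taxa)),
                        nrow = length(taxa),
                        dimnames = list(taxa, vars$key))
  for (s in matrix$samples) {
    chars[s, pres[, s]] <- vars$alt[pres[, s]]
  }
  structure(list(taxa = taxa, chars = chars, variants = vars),
            class = "pseudo_alignment")
}

#' Construct a pseudo-alignment directly from a character matrix
#' @param chars taxa-by-columns character matrix over A,C,G,T with taxon
#'   rownames
#' @return `pseudo_alignment`
#' @export
as_pseudoalignment <- function(chars) {
  if (is.null(rownames(chars))) stop("character matrix needs taxon rownames")
  structure(list(taxa = rownames(chars), chars = chars, variants = NULL),
            class = "pseudo_alignment")
}

#' @export
print.pseudo_alignment <- function(x, ...) {
  cat("pseudo_alignment:", length(x$taxa), "taxa x", ncol(x$chars),
      "SNV columns\n")
  invisible(x)
}

#' Write a pseudo-alignment as FASTA
#' @param aln `pseudo_alignment`
#' @param path output file
#' @export
write_alignment_fasta <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tx in aln$taxa) {
    writeLines(c(paste0(">", tx), paste(aln$chars[tx, ], collapse = "")), con)
  }
  invisible(path)
}

#' Write a pseudo-alignment as relaxed PHYLIP
#' @param aln `pseudo_alignment`
#' @param path output file
#' @export
write_alignment_phylip <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(length(aln$taxa), ncol(aln$chars)), con)
  for (tx in aln$taxa) {
    writeLines(paste(tx, paste(aln$chars[tx, ], collapse = "")), con)
  }
  invisible(path)
}

#' Read a FASTA alignment into a pseudo-alignment
#' @param path FASTA file
#' @return `pseudo_alignment`
#' @export
read_alignment_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop("no FASTA records in ", path)
  taxa <- sub("^>\\s*", "", lines[hdr])
  ends <- c(hdr[-1] - 1, length(lines))
  seqs <- vapply(seq_along(hdr), function(i)
    paste(lines[(hdr[i] + 1):ends[i]], collapse = ""), character(1))
  chars <- t(vapply(seqs, function(s) strsplit(toupper(s), "")[[1]],
                    character(nchar(seqs[1]))))
  rownames(chars) <- taxa
  as_pseudoalignment(chars)
}
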