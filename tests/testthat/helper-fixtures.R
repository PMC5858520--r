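# Shared fixture builders: variant tables, VCF text, alignments simulated
# under a substitution model.

make_variants <- function(pos, ref = "A", alt = "G", chrom = "chr1",
                          kind = NULL, tumor_depth = 50L,
                          tumor_alt_depth = 15L, callers = "c1") {
  n <- length(pos)
  ref <- rep_len(ref, n)
  alt <- rep_len(alt, n)
  kind <- kind %||% ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV", "INDEL")
  td <- rep_len(tumor_depth, n)
  tad <- rep_len(tumor_alt_depth, n)
  data.frame(
    chrom = rep_len(chrom, n), pos = as.integer(pos), ref = ref, alt = alt,
    kind = rep_len(kind, n), callers = rep_len(callers, n),
    tumor_depth = td, tumor_alt_depth = tad,
    normal_depth = rep(NA_integer_, n), vaf = tad / td,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_test_vcf <- function(records, path, sample = "TUMOR") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="AD">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="DP">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  writeLines(c(hdr, records), path)
  path
}

# simulate characters column-by-column under a model down a tree
sim_chars_under_model <- function(tree, ncol, model) {
  tr <- stats::reorder(ape::unroot(tree), "postorder")
  nt <- length(tr$tip.label)
  root <- tr$edge[nrow(tr$edge), 1]
  P_edge <- lapply(seq_len(nrow(tr$edge)), function(k)
    transition_prob(model, tr$edge.length[k]))
  out <- matrix("", nt, ncol, dimnames = list(tr$tip.label, NULL))
  for (col in seq_len(ncol)) {
    st <- integer(nt + tr$Nnode)
    st[root] <- sample(4, 1, prob = model$pi)
    for (k in rev(seq_len(nrow(tr$edge)))) {
      st[tr$edge[k, 2]] <- sample(4, 1, prob = P_edge[[k]][st[tr$edge[k, 1]], ])
    }
    out[, col] <- c("A", "C", "G", "T")[st[seq_len(nt)]]
  }
  out
}

make_depth_table <- function(pos, samples, depth, chrom = "chr1") {
  do.call(rbind, lapply(samples, function(s)
    data.frame(chrom = chrom, pos = as.integer(pos), sample = s,
               depth = as.integer(rep_len(depth, length(pos))),
               stringsAsFactors = FALSE)))
}
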