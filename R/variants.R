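# Consensus somatic-variant layer: VCF ingestion, allele normalization,
# multi-caller intersection.

#' Left-normalize a variant representation
#'
#' Trims shared suffix bases, then shared prefix bases (keeping at least one
#' base on each allele and advancing `pos` past trimmed prefix), so that the
#' same INDEL emitted with different padding by different callers maps to a
#' single `(chrom, pos, ref, alt)` key.
#'
#' @param pos 1-based position
#' @param ref,alt allele strings
#' @return list with `pos`, `ref`, `alt`
#' @export
normalize_allele <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]
    a <- a[-1]
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

#' Read one caller's VCF into a variant table
#'
#' Thin layer over [vcfR::read.vcfR]. Multi-allelic records are split into
#' one row per alternate allele; alleles are left-normalized; depths are
#' taken from the first sample column's `AD`/`DP` FORMAT fields when
#' present, otherwise from INFO `DP`, otherwise left `NA` (the variant is
#' retained with depths marked unknown). Duplicate keys keep the
#' highest-`DP` record.
#'
#' @param path VCF 4.x file
#' @param caller_id identifier recorded in the `callers` column
#' @return variant table (data.frame): `chrom`, `pos`, `ref`, `alt`,
#'   `kind` (`"SNV"`/`"INDEL"`), `callers`, `tumor_depth`,
#'   `tumor_alt_depth`, `normal_depth` (`NA`; filled later), `vaf`
#' @export
read_caller_vcf <- function(path, caller_id) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- vcfR::getFIX(v)
  if (!is.matrix(fix)) fix <- t(fix)   # single records drop to a vector
  if (is.null(fix) || nrow(fix) == 0) return(empty_variant_table())
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)

  has_gt <- ncol(v@gt) >= 2
  ad <- if (has_gt) tryCatch(
    vcfR::extract.gt(v, element = "AD")[, 1],
    error = function(e) rep(NA_character_, nrow(fix))) else
      rep(NA_character_, nrow(fix))
  dp <- if (has_gt) tryCatch(
    suppressWarnings(as.integer(vcfR::extract.gt(v, element = "DP")[, 1])),
    error = function(e) rep(NA_integer_, nrow(fix))) else
      rep(NA_integer_, nrow(fix))
  info_dp <- suppressWarnings(as.integer(vcfR::extract.info(v, "DP")))
  dp[is.na(dp)] <- info_dp[is.na(dp)]

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ads <- if (!is.na(ad[i])) {
      suppressWarnings(as.integer(strsplit(ad[i], ",", fixed = TRUE)[[1]]))
    } else NULL
    sub <- vector("list", length(alts))
    for (j in seq_along(alts)) {
      norm <- normalize_allele(as.integer(fix$POS[i]), fix$REF[i], alts[j])
      alt_d <- if (!is.null(ads) && length(ads) >= j + 1) ads[j + 1] else
        NA_integer_
      d <- dp[i]
      if (is.na(d) && !is.null(ads)) d <- sum(ads, na.rm = TRUE)
      sub[[j]] <- data.frame(
        chrom = fix$CHROM[i], pos = norm$pos, ref = norm$ref,
        alt = norm$alt,
        kind = if (nchar(norm$ref) == 1 && nchar(norm$alt) == 1) "SNV"
               else "INDEL",
        callers = caller_id,
        tumor_depth = d, tumor_alt_depth = alt_d,
        normal_depth = NA_integer_,
        vaf = if (!is.na(d) && d > 0 && !is.na(alt_d)) alt_d / d else
          NA_real_,
        stringsAsFactors = FALSE
      )
    }
    rows[[i]] <- do.call(rbind, sub)
  }
  out <- do.call(rbind, rows)
  # duplicate keys (e.g. normalization collisions): keep max depth
  ord <- order(variant_key(out), -ifelse(is.na(out$tumor_depth), -1,
                                         out$tumor_depth))
  out <- out[ord, , drop = FALSE]
  out <- out[!duplicated(variant_key(out)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect per-caller variant sets into consensus calls
#'
#' A variant key is kept iff it was reported by at least `min_callers`
#' distinct callers. Depth fields come from the reporting record with the
#' highest tumor depth (stable across caller orderings); `callers` is the
#' sorted union of reporting callers.
#'
#' @param call_sets list of variant tables (one per caller, from
#'   [read_caller_vcf])
#' @param min_callers minimum number of callers that must agree
#' @return consensus variant table
#' @export
intersect_calls <- function(call_sets, min_callers) {
  if (min_callers > length(call_sets)) {
    stop("min_callers (", min_callers, ") exceeds number of call sets (",
         length(call_sets), ")")
  }
  all <- do.call(rbind, lapply(seq_along(call_sets), function(i) {
    x <- call_sets[[i]]
    stopifnot_variant_table(x)
    if (nrow(x) == 0) return(NULL)
    x$.set <- i
    x[!duplicated(variant_key(x)), , drop = FALSE]
  }))
  if (is.null(all) || nrow(all) == 0) return(empty_variant_table())
  key <- variant_key(all)
  support <- tapply(all$.set, key, function(s) length(unique(s)))
  keep_keys <- names(support)[support >= min_callers]
  if (length(keep_keys) == 0) return(empty_variant_table())
  sub <- all[key %in% keep_keys, , drop = FALSE]
  skey <- variant_key(sub)
  # representative record per key: max tumor depth, NA last
  d <- ifelse(is.na(sub$tumor_depth), -1, sub$tumor_depth)
  ord <- order(skey, -d)
  sub <- sub[ord, , drop = FALSE]
  skey <- skey[ord]
  rep_rows <- sub[!duplicated(skey), , drop = FALSE]
  caller_union <- tapply(sub$callers, skey, function(cl)
    paste(sort(unique(unlist(strsplit(cl, ",", fixed = TRUE)))),
          collapse = ","))
  rep_rows$callers <- as.character(caller_union[variant_key(rep_rows)])
  rep_rows$.set <- NULL
  rep_rows <- rep_rows[order(rep_rows$chrom, rep_rows$pos, rep_rows$ref,
                             rep_rows$alt), , drop = FALSE]
  rownames(rep_rows) <- NULL
  rep_rows
}

#' Consensus calling for SNVs and INDELs with separate caller minima
#'
#' SNVs require agreement of `min_snv_callers` among the SNV callers;
#' INDELs require `min_indel_callers` among the INDEL-capable callers.
#'
#' @param snv_sets list of per-caller variant tables used for SNV consensus
#' @param indel_sets list of per-caller tables used for INDEL consensus
#'   (default: `snv_sets`)
#' @param cfg a [filter_config]
#' @return consensus variant table (SNVs and INDELs combined)
#' @export
consensus_calls <- function(snv_sets, indel_sets = snv_sets, cfg = filter_config()) {
  snv <- if (length(snv_sets) >= cfg$min_snv_callers) {
    intersect_calls(lapply(snv_sets, function(x)
      x[x$kind == "SNV", , drop = FALSE]), cfg$min_snv_callers)
  } else empty_variant_table()
  ind <- if (length(indel_sets) >= cfg$min_indel_callers) {
    intersect_calls(lapply(indel_sets, function(x)
      x[x$kind == "INDEL", , drop = FALSE]), cfg$min_indel_callers)
  } else empty_variant_table()
  out <- rbind(snv, ind)
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}
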