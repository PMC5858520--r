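# Clonal-evolution simulator: ground-truthed cohorts with the sampling
# design of the study (per patient: 3 ovary + 3 omentum + 3 bowel tumor
# regions and a matched normal), binomial read counts from clone mixtures,
# and caller-specific false-positive/-negative noise.

SIM_CALLERS <- c("mutect2", "snpir", "rvboost")

#' Simulator configuration
#'
#' Defaults encode the study conditions the package is designed around:
#' four patients with nine tumor regions each (three per anatomical site),
#' a truncal mutation load shared by all regions, site-structured
#' subclones, negative-binomial RNA-seq-like coverage (mean 100x,
#' dispersion 5) and modest caller noise.
#'
#' @param n_patients number of patients
#' @param samples_per_site tumor regions per anatomical site
#' @param sites anatomical sites
#' @param n_clones clone nodes below the normal root (>= 2)
#' @param n_mutations somatic mutations per patient
#' @param truncal_fraction fraction of mutations on the trunk (clone B)
#' @param scenario `"early_divergence"` (an ancestral clone, direct child
#'   of the root, colonizes the peritoneal sites) or `"late_divergence"`
#'   (peritoneal sites carry only late leaf clones)
#' @param depth_mean,depth_dispersion negative-binomial coverage parameters
#' @param fp_rate per-caller false-positive probability per decoy site
#'   (scalar or named vector over callers)
#' @param fn_rate per-caller false-negative probability per true record
#' @param germline_site_count,population_site_count,editing_site_count,decoy_site_count
#'   sizes of the nuisance-site pools
#' @param seed integer seed; all randomness derives from it
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_patients = 4, samples_per_site = 3,
                       sites = c("ovary", "omentum", "bowel"),
                       n_clones = 4, n_mutations = 130,
                       truncal_fraction = 0.4,
                       scenario = c("early_divergence", "late_divergence"),
                       depth_mean = 100, depth_dispersion = 5,
                       fp_rate = 0.02, fn_rate = 0.05,
                       germline_site_count = 30,
                       population_site_count = 20,
                       editing_site_count = 10,
                       decoy_site_count = 60,
                       seed = 1) {
  scenario <- match.arg(scenario)
  if (n_clones < 2) stop("n_clones must be >= 2")
  if (truncal_fraction <= 0 || truncal_fraction > 1) {
    stop("truncal_fraction must be in (0, 1]")
  }
  if (length(fp_rate) == 1) fp_rate <- stats::setNames(rep(fp_rate, 3), SIM_CALLERS)
  if (length(fn_rate) == 1) fn_rate <- stats::setNames(rep(fn_rate, 3), SIM_CALLERS)
  rates <- c(fp_rate, fn_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  structure(as.list(environment()), class = "sim_config")
}

sample_names_for <- function(cfg) {
  prefix <- c(ovary = "Ov", omentum = "Om", bowel = "Bw")[cfg$sites]
  nm <- unlist(lapply(seq_along(cfg$sites), function(i)
    paste0(prefix[i], seq_len(cfg$samples_per_site))))
  sites <- rep(cfg$sites, each = cfg$samples_per_site)
  stats::setNames(sites, nm)
}

# Clone topology + role bookkeeping for one patient. B is the trunk; C the
# ovarian-lineage clone shared by all ovarian samples; D the
# metastasis-founding clone — a direct child of B under early divergence,
# but a descendant of an ovarian-sample-private subclone (the last extra,
# when present) under late divergence, so that late-divergent peritoneal
# samples nest inside the ovarian radiation of the sample tree; remaining
# clones are ovarian-sample-private children of C.
sim_clone_tree <- function(cfg) {
  K <- cfg$n_clones
  labels <- LETTERS[seq_len(K + 1)]          # A + K clones
  parent <- stats::setNames(rep("", K + 1), labels)
  parent["B"] <- "A"
  ovarian_clone <- peritoneal_clone <- NULL
  if (K >= 2) {
    parent["C"] <- "B"
    ovarian_clone <- "C"
  }
  extras <- if (K >= 4) labels[5:(K + 1)] else character(0)
  for (e in extras) parent[e] <- "C"
  if (K >= 3) {
    peritoneal_clone <- "D"
    parent["D"] <- if (cfg$scenario == "early_divergence") "B" else {
      if (length(extras) > 0) extras[length(extras)] else "C"
    }
  }
  list(labels = labels, parent = parent, ovarian_clone = ovarian_clone,
       peritoneal_clone = peritoneal_clone, extras = extras)
}

#' Simulate ground truth for a cohort
#'
#' Draws, per patient, a clone tree (normal root A with founder trunk B),
#' mutation-to-clone assignments with a designated truncal TP53-like
#' mutation, and per-sample clone-frequency simplexes following the
#' scenario: under early divergence every peritoneal (omentum/bowel)
#' sample carries the ancestral clone B — a direct child of A — at
#' frequency >= 0.2 while ovarian samples exclude it; under late
#' divergence peritoneal samples carry only leaf-clone mass. True VAFs are
#' half the carrying clone's subtree prevalence. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg a [sim_config]
#' @return object of class `sim_truth`: `cfg` plus `patients`, each with
#'   `clone_parent`, `mutations`, `freqs` (clones incl. A x samples),
#'   `prevalence`, `true_vaf`, `samples`, `sites`
#' @export
simulate_truth <- function(cfg) {
  set.seed(cfg$seed)
  sites <- sample_names_for(cfg)
  samples <- names(sites)
  patients <- lapply(seq_len(cfg$n_patients), function(p) {
    topo <- sim_clone_tree(cfg)
    K <- cfg$n_clones
    clones <- topo$labels[-1]

    n_truncal <- max(1L, round(cfg$truncal_fraction * cfg$n_mutations))
    rest <- cfg$n_mutations - n_truncal
    others <- setdiff(clones, "B")
    assign <- c(rep("B", n_truncal),
                if (rest > 0 && length(others) > 0)
                  others[(seq_len(rest) - 1L) %% length(others) + 1L]
                else rep("B", rest))
    pos <- sort(sample.int(2e6, cfg$n_mutations +
                             cfg$germline_site_count +
                             cfg$decoy_site_count +
                             cfg$editing_site_count + 50))
    mut_pos <- pos[seq_len(cfg$n_mutations)]
    aux_pos <- pos[-seq_len(cfg$n_mutations)]
    ref <- sample(NUC, cfg$n_mutations, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(NUC, r), 1), character(1))
    cls <- ifelse(stats::runif(cfg$n_mutations) < 0.7,
                  "nonsynonymous", "synonymous")
    cls[1] <- "nonsynonymous"
    gene <- sprintf("GENE%04d", seq_len(cfg$n_mutations))
    gene[1] <- "TP53"
    mutations <- data.frame(
      chrom = "chr1", pos = mut_pos, ref = ref, alt = alt, kind = "SNV",
      clone = assign, gene = gene, class = cls,
      cosmic = c(TRUE, rep(FALSE, cfg$n_mutations - 1)),
      stringsAsFactors = FALSE
    )
    mutations$key <- variant_key(mutations)

    freqs <- matrix(0, K + 1, length(samples),
                    dimnames = list(topo$labels, samples))
    jit <- function(x, a = 0.03) pmax(0, x + stats::runif(1, -a, a))
    ov_i <- 0
    for (s in samples) {
      f <- stats::setNames(rep(0, K + 1), topo$labels)
      if (sites[[s]] == "ovary") {
        ov_i <- ov_i + 1
        oc <- topo$ovarian_clone
        if (cfg$scenario == "early_divergence") {
          f[oc] <- jit(0.5)
        } else {
          f["B"] <- jit(0.1)
          f[oc] <- jit(0.4)
        }
        if (ov_i <= length(topo$extras)) {
          f[topo$extras[ov_i]] <- jit(0.3)   # sample-private ovarian subclone
        } else {
          f[oc] <- f[oc] + 0.3
        }
      } else {
        if (cfg$scenario == "early_divergence") {
          f["B"] <- jit(0.45)          # ancestral clone, >= 0.2 by design
          pc <- topo$peritoneal_clone %||% "B"
          f[pc] <- f[pc] + jit(0.3)
        } else {
          pc <- topo$peritoneal_clone %||% topo$ovarian_clone
          f[pc] <- jit(0.7)
        }
      }
      tumor <- sum(f)
      if (tumor > 0.95) f <- f * 0.95 / tumor
      f["A"] <- 1 - sum(f)
      freqs[, s] <- f
    }

    sub <- local({
      m <- diag(K + 1) == 1
      dimnames(m) <- list(topo$labels, topo$labels)
      for (u in topo$labels[-1]) {
        anc <- topo$parent[[u]]
        while (anc != "") {
          m[anc, u] <- TRUE
          anc <- topo$parent[[anc]]
        }
      }
      m
    })
    prevalence <- (sub + 0) %*% freqs      # clones x samples subtree sums
    true_vaf <- 0.5 * prevalence[mutations$clone, , drop = FALSE]
    rownames(true_vaf) <- mutations$key

    list(patient = paste0("patient", p), samples = samples, sites = sites,
         clone_parent = topo$parent, clone_roles = topo,
         mutations = mutations, freqs = freqs, prevalence = prevalence,
         true_vaf = true_vaf, aux_pos = aux_pos)
  })
  structure(list(cfg = cfg, patients = patients), class = "sim_truth")
}

#' Simulate read counts for a cohort truth
#'
#' Per (sample, mutation): total depth is negative binomial with the
#' configured mean and dispersion; alt-supporting reads are binomial with
#' success probability the true VAF. Normal depths are drawn at every
#' variant site the same way. Deterministic given the configuration seed.
#'
#' @param truth a [simulate_truth] result
#' @param cfg a [sim_config] (defaults to the one inside `truth`)
#' @return list (per patient) with matrices `depth`, `alt`, `obs_vaf` and
#'   vector `normal_depth`
#' @export
simulate_read_counts <- function(truth, cfg = truth$cfg) {
  set.seed(cfg$seed + 1000L)
  lapply(truth$patients, function(pt) {
    nm <- nrow(pt$mutations)
    ns <- length(pt$samples)
    depth <- matrix(stats::rnbinom(nm * ns, size = cfg$depth_dispersion,
                                   mu = cfg$depth_mean),
                    nm, ns, dimnames = dimnames(pt$true_vaf))
    alt <- matrix(stats::rbinom(nm * ns, as.vector(depth),
                                as.vector(pt$true_vaf)),
                  nm, ns, dimnames = dimnames(depth))
    obs <- ifelse(depth > 0, alt / depth, 0)
    normal_depth <- stats::rnbinom(nm, size = cfg$depth_dispersion,
                                   mu = cfg$depth_mean)
    names(normal_depth) <- pt$mutations$key
    list(patient = pt$patient, depth = depth, alt = alt, obs_vaf = obs,
         normal_depth = normal_depth)
  })
}

write_variant_vcf <- function(records, path, sample_name) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  body <- if (nrow(records) == 0) character(0) else {
    ad <- paste(records$ref_depth, records$alt_depth, sep = ",")
    paste(records$chrom, records$pos, ".", records$ref, records$alt, ".",
          "PASS", ".", "GT:AD:DP",
          paste("0/1", ad, records$depth, sep = ":"), sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Emit synthetic caller VCFs, depth table and site lists
#'
#' Writes, per patient, one VCF per (tumor sample, caller) where each of
#' the three synthetic callers reports a true variant record with
#' probability `1 - fn_rate` and reports decoy (false-positive) sites with
#' probability `fp_rate`; germline variants go into the normal VCF and are
#' spiked into every tumor caller's output; population and editing site
#' lists overlap true/germline/decoy positions so the corresponding
#' filters have work to do. A long-format depth table covers every emitted
#' position in every sample plus the normal, and `truth.json` records the
#' ground truth (including, per sample, the expected consensus calls: true
#' variants with at least one alt read).
#'
#' @param truth a [simulate_truth] result
#' @param counts a [simulate_read_counts] result
#' @param cfg a [sim_config]
#' @param dir output directory (created)
#' @return named list of per-patient directories, invisibly
#' @export
emit_caller_vcfs <- function(truth, counts, cfg = truth$cfg, dir) {
  set.seed(cfg$seed + 2000L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  for (i in seq_along(truth$patients)) {
    pt <- truth$patients[[i]]
    ct <- counts[[i]]
    pdir <- file.path(dir, pt$patient)
    dir.create(pdir, showWarnings = FALSE)

    aux <- pt$aux_pos
    germ_pos <- aux[seq_len(cfg$germline_site_count)]
    aux <- aux[-seq_len(cfg$germline_site_count)]
    decoy_pos <- aux[seq_len(cfg$decoy_site_count)]
    aux <- aux[-seq_len(cfg$decoy_site_count)]
    edit_pos <- aux[seq_len(cfg$editing_site_count)]

    base_of <- function(n) sample(NUC, n, replace = TRUE)
    alt_of <- function(ref) vapply(ref, function(r)
      sample(setdiff(NUC, r), 1), character(1))
    germ <- data.frame(chrom = "chr1", pos = germ_pos,
                       ref = base_of(length(germ_pos)),
                       stringsAsFactors = FALSE)
    germ$alt <- alt_of(germ$ref)
    decoy <- data.frame(chrom = "chr1", pos = decoy_pos,
                        ref = base_of(length(decoy_pos)),
                        stringsAsFactors = FALSE)
    decoy$alt <- alt_of(decoy$ref)

    # population list: a third true somatic positions (exercises the
    # normal-coverage rescue), a third germline, a third decoys
    thirds <- ceiling(cfg$population_site_count / 3)
    pop_pos <- unique(c(
      pt$mutations$pos[seq_len(min(thirds, nrow(pt$mutations)))],
      germ_pos[seq_len(min(thirds, length(germ_pos)))],
      decoy_pos[seq_len(min(thirds, length(decoy_pos)))]
    ))
    pop_sites <- data.frame(chrom = "chr1", pos = pop_pos,
                            stringsAsFactors = FALSE)
    edit_sites <- data.frame(
      chrom = "chr1",
      pos = c(edit_pos, decoy_pos[seq_len(min(5, length(decoy_pos)))]),
      stringsAsFactors = FALSE
    )
    write_bed_sites(pop_sites, file.path(pdir, "population_sites.bed"))
    write_bed_sites(edit_sites, file.path(pdir, "editing_sites.bed"))

    # germline read counts (shared across tumor samples for simplicity of
    # the normal VCF; per-tumor-sample counts drawn below)
    germ_norm_depth <- stats::rnbinom(nrow(germ), cfg$depth_dispersion,
                                      mu = cfg$depth_mean)
    germ_norm_alt <- stats::rbinom(nrow(germ), germ_norm_depth, 0.5)
    normal_vcf <- data.frame(
      chrom = germ$chrom, pos = germ$pos, ref = germ$ref, alt = germ$alt,
      depth = germ_norm_depth,
      alt_depth = germ_norm_alt,
      ref_depth = germ_norm_depth - germ_norm_alt,
      stringsAsFactors = FALSE
    )
    write_variant_vcf(normal_vcf, file.path(pdir, "normal.vcf"), "normal")

    expected_calls <- list()
    for (s in pt$samples) {
      present <- ct$alt[, s] >= 1
      expected_calls[[s]] <- pt$mutations$key[present]
      true_rec <- data.frame(
        chrom = pt$mutations$chrom, pos = pt$mutations$pos,
        ref = pt$mutations$ref, alt = pt$mutations$alt,
        depth = ct$depth[, s],
        alt_depth = ct$alt[, s],
        ref_depth = ct$depth[, s] - ct$alt[, s],
        stringsAsFactors = FALSE
      )[present, , drop = FALSE]
      germ_depth <- stats::rnbinom(nrow(germ), cfg$depth_dispersion,
                                   mu = cfg$depth_mean)
      germ_alt <- stats::rbinom(nrow(germ), germ_depth, 0.5)
      germ_rec <- data.frame(
        chrom = germ$chrom, pos = germ$pos, ref = germ$ref, alt = germ$alt,
        depth = germ_depth, alt_depth = germ_alt,
        ref_depth = germ_depth - germ_alt, stringsAsFactors = FALSE
      )
      for (caller in SIM_CALLERS) {
        keep <- stats::runif(nrow(true_rec)) >= cfg$fn_rate[[caller]]
        fp_take <- stats::runif(nrow(decoy)) < cfg$fp_rate[[caller]]
        fp_depth <- stats::rnbinom(sum(fp_take), cfg$depth_dispersion,
                                   mu = cfg$depth_mean)
        fp_alt <- pmax(1L, stats::rbinom(sum(fp_take), fp_depth, 0.05))
        fp_rec <- data.frame(
          chrom = decoy$chrom[fp_take], pos = decoy$pos[fp_take],
          ref = decoy$ref[fp_take], alt = decoy$alt[fp_take],
          depth = fp_depth, alt_depth = fp_alt,
          ref_depth = pmax(0L, fp_depth - fp_alt),
          stringsAsFactors = FALSE
        )
        rec <- rbind(true_rec[keep, , drop = FALSE], germ_rec, fp_rec)
        rec <- rec[order(rec$pos), , drop = FALSE]
        write_variant_vcf(rec, file.path(pdir, paste0(s, ".", caller, ".vcf")),
                          s)
      }
    }

    # depth table over every emitted position x (tumor samples + normal)
    all_pos <- sort(unique(c(pt$mutations$pos, germ$pos, decoy$pos,
                             pop_sites$pos, edit_sites$pos)))
    depth_rows <- list()
    for (s in c(pt$samples, "normal")) {
      d <- stats::rnbinom(length(all_pos), cfg$depth_dispersion,
                          mu = cfg$depth_mean)
      idx <- match(pt$mutations$pos, all_pos)
      if (s == "normal") {
        d[idx] <- ct$normal_depth
      } else {
        d[idx] <- ct$depth[, s]
      }
      depth_rows[[s]] <- data.frame(chrom = "chr1", pos = all_pos,
                                    sample = s, depth = d,
                                    stringsAsFactors = FALSE)
    }
    utils::write.table(do.call(rbind, depth_rows),
                       file.path(pdir, "depths.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    ann <- pt$mutations[, c("chrom", "pos", "ref", "alt", "gene", "class",
                            "cosmic")]
    utils::write.table(ann, file.path(pdir, "annotations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    jsonlite::write_json(list(
      patient = pt$patient,
      scenario = cfg$scenario,
      sites = as.list(pt$sites),
      clone_parent = as.list(pt$clone_parent),
      mutations = pt$mutations[, c("key", "clone", "gene", "class")],
      clone_frequencies = as.data.frame(t(pt$freqs)),
      expected_calls = expected_calls
    ), file.path(pdir, "truth.json"), auto_unbox = TRUE, digits = NA)

    out[[pt$patient]] <- pdir
  }
  invisible(out)
}

#' Simulate a full cohort to disk
#'
#' Convenience wrapper: [simulate_truth] -> [simulate_read_counts] ->
#' [emit_caller_vcfs].
#'
#' @param cfg a [sim_config]
#' @param dir output directory
#' @return the `sim_truth`, invisibly, with attribute `counts`
#' @export
simulate_cohort <- function(cfg, dir) {
  truth <- simulate_truth(cfg)
  counts <- simulate_read_counts(truth, cfg)
  emit_caller_vcfs(truth, counts, cfg, dir)
  attr(truth, "counts") <- counts
  invisible(truth)
}
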