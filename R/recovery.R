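# Recovery harness: simulate -> full pipeline -> metrics against truth.

read_truth_json <- function(pdir) {
  jsonlite::read_json(file.path(pdir, "truth.json"), simplifyVector = TRUE)
}

# precision/recall of somatic consensus calls (after germline subtraction)
# against the expected per-sample calls recorded in the truth
consensus_accuracy <- function(consensus, expected_calls) {
  tp <- fp <- fn <- 0
  for (s in names(expected_calls)) {
    got <- variant_key(consensus[[s]])
    want <- unlist(expected_calls[[s]])
    tp <- tp + length(intersect(got, want))
    fp <- fp + length(setdiff(got, want))
    fn <- fn + length(setdiff(want, got))
  }
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

# RMSE between fitted clone frequencies and truth, matching fitted nodes to
# true clones by majority membership of their mutation clusters
clone_frequency_rmse <- function(fit, mut_keys, truth_mut, truth_freqs) {
  assignment <- attr(fit, "assignment")
  true_clone_of <- stats::setNames(truth_mut$clone, truth_mut$key)
  errs <- c()
  for (ci in seq_along(fit$cluster_nodes)) {
    members <- mut_keys[assignment == ci]
    tc <- true_clone_of[members]
    tc <- tc[!is.na(tc)]
    if (length(tc) == 0) next
    maj <- names(sort(table(tc), decreasing = TRUE))[1]
    fitted <- fit$freqs[fit$cluster_nodes[ci], ]
    truth_f <- truth_freqs[maj, names(fitted)]
    errs <- c(errs, fitted - truth_f)
  }
  if (length(errs) == 0) return(NA_real_)
  sqrt(mean(errs^2))
}

#' Run the simulate-analyze-score recovery suite
#'
#' For each configuration in the grid: simulate a cohort, run the full
#' pipeline, and score (a) somatic-consensus precision/recall against the
#' expected calls, (b) sample-tree topology agreement with the tree
#' implied by the noise-free truth, (c) clone-frequency RMSE after
#' matching fitted clones to true clones by mutation membership, and (d)
#' early- vs late-divergence classification accuracy.
#'
#' @param cfg_grid list of [sim_config] objects
#' @param pipeline_cfg [pipeline_config] used for every run (bootstrap is
#'   off by default here; supports are exercised separately)
#' @param metrics which of the four metric groups to compute (consensus
#'   precision/recall and scenario classification are always cheap;
#'   `"topology"` and `"clones"` add extra tree searches / fits)
#' @param out optional JSON report path
#' @return list with `runs` (per-run data.frame) and `summary`
#' @export
run_recovery_suite <- function(cfg_grid,
                               pipeline_cfg = pipeline_config(
                                 n_boot = 0L, max_nodes = 4L,
                                 model_candidates = "JC69"),
                               metrics = c("topology", "clones"),
                               out = NULL) {
  rows <- list()
  for (g in seq_along(cfg_grid)) {
    cfg <- cfg_grid[[g]]
    dir <- tempfile("simcohort")
    truth <- simulate_cohort(cfg, dir)
    for (i in seq_along(truth$patients)) {
      pt <- truth$patients[[i]]
      pdir <- file.path(dir, pt$patient)
      res <- run_patient_analysis(pdir, out_dir = NULL, cfg = pipeline_cfg)
      tj <- read_truth_json(pdir)
      acc <- consensus_accuracy(res$somatic, tj$expected_calls)

      # topology agreement: identical searches (model, starts, seed) on the
      # called presence vs the noise-free truth presence, over the variants
      # both sides retain, so disagreement reflects call noise only
      topo_match <- NA
      if ("topology" %in% metrics) {
        keys <- intersect(res$matrix$variants$key, pt$mutations$key)
        mk_chars <- function(pres) {
          ref <- pt$mutations$ref[match(keys, pt$mutations$key)]
          alt <- pt$mutations$alt[match(keys, pt$mutations$key)]
          chars <- matrix(rep(ref, each = length(pt$samples) + 1),
                          nrow = length(pt$samples) + 1,
                          dimnames = list(c("normal", pt$samples), keys))
          for (s in pt$samples) chars[s, pres[keys, s]] <- alt[pres[keys, s]]
          chars
        }
        model <- substitution_model("JC69")
        tree_data <- search_ml_tree(
          as_pseudoalignment(mk_chars(res$matrix$presence)), model,
          n_starts = 5, seed = cfg$seed + 7L)
        true_pres <- attr(truth, "counts")[[i]]$alt >= 1
        tree_truth <- search_ml_tree(
          as_pseudoalignment(mk_chars(true_pres)), model,
          n_starts = 5, seed = cfg$seed + 7L)
        topo_match <- canonical_newick(tree_data) ==
          canonical_newick(tree_truth)
      }

      rmse <- if ("clones" %in% metrics && !is.null(res$clone_fit)) {
        clone_frequency_rmse(
          res$clone_fit,
          mut_keys = attr(res$clone_fit, "mutation_keys"),
          truth_mut = pt$mutations,
          truth_freqs = pt$freqs
        )
      } else NA_real_

      classified_early <- res$divergence$peritoneal_early
      rows[[length(rows) + 1]] <- data.frame(
        grid = g, patient = pt$patient, scenario = cfg$scenario,
        seed = cfg$seed,
        precision = acc$precision, recall = acc$recall,
        topology_match = topo_match,
        clone_rmse = rmse,
        classified_early = classified_early,
        scenario_correct = classified_early ==
          (cfg$scenario == "early_divergence"),
        stringsAsFactors = FALSE
      )
    }
    unlink(dir, recursive = TRUE)
  }
  runs <- do.call(rbind, rows)
  summary <- list(
    mean_precision = mean(runs$precision, na.rm = TRUE),
    mean_recall = mean(runs$recall, na.rm = TRUE),
    topology_match_rate = mean(runs$topology_match, na.rm = TRUE),
    mean_clone_rmse = mean(runs$clone_rmse, na.rm = TRUE),
    scenario_accuracy = mean(runs$scenario_correct)
  )
  report <- list(runs = runs, summary = summary)
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA)
  }
  report
}
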