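test_that("simulated truth respects the scenario construction rules", {
  for (scen in c("early_divergence", "late_divergence")) {
    cfg <- sim_config(n_patients = 2, scenario = scen, seed = 101)
    truth <- simulate_truth(cfg)
    for (pt in truth$patients) {
      expect_equal(unname(colSums(pt$freqs)), rep(1, 9), tolerance = 1e-12)
      expect_true(all(pt$freqs >= 0))
      # truncal TP53-like mutation has positive VAF in all nine samples
      expect_true(all(pt$true_vaf[pt$mutations$gene == "TP53", ] > 0))
      peri <- names(pt$sites)[pt$sites != "ovary"]
      ov <- names(pt$sites)[pt$sites == "ovary"]
      if (scen == "early_divergence") {
        expect_true(all(pt$freqs["B", peri] >= 0.2))
        expect_true(all(pt$freqs["B", ov] == 0))
      } else {
        expect_true(all(pt$freqs["B", peri] == 0))
      }
    }
  }
  expect_error(sim_config(n_clones = 1), "n_clones")
  expect_error(sim_config(truncal_fraction = 0), "truncal_fraction")
})

test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(n_patients = 1, seed = 303)
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_identical(t1$patients[[1]]$mutations, t2$patients[[1]]$mutations)
  expect_identical(t1$patients[[1]]$freqs, t2$patients[[1]]$freqs)
  c1 <- simulate_read_counts(t1, cfg)
  c2 <- simulate_read_counts(t2, cfg)
  expect_identical(c1[[1]]$alt, c2[[1]]$alt)
})

test_that("read counts follow the binomial/negative-binomial model", {
  # hand-built truth: one sample, 1000 truncal sites at full prevalence
  cfg <- sim_config(n_patients = 1, seed = 7)
  pt <- list(patient = "patient1", samples = "s1",
             mutations = data.frame(key = sprintf("chr1:%d:A:G", 1:1000)),
             true_vaf = matrix(0.5, 1000, 1,
                               dimnames = list(sprintf("chr1:%d:A:G", 1:1000),
                                               "s1")))
  truth <- structure(list(cfg = cfg, patients = list(pt)), class = "sim_truth")
  ct <- simulate_read_counts(truth, cfg)[[1]]
  vaf_hat <- sum(ct$alt) / sum(ct$depth)
  se <- sqrt(0.25 / sum(ct$depth))
  expect_lt(abs(vaf_hat - 0.5), 3 * se)
  expect_equal(mean(ct$depth), cfg$depth_mean, tolerance = 0.1)
  # zero prevalence yields zero alt reads
  pt0 <- pt
  pt0$true_vaf[] <- 0
  truth0 <- structure(list(cfg = cfg, patients = list(pt0)),
                      class = "sim_truth")
  expect_true(all(simulate_read_counts(truth0, cfg)[[1]]$alt == 0))
})

test_that("emitted VCFs round-trip losslessly through the reader", {
  cfg <- sim_config(n_patients = 1, fp_rate = 0, fn_rate = 0,
                    n_mutations = 40, seed = 11)
  dir <- withr::local_tempdir()
  truth <- simulate_cohort(cfg, dir)
  counts <- attr(truth, "counts")[[1]]
  pt <- truth$patients[[1]]
  v <- read_caller_vcf(file.path(dir, "patient1", "Ov1.mutect2.vcf"),
                       "mutect2")
  present <- counts$alt[, "Ov1"] >= 1
  germ_n <- cfg$germline_site_count
  expect_equal(nrow(v), sum(present) + germ_n)  # true calls + germline spikes
  got <- variant_key(v)
  expect_true(all(pt$mutations$key[present] %in% got))
  # depths survive the round trip
  idx <- match(pt$mutations$key[present], got)
  expect_equal(v$tumor_depth[idx], unname(counts$depth[present, "Ov1"]))
  expect_equal(v$tumor_alt_depth[idx], unname(counts$alt[present, "Ov1"]))
})

test_that("caller noise rates are realized at their configured values", {
  cfg <- sim_config(n_patients = 1, n_mutations = 700, fp_rate = 0.1,
                    fn_rate = 0.2, decoy_site_count = 700,
                    germline_site_count = 5, seed = 19)
  dir <- withr::local_tempdir()
  truth <- simulate_cohort(cfg, dir)
  counts <- attr(truth, "counts")[[1]]
  pt <- truth$patients[[1]]
  v <- read_caller_vcf(file.path(dir, "patient1", "Ov1.mutect2.vcf"),
                       "mutect2")
  got <- variant_key(v)
  present_keys <- pt$mutations$key[counts$alt[, "Ov1"] >= 1]
  n_true <- length(present_keys)
  fn_hat <- 1 - mean(present_keys %in% got)
  expect_lt(abs(fn_hat - 0.2), 3 * sqrt(0.2 * 0.8 / n_true))
  truthy <- c(pt$mutations$key)
  germ_pos <- setdiff(got, truthy)
  # decoy reports among non-true, non-germline records
  n_fp <- length(germ_pos) - cfg$germline_site_count
  expect_lt(abs(n_fp / cfg$decoy_site_count - 0.1),
            3 * sqrt(0.1 * 0.9 / cfg$decoy_site_count))
})

test_that("noiseless callers agree and caller-minimum logic gates consensus", {
  cfg <- sim_config(n_patients = 1, fp_rate = 0, fn_rate = 0,
                    n_mutations = 30, germline_site_count = 4, seed = 23)
  dir <- withr::local_tempdir()
  truth <- simulate_cohort(cfg, dir)
  pdir <- file.path(dir, "patient1")
  sets <- lapply(c("mutect2", "snpir", "rvboost"), function(cl)
    read_caller_vcf(file.path(pdir, paste0("Om2.", cl, ".vcf")), cl))
  keys <- lapply(sets, variant_key)
  expect_identical(sort(keys[[1]]), sort(keys[[2]]))
  expect_identical(sort(keys[[1]]), sort(keys[[3]]))

  # a fully silenced caller empties min-3 consensus but not min-2
  empty <- sets[[3]][0, ]
  expect_equal(nrow(intersect_calls(list(sets[[1]], sets[[2]], empty), 3)), 0)
  expect_setequal(variant_key(intersect_calls(list(sets[[1]], sets[[2]],
                                                   empty), 2)),
                  keys[[1]])
})
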