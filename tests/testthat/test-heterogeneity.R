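cfg <- filter_config()

# small two-patient-free fixture: 3 samples, 4 variants
fix_matrix <- function(depths_ok = TRUE) {
  pos <- c(100, 200, 300, 400)
  samples <- c("Ov1", "Ov2", "Bw1")
  per <- list(
    Ov1 = make_variants(c(100, 200, 300)),
    Ov2 = make_variants(c(100, 300)),
    Bw1 = make_variants(c(100, 400))
  )
  d <- rbind(make_depth_table(pos, samples, 50),
             make_depth_table(pos, "normal", 20))
  if (!depths_ok) d$depth[d$pos == 200 & d$sample == "Bw1"] <- 3L
  build_mutation_matrix(per, d, cfg, patient = "p1")
}

test_that("mutation matrix keeps only jointly covered variant positions", {
  m <- fix_matrix()
  expect_equal(nrow(m$variants), 4)
  expect_true(all(m$presence[, "Ov1"][1:3]))
  # variant covered in 2/3 samples drops out entirely
  m2 <- fix_matrix(depths_ok = FALSE)
  expect_equal(sort(m2$variants$pos), c(100L, 300L, 400L))
  expect_true(all(m2$presence <= m2$covered))
  expect_error(build_mutation_matrix(list(a = make_variants(1)),
                                     make_depth_table(1, "a", 50), cfg),
               "at least 2")
})

test_that("mutation matrix equals a brute-force row filter", {
  set.seed(41)
  pos <- sort(sample(1e4, 80))
  samples <- paste0("s", 1:5)
  per <- lapply(samples, function(s) make_variants(sort(sample(pos, 40))))
  names(per) <- samples
  d <- do.call(rbind, lapply(c(samples, "normal"), function(s)
    data.frame(chrom = "chr1", pos = pos, sample = s,
               depth = sample(c(3, 8, 50), length(pos), replace = TRUE),
               stringsAsFactors = FALSE)))
  m <- build_mutation_matrix(per, d, cfg, sites = stats::setNames(
    rep("ovary", 5), samples))
  union_pos <- sort(unique(unlist(lapply(per, `[[`, "pos"))))
  want <- Filter(function(p) {
    ds <- stats::setNames(d$depth[d$pos == p], d$sample[d$pos == p])
    all(ds[samples] >= 10) && ds["normal"] >= 5
  }, union_pos)
  expect_setequal(m$variants$pos, want)
})

test_that("shared_fraction reproduces published-style percent arithmetic", {
  # a group with total 36 and shared 17 must print 47.22
  pos <- seq_len(36)
  shared_pos <- pos[1:17]
  per <- list(Ov1 = make_variants(pos),
              Ov2 = make_variants(c(shared_pos, 37)),
              Ov3 = make_variants(shared_pos))
  d <- rbind(make_depth_table(c(pos, 37), c("Ov1", "Ov2", "Ov3"), 50),
             make_depth_table(c(pos, 37), "normal", 20))
  m <- build_mutation_matrix(per, d, cfg)
  sf <- shared_fraction(m, c("Ov1", "Ov2", "Ov3"))
  expect_equal(sf$total, 37)
  expect_equal(sf$shared, 17)
  sf_ov <- shared_fraction(m, "ovary")
  expect_equal(sf_ov$percent, round_half_up(100 * sf_ov$shared / sf_ov$total, 2))

  # identical samples share everything
  per2 <- list(a = make_variants(pos), b = make_variants(pos))
  d2 <- rbind(make_depth_table(pos, c("a", "b"), 50),
              make_depth_table(pos, "normal", 20))
  m2 <- build_mutation_matrix(per2, d2, cfg,
                              sites = c(a = "ovary", b = "ovary"))
  expect_equal(shared_fraction(m2, c("a", "b"))$percent, 100.00)
  expect_error(shared_fraction(m2, character(0)), "empty")
})

test_that("sharing counts match brute-force column logic on random matrices", {
  set.seed(43)
  pos <- seq_len(200)
  samples <- paste0("s", 1:6)
  per <- lapply(samples, function(s) make_variants(sort(sample(pos, 120))))
  names(per) <- samples
  d <- rbind(make_depth_table(pos, samples, 50),
             make_depth_table(pos, "normal", 20))
  m <- build_mutation_matrix(per, d, cfg,
                             sites = stats::setNames(rep("ovary", 6), samples))
  grp <- samples[1:4]
  sf <- shared_fraction(m, grp)
  in_grp <- sapply(per[grp], function(v) pos %in% v$pos)
  expect_equal(sf$total, sum(rowSums(in_grp) >= 1))
  expect_equal(sf$shared, sum(rowSums(in_grp) == 4))
})

test_that("adding a sample to a group cannot increase the shared count", {
  m <- fix_matrix()
  s2 <- shared_fraction(m, c("Ov1", "Ov2"))$shared
  s3 <- shared_fraction(m, c("Ov1", "Ov2", "Bw1"))$shared
  expect_lte(s3, s2)
})

test_that("per_sample_counts returns the count table with median and range", {
  counts <- stats::setNames(c(10, 20, 30), c("a", "b", "c"))
  res <- per_sample_counts(counts)
  expect_equal(res$median, 20)
  expect_equal(per_sample_counts(c(one = 7))$median, 7)
  set.seed(47)
  x <- sample(200, 36, replace = TRUE)
  r <- per_sample_counts(x)
  expect_equal(r$median, sort(x)[18:19] |> mean())
  expect_equal(c(r$min, r$max), range(x))
})

test_that("VAF matrix export orders truncal variants first", {
  m <- fix_matrix()
  out <- vaf_matrix_export(m)
  expect_true(out$truncal[1])
  expect_equal(out$pos[1], 100L)      # present in all three samples
  expect_false(any(out$truncal[-1]))
  # absent call renders 0
  expect_equal(out[out$pos == 400, "Ov1"], 0)
  # ordering oracle: truncal desc, then carrier count
  n_present <- rowSums(m$presence)[out$key]
  expect_true(all(diff(n_present) <= 0))
})
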