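cfg <- filter_config()

test_that("filter_config validates thresholds", {
  expect_error(filter_config(min_tumor_depth = 0), ">= 1")
  expect_equal(cfg$min_snv_callers, 3L)
  expect_equal(cfg$min_indel_callers, 2L)
  expect_equal(cfg$min_tumor_depth, 10L)
  expect_equal(cfg$min_normal_depth, 5L)
})

test_that("coverage thresholds are inclusive and joint across samples", {
  v <- make_variants(c(100, 200))
  samples <- paste0("s", 1:3)
  d <- data.frame(
    chrom = "chr1",
    pos = c(100, 100, 100, 200, 200, 200, 100, 200),
    sample = c(samples, samples, "normal", "normal"),
    depth = c(12, 11, 10, 12, 9, 30, 5, 5),
    stringsAsFactors = FALSE
  )
  res <- apply_coverage_filter(v, d, cfg, samples)
  expect_equal(res$variants$pos, 100L)   # boundary 10x/5x retained, 9x removed
  expect_equal(res$ledger$n_in, 2L)
  expect_equal(res$ledger$n_out, 1L)

  # per-sample mode only requires the calling sample
  res2 <- apply_coverage_filter(v, d, cfg, "s1", mode = "per-sample")
  expect_equal(nrow(res2$variants), 2)

  # missing position counts as depth 0
  v3 <- make_variants(999)
  expect_equal(nrow(apply_coverage_filter(v3, d, cfg, samples)$variants), 0)
})

test_that("coverage filter equals a brute-force threshold scan", {
  set.seed(23)
  pos <- sample(1e4, 100)
  v <- make_variants(pos)
  samples <- paste0("s", 1:9)
  d <- do.call(rbind, lapply(c(samples, "normal"), function(s)
    data.frame(chrom = "chr1", pos = pos, sample = s,
               depth = sample(0:20, 100, replace = TRUE),
               stringsAsFactors = FALSE)))
  got <- apply_coverage_filter(v, d, cfg, samples)$variants$pos
  want <- Filter(function(p) {
    ds <- d$depth[d$pos == p]
    names(ds) <- d$sample[d$pos == p]
    all(ds[samples] >= 10) && ds["normal"] >= 5
  }, pos)
  expect_setequal(got, want)
})

test_that("germline filter removes exact key matches only", {
  v <- make_variants(c(100, 200, 300))
  expect_equal(apply_germline_filter(v, empty_germ <- make_variants(integer(0)))$variants,
               v)
  germ <- make_variants(c(100, 200))
  germ2 <- rbind(germ, make_variants(300, alt = "T"))  # same pos, other alt
  res <- apply_germline_filter(v, germ2)
  expect_equal(res$variants$pos, 300L)   # 300 A>G retained: alt differs
  expect_equal(res$ledger$n_out, 1L)
})

test_that("population filter applies the normal-coverage rescue clause", {
  v <- make_variants(c(100, 200, 300))
  sites <- data.frame(chrom = "chr1", pos = c(100, 200))
  d <- make_depth_table(c(100, 200, 300), "normal", c(15, 4, 0))
  res <- apply_population_filter(v, sites, d, germline_calls = NULL, cfg)
  # 100: at site but normal 15x and no call -> rescued; 200: 4x -> removed
  expect_setequal(res$variants$pos, c(100L, 300L))

  # a germline call at the position blocks the rescue
  res2 <- apply_population_filter(v, sites, d,
                                  germline_calls = make_variants(100), cfg)
  expect_equal(res2$variants$pos, 300L)
})

test_that("population filter matches brute-force rule application", {
  set.seed(31)
  pos <- sample(5000, 50)
  v <- make_variants(pos)
  site_pos <- sample(pos, 20)
  sites <- data.frame(chrom = "chr1", pos = site_pos)
  nd <- sample(0:20, 50, replace = TRUE)
  d <- data.frame(chrom = "chr1", pos = pos, sample = "normal", depth = nd)
  got <- apply_population_filter(v, sites, d, NULL, cfg)$variants$pos
  want <- pos[!(pos %in% site_pos) | nd >= 10]
  expect_setequal(got, want)
})

test_that("editing filter is position-only", {
  v <- make_variants(c(100, 200), ref = c("A", "C"), alt = c("G", "T"))
  expect_equal(nrow(apply_editing_filter(v, data.frame(chrom = character(),
                                                       pos = integer()))$variants), 2)
  res <- apply_editing_filter(v, data.frame(chrom = "chr1", pos = 100))
  expect_equal(res$variants$pos, 200L)
})

test_that("BED site lists round-trip through 0-based half-open intervals", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t100", "chr2\t10\t13"), path)
  sites <- read_bed_sites(path)
  expect_equal(sites$pos, c(100L, 11L, 12L, 13L))
  expect_equal(sites$chrom, c("chr1", "chr2", "chr2", "chr2"))
})

test_that("classify_and_split partitions by class with INDELs routed apart", {
  v <- rbind(make_variants(c(100, 200)),
             make_variants(300, ref = "AT", alt = "A"))
  ann <- data.frame(chrom = "chr1", pos = c(100, 300), ref = c("A", "AT"),
                    alt = c("G", "A"),
                    class = c("synonymous", "nonsynonymous"))
  parts <- classify_and_split(v, ann)
  expect_equal(parts$synonymous$pos, 100L)
  expect_equal(parts$unknown$pos, 200L)          # unannotated SNV
  expect_equal(parts$indel$pos, 300L)            # INDEL regardless of class
  expect_equal(nrow(parts$nonsynonymous), 0)
  total <- sum(vapply(parts, nrow, integer(1)))
  expect_equal(total, nrow(v))
})

test_that("filters are idempotent, commute, and the cascade is monotone", {
  set.seed(37)
  pos <- sample(5000, 60)
  v <- make_variants(pos)
  germ <- make_variants(sample(pos, 10))
  sites <- data.frame(chrom = "chr1", pos = sample(pos, 15))
  edit <- data.frame(chrom = "chr1", pos = sample(pos, 8))
  d <- data.frame(chrom = "chr1", pos = pos, sample = "normal",
                  depth = sample(0:30, 60, replace = TRUE))

  f_g <- function(x) apply_germline_filter(x, germ)$variants
  f_p <- function(x) apply_population_filter(x, sites, d, germ, cfg)$variants
  f_e <- function(x) apply_editing_filter(x, edit)$variants

  for (f in list(f_g, f_p, f_e)) {
    once <- f(v)
    expect_identical(f(once), once)              # idempotent
  }
  expect_identical(f_e(f_p(f_g(v))), f_g(f_p(f_e(v))))   # commute

  ledger <- apply_filter_cascade(
    v, rbind(d, make_depth_table(pos, paste0("s", 1:2), 50)), cfg,
    paste0("s", 1:2), normal_vcf = germ, population_sites = sites,
    editing_sites = edit
  )$ledger
  expect_true(all(diff(c(ledger$n_in[1], ledger$n_out)) <= 0))
  expect_true(all(ledger$n_out <= ledger$n_in))
  expect_error(ledger_add(new_filter_ledger(), "bad", 5, 6), "increased")
})
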