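test_that("OTU table TSV round-trips bit-identically", {
  tab <- toy_table()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(tab, f)
  back <- read_otu_table(f)
  expect_identical(unclass(back), unclass(tab))
  expect_identical(colSums(back), c(s1 = 4, s2 = 5))
  # second write is byte-identical
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("degenerate and malformed tables follow the error contract", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("#OTU ID\ts1\ts2", f)
  empty <- read_otu_table(f)
  expect_identical(dim(empty), c(0L, 2L))

  writeLines(c("#OTU ID\ts1", "dup\t1", "dup\t2"), f)
  expect_error(read_otu_table(f), "dup")
  writeLines(c("#OTU ID\ts1", "a\t-1"), f)
  expect_error(read_otu_table(f), "negative|non-integer")
  writeLines(c("#OTU ID\ts1", "a\t1.5"), f)
  expect_error(read_otu_table(f), "non-integer")
  writeLines(c("#OTU ID\ts1", "a\t1\t2"), f)
  expect_error(read_otu_table(f), "cells")
  expect_error(otu_table(matrix(1L, 1, 2), "x", c("s", "s")), "duplicate sample")
})

test_that("BIOM input is supported through biomformat", {
  m <- matrix(c(5L, 0L, 2L, 7L), 2, 2,
              dimnames = list(c("o1", "o2"), c("s1", "s2")))
  f <- withr::local_tempfile(fileext = ".biom")
  biomformat::write_biom(biomformat::make_biom(m), f)
  tab <- read_otu_table(f, format = "biom")
  expect_identical(unclass(tab)[rownames(m), colnames(m)], m)
})

test_that("relative abundances are proper per-sample proportions", {
  tab <- toy_table()
  rel <- to_relative_abundance(tab)
  expect_equal(rel[, "s1"], c(otu1 = 0.75, otu2 = 0.25))
  expect_equal(rel[, "s2"], c(otu1 = 0, otu2 = 1))

  set.seed(99)
  big <- otu_table(matrix(rpois(1000, 5), 100, 10,
                          dimnames = list(sprintf("o%03d", 1:100),
                                          sprintf("s%02d", 1:10))))
  relb <- to_relative_abundance(big)
  expect_true(all(abs(colSums(relb) - 1) < 1e-12))
  # multiplying back by the column totals reproduces the counts exactly
  expect_equal(sweep(relb, 2, colSums(big), "*"),
               unclass(big) * 1, ignore_attr = FALSE, tolerance = 1e-12)

  zero <- otu_table(matrix(c(1L, 0L), 1, 2,
                           dimnames = list("o", c("ok", "bad"))))
  expect_error(to_relative_abundance(zero), "bad")
})

test_that("rarefaction subsamples without replacement to exact depth", {
  set.seed(7)
  counts <- matrix(rpois(200, 20), 50, 4,
                   dimnames = list(sprintf("o%02d", 1:50), sprintf("s%d", 1:4)))
  tab <- otu_table(counts)
  r <- rarefy(tab, 300, seed = 5)
  expect_true(all(colSums(r) == 300))
  expect_true(all(unclass(r) <= unclass(tab)))
  # determinism
  expect_identical(unclass(rarefy(tab, 300, seed = 5)),
                   unclass(rarefy(tab, 300, seed = 5)))
  # depth == column total leaves the column unchanged
  tot <- colSums(tab)[1L]
  r_full <- rarefy(tab[, 1, drop = FALSE], tot, seed = 1)
  expect_identical(unclass(r_full)[, 1L], counts[, 1L])
  # zeros stay zero
  one <- otu_table(matrix(c(10L, 0L), 2, 1,
                          dimnames = list(c("a", "b"), "s")))
  expect_identical(as.integer(unclass(rarefy(one, 5, seed = 3))), c(5L, 0L))
  expect_error(rarefy(tab, 0), "depth")
  expect_warning(rarefy(tab, max(colSums(tab)) - 1, seed = 1), "dropping")
})

test_that("rarefaction matches the hypergeometric expectation", {
  # one 50-feature column, depth 1000: per-feature mean over 500 seeds
  # must lie within 3 SE of the hypergeometric mean depth * k / N
  set.seed(11)
  col <- as.integer(rmultinom(1, 5000, prob = runif(50) + 0.02))
  tab <- otu_table(matrix(col, 50, 1,
                          dimnames = list(sprintf("o%02d", 1:50), "s")))
  draws <- vapply(seq_len(500),
                  function(s) as.numeric(unclass(rarefy(tab, 1000, seed = s))),
                  numeric(50))
  N <- sum(col); n <- 1000
  expected <- n * col / N
  vr <- n * (col / N) * (1 - col / N) * (N - n) / (N - 1)
  se <- sqrt(vr / 500)
  keep <- se > 0
  expect_true(all(abs(rowMeans(draws)[keep] - expected[keep]) <= 3 * se[keep]))
})

test_that("sample metadata round-trips with explicit missing values", {
  b <- small_bundle()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sample_metadata(b$metadata, f)
  back <- read_sample_metadata(f)
  expect_identical(back$sample_id, b$metadata$sample_id)
  expect_identical(is.na(back$PO4), is.na(b$metadata$PO4))
  expect_equal(back$temperature, b$metadata$temperature, tolerance = 1e-6)

  # QIIME2 dialect: 'sample-id' first column and a #q2:types row
  lines <- readLines(f)
  writeLines(c(lines[1], "#q2:types\tcategorical", lines[-1]), f)
  back2 <- read_sample_metadata(f)
  expect_identical(back2$sample_id, b$metadata$sample_id)

  md_bad <- b$metadata
  md_bad$location[1] <- "lagoon"
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_sample_metadata(md_bad, f2)
  expect_error(read_sample_metadata(f2), "lagoon")
})

test_that("reactor spec validates columns and flow closure", {
  b <- small_bundle()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_reactor_spec(b$reactor, f)
  back <- read_reactor_spec(f)
  expect_equal(back$Q_in_m3d, b$reactor$Q_in_m3d)
  bad <- b$reactor
  bad$Q_eff_m3d <- bad$Q_eff_m3d * 0.5
  write_reactor_spec(bad, f)
  expect_warning(read_reactor_spec(f), "flow closure")
  bad2 <- b$reactor[, -3]
  expect_error(validate_reactor_spec <- growthseq:::validate_reactor_spec(bad2),
               "missing column")
})
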