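# Vst statistic, top-fraction selection, CNVR summary statistics

test_that("vst matches hand-computed values on worked examples", {
  split <- two_pop_split(3, 3)
  # identical diploid samples: Vtotal = 0 -> vst 0 by convention
  expect_equal(vst(rep(2, 6), split)$vst, 0)
  # fixed difference: zero within-population variance -> vst 1
  r <- vst(c(2, 2, 2, 4, 4, 4), split)
  expect_equal(r$vst, 1)
  expect_equal(r$v_pop1, 0)
  expect_equal(r$v_pop2, 0)
  # pop1 [2,2,2], pop2 [2,4,4]: Vtotal 8/9, weighted within 4/9, vst 0.5
  r2 <- vst(c(2, 2, 2, 2, 4, 4), split)
  expect_equal(r2$v_total, 8 / 9, tolerance = 1e-12)
  expect_equal((r2$v_pop1 * 3 + r2$v_pop2 * 3) / 6, 4 / 9, tolerance = 1e-12)
  expect_equal(r2$vst, 0.5, tolerance = 1e-12)
})

test_that("vst equals the between-group variance fraction (oracle, 1000 draws)", {
  set.seed(99)
  for (i in 1:1000) {
    n1 <- sample(2:10, 1)
    n2 <- sample(2:10, 1)
    cn <- c(sample(0:6, n1, TRUE), sample(0:6, n2, TRUE)) +
      rnorm(n1 + n2, sd = 0.2)
    split <- two_pop_split(n1, n2)
    v <- vst(cn, split)$vst
    # independent decomposition: between-group variance over total
    x1 <- cn[1:n1]
    x2 <- cn[(n1 + 1):(n1 + n2)]
    m <- mean(cn)
    between <- (n1 * (mean(x1) - m)^2 + n2 * (mean(x2) - m)^2) / (n1 + n2)
    vt <- mean((cn - m)^2)
    oracle <- if (vt > 0) between / vt else 0
    expect_lt(abs(v - oracle), 1e-12)
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
})

test_that("vst handles missing samples by recomputing population sizes", {
  split <- two_pop_split(4, 4)
  cn <- c(2, 2, NA, NA, 4, 4, 4, NA)
  r <- vst(cn, split)
  expect_equal(r$n_pop1, 2)
  expect_equal(r$n_pop2, 3)
  expect_equal(r$vst, 1)
  # fewer than two observed in a population -> NA record
  cn2 <- c(2, NA, NA, NA, 4, 4, 4, 4)
  expect_true(is.na(vst(cn2, split)$vst))
})

test_that("pop_split validates its inputs", {
  expect_error(pop_split(data.frame(sample = "a", population = "x")),
               "two population")
  three <- data.frame(sample = letters[1:6],
                      population = rep(c("x", "y", "z"), 2))
  expect_error(pop_split(three), "two population")
  small <- data.frame(sample = letters[1:3],
                      population = c("x", "x", "y"))
  expect_error(pop_split(small), "at least two")
})

test_that("select_top flags exactly ceil(fraction * M) records", {
  # M = 100 -> k = 1
  r100 <- data.frame(vst = runif(100))
  expect_equal(sum(select_top(r100)$selected), 1)
  # M = 250 distinct values -> k = 3, and they are the three largest
  set.seed(5)
  v <- sample(seq(0, 1, length.out = 250))
  r250 <- select_top(data.frame(vst = v))
  expect_equal(sum(r250$selected), 3)
  expect_setequal(r250$vst[r250$selected], sort(v, decreasing = TRUE)[1:3])
  expect_equal(attr(r250, "threshold"), sort(v, decreasing = TRUE)[3])
  # property: exact count for a sweep of M
  for (M in c(1, 2, 57, 99, 101, 1000)) {
    expect_equal(sum(select_top(data.frame(vst = runif(M)))$selected),
                 ceiling(0.01 * M))
  }
  expect_error(select_top(data.frame(vst = 0.5), fraction = 0), "fraction")
})

test_that("ties at the threshold break by genome position, deterministically", {
  rec <- data.frame(chrom = c("chr2", "chr1", "chr1", "chr2"),
                    start = c(100, 500, 100, 900),
                    vst = c(0.9, 0.9, 0.9, 0.9))
  out <- select_top(rec, fraction = 0.5, chrom_levels = c("chr1", "chr2"))
  expect_equal(sum(out$selected), 2)
  # chrom order then start ascending: chr1:100, chr1:500 win the tie
  expect_equal(out$selected, c(FALSE, TRUE, TRUE, FALSE))
  # permuting rows selects the same records
  perm <- c(3, 1, 4, 2)
  out2 <- select_top(rec[perm, ], fraction = 0.5,
                     chrom_levels = c("chr1", "chr2"))
  expect_equal(paste(out2$chrom, out2$start)[out2$selected],
               c("chr1 100", "chr1 500"))
  # missing vst records are never selected and do not count toward M
  rec$vst[1] <- NA
  out3 <- select_top(rec, fraction = 0.5, chrom_levels = c("chr1", "chr2"))
  expect_equal(sum(out3$selected), 2)
  expect_false(out3$selected[1])
})

test_that("cnvr_summary reports counts, sizes, coverage and correlation", {
  # counts [2,4,6] against lengths [1,2,3] Mb -> r = 1
  layout <- data.frame(chrom = c("c1", "c2", "c3"),
                       length = c(1e6, 2e6, 3e6))
  df <- data.frame(chrom = rep(c("c1", "c2", "c3"), c(2, 4, 6)),
                   start = 0, end = 3000,
                   class = rep(c("duplication", "deletion", "both"),
                               c(6, 2, 4)))
  cn <- matrix(3, 12, 2, dimnames = list(NULL, c("a", "b")))
  s <- cnvr_summary(toy_cnvr_set(df, cn), layout)
  expect_equal(s$count_length_r, 1)
  expect_equal(s$n_total, 12)
  expect_equal(sum(s$class_counts), s$n_total)
  expect_equal(unname(s$class_counts),
               c(duplication = 6, deletion = 2, both = 4), ignore_attr = TRUE)
  expect_equal(s$per_chrom$n_cnvr, c(2, 4, 6))
  # one 3000 bp CNVR on a 300 kb genome covers 1%
  one <- toy_cnvr_set(data.frame(chrom = "c1", start = 0, end = 3000),
                      matrix(3, 1, 2, dimnames = list(NULL, c("a", "b"))))
  s1 <- cnvr_summary(one, data.frame(chrom = "c1", length = 3e5))
  expect_equal(s1$coverage_fraction, 0.01)
  expect_equal(s1$mean_span_bp, 3000)
  # size histogram bins by kb
  expect_equal(sum(s$size_hist$count), 12)
  expect_equal(s$size_hist$count[s$size_hist$bin == "[2,5)"], 12)
  # empty input warns and returns an empty summary
  empty <- toy_cnvr_set(df[0, ], cn[0, , drop = FALSE])
  expect_warning(s0 <- cnvr_summary(empty, layout), "no CNVR")
  expect_equal(s0$n_total, 0)
})

test_that("export_manhattan writes a genome-sorted table with the threshold", {
  rec <- data.frame(chrom = c("chr2", "chr1", "chr1"),
                    start = c(100, 900, 100),
                    end = c(200, 1000, 200),
                    vst = c(0.2, 0.9, 0.5))
  out <- select_top(rec, fraction = 0.3, chrom_levels = c("chr1", "chr2"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_manhattan(out, tsv, chrom_levels = c("chr1", "chr2"))
  got <- read.delim(tsv)
  expect_equal(got$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(got$start, c(100, 900, 100))
  expect_equal(unique(got$threshold), 0.9)
  expect_equal(got$selected, c(FALSE, TRUE, FALSE))
})

test_that("estimated Vst tracks truth on simulated data", {
  fx <- acceptance_fixture()
  ev <- evaluate_calls(fx$cnvrs, fx$sim$truth$loci)
  vt <- vst_table(fx$cnvrs, fx$split)
  m <- merge(ev$matches, data.frame(cnvr_id = vt$id, vst_est = vt$vst))
  m <- merge(m, fx$sim$truth$loci[, c("locus_id", "true_vst")])
  expect_gte(nrow(m), 25)
  expect_lt(max(abs(m$vst_est - m$true_vst)), 0.15)
})
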