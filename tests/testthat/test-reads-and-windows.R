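# read QC, window grids, read counting, count IO, GC normalization

phred_chars <- function(q, n) strrep(intToUtf8(q + 33), n)

test_that("qc_filter drops reads on N content, low quality and adapters", {
  seqs <- c(paste0(strrep("N", 10), strrep("A", 90)),   # 10% N -> dropped
            paste0(strrep("N", 9), strrep("A", 91)),    # 9% N -> kept
            strrep("A", 100),                           # 50% at Q20 -> kept
            strrep("A", 100),                           # 51% at Q20 -> dropped
            paste0(strrep("G", 40), "ACGTACGTACGT", strrep("G", 48)))
  quals <- c(phred_chars(30, 100),
             phred_chars(30, 100),
             paste0(phred_chars(20, 50), phred_chars(30, 50)),
             paste0(phred_chars(20, 51), phred_chars(30, 49)),
             phred_chars(30, 100))
  fin <- withr::local_tempfile(fileext = ".fastq")
  fout <- withr::local_tempfile(fileext = ".fastq")
  write_toy_fastq(fin, seqs, quals)
  rule <- qc_rule(adapter_sequences = "ACGTACGTACGT")
  res <- qc_filter(fin, fout, rule)
  expect_equal(res$total, 5)
  expect_equal(res$kept, 2)
  expect_equal(res$kept + res$dropped, res$total)
  expect_equal(unname(res$dropped_by_criterion[c("n_content", "low_quality",
                                                 "adapter")]),
               c(1L, 1L, 1L))
  kept <- Biostrings::readDNAStringSet(fout, format = "fastq")
  expect_equal(length(kept), 2)
})

test_that("qc_filter is idempotent", {
  set.seed(1)
  seqs <- vapply(sample(c(60, 100, 150), 30, TRUE), function(n) {
    paste(sample(c("A", "C", "G", "T", "N"), n, TRUE,
                 prob = c(.24, .24, .24, .24, .04)), collapse = "")
  }, character(1))
  quals <- vapply(nchar(seqs), function(n) {
    paste(intToUtf8(sample(20:40, n, TRUE) + 33, multiple = TRUE),
          collapse = "")
  }, character(1))
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  f3 <- withr::local_tempfile(fileext = ".fastq")
  write_toy_fastq(f1, seqs, quals)
  r1 <- qc_filter(f1, f2, qc_rule())
  r2 <- qc_filter(f2, f3, qc_rule())
  expect_equal(r2$dropped, 0)
  expect_equal(r2$total, r1$kept)
})

test_that("paired reads are dropped as a pair when either mate fails", {
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  o1 <- withr::local_tempfile(fileext = ".fastq")
  o2 <- withr::local_tempfile(fileext = ".fastq")
  write_toy_fastq(f1, c(strrep("A", 50), strrep("A", 50)),
                  c(phred_chars(30, 50), phred_chars(30, 50)))
  write_toy_fastq(f2, c(strrep("N", 50), strrep("C", 50)),
                  c(phred_chars(30, 50), phred_chars(30, 50)))
  res <- qc_filter(f1, o1, qc_rule(), mate_in = f2, mate_out = o2)
  expect_equal(res$kept, 1)
  expect_equal(unname(res$dropped_by_criterion["mate"]), 1L)
  expect_equal(length(Biostrings::readDNAStringSet(o1, format = "fastq")), 1)
  expect_equal(length(Biostrings::readDNAStringSet(o2, format = "fastq")), 1)
})

test_that("build_grid enumerates half-overlapping windows correctly", {
  g <- build_grid(c(chr1 = 2000), gc = rep(0.5, 4))
  expect_equal(g$start, c(0, 400, 800, 1200))
  expect_equal(g$end, c(800, 1200, 1600, 2000))
  expect_equal(nrow(build_grid(c(chr1 = 799), gc = numeric())), 0)
  g1 <- build_grid(c(chr1 = 800), gc = 0.3)
  expect_equal(nrow(g1), 1)
  expect_equal(c(g1$start, g1$end), c(0, 800))
  # trailing partial window omitted
  g2 <- build_grid(c(chr1 = 2399), gc = rep(0.5, 4))
  expect_equal(max(g2$end), 2000)
})

test_that("build_grid excludes sex chromosomes by default and needs GC", {
  layout <- c(chr1 = 2000, chrX = 2000, MT = 16000)
  g <- build_grid(layout, gc = rep(0.5, 4))
  expect_equal(unique(g$chrom), "chr1")
  g2 <- build_grid(layout, gc = rep(0.5, 4 + 4 + 39), include_sex = TRUE)
  expect_setequal(unique(g2$chrom), c("chr1", "chrX", "MT"))
  expect_error(build_grid(layout), "GC source")
})

test_that("GC is computed from FASTA sequence per window", {
  seq <- Biostrings::DNAStringSet(c(chr1 = paste0(strrep("G", 800),
                                                  strrep("A", 800))))
  g <- build_grid(c(chr1 = 1600), fasta = seq)
  expect_equal(g$gc, c(1, 0.5, 0))
})

test_that("count_reads assigns reads to windows by alignment midpoint", {
  grid <- toy_grid(4) # [0,800) [400,1200) [800,1600) [1200,2000)
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:2000",
    "@SQ\tSN:chrZZ\tLN:2000",
    # pos0 550, span 100 -> midpoint 600: windows 1 and 2
    sprintf("r1\t0\tchr1\t551\t60\t100M\t*\t0\t0\t%s\t%s",
            strrep("A", 100), strrep("I", 100)),
    # pos0 150, span 100 -> midpoint 200: window 1 only
    sprintf("r2\t0\tchr1\t151\t60\t100M\t*\t0\t0\t%s\t%s",
            strrep("A", 100), strrep("I", 100)),
    # unmapped: contributes nothing
    sprintf("r3\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s",
            strrep("A", 100), strrep("I", 100)),
    # below MAPQ threshold
    sprintf("r4\t0\tchr1\t551\t5\t100M\t*\t0\t0\t%s\t%s",
            strrep("A", 100), strrep("I", 100)),
    # chromosome absent from the grid
    sprintf("r5\t0\tchrZZ\t551\t60\t100M\t*\t0\t0\t%s\t%s",
            strrep("A", 100), strrep("I", 100))), sam)
  expect_message(dm <- count_reads(c(a = sam), grid, min_mapq = 10),
                 "skipped")
  expect_equal(as.vector(dm$counts), c(2, 1, 0, 0))
  expect_equal(unname(attr(dm, "skipped")["a"]), 2L)
})

test_that("count_reads totals match a brute-force midpoint recount", {
  layout <- c(chr1 = 40000, chr2 = 20000)
  sam <- withr::local_tempfile(fileext = ".sam")
  sim_sam(sam, layout, n_reads = 500, read_len = 100, n_unmapped = 3,
          seed = 9)
  grid <- build_grid(layout, gc = rep(0.4, 99 + 49))
  dm <- count_reads(c(x = sam), grid, min_mapq = 10)
  # independent recount straight from the SAM text
  lines <- grep("^@", readLines(sam), value = TRUE, invert = TRUE)
  f <- strsplit(lines, "\t")
  expected <- numeric(nrow(grid))
  for (r in f) {
    if (bitwAnd(as.integer(r[2]), 4L) > 0) next
    pos0 <- as.integer(r[4]) - 1
    mid <- pos0 + floor(100 / 2)
    hit <- which(grid$chrom == r[3] & grid$start <= mid & mid < grid$end)
    expected[hit] <- expected[hit] + 1
  }
  expect_equal(as.vector(dm$counts), expected)
})

test_that("counts round-trip through TSV and reject bad input", {
  grid <- toy_grid(5, gc = c(0.3, 0.35, 0.4, 0.45, 0.5))
  counts <- matrix(rpois(10, 50), 5, 2, dimnames = list(NULL, c("a", "b")))
  dm <- depth_matrix(grid, counts)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_counts(dm, tsv)
  dm2 <- load_counts(tsv)
  expect_equal(dm2$counts, dm$counts)
  expect_equal(attr(dm2$grid, "window_size"), 800)
  expect_equal(attr(dm2$grid, "window_step"), 400)
  expect_equal(dm2$grid$gc, grid$gc)
  bad <- read.delim(tsv, check.names = FALSE)
  bad$a[1] <- -5
  write.table(bad, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_counts(tsv), "negative")
})

test_that("gc_normalize rescales each GC bin to the sample's global median", {
  # bin A median 100, bin B median 50, global median 75
  gc <- c(rep(0.105, 40), rep(0.205, 40))
  grid <- toy_grid(80, gc = gc)
  counts <- matrix(c(rep(100, 40), rep(50, 40)), ncol = 1,
                   dimnames = list(NULL, "s1"))
  dm <- depth_matrix(grid, counts)
  out <- gc_normalize(dm)
  expect_true(out$normalized)
  expect_equal(unique(out$counts[1:40, 1]), 75)   # scale 0.75
  expect_equal(unique(out$counts[41:80, 1]), 75)  # scale 1.5
})

test_that("gc_normalize is the identity on unbiased input and masks zero bins", {
  gc <- c(rep(0.105, 40), rep(0.205, 40))
  grid <- toy_grid(80, gc = gc)
  dm <- depth_matrix(grid, matrix(60, 80, 2,
                                  dimnames = list(NULL, c("a", "b"))))
  expect_equal(gc_normalize(dm)$counts, dm$counts + 0)
  # a bin whose counts are all zero is masked; others untouched
  gc2 <- c(rep(0.105, 20), rep(0.205, 60))
  counts2 <- matrix(c(rep(0, 20), rep(100, 60)), ncol = 1,
                    dimnames = list(NULL, "s1"))
  out <- gc_normalize(depth_matrix(toy_grid(80, gc = gc2), counts2))
  expect_true(all(is.na(out$counts[1:20, 1])))
  expect_equal(out$counts[21:80, 1], rep(100, 60))
})

test_that("gc_normalize masks sparse bins and rejects all-zero samples", {
  gc <- c(rep(0.105, 5), rep(0.205, 75))  # first bin below min_bin_windows
  grid <- toy_grid(80, gc = gc)
  counts <- matrix(100, 80, 1, dimnames = list(NULL, "s1"))
  out <- gc_normalize(depth_matrix(grid, counts))
  expect_true(all(is.na(out$counts[1:5, 1])))
  expect_true(all(!is.na(out$counts[6:80, 1])))
  zero <- depth_matrix(grid, matrix(0L, 80, 1, dimnames = list(NULL, "z")))
  expect_error(gc_normalize(zero), "all-zero")
})
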