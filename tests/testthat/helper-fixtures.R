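# fixtures are built in code; nothing is read from disk

# a grid of `n` consecutive windows on one chromosome
toy_grid <- function(n = 4, chrom = "chr1", size = 800, step = 400,
                     gc = rep(0.4, n)) {
  len <- (n - 1) * step + size
  build_grid(stats::setNames(len, chrom), gc = gc,
             window_size = size, window_step = step)
}

# normalized depth matrix with given windows-by-samples counts
toy_norm_dm <- function(counts, grid = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  }
  grid <- grid %||% toy_grid(nrow(counts))
  depth_matrix(grid, counts, normalized = TRUE)
}

toy_cnm <- function(cn, grid = NULL) {
  cn <- as.matrix(cn)
  if (is.null(colnames(cn))) {
    colnames(cn) <- sprintf("s%02d", seq_len(ncol(cn)))
  }
  grid <- grid %||% toy_grid(nrow(cn))
  structure(list(grid = grid, cn = cn), class = "copy_number_matrix")
}

# hand-built cnvr_set: df needs chrom/start/end (+ optional class),
# cn_mean is regions x samples
toy_cnvr_set <- function(df, cn_mean = NULL) {
  n <- nrow(df)
  if (is.null(cn_mean)) {
    cn_mean <- matrix(2, n, 4, dimnames = list(NULL, paste0("s", 1:4)))
  }
  cn_int <- floor(cn_mean + 0.5)
  df$id <- df$id %||% sprintf("CNVR%05d", seq_len(n))
  df$class <- df$class %||% rep("duplication", n)
  df$n_windows <- df$n_windows %||% rep(2L, n)
  df$n_flagged <- df$n_flagged %||% rep(2L, n)
  df$n_carriers <- df$n_carriers %||% rowSums(cn_int != 2)
  df$idx_first <- df$idx_first %||% rep(1L, n)
  df$idx_last <- df$idx_last %||% rep(2L, n)
  structure(list(regions = df, cn_mean = cn_mean, cn_int = cn_int),
            class = "cnvr_set")
}

two_pop_split <- function(n1 = 3, n2 = 3, labels = c("A", "B")) {
  pop_split(data.frame(
    sample = sprintf("s%02d", seq_len(n1 + n2)),
    population = rep(labels, c(n1, n2))))
}

write_toy_fastq <- function(path, seqs, quals, ids = NULL) {
  ids <- ids %||% sprintf("read%d", seq_along(seqs))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# the study-scale simulation used by the recovery, bias-removal and
# structure checks; computed once per test run
acceptance_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_depths(sim_config(seed = 1))
      dm_norm <- gc_normalize(sim$depth)
      cnvrs <- call_cnvrs(dm_norm)
      cache <<- list(sim = sim, dm_norm = dm_norm, cnvrs = cnvrs,
                     split = pop_split(sim$sample_map))
    }
    cache
  }
})
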