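# window read-count containers, SAM/TSV ingestion, GC normalization

#' Construct a window read-count matrix
#'
#' Container pairing a [build_grid()] window grid with a windows-by-samples
#' count matrix.  Raw matrices hold non-negative integer read counts;
#' normalized matrices (after [gc_normalize()]) hold non-negative reals
#' with `NA` marking masked windows.
#'
#' @param grid a `window_grid`.
#' @param counts numeric matrix, one row per window, one named column per
#'   sample.
#' @param normalized logical; whether counts have been GC-normalized.
#' @return a `depth_matrix` object.
#' @export
depth_matrix <- function(grid, counts, normalized = FALSE) {
  stopifnot(inherits(grid, "window_grid"))
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(grid)) {
    stop("counts must have one row per grid window")
  }
  if (is.null(colnames(counts))) stop("counts must have sample column names")
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  if (!normalized && !all(counts == floor(counts), na.rm = TRUE)) {
    stop("raw counts must be integers")
  }
  structure(list(grid = grid, counts = counts, normalized = normalized),
            class = "depth_matrix")
}

#' @export
print.depth_matrix <- function(x, ...) {
  cat(sprintf("depth_matrix: %d windows x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' Count aligned reads per window from SAM files
#'
#' Each mapped read with mapping quality at least `min_mapq` adds one to
#' every window containing its alignment midpoint,
#' `floor((start0 + start0 + span) / 2)` in 0-based coordinates, where the
#' span is the reference width implied by the CIGAR.  With half-overlapping
#' windows a midpoint falls in at most two windows.  Unmapped reads are
#' skipped; reads on chromosomes absent from the grid are tallied as
#' skipped and reported via a message.
#'
#' @param sam_files character vector of SAM (or BAM) paths, one per
#'   sample; names are used as sample ids (file base names otherwise).
#' @param grid a `window_grid`.
#' @param min_mapq minimum mapping quality (default 10); records with
#'   missing MAPQ are skipped.
#' @return a raw `depth_matrix`; attribute `skipped` counts reads ignored
#'   per sample (unknown chromosome or MAPQ below threshold).
#' @export
count_reads <- function(sam_files, grid, min_mapq = 10) {
  stopifnot(inherits(grid, "window_grid"), length(sam_files) >= 1)
  ids <- names(sam_files) %||% sub("\\.(sam|bam)$", "", basename(sam_files))
  gr_grid <- grid_granges(grid)
  counts <- matrix(0L, nrow = nrow(grid), ncol = length(sam_files),
                   dimnames = list(NULL, ids))
  skipped <- integer(length(sam_files))
  for (j in seq_along(sam_files)) {
    f <- sam_files[[j]]
    bam <- if (grepl("\\.bam$", f)) f else
      Rsamtools::asBam(f, tempfile(), overwrite = TRUE,
                       indexDestination = FALSE)
    ga <- GenomicAlignments::readGAlignments(
      bam,
      param = Rsamtools::ScanBamParam(
        what = "mapq",
        flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))
    mapq <- S4Vectors::mcols(ga)$mapq
    keep <- !is.na(mapq) & mapq >= min_mapq
    skipped[j] <- skipped[j] + sum(!keep)
    ga <- ga[keep]
    chrom <- as.character(GenomicAlignments::seqnames(ga))
    known <- chrom %in% unique(grid$chrom)
    if (any(!known)) {
      skipped[j] <- skipped[j] + sum(!known)
      message(sprintf("%s: %d read(s) on chromosomes absent from the grid skipped",
                      ids[j], sum(!known)))
      ga <- ga[known]
      chrom <- chrom[known]
    }
    if (length(ga)) {
      mid0 <- (GenomicAlignments::start(ga) - 1L) +
        GenomicAlignments::width(ga) %/% 2L
      gr_mid <- GenomicRanges::GRanges(chrom,
                                       IRanges::IRanges(mid0 + 1L, width = 1L))
      hits <- GenomicRanges::findOverlaps(gr_mid, gr_grid)
      counts[, j] <- tabulate(S4Vectors::subjectHits(hits), nrow(grid))
    }
  }
  dm <- depth_matrix(grid, counts, normalized = FALSE)
  attr(dm, "skipped") <- stats::setNames(skipped, ids)
  dm
}

#' Read a per-window count matrix from TSV
#'
#' Expects columns `chrom`, `start`, `end`, `gc` followed by one numeric
#' column per sample; the window grid (including window size and step) is
#' reconstructed from the coordinates.
#'
#' @param path TSV file written by [write_counts()] or an equivalent tool.
#' @param normalized logical; whether the stored counts are normalized.
#' @return a `depth_matrix`.
#' @export
load_counts <- function(path, normalized = FALSE) {
  df <- read_tsv(path)
  need <- c("chrom", "start", "end", "gc")
  if (!all(need %in% names(df))) {
    stop("counts TSV must have columns chrom, start, end, gc")
  }
  samples <- setdiff(names(df), need)
  if (length(samples) == 0L) stop("counts TSV has no sample columns")
  counts <- as.matrix(df[, samples, drop = FALSE])
  if (!is.numeric(counts)) stop("sample columns must be numeric")
  if (any(counts < 0, na.rm = TRUE)) stop("negative counts in ", path)
  sizes <- unique(df$end - df$start)
  if (length(sizes) != 1L) stop("windows are not of constant size")
  step <- sizes
  for (chrom in unique(df$chrom)) {
    s <- df$start[df$chrom == chrom]
    if (length(s) > 1L) step <- min(step, diff(s))
  }
  grid <- new_window_grid(df[, need], window_size = sizes, window_step = step)
  depth_matrix(grid, counts, normalized = normalized)
}

#' Write a per-window count matrix to TSV
#'
#' @param dm a `depth_matrix`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_counts <- function(dm, path) {
  stopifnot(inherits(dm, "depth_matrix"))
  write_tsv(cbind(as.data.frame(dm$grid), as.data.frame(dm$counts)), path)
}

#' Remove GC bias from window read counts by per-bin median scaling
#'
#' Sequencing depth depends systematically on window GC content.  For each
#' sample, windows are binned by GC fraction (bins of `bin_width`) and the
#' counts in a bin are rescaled by the ratio of the sample's global median
#' count to its median in that bin, so that after normalization every
#' retained GC bin has the same median depth.  Bins holding fewer than
#' `min_bin_windows` windows are masked (too few observations for a stable
#' median), as are, per sample, windows in bins whose median count is zero.
#' Masked entries are `NA` and are excluded from all downstream steps.
#'
#' @param dm raw `depth_matrix`.
#' @param bin_width GC bin width (default 0.01).
#' @param min_bin_windows minimum windows per usable GC bin (default 20).
#' @return a normalized `depth_matrix`.
#' @export
gc_normalize <- function(dm, bin_width = 0.01, min_bin_windows = 20) {
  stopifnot(inherits(dm, "depth_matrix"))
  if (dm$normalized) stop("depth matrix is already normalized")
  gc <- dm$grid$gc
  bin <- pmin(floor(gc / bin_width), floor(1 / bin_width) - 1L)
  bin[is.na(gc)] <- NA
  tab <- table(bin)
  good_bins <- as.numeric(names(tab)[tab >= min_bin_windows])
  usable <- !is.na(bin) & bin %in% good_bins
  all_zero <- colSums(dm$counts, na.rm = TRUE) == 0
  if (any(all_zero)) {
    stop("all-zero count column(s): ",
         paste(colnames(dm$counts)[all_zero], collapse = ", "))
  }
  norm <- matrix(NA_real_, nrow(dm$counts), ncol(dm$counts),
                 dimnames = dimnames(dm$counts))
  for (j in seq_len(ncol(dm$counts))) {
    x <- dm$counts[, j]
    gmed <- stats::median(x[usable])
    meds <- tapply(x[usable], bin[usable], stats::median)
    scale <- gmed / meds            # bins with median 0 -> Inf -> masked
    s <- scale[as.character(bin)]
    s[!usable] <- NA
    s[!is.finite(s)] <- NA
    norm[, j] <- x * s
  }
  depth_matrix(dm$grid, norm, normalized = TRUE)
}
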