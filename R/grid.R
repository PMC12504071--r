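# genome tiling into fixed half-overlapping windows

# bare tiling, no GC; used by build_grid() and the simulator
tile_windows <- function(layout, window_size, window_step) {
  layout <- as_layout(layout)
  pieces <- lapply(seq_len(nrow(layout)), function(i) {
    len <- layout$length[i]
    if (len < window_size) {
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric(), stringsAsFactors = FALSE))
    }
    starts <- seq.int(0, len - window_size, by = window_step)
    data.frame(chrom = layout$chrom[i], start = starts,
               end = starts + window_size, stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

new_window_grid <- function(df, window_size, window_step) {
  structure(df,
            window_size = window_size,
            window_step = window_step,
            class = c("window_grid", "data.frame"))
}

#' Tile a genome into fixed half-overlapping windows
#'
#' Builds the window grid used for read-depth copy-number estimation:
#' fixed-length windows advanced by `window_step` (half the window size by
#' default, so consecutive windows overlap by half), in 0-based half-open
#' coordinates.  A trailing partial window that would extend past the
#' chromosome end is omitted.  Sex chromosomes and the mitochondrion are
#' excluded by default; copy-number analysis of read depth assumes a
#' diploid background, which only holds on autosomes.
#'
#' Every window carries its G+C base fraction, used later by
#' [gc_normalize()].  Supply either a FASTA file (or `DNAStringSet`), from
#' which GC is computed per window, or a precomputed per-window `gc`
#' vector.
#'
#' @param layout genome layout: a data.frame with columns `chrom` and
#'   `length` (bp), or a named numeric vector of chromosome lengths.
#' @param fasta optional path to a FASTA file, or a
#'   `Biostrings::DNAStringSet`, used to compute per-window GC.
#' @param gc optional numeric vector of per-window GC fractions, in grid
#'   order; used when no FASTA is available.
#' @param window_size window length in bp (default 800).
#' @param window_step distance between consecutive window starts in bp
#'   (default 400, i.e. half-overlapping windows).
#' @param include_sex keep chromosomes named like X/Y/MT (default FALSE).
#' @return a `window_grid`: a data.frame with columns `chrom`, `start`,
#'   `end`, `gc` and attributes `window_size`, `window_step`.
#' @examples
#' build_grid(c(chr1 = 2000), gc = rep(0.4, 4))
#' @export
build_grid <- function(layout, fasta = NULL, gc = NULL,
                       window_size = 800, window_step = 400,
                       include_sex = FALSE) {
  stopifnot(window_size >= 2, window_step >= 1, window_step <= window_size)
  layout <- as_layout(layout)
  if (!include_sex) {
    layout <- layout[!is_sex_chrom(layout$chrom), , drop = FALSE]
  }
  if (nrow(layout) == 0L) stop("no chromosomes left to tile")
  df <- tile_windows(layout, window_size, window_step)
  if (!is.null(fasta)) {
    gc <- gc_from_fasta(fasta, df)
  }
  if (is.null(gc)) {
    stop("build_grid() needs a GC source: supply `fasta` or a per-window `gc` vector")
  }
  if (length(gc) != nrow(df)) {
    stop(sprintf("`gc` has length %d but the grid has %d windows",
                 length(gc), nrow(df)))
  }
  if (any(gc < 0 | gc > 1, na.rm = TRUE)) stop("GC fractions must lie in [0, 1]")
  df$gc <- as.numeric(gc)
  new_window_grid(df, window_size, window_step)
}

# per-window GC fraction from sequence; ambiguous bases excluded from the
# denominator, all-N windows give NA
gc_from_fasta <- function(fasta, df) {
  seqs <- if (methods::is(fasta, "DNAStringSet")) fasta else
    Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(unique(df$chrom), names(seqs))
  if (length(missing)) {
    stop("chromosomes absent from FASTA: ", paste(missing, collapse = ", "))
  }
  gc <- rep(NA_real_, nrow(df))
  for (chrom in unique(df$chrom)) {
    i <- which(df$chrom == chrom)
    v <- Biostrings::Views(seqs[[chrom]], start = df$start[i] + 1L,
                           end = df$end[i])
    af <- Biostrings::letterFrequency(v, c("G", "C", "A", "T"))
    denom <- rowSums(af)
    gc[i] <- ifelse(denom > 0, (af[, "G"] + af[, "C"]) / denom, NA_real_)
  }
  gc
}

window_size <- function(grid) attr(grid, "window_size")
window_step <- function(grid) attr(grid, "window_step")

grid_granges <- function(grid) {
  GenomicRanges::GRanges(grid$chrom,
                         IRanges::IRanges(start = grid$start + 1L,
                                          end = grid$end))
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("window_grid: %d windows of %d bp (step %d bp) on %d chromosome(s)\n",
              nrow(x), window_size(x), window_step(x),
              length(unique(x$chrom))))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}
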