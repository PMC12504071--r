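# copy-number estimation, candidate-window detection, CNVR merging,
# genotyping, classification and length filtering

#' Convert normalized window counts into copy numbers
#'
#' Scales each sample so that its median window sits at the diploid
#' expectation: `CN = 2 * count / median(count)` with the median taken
#' over the sample's unmasked autosomal windows.  By construction the
#' per-sample median copy number is 2.  Masked windows stay `NA`.
#'
#' @param dm a normalized `depth_matrix` (see [gc_normalize()]).
#' @return a `copy_number_matrix`: list with the grid and a
#'   windows-by-samples matrix `cn`.
#' @export
copy_number <- function(dm) {
  stopifnot(inherits(dm, "depth_matrix"))
  if (!dm$normalized) stop("copy_number() expects a GC-normalized depth matrix")
  med <- apply(dm$counts, 2, stats::median, na.rm = TRUE)
  zero <- !is.na(med) & med == 0
  if (any(zero)) {
    stop("sample(s) with zero median depth: ",
         paste(colnames(dm$counts)[zero], collapse = ", "))
  }
  cn <- sweep(dm$counts, 2, med, "/") * 2
  structure(list(grid = dm$grid, cn = cn), class = "copy_number_matrix")
}

#' @export
print.copy_number_matrix <- function(x, ...) {
  cat(sprintf("copy_number_matrix: %d windows x %d samples\n",
              nrow(x$cn), ncol(x$cn)))
  invisible(x)
}

#' Flag candidate CNV windows
#'
#' A window is a CNV candidate when (i) the fraction of samples whose copy
#' number is at or above `gain_cn` or at or below `loss_cn` reaches
#' `min_carrier_frac` (missing samples are excluded from both numerator
#' and denominator), and (ii), unless `neighbor_cor` is `NULL`, the
#' window's copy numbers correlate across samples (Pearson r at least
#' `neighbor_cor`) with at least one of its nearest non-overlapping
#' neighbor windows.  Real copy-number changes span several windows and
#' leave the same sample-ranking signature on neighbors, whereas counting
#' noise does not, so the correlation test suppresses isolated
#' depth-noise windows that the carrier-fraction rule alone would flag.
#'
#' @param cnm a `copy_number_matrix` on a window grid.
#' @param gain_cn copy number at or above which a sample counts as a gain
#'   carrier (default 2.5).
#' @param loss_cn copy number at or below which a sample counts as a loss
#'   carrier (default 1.5).
#' @param min_carrier_frac minimum carrier fraction (inclusive, default
#'   0.1).
#' @param neighbor_cor correlation threshold with the nearest
#'   non-overlapping neighbor window, or `NULL` to disable the test
#'   (default 0.5).
#' @return logical vector, one flag per window, with attribute
#'   `carrier_frac`.
#' @export
candidate_windows <- function(cnm, gain_cn = 2.5, loss_cn = 1.5,
                              min_carrier_frac = 0.1, neighbor_cor = 0.5) {
  stopifnot(inherits(cnm, "copy_number_matrix"), gain_cn > loss_cn)
  cn <- cnm$cn
  carrier <- (cn >= gain_cn | cn <= loss_cn)
  n_obs <- rowSums(!is.na(cn))
  frac <- rowSums(carrier, na.rm = TRUE) / n_obs
  flags <- n_obs > 0 & frac >= min_carrier_frac
  if (!is.null(neighbor_cor)) {
    # nearest non-overlapping window: `k` grid steps away
    k <- ceiling(window_size(cnm$grid) / window_step(cnm$grid))
    r_fwd <- r_rev <- rep(NA_real_, nrow(cn))
    for (chrom in unique(cnm$grid$chrom)) {
      i <- which(cnm$grid$chrom == chrom)
      if (length(i) > k) {
        a <- i[seq_len(length(i) - k)]
        b <- i[(k + 1):length(i)]
        r <- row_cor(cn[a, , drop = FALSE], cn[b, , drop = FALSE])
        r_fwd[a] <- r
        r_rev[b] <- r
      }
    }
    cor_ok <- (!is.na(r_fwd) & r_fwd >= neighbor_cor) |
      (!is.na(r_rev) & r_rev >= neighbor_cor)
    flags <- flags & cor_ok
  }
  attr(flags, "carrier_frac") <- frac
  flags
}

#' Merge flagged windows into raw CNV regions
#'
#' Maximal runs of flagged windows on one chromosome, allowing up to
#' `max_gap_windows` consecutive unflagged windows inside a run.  A run
#' must contain at least `min_windows` flagged windows; the region spans
#' from the first flagged window's start to the last flagged window's
#' end.  Regions never cross chromosomes.
#'
#' @param flags logical vector from [candidate_windows()].
#' @param grid the matching `window_grid`.
#' @param max_gap_windows tolerated unflagged windows inside a run
#'   (default 1).
#' @param min_windows minimum flagged windows per region (default 2).
#' @return data.frame with `chrom`, `start`, `end`, `idx_first`,
#'   `idx_last` (grid row indices), `n_windows` (windows spanned) and
#'   `n_flagged`.
#' @export
merge_cnvrs <- function(flags, grid, max_gap_windows = 1, min_windows = 2) {
  stopifnot(length(flags) == nrow(grid), min_windows >= 1, max_gap_windows >= 0)
  out <- list()
  for (chrom in unique(grid$chrom)) {
    i <- which(grid$chrom == chrom & flags)
    if (length(i) == 0L) next
    grp <- cumsum(c(0L, diff(i) > max_gap_windows + 1L))
    for (g in split(i, grp)) {
      if (length(g) < min_windows) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom,
        start = grid$start[min(g)],
        end = grid$end[max(g)],
        idx_first = min(g),
        idx_last = max(g),
        n_windows = max(g) - min(g) + 1L,
        n_flagged = length(g),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      idx_first = integer(), idx_last = integer(),
                      n_windows = integer(), n_flagged = integer()))
  }
  do.call(rbind, out)
}

#' Genotype samples per region and classify regions
#'
#' Per region and sample, the mean copy number over the region's unmasked
#' windows is rounded half-up to an integer genotype; carriers are
#' samples whose integer copy number differs from 2.  A region is a
#' `duplication` when every carrier is above 2, a `deletion` when every
#' carrier is below 2, and `both` otherwise.  Regions with no
#' informative sample are discarded, as are regions whose genotyped
#' carrier fraction falls below `min_carrier_frac`: a region must be
#' supported at the genotype level by the same carrier fraction demanded
#' of its candidate windows, which removes regions whose window-level
#' outliers do not persist once averaged over the region (zero carriers
#' is the degenerate case).  Set `min_carrier_frac = 0` to keep every
#' region with at least one carrier.
#'
#' @param regions data.frame from [merge_cnvrs()].
#' @param cnm the `copy_number_matrix` the regions were called on.
#' @param min_carrier_frac minimum genotyped carrier fraction (default
#'   0.1).
#' @return a `cnvr_set`: list with `regions` (adds `id`, `class`,
#'   `n_carriers`) and per-sample matrices `cn_mean` and `cn_int`.
#' @export
genotype_and_classify <- function(regions, cnm, min_carrier_frac = 0.1) {
  stopifnot(inherits(cnm, "copy_number_matrix"))
  ns <- ncol(cnm$cn)
  keep <- logical(nrow(regions))
  cls <- character(nrow(regions))
  ncar <- integer(nrow(regions))
  cn_mean <- matrix(NA_real_, nrow(regions), ns,
                    dimnames = list(NULL, colnames(cnm$cn)))
  cn_int <- cn_mean
  dropped_missing <- 0L
  for (i in seq_len(nrow(regions))) {
    sub <- cnm$cn[regions$idx_first[i]:regions$idx_last[i], , drop = FALSE]
    m <- colMeans(sub, na.rm = TRUE)
    m[!is.finite(m)] <- NA
    if (all(is.na(m))) {
      dropped_missing <- dropped_missing + 1L
      next
    }
    g <- round_half_up(m)
    carrier <- !is.na(g) & g != 2
    if (!any(carrier) || sum(carrier) / sum(!is.na(g)) < min_carrier_frac) next
    cn_mean[i, ] <- m
    cn_int[i, ] <- g
    ncar[i] <- sum(carrier)
    cg <- g[carrier]
    cls[i] <- if (all(cg > 2)) "duplication" else
      if (all(cg < 2)) "deletion" else "both"
    keep[i] <- TRUE
  }
  if (dropped_missing > 0L) {
    message(dropped_missing, " region(s) with no informative sample discarded")
  }
  reg <- regions[keep, , drop = FALSE]
  reg$class <- cls[keep]
  reg$n_carriers <- ncar[keep]
  reg$id <- sprintf("CNVR%05d", seq_len(nrow(reg)))
  rownames(reg) <- NULL
  structure(list(regions = reg[, c("id", "chrom", "start", "end", "n_windows",
                                   "n_flagged", "class", "n_carriers",
                                   "idx_first", "idx_last")],
                 cn_mean = cn_mean[keep, , drop = FALSE],
                 cn_int = cn_int[keep, , drop = FALSE]),
            class = "cnvr_set")
}

#' @export
print.cnvr_set <- function(x, ...) {
  cat(sprintf("cnvr_set: %d regions (%s)\n", nrow(x$regions),
              paste(sprintf("%s=%d", names(table(x$regions$class)),
                            table(x$regions$class)), collapse = ", ")))
  invisible(x)
}

#' Filter CNV regions on class-specific length limits
#'
#' Deletion and mixed (duplication-deletion) regions are kept when their
#' span is at most `max_del_bp`; duplications when their span is strictly
#' below `max_dup_bp`.
#'
#' @param cnvrs a `cnvr_set`.
#' @param max_del_bp inclusive span limit for deletion/both regions
#'   (default 50 kb).
#' @param max_dup_bp exclusive span limit for duplications (default
#'   500 kb).
#' @return the filtered `cnvr_set`.
#' @export
length_filter <- function(cnvrs, max_del_bp = 50000, max_dup_bp = 500000) {
  stopifnot(inherits(cnvrs, "cnvr_set"))
  span <- cnvrs$regions$end - cnvrs$regions$start
  keep <- ifelse(cnvrs$regions$class == "duplication",
                 span < max_dup_bp, span <= max_del_bp)
  subset_cnvrs(cnvrs, keep)
}

subset_cnvrs <- function(cnvrs, keep) {
  reg <- cnvrs$regions[keep, , drop = FALSE]
  rownames(reg) <- NULL
  structure(list(regions = reg,
                 cn_mean = cnvrs$cn_mean[keep, , drop = FALSE],
                 cn_int = cnvrs$cn_int[keep, , drop = FALSE]),
            class = "cnvr_set")
}

#' Call CNV regions from a normalized depth matrix
#'
#' Convenience wrapper running [copy_number()], [candidate_windows()],
#' [merge_cnvrs()], [genotype_and_classify()] and [length_filter()] with
#' one set of parameters.
#'
#' @param dm a normalized `depth_matrix`.
#' @inheritParams candidate_windows
#' @inheritParams merge_cnvrs
#' @inheritParams length_filter
#' @return a `cnvr_set`.
#' @export
call_cnvrs <- function(dm, gain_cn = 2.5, loss_cn = 1.5,
                       min_carrier_frac = 0.1, neighbor_cor = 0.5,
                       max_gap_windows = 1, min_windows = 2,
                       max_del_bp = 50000, max_dup_bp = 500000) {
  cnm <- copy_number(dm)
  flags <- candidate_windows(cnm, gain_cn = gain_cn, loss_cn = loss_cn,
                             min_carrier_frac = min_carrier_frac,
                             neighbor_cor = neighbor_cor)
  regions <- merge_cnvrs(flags, cnm$grid, max_gap_windows = max_gap_windows,
                         min_windows = min_windows)
  cnvrs <- genotype_and_classify(regions, cnm,
                                 min_carrier_frac = min_carrier_frac)
  length_filter(cnvrs, max_del_bp = max_del_bp, max_dup_bp = max_dup_bp)
}

#' Export a CNVR set as BED-compatible TSVs
#'
#' Writes a region table (`chrom`, `start`, `end`, `id`, `class`,
#' `n_windows`, `n_carriers`) and, optionally, the per-sample mean
#' copy-number matrix keyed by region id.
#'
#' @param cnvrs a `cnvr_set`.
#' @param path output TSV for the region table.
#' @param cn_path optional output TSV for the per-sample matrix.
#' @return `path`, invisibly.
#' @export
write_cnvrs <- function(cnvrs, path, cn_path = NULL) {
  stopifnot(inherits(cnvrs, "cnvr_set"))
  reg <- cnvrs$regions
  write_tsv(reg[, c("chrom", "start", "end", "id", "class", "n_windows",
                    "n_carriers")], path)
  if (!is.null(cn_path)) {
    write_tsv(cbind(data.frame(id = reg$id), as.data.frame(cnvrs$cn_mean)),
              cn_path)
  }
  invisible(path)
}
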