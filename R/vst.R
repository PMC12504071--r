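# Vst copy-number differentiation between two populations,
# top-percentile selection, and CNVR summary statistics

#' Build and validate a two-population sample split
#'
#' @param sample_map data.frame with columns `sample` and `population`
#'   (exactly two distinct labels, each with at least two samples), or a
#'   path to such a TSV.
#' @return a `pop_split` data.frame; attribute `populations` gives the
#'   two labels in order of first appearance.
#' @export
pop_split <- function(sample_map) {
  if (is.character(sample_map) && length(sample_map) == 1L) {
    sample_map <- read_tsv(sample_map)
  }
  sample_map <- as.data.frame(sample_map)
  stopifnot(all(c("sample", "population") %in% names(sample_map)))
  sample_map$sample <- as.character(sample_map$sample)
  sample_map$population <- as.character(sample_map$population)
  if (anyDuplicated(sample_map$sample)) stop("duplicated sample ids")
  pops <- unique(sample_map$population)
  if (length(pops) != 2L) {
    stop("exactly two population labels are required, got: ",
         paste(pops, collapse = ", "))
  }
  if (any(table(sample_map$population) < 2L)) {
    stop("each population needs at least two samples")
  }
  structure(sample_map[, c("sample", "population")], populations = pops,
            class = c("pop_split", "data.frame"))
}

#' Vst: between-population variance fraction of copy number
#'
#' For per-sample copy numbers split into two populations,
#' `Vst = (Vtotal - (Vpop1 * Npop1 + Vpop2 * Npop2) / Ntotal) / Vtotal`,
#' where `Vtotal` is the variance over all samples and `Vpop1`, `Vpop2`
#' the within-population variances.  All variances are population
#' variances (divide by N, not N-1); with that convention the weighted
#' within-population variance never exceeds the total variance (law of
#' total variance), so Vst lies in `[0, 1]`: 0 means identical
#' copy-number distributions, 1 a fixed difference.  When `Vtotal` is 0,
#' Vst is 0 by convention.  Missing copy numbers are dropped and the
#' population sizes in the formula are the non-missing counts; when
#' fewer than two non-missing samples remain in either population, Vst
#' is `NA`.
#'
#' @param cn numeric vector of per-sample copy numbers, named by sample
#'   or aligned with `split$sample`.
#' @param split a [pop_split()].
#' @return list with `v_total`, `v_pop1`, `v_pop2`, `n_pop1`, `n_pop2`,
#'   `vst`.
#' @examples
#' sm <- data.frame(sample = paste0("s", 1:6),
#'                  population = rep(c("A", "B"), each = 3))
#' vst(c(2, 2, 2, 2, 4, 4), pop_split(sm))$vst  # 0.5
#' @export
vst <- function(cn, split) {
  stopifnot(inherits(split, "pop_split"))
  if (!is.null(names(cn))) cn <- cn[split$sample]
  if (length(cn) != nrow(split)) {
    stop("cn must have one value per sample in the split")
  }
  pops <- attr(split, "populations")
  pvar <- function(x) mean((x - mean(x))^2)
  x1 <- cn[split$population == pops[1] & !is.na(cn)]
  x2 <- cn[split$population == pops[2] & !is.na(cn)]
  n1 <- length(x1)
  n2 <- length(x2)
  if (n1 < 2L || n2 < 2L) {
    return(list(v_total = NA_real_, v_pop1 = NA_real_, v_pop2 = NA_real_,
                n_pop1 = n1, n_pop2 = n2, vst = NA_real_))
  }
  vt <- pvar(c(x1, x2))
  v1 <- pvar(x1)
  v2 <- pvar(x2)
  v <- if (vt > 0) (vt - (v1 * n1 + v2 * n2) / (n1 + n2)) / vt else 0
  list(v_total = vt, v_pop1 = v1, v_pop2 = v2, n_pop1 = n1, n_pop2 = n2,
       vst = min(max(v, 0), 1))
}

#' Per-CNVR Vst table
#'
#' Applies [vst()] to every region of a CNVR set, using the per-sample
#' mean copy numbers (or the rounded integer genotypes when
#' `integer_cn = TRUE`).
#'
#' @param cnvrs a `cnvr_set`.
#' @param split a [pop_split()]; its samples must all be present in the
#'   CNVR matrices.
#' @param integer_cn use rounded integer copy numbers instead of real
#'   means (default FALSE).
#' @return data.frame with region coordinates, variance components and
#'   `vst`.
#' @export
vst_table <- function(cnvrs, split, integer_cn = FALSE) {
  stopifnot(inherits(cnvrs, "cnvr_set"), inherits(split, "pop_split"))
  m <- if (integer_cn) cnvrs$cn_int else cnvrs$cn_mean
  missing <- setdiff(split$sample, colnames(m))
  if (length(missing)) {
    stop("samples absent from CNVR matrix: ", paste(missing, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(cnvrs$regions)), function(i) {
    as.data.frame(vst(m[i, split$sample], split))
  })
  cbind(cnvrs$regions[, c("id", "chrom", "start", "end", "class")],
        do.call(rbind, rows))
}

#' Flag the top fraction of Vst records
#'
#' Flags the `k = ceiling(fraction * M)` records with the largest Vst,
#' where `M` counts records with non-missing Vst.  Ties at the k-th value
#' are broken by chromosome order then start position, ascending, so
#' exactly `k` records are flagged and re-running is deterministic.
#'
#' @param records data.frame with at least `vst` and, for tie-breaking,
#'   `chrom` and `start` columns (as from [vst_table()]).
#' @param fraction top fraction to select, in `(0, 1]` (default 0.01).
#' @param chrom_levels chromosome order for tie-breaking; defaults to
#'   order of first appearance.
#' @return `records` with a logical `selected` column; attribute
#'   `threshold` holds the k-th largest Vst.
#' @export
select_top <- function(records, fraction = 0.01,
                       chrom_levels = unique(records$chrom)) {
  stopifnot(is.data.frame(records), "vst" %in% names(records))
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  ok <- which(!is.na(records$vst))
  if (length(ok) == 0L) stop("no records with non-missing vst")
  k <- ceiling(fraction * length(ok))
  co <- if ("chrom" %in% names(records)) {
    match(records$chrom, chrom_levels)
  } else rep(1L, nrow(records))
  st <- records$start %||% seq_len(nrow(records))
  ord <- ok[order(-records$vst[ok], co[ok], st[ok])]
  sel <- ord[seq_len(k)]
  records$selected <- FALSE
  records$selected[sel] <- TRUE
  attr(records, "threshold") <- records$vst[ord[k]]
  records
}

#' Summary statistics for a CNVR set
#'
#' Produces the descriptive summaries usually reported with a CNV map:
#' per-class counts (a partition of the total), mean and total span,
#' fraction of the genome covered, a size-class histogram, per-chromosome
#' counts, and the Pearson correlation between per-chromosome CNVR count
#' and chromosome length (requires at least three chromosomes, `NA`
#' otherwise).
#'
#' @param cnvrs a `cnvr_set`.
#' @param layout genome layout (see [build_grid()]); chromosome lengths
#'   are used for the coverage fraction and the count-length correlation.
#' @param size_breaks_kb histogram bin edges in kb (default
#'   `c(0, 1.6, 2, 5, 10, 50, Inf)`).
#' @return a `cnvr_summary` list with elements `n_total`, `class_counts`,
#'   `mean_span_bp`, `total_span_bp`, `genome_bp`, `coverage_fraction`,
#'   `size_hist` (with unrounded `share_pct`), `per_chrom`,
#'   `count_length_r`.
#' @export
cnvr_summary <- function(cnvrs, layout,
                         size_breaks_kb = c(0, 1.6, 2, 5, 10, 50, Inf)) {
  stopifnot(inherits(cnvrs, "cnvr_set"))
  layout <- as_layout(layout)
  reg <- cnvrs$regions
  if (nrow(reg) == 0L) {
    warning("no CNVRs; returning an empty summary")
    return(structure(list(n_total = 0L), class = "cnvr_summary"))
  }
  span <- reg$end - reg$start
  classes <- c("duplication", "deletion", "both")
  class_counts <- table(factor(reg$class, classes))
  hist_cut <- cut(span / 1000, breaks = size_breaks_kb, right = FALSE)
  size_hist <- as.data.frame(table(bin = hist_cut))
  names(size_hist)[2] <- "count"
  size_hist$share_pct <- 100 * size_hist$count / nrow(reg)
  per_chrom <- data.frame(
    chrom = layout$chrom,
    length = layout$length,
    n_cnvr = as.integer(table(factor(reg$chrom, layout$chrom))))
  r <- if (nrow(per_chrom) >= 3) {
    stats::cor(per_chrom$n_cnvr, per_chrom$length)
  } else NA_real_
  structure(list(
    n_total = nrow(reg),
    class_counts = c(class_counts),
    mean_span_bp = mean(span),
    total_span_bp = sum(span),
    genome_bp = sum(layout$length),
    coverage_fraction = sum(span) / sum(layout$length),
    size_hist = size_hist,
    per_chrom = per_chrom,
    count_length_r = r), class = "cnvr_summary")
}

#' @export
print.cnvr_summary <- function(x, ...) {
  cat(sprintf("CNVRs: %d", x$n_total))
  if (x$n_total == 0L) {
    cat("\n")
    return(invisible(x))
  }
  cat(sprintf(" (%s)\n", paste(sprintf("%s=%d", names(x$class_counts),
                                       x$class_counts), collapse = ", ")))
  cat(sprintf("mean span: %.1f bp; genome coverage: %.4f%%\n",
              x$mean_span_bp, 100 * x$coverage_fraction))
  cat(sprintf("count-vs-chromosome-length Pearson r: %s\n",
              format(x$count_length_r, digits = 3)))
  invisible(x)
}

#' Export a Vst table for Manhattan-style plotting
#'
#' Writes `chrom`, `start`, `end`, `vst`, `selected` and the selection
#' threshold, sorted by genome order.
#'
#' @param records output of [select_top()].
#' @param path output TSV.
#' @param chrom_levels chromosome sort order (default: first appearance).
#' @return the path, invisibly.
#' @export
export_manhattan <- function(records, path,
                             chrom_levels = unique(records$chrom)) {
  stopifnot(all(c("chrom", "start", "end", "vst", "selected") %in%
                  names(records)))
  ord <- order(match(records$chrom, chrom_levels), records$start)
  out <- records[ord, c("chrom", "start", "end", "vst", "selected")]
  out$threshold <- attr(records, "threshold") %||% NA_real_
  write_tsv(out, path)
}
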