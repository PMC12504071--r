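# gene overlap of selected CNVRs and hypergeometric term enrichment

#' Read gene models from BED or GFF3
#'
#' Coordinates are converted to 0-based half-open on load.  For GFF3,
#' records of type `gene` are used (all records when none are typed
#' `gene`); gene ids are taken from `ID`, `gene_id` or `Name`, in that
#' order.  For BED, the name column is the gene id.
#'
#' @param path BED or GFF3 file.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  if ("type" %in% names(md) && any(md$type == "gene")) {
    gr <- gr[md$type == "gene"]
    md <- S4Vectors::mcols(gr)
  }
  id <- NULL
  for (f in c("ID", "gene_id", "Name", "name")) {
    if (f %in% names(md) && !all(is.na(md[[f]]))) {
      id <- as.character(md[[f]])
      break
    }
  }
  if (is.null(id)) stop("no gene identifier column found in ", path)
  data.frame(gene_id = id,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Overlap CNV regions with gene models
#'
#' A gene is reported for a region when their half-open intervals
#' intersect by at least one bp (strand is ignored; `flank_bp` widens the
#' regions symmetrically before the test).  Genes on chromosomes absent
#' from the regions are skipped with a message.
#'
#' @param cnvrs a `cnvr_set`, or a data.frame with `chrom`, `start`,
#'   `end` and an `id` column (0-based half-open).
#' @param genes gene models from [read_gene_models()] or an equivalent
#'   data.frame.
#' @param flank_bp symmetric flank added to each region (default 0).
#' @return data.frame of (`cnvr_id`, `gene_id`) pairs; attribute `genes`
#'   holds the deduplicated gene list.
#' @export
annotate_cnvrs <- function(cnvrs, genes, flank_bp = 0) {
  reg <- if (inherits(cnvrs, "cnvr_set")) cnvrs$regions else
    as.data.frame(cnvrs)
  stopifnot(all(c("chrom", "start", "end", "id") %in% names(reg)),
            all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  unknown <- !(genes$chrom %in% unique(reg$chrom))
  if (any(unknown)) {
    message(sum(unknown), " gene(s) on chromosomes without CNVRs skipped")
  }
  if (nrow(reg) == 0L || all(unknown)) {
    out <- data.frame(cnvr_id = character(), gene_id = character())
    attr(out, "genes") <- character()
    return(out)
  }
  gr_reg <- GenomicRanges::GRanges(
    reg$chrom,
    IRanges::IRanges(start = pmax(reg$start - flank_bp, 0) + 1L,
                     end = reg$end + flank_bp))
  gr_gene <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = genes$start + 1L, end = genes$end))
  hits <- GenomicRanges::findOverlaps(gr_reg, gr_gene, minoverlap = 1L,
                                      ignore.strand = TRUE)
  out <- data.frame(cnvr_id = reg$id[S4Vectors::queryHits(hits)],
                    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
                    stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(match(out$cnvr_id, reg$id)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "genes") <- unique(out$gene_id)
  out
}

#' Read a gene-to-term annotation table
#'
#' @param path TSV with columns `gene_id`, `term_id` and optionally
#'   `term_name`.
#' @return data.frame with those columns.
#' @export
read_term_map <- function(path) {
  df <- read_tsv(path)
  stopifnot(all(c("gene_id", "term_id") %in% names(df)))
  if (!"term_name" %in% names(df)) df$term_name <- df$term_id
  unique(df[, c("gene_id", "term_id", "term_name")])
}

#' Hypergeometric term over-representation with BH-FDR
#'
#' For each term with at least one annotated background gene, tests
#' whether the selected gene set over-represents the term: with `N`
#' background genes of which `K` carry the term, and `n` selected genes
#' of which `k` carry it, the p-value is the upper tail
#' `P(X >= k)` of the hypergeometric distribution.  P-values are adjusted
#' across terms with Benjamini-Hochberg and a term is significant when
#' its adjusted p is below `alpha`.
#'
#' @param selected character vector of selected gene ids (e.g. from
#'   [annotate_cnvrs()]); genes outside the background are dropped with a
#'   warning.
#' @param term_map data.frame from [read_term_map()].
#' @param background background gene set (default: all genes in
#'   `term_map`).
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @return data.frame sorted by adjusted then raw p: `term_id`,
#'   `term_name`, `k`, `n`, `K`, `N`, `p`, `q`, `significant`.
#' @export
hypergeom_enrich <- function(selected, term_map, background = NULL,
                             alpha = 0.05) {
  stopifnot(all(c("gene_id", "term_id") %in% names(term_map)))
  if (!"term_name" %in% names(term_map)) term_map$term_name <- term_map$term_id
  background <- unique(background %||% term_map$gene_id)
  selected <- unique(selected)
  outside <- setdiff(selected, background)
  if (length(outside)) {
    warning(length(outside), " selected gene(s) outside the background dropped")
    selected <- intersect(selected, background)
  }
  empty <- data.frame(term_id = character(), term_name = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p = numeric(), q = numeric(),
                      significant = logical())
  if (length(selected) == 0L) {
    warning("empty selected gene set")
    return(empty)
  }
  tm <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  tm <- unique(tm[, c("gene_id", "term_id", "term_name")])
  if (nrow(tm) == 0L) return(empty)
  terms <- unique(tm[, c("term_id", "term_name")])
  N <- length(background)
  n <- length(selected)
  res <- lapply(seq_len(nrow(terms)), function(i) {
    g <- tm$gene_id[tm$term_id == terms$term_id[i]]
    K <- length(unique(g))
    k <- length(intersect(selected, g))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = terms$term_id[i], term_name = terms$term_name[i],
               k = k, n = n, K = K, N = N, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$q < alpha
  res <- res[order(res$q, res$p), , drop = FALSE]
  rownames(res) <- NULL
  res
}
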