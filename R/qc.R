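# FASTQ read quality filtering

#' Read-filtering rule set
#'
#' Defaults follow standard resequencing practice: discard a read when at
#' least 10% of its bases are undetermined (N), when more than half of its
#' bases have Phred quality at or below 20, or when it contains a
#' configured adapter sequence verbatim.
#'
#' @param max_n_fraction drop a read when its N fraction is `>=` this
#'   value (default 0.10).
#' @param max_lowq_fraction drop a read when the fraction of bases at or
#'   below `lowq_phred_threshold` is strictly greater than this value
#'   (default 0.50).
#' @param lowq_phred_threshold Phred score at or below which a base counts
#'   as low quality (default 20).
#' @param adapter_sequences character vector of adapter strings matched as
#'   exact substrings.
#' @return a `qc_rule` list.
#' @export
qc_rule <- function(max_n_fraction = 0.10, max_lowq_fraction = 0.50,
                    lowq_phred_threshold = 20,
                    adapter_sequences = character()) {
  stopifnot(max_n_fraction >= 0, max_n_fraction <= 1,
            max_lowq_fraction >= 0, max_lowq_fraction <= 1,
            lowq_phred_threshold >= 0)
  structure(list(max_n_fraction = max_n_fraction,
                 max_lowq_fraction = max_lowq_fraction,
                 lowq_phred_threshold = lowq_phred_threshold,
                 adapter_sequences = as.character(adapter_sequences)),
            class = "qc_rule")
}

# per-read failure category under a qc_rule; "" = pass.
# categories are assigned in rule order so counts partition the drops.
qc_classify <- function(seqs, rule) {
  quals <- S4Vectors::mcols(seqs)$qualities
  if (is.null(quals)) stop("FASTQ records carry no quality strings")
  wq <- Biostrings::width(quals)
  ws <- Biostrings::width(seqs)
  if (any(wq != ws)) {
    stop("sequence/quality length mismatch at record(s): ",
         paste(utils::head(which(wq != ws)), collapse = ", "))
  }
  n_frac <- as.vector(Biostrings::letterFrequency(seqs, "N")) / ws
  phred <- methods::as(Biostrings::PhredQuality(quals), "IntegerList")
  lowq_frac <- sum(phred <= rule$lowq_phred_threshold) / ws
  adapter <- rep(FALSE, length(seqs))
  for (a in rule$adapter_sequences) {
    adapter <- adapter |
      Biostrings::vcountPattern(a, seqs, fixed = TRUE) > 0
  }
  cat <- character(length(seqs))
  cat[adapter] <- "adapter"
  cat[lowq_frac > rule$max_lowq_fraction] <- "low_quality"
  cat[n_frac >= rule$max_n_fraction] <- "n_content"
  cat
}

#' Filter FASTQ reads on N content, base quality, and adapters
#'
#' A read is dropped iff its fraction of N bases is `>=` the rule's
#' `max_n_fraction`, or the fraction of bases with Phred quality `<=` the
#' rule's threshold is strictly greater than `max_lowq_fraction`, or any
#' configured adapter occurs in it as an exact substring.  When a mate
#' file is supplied, reads are dropped as a pair if either mate fails.
#' Qualities are interpreted as Phred+33.
#'
#' @param fastq_in input FASTQ path.
#' @param fastq_out output FASTQ path for kept reads.
#' @param rule a [qc_rule()].
#' @param mate_in,mate_out optional paths for the second read of a pair.
#' @return list with `kept`, `dropped` (total), `total`, and
#'   `dropped_by_criterion` (`n_content`, `low_quality`, `adapter`, plus
#'   `mate` for reads removed only because their mate failed).
#' @export
qc_filter <- function(fastq_in, fastq_out, rule = qc_rule(),
                      mate_in = NULL, mate_out = NULL) {
  stopifnot(inherits(rule, "qc_rule"))
  r1 <- Biostrings::readDNAStringSet(fastq_in, format = "fastq",
                                     with.qualities = TRUE)
  cat1 <- qc_classify(r1, rule)
  if (is.null(mate_in)) {
    keep <- cat1 == ""
    by_crit <- c(table(factor(cat1[!keep],
                              c("n_content", "low_quality", "adapter", "mate"))))
    write_fastq(r1[keep], fastq_out)
  } else {
    if (is.null(mate_out)) stop("mate_out is required when mate_in is given")
    r2 <- Biostrings::readDNAStringSet(mate_in, format = "fastq",
                                       with.qualities = TRUE)
    if (length(r2) != length(r1)) {
      stop("mate files differ in record count")
    }
    cat2 <- qc_classify(r2, rule)
    keep <- cat1 == "" & cat2 == ""
    # a pair counts once, under the first failing criterion of either mate;
    # "mate" tags reads that only fail through their partner
    pair_cat <- ifelse(cat1 != "", cat1, ifelse(cat2 != "", "mate", ""))
    by_crit <- c(table(factor(pair_cat[!keep],
                              c("n_content", "low_quality", "adapter", "mate"))))
    write_fastq(r1[keep], fastq_out)
    write_fastq(r2[keep], mate_out)
  }
  list(kept = sum(keep), dropped = sum(!keep), total = length(r1),
       dropped_by_criterion = by_crit)
}

write_fastq <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = S4Vectors::mcols(seqs)$qualities)
  invisible(path)
}
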