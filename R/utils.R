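# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic round-half-up (2.5 -> 3); base round() uses banker's rounding
round_half_up <- function(x) floor(x + 0.5)

# rowwise Pearson correlation between paired rows of A and B.
# A column contributes to a row only when finite in both matrices;
# rows with fewer than `min_obs` shared observations give NA.
row_cor <- function(A, B, min_obs = 3L) {
  stopifnot(identical(dim(A), dim(B)))
  ok <- is.finite(A) & is.finite(B)
  A[!ok] <- NA
  B[!ok] <- NA
  n <- rowSums(ok)
  ma <- rowMeans(A, na.rm = TRUE)
  mb <- rowMeans(B, na.rm = TRUE)
  Ac <- A - ma
  Bc <- B - mb
  Ac[!ok] <- 0
  Bc[!ok] <- 0
  den <- sqrt(rowSums(Ac^2) * rowSums(Bc^2))
  r <- ifelse(n >= min_obs & den > 0, rowSums(Ac * Bc) / den, NA_real_)
  r
}

# coerce a genome layout (data.frame with chrom/length, or a named
# numeric vector) into a canonical data.frame
as_layout <- function(layout) {
  if (is.numeric(layout)) {
    stopifnot(!is.null(names(layout)))
    layout <- data.frame(chrom = names(layout), length = as.numeric(layout),
                         stringsAsFactors = FALSE)
  }
  layout <- as.data.frame(layout)
  stopifnot(all(c("chrom", "length") %in% names(layout)))
  layout$chrom <- as.character(layout$chrom)
  layout$length <- as.numeric(layout$length)
  if (anyDuplicated(layout$chrom)) stop("duplicated chromosome names in layout")
  if (any(layout$length <= 0)) stop("chromosome lengths must be positive")
  layout[, c("chrom", "length")]
}

is_sex_chrom <- function(chrom) {
  grepl("^(chr)?(x|y|mt?|m)$", tolower(chrom))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}
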