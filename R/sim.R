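# two-population read-depth simulator with planted CNV loci and a
# ground-truth channel for end-to-end validation

#' Simulation configuration
#'
#' Describes a two-population short-read depth experiment at the window
#' level: window counts for a diploid region are negative-binomial with
#' mean `mean_depth` (scaled by copy number over 2 and by a quadratic
#' GC-bias curve normalized to mean 1), and CNV loci are planted with
#' population-differentiated copy-number frequencies.  Defaults model
#' 10x coverage of 150 bp reads counted in 800 bp half-overlapping
#' windows (`10 * 800 / 150` is about 53 reads per window), 13 + 15
#' samples, and 30 loci with lengths log-uniform on 1.6-282 kb (deletion
#' and mixed loci capped at 50 kb, matching the class-specific size
#' ranges of read-depth CNV maps).
#'
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param n_pop1,n_pop2 sample counts per population (each at least 2).
#' @param mean_depth expected reads per window at copy number 2.
#' @param window_size,window_step window geometry in bp.
#' @param n_cnv_loci number of planted CNV loci.
#' @param cnv_length_range locus length range in bp; must be at least two
#'   windows and at most the longest chromosome.
#' @param dispersion negative-binomial size parameter (`Inf` for
#'   Poisson); default 250 gives roughly 20% extra variance over Poisson
#'   at the default depth, typical of residual overdispersion after GC
#'   correction.
#' @param gc_shape Beta shape parameters for per-window GC (default
#'   `c(14, 18)`: mean 0.44).
#' @param gc_bias_coeffs coefficients `(c0, c1, c2)` of the quadratic
#'   depth-vs-GC bias `c0 + c1*gc + c2*gc^2` (normalized to mean 1 over
#'   windows before use); set `c(1, 0, 0)` for no bias.
#' @param class_probs sampling probabilities for locus classes
#'   `duplication`, `deletion`, `both`.
#' @param loci optional data.frame (`chrom`, `start`, `end`) of planted
#'   locus positions; they must not overlap and must fit their
#'   chromosomes.
#' @param cn_states optional list, one element per locus, each a list of
#'   two named numeric vectors (`pop1`, `pop2`) giving per-population
#'   frequencies over integer copy numbers `0..6` (each summing to 1).
#'   When omitted, differentiated frequencies are generated per locus
#'   (carrier frequency uniform on 0.5-0.95 in one population and 0-0.3
#'   in the other).
#' @param pop_labels labels for the two populations.
#' @param min_locus_gap minimum distance between planted loci in bp.
#' @param seed integer seed governing all draws.
#' @return a `sim_config` list.
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                       n_pop1 = 13, n_pop2 = 15,
                       mean_depth = 53,
                       window_size = 800, window_step = 400,
                       n_cnv_loci = 30,
                       cnv_length_range = c(1600, 282000),
                       dispersion = 250,
                       gc_shape = c(14, 18),
                       gc_bias_coeffs = c(-0.3, 6, -6.6),
                       class_probs = c(duplication = 0.45, deletion = 0.25,
                                       both = 0.30),
                       loci = NULL, cn_states = NULL,
                       pop_labels = c("pop1", "pop2"),
                       min_locus_gap = 4000,
                       seed = 1) {
  stopifnot(n_pop1 >= 2, n_pop2 >= 2, mean_depth > 0,
            length(cnv_length_range) == 2,
            cnv_length_range[1] >= 2 * window_size,
            cnv_length_range[1] <= cnv_length_range[2],
            dispersion > 0, length(pop_labels) == 2)
  layout <- as_layout(chrom_lengths)
  if (is.null(loci) && n_cnv_loci > 0 &&
      cnv_length_range[2] > max(layout$length)) {
    stop("cnv_length_range exceeds the longest chromosome")
  }
  if (!is.null(loci)) {
    loci <- as.data.frame(loci)
    stopifnot(all(c("chrom", "start", "end") %in% names(loci)))
    check_loci(loci, layout)
    n_cnv_loci <- nrow(loci)
  }
  if (!is.null(cn_states)) {
    if (length(cn_states) != n_cnv_loci) {
      stop("cn_states must have one element per locus")
    }
    for (st in cn_states) {
      for (p in c("pop1", "pop2")) {
        f <- st[[p]]
        if (is.null(names(f)) ||
            !all(names(f) %in% as.character(0:6)) ||
            abs(sum(f) - 1) > 1e-8) {
          stop("cn_states frequencies must be named by copy numbers 0..6 and sum to 1")
        }
      }
    }
  }
  structure(list(chrom_lengths = layout, n_pop1 = n_pop1, n_pop2 = n_pop2,
                 mean_depth = mean_depth, window_size = window_size,
                 window_step = window_step, n_cnv_loci = n_cnv_loci,
                 cnv_length_range = cnv_length_range,
                 dispersion = dispersion, gc_shape = gc_shape,
                 gc_bias_coeffs = gc_bias_coeffs, class_probs = class_probs,
                 loci = loci, cn_states = cn_states,
                 pop_labels = pop_labels, min_locus_gap = min_locus_gap,
                 seed = as.integer(seed)),
            class = "sim_config")
}

check_loci <- function(loci, layout) {
  len <- layout$length[match(loci$chrom, layout$chrom)]
  if (any(is.na(len))) stop("locus on unknown chromosome")
  if (any(loci$start < 0) || any(loci$end > len)) {
    stop("planted locus extends beyond its chromosome")
  }
  if (any(loci$end <= loci$start)) stop("planted locus has non-positive span")
  o <- order(loci$chrom, loci$start)
  s <- loci[o, ]
  same <- s$chrom[-1] == s$chrom[-nrow(s)]
  if (nrow(s) > 1 && any(same & s$start[-1] < s$end[-nrow(s)])) {
    stop("planted loci overlap")
  }
  invisible(TRUE)
}

# place loci uniformly, rejecting overlaps / gaps below min_locus_gap
place_loci <- function(layout, lengths, min_gap, max_tries = 20000L) {
  placed <- data.frame(chrom = character(), start = numeric(),
                       end = numeric())
  for (L in lengths) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      ci <- sample.int(nrow(layout), 1, prob = layout$length)
      maxs <- layout$length[ci] - L
      if (maxs < 0) next
      s <- floor(stats::runif(1, 0, maxs + 1))
      e <- s + L
      clash <- placed$chrom == layout$chrom[ci] &
        placed$start < e + min_gap & placed$end > s - min_gap
      if (!any(clash)) {
        placed <- rbind(placed, data.frame(chrom = layout$chrom[ci],
                                           start = s, end = e))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place planted loci; genome too crowded")
  }
  placed
}

# default per-locus frequency tables: a high-carrier population
# (f ~ U(0.5, 0.95)) versus a low-carrier one (f ~ U(0, 0.3))
default_states <- function(class) {
  f_hi <- stats::runif(1, 0.5, 0.95)
  f_lo <- stats::runif(1, 0, 0.3)
  alt <- switch(class,
                duplication = sample(c(3, 4), 1, prob = c(0.7, 0.3)),
                deletion = sample(c(0, 1), 1, prob = c(0.2, 0.8)),
                both = c(1, 3))
  tab <- function(f) {
    fr <- stats::setNames(rep(0, 7), as.character(0:6))
    fr[as.character(alt)] <- f / length(alt)
    fr["2"] <- fr["2"] + 1 - f
    fr
  }
  states <- list(tab(f_hi), tab(f_lo))
  if (sample(2, 1) == 2) states <- rev(states)
  names(states) <- c("pop1", "pop2")
  states
}

pop_variance <- function(x) mean((x - mean(x))^2)

# Vst on true integer copy numbers (kept inline so the truth channel is
# independent of vst())
true_vst_values <- function(cn_mat, pop) {
  apply(cn_mat, 1, function(x) {
    x1 <- x[pop == 1]
    x2 <- x[pop == 2]
    vt <- pop_variance(c(x1, x2))
    if (vt == 0) return(0)
    w <- (pop_variance(x1) * length(x1) + pop_variance(x2) * length(x2)) /
      length(x)
    min(max((vt - w) / vt, 0), 1)
  })
}

#' Simulate two-population window read depths with planted CNVs
#'
#' Generates per-window GC from a Beta distribution, plants
#' non-overlapping CNV loci, draws each sample's integer copy number at
#' each locus from its population's frequency table, and draws window
#' counts from a negative binomial whose expectation is
#' `mean_depth * (CN / 2) * g(GC)`, with `g` the configured quadratic
#' GC-bias curve normalized to mean 1 over windows.  Windows fully
#' inside a planted locus carry the sample's locus copy number; all
#' others are diploid.  A single seed governs all draws, with per-sample
#' sub-streams derived deterministically, so identical configurations
#' give byte-identical output.
#'
#' @param cfg a [sim_config()].
#' @return list with `depth` (raw `depth_matrix`), `grid`, `sample_map`
#'   (columns `sample`, `population`) and `truth`: `loci` (with class and
#'   per-locus `true_vst`), the loci-by-samples integer copy-number
#'   matrix `cn`, and `gc_bias` (the per-window bias factors actually
#'   applied).
#' @export
simulate_depths <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  layout <- cfg$chrom_lengths
  df <- tile_windows(layout, cfg$window_size, cfg$window_step)
  nw <- nrow(df)
  gc <- stats::rbeta(nw, cfg$gc_shape[1], cfg$gc_shape[2])
  df$gc <- gc
  grid <- new_window_grid(df, cfg$window_size, cfg$window_step)
  # GC-bias curve, normalized to mean 1 over the realized windows
  b <- cfg$gc_bias_coeffs
  g_raw <- pmax(b[1] + b[2] * gc + b[3] * gc^2, 0.05)
  g <- g_raw / mean(g_raw)

  # loci: classes, lengths (log-uniform; deletion/both capped at 50 kb),
  # placement, per-population copy-number frequency tables
  n_loci <- cfg$n_cnv_loci
  classes <- sample(names(cfg$class_probs), n_loci, replace = TRUE,
                    prob = cfg$class_probs)
  if (is.null(cfg$loci)) {
    lmax <- ifelse(classes == "duplication", cfg$cnv_length_range[2],
                   pmin(cfg$cnv_length_range[2], 50000))
    lmin <- pmin(cfg$cnv_length_range[1], lmax)
    lens <- round(exp(stats::runif(n_loci, log(lmin), log(lmax))))
    loci <- place_loci(layout, lens, cfg$min_locus_gap)
  } else {
    loci <- cfg$loci[, c("chrom", "start", "end")]
  }
  states <- cfg$cn_states %||% lapply(classes, default_states)

  n1 <- cfg$n_pop1
  n2 <- cfg$n_pop2
  samples <- c(sprintf("%s_s%02d", cfg$pop_labels[1], seq_len(n1)),
               sprintf("%s_s%02d", cfg$pop_labels[2], seq_len(n2)))
  pop <- rep(1:2, c(n1, n2))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n1 + n2)

  # windows fully inside each locus
  locus_windows <- lapply(seq_len(nrow(loci)), function(i) {
    which(grid$chrom == loci$chrom[i] & grid$start >= loci$start[i] &
            grid$end <= loci$end[i])
  })

  cn_truth <- matrix(2L, nrow(loci), n1 + n2,
                     dimnames = list(NULL, samples))
  counts <- matrix(0L, nw, n1 + n2, dimnames = list(NULL, samples))
  for (s in seq_len(n1 + n2)) {
    set.seed(sub_seeds[s])
    cn_w <- rep(2, nw)
    for (i in seq_len(nrow(loci))) {
      st <- states[[i]][[pop[s]]]
      cn <- as.integer(sample(names(st), 1, prob = st))
      cn_truth[i, s] <- cn
      cn_w[locus_windows[[i]]] <- cn
    }
    mu <- cfg$mean_depth * (cn_w / 2) * g
    counts[, s] <- if (is.finite(cfg$dispersion)) {
      stats::rnbinom(nw, mu = mu, size = cfg$dispersion)
    } else {
      stats::rpois(nw, mu)
    }
  }

  loci_out <- data.frame(locus_id = sprintf("LOCUS%03d", seq_len(nrow(loci))),
                         loci, class = classes,
                         true_vst = true_vst_values(cn_truth, pop),
                         stringsAsFactors = FALSE)
  sample_map <- data.frame(sample = samples,
                           population = cfg$pop_labels[pop],
                           stringsAsFactors = FALSE)
  list(depth = depth_matrix(grid, counts, normalized = FALSE),
       grid = grid,
       sample_map = sample_map,
       truth = list(loci = loci_out, cn = cn_truth, gc_bias = g))
}

#' Write simulation ground truth to plain-text files
#'
#' Emits the planted loci as BED (0-based half-open; name = locus id,
#' score = true Vst), the loci-by-samples integer copy-number matrix as
#' TSV, and a per-locus true-Vst TSV.
#'
#' @param truth the `truth` element of a [simulate_depths()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bed <- truth$loci[, c("chrom", "start", "end", "locus_id")]
  bed$score <- truth$loci$true_vst
  bed$strand <- "."
  utils::write.table(bed, file.path(dir, "truth_loci.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_tsv(cbind(data.frame(locus_id = truth$loci$locus_id),
                  as.data.frame(truth$cn)),
            file.path(dir, "truth_cn.tsv"))
  write_tsv(truth$loci[, c("locus_id", "chrom", "start", "end", "class",
                           "true_vst")],
            file.path(dir, "truth_vst.tsv"))
  invisible(dir)
}

#' Emit a minimal SAM file of simulated single-end alignments
#'
#' A tiny alignment emitter used to exercise the SAM ingestion path:
#' reads are placed uniformly on the genome with fixed-length matches,
#' and a few unmapped and low-MAPQ records are included.
#'
#' @param path output SAM path.
#' @param layout genome layout (see [build_grid()]).
#' @param n_reads mapped reads to emit (default 300).
#' @param read_len read length in bp (default 100).
#' @param n_unmapped unmapped records to append (default 2).
#' @param mapq mapping quality for regular reads (default 60).
#' @param seed integer seed.
#' @return the path, invisibly.
#' @export
sim_sam <- function(path, layout, n_reads = 300, read_len = 100,
                    n_unmapped = 2, mapq = 60, seed = 1) {
  layout <- as_layout(layout)
  set.seed(seed)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", layout$chrom,
                      as.integer(layout$length)))
  ci <- sample.int(nrow(layout), n_reads, replace = TRUE,
                   prob = layout$length)
  pos1 <- vapply(ci, function(i) {
    1L + floor(stats::runif(1, 0, layout$length[i] - read_len))
  }, numeric(1))
  seq <- strrep("A", read_len)
  qual <- strrep("I", read_len)
  rec <- sprintf("read%04d\t0\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
                 seq_len(n_reads), layout$chrom[ci], as.integer(pos1),
                 mapq, read_len, seq, qual)
  if (n_unmapped > 0) {
    rec <- c(rec, sprintf("unmapped%02d\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s",
                          seq_len(n_unmapped), seq, qual))
  }
  writeLines(c(header, rec), path)
  invisible(path)
}

#' Compare called CNVRs with planted truth loci
#'
#' Matches called regions to truth loci at a reciprocal-overlap
#' threshold (the intersection must cover at least `min_reciprocal` of
#' both intervals) and reports recall (matched truth loci / truth loci)
#' and precision (matched calls / calls).
#'
#' @param cnvrs a `cnvr_set` or a data.frame with `chrom`, `start`,
#'   `end`, `id`.
#' @param truth_loci data.frame with `chrom`, `start`, `end`,
#'   `locus_id` (as in the simulator truth).
#' @param min_reciprocal reciprocal-overlap threshold (default 0.5).
#' @return list with `recall`, `precision`, `n_truth`, `n_called`, and
#'   `matches` (data.frame `locus_id`, `cnvr_id`).
#' @export
evaluate_calls <- function(cnvrs, truth_loci, min_reciprocal = 0.5) {
  reg <- if (inherits(cnvrs, "cnvr_set")) cnvrs$regions else
    as.data.frame(cnvrs)
  matches <- data.frame(locus_id = character(), cnvr_id = character())
  if (nrow(reg) > 0 && nrow(truth_loci) > 0) {
    gr_c <- GenomicRanges::GRanges(reg$chrom,
                                   IRanges::IRanges(reg$start + 1L, reg$end))
    gr_t <- GenomicRanges::GRanges(truth_loci$chrom,
                                   IRanges::IRanges(truth_loci$start + 1L,
                                                    truth_loci$end))
    hits <- GenomicRanges::findOverlaps(gr_c, gr_t)
    if (length(hits)) {
      qi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      ov <- GenomicRanges::width(GenomicRanges::pintersect(gr_c[qi],
                                                           gr_t[si]))
      rec_ok <- ov >= min_reciprocal * GenomicRanges::width(gr_c[qi]) &
        ov >= min_reciprocal * GenomicRanges::width(gr_t[si])
      matches <- unique(data.frame(locus_id = truth_loci$locus_id[si[rec_ok]],
                                   cnvr_id = reg$id[qi[rec_ok]],
                                   stringsAsFactors = FALSE))
    }
  }
  list(recall = if (nrow(truth_loci)) {
         length(unique(matches$locus_id)) / nrow(truth_loci)
       } else NA_real_,
       precision = if (nrow(reg)) {
         length(unique(matches$cnvr_id)) / nrow(reg)
       } else NA_real_,
       n_truth = nrow(truth_loci), n_called = nrow(reg),
       matches = matches)
}
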