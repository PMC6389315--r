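# K-mer spectrum genome-size estimation.  Samples are haploid males, so
# the spectrum has a single coverage peak and no heterozygosity mixture;
# the estimator is the standard peak-normalised k-mer-mass method.

#' Build a canonical k-mer multiplicity histogram
#'
#' Counts canonical k-mers (the lexicographic minimum of a k-mer and its
#' reverse complement, in 2-bit encoding) across a read set and tabulates
#' the multiplicity spectrum.  K-mers containing non-ACGT characters are
#' skipped and reported in `skipped`.  The histogram satisfies exact mass
#' conservation: `total_kmers + skipped` equals the sum over reads of
#' `read_length - k + 1`.
#'
#' @param reads a [simulate_reads()] result, a character vector of
#'   sequences, or a path to a FASTQ file.
#' @param k k-mer length, 1--32; default 21.
#' @param max_multiplicity histogram cap; k-mers seen more often are
#'   pooled into the top bin.
#' @return Object of class `kmer_histogram`: `entries`
#'   (data.frame `multiplicity`, `count`), `k`, `total_kmers`,
#'   `distinct`, `skipped`.
#' @export
build_kmer_histogram <- function(reads, k = 21, max_multiplicity = 10000) {
  if (inherits(reads, "read_set")) reads <- reads$reads
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- read_fastq(reads)
  stopifnot(is.character(reads))
  res <- kmer_count_cpp(reads, as.integer(k), as.integer(max_multiplicity))
  nz <- which(res$hist > 0)
  structure(list(entries = data.frame(multiplicity = nz,
                                      count = res$hist[nz]),
                 k = k, total_kmers = res$total_kmers,
                 distinct = res$distinct, skipped = res$skipped,
                 max_multiplicity = max_multiplicity),
            class = "kmer_histogram")
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat("kmer_histogram (k =", x$k, "):",
      format(x$total_kmers, big.mark = ","), "k-mers,",
      format(x$distinct, big.mark = ","), "distinct,",
      x$skipped, "skipped\n")
  invisible(x)
}

#' Write a k-mer histogram as two-column TSV
#'
#' Format matches common k-mer-counter `histo` output: multiplicity and
#' count, tab-separated, no header.
#'
#' @param hist a `kmer_histogram`.
#' @param path output file.
#' @export
write_kmer_histogram <- function(hist, path) {
  write.table(hist$entries, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column multiplicity/count histogram TSV
#'
#' @param path input file.
#' @param k the k-mer length the histogram was built with.
#' @return A `kmer_histogram`.
#' @export
read_kmer_histogram <- function(path, k = 21) {
  df <- read.delim(path, header = FALSE, col.names = c("multiplicity", "count"))
  kmer_histogram_from_entries(df, k)
}

#' Construct a histogram object from explicit entries
#'
#' Mostly useful for idealised spectra in examples and tests.
#'
#' @param entries data.frame with columns `multiplicity`, `count`.
#' @param k k-mer length.
#' @return A `kmer_histogram`.
#' @export
kmer_histogram_from_entries <- function(entries, k = 21) {
  stopifnot(all(c("multiplicity", "count") %in% names(entries)),
            all(entries$multiplicity >= 1), all(entries$count >= 0))
  entries <- entries[order(entries$multiplicity), , drop = FALSE]
  structure(list(entries = entries, k = k,
                 total_kmers = sum(entries$multiplicity * entries$count),
                 distinct = sum(entries$count), skipped = 0,
                 max_multiplicity = max(entries$multiplicity)),
            class = "kmer_histogram")
}

#' Estimate genome size and repeat fraction from a k-mer histogram
#'
#' Peak-normalised k-mer mass: the error cutoff is the first local
#' minimum of the spectrum, the coverage peak is the mode above the
#' cutoff (refined by a local mass centroid so the estimate is not
#' quantised to integer multiplicities), and
#' `genome_size = sum(m * count_m, m > cutoff) / coverage_peak`.
#' The repeat fraction is the k-mer mass at multiplicities above
#' `repeat_threshold * coverage_peak` relative to all above-cutoff mass;
#' with haploid samples a multiplier of 1.5 separates single-copy from
#' multi-copy sequence.
#'
#' @param hist a `kmer_histogram`.
#' @param repeat_threshold multiplier on the coverage peak above which
#'   k-mers are counted as repetitive; default 1.5.
#' @param sample,variant optional labels carried into the result.
#' @return Object of class `genome_size_estimate` with fields
#'   `genome_size`, `coverage_peak`, `error_cutoff`, `repeat_fraction`,
#'   `sample`, `variant`.
#' @export
#' @examples
#' h <- kmer_histogram_from_entries(
#'   data.frame(multiplicity = c(30, 60), count = c(9e5, 5e4)))
#' estimate_genome_size(h)   # 1 Mb, repeat fraction 0.1
estimate_genome_size <- function(hist, repeat_threshold = 1.5,
                                 sample = NA_character_,
                                 variant = NA_character_) {
  stopifnot(inherits(hist, "kmer_histogram"), repeat_threshold > 1)
  mx <- max(hist$entries$multiplicity)
  cnt <- numeric(mx)
  cnt[hist$entries$multiplicity] <- hist$entries$count
  if (mx < 2) stop("histogram too narrow for a coverage peak")
  rising <- which(cnt[-1] > cnt[-mx])
  if (length(rising) == 0)
    stop("no local minimum in the spectrum; coverage too low or ",
         "error rate too high to separate the coverage peak")
  cutoff <- rising[1]
  above <- (cutoff + 1):mx
  if (sum(cnt[above]) == 0) stop("no k-mer mass above the error cutoff")
  mode_m <- above[which.max(cnt[above])]
  # centroid refinement of the peak position over a local window
  hw <- max(1, floor(mode_m / 8))
  win <- max(cutoff + 1, mode_m - hw):min(mx, mode_m + hw)
  peak <- sum(win * cnt[win]) / sum(cnt[win])
  mass <- sum(above * cnt[above])
  rep_from <- which(seq_len(mx) > repeat_threshold * peak)
  rep_from <- rep_from[rep_from > cutoff]
  structure(list(genome_size = mass / peak, coverage_peak = peak,
                 coverage_mode = mode_m, error_cutoff = cutoff,
                 repeat_fraction = sum(rep_from * cnt[rep_from]) / mass,
                 repeat_threshold = repeat_threshold,
                 sample = sample, variant = variant),
            class = "genome_size_estimate")
}

#' @export
print.genome_size_estimate <- function(x, ...) {
  cat(sprintf(
    "genome size %.0f bp (coverage peak %.1f, error cutoff %d, repeat fraction %.3f)\n",
    x$genome_size, x$coverage_peak, x$error_cutoff, x$repeat_fraction))
  invisible(x)
}

#' Paired b-vs-B percent difference with confidence interval
#'
#' Per-pair percent difference `100 * (b - B) / B`, its mean, the
#' two-sided 95% t confidence interval on the mean, and a one-sided
#' paired t-test of b > B.  Pairs with a missing member are dropped with
#' a warning.  When all differences are identical the t statistic is
#' degenerate: the CI collapses to the mean and the p-value is 0.5 at
#' exactly zero mean (0 or 1 for a nonzero constant difference).
#'
#' @param B,b numeric vectors of per-sample values (e.g. genome sizes),
#'   aligned by pair.
#' @param conf confidence level for the two-sided CI.
#' @return Object of class `paired_difference` with `per_pair_pct`,
#'   `mean_pct`, `ci95`, `t_stat`, `p_one_sided`, `n_pairs`.
#' @export
#' @examples
#' paired_comparison(rep(100, 5), rep(103.59, 5))   # 3.59%, zero-width CI
paired_comparison <- function(B, b, conf = 0.95) {
  stopifnot(length(B) == length(b))
  ok <- is.finite(B) & is.finite(b)
  if (any(!ok)) {
    warning(sum(!ok), " incomplete pair(s) dropped")
    B <- B[ok]; b <- b[ok]
  }
  n <- length(B)
  if (n < 2) stop("need at least 2 complete pairs")
  pct <- 100 * (b - B) / B
  m <- mean(pct)
  if (sd(pct) == 0) {
    ci <- c(m, m)
    t_stat <- NA_real_
    p <- if (m > 0) 0 else if (m < 0) 1 else 0.5
  } else {
    tt2 <- t.test(pct, conf.level = conf)
    tt1 <- t.test(pct, alternative = "greater")
    ci <- as.numeric(tt2$conf.int)
    t_stat <- unname(tt1$statistic)
    p <- tt1$p.value
  }
  structure(list(per_pair_pct = pct, mean_pct = m, ci95 = ci,
                 t_stat = t_stat, p_one_sided = p, n_pairs = n),
            class = "paired_difference")
}

#' @export
print.paired_difference <- function(x, ...) {
  cat(sprintf("paired difference: %.2f%% (95%% CI %.2f-%.2f%%), n = %d, one-sided p = %s\n",
              x$mean_pct, x$ci95[1], x$ci95[2], x$n_pairs,
              format.pval(x$p_one_sided)))
  invisible(x)
}
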