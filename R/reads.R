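# Short-read simulation for the k-mer stage: uniform start positions,
# substitution-only errors.  Sufficient for k-mer spectra; read indels
# and quality profiles are deliberately not modelled.

#' Simulate short reads from a genome
#'
#' Draws `round(coverage * L / read_length)` reads with uniform start
#' positions from each strand's forward sequence and applies independent
#' per-base substitution errors.  The expected total base count is
#' `coverage * L` by construction.
#'
#' @param genome a character string, or a named character vector of
#'   chromosome sequences (concatenated coverage is preserved per
#'   chromosome).
#' @param coverage fold coverage (> 0).
#' @param read_length read length in bp; must not exceed the shortest
#'   sequence.
#' @param error_rate per-base substitution probability in \[0, 1).
#' @param seed optional RNG seed.
#' @return Object of class `read_set`: list with `reads` (character
#'   vector), `read_length`, `coverage`, `error_rate`.
#' @export
simulate_reads <- function(genome, coverage, read_length = 125,
                           error_rate = 0, seed = NULL) {
  stopifnot(coverage > 0, error_rate >= 0, error_rate < 1)
  if (!is.null(seed)) withr::local_seed(seed)
  seqs <- if (length(genome) > 1 || !is.null(names(genome))) genome else c(g = genome)
  if (any(nchar(seqs) < read_length))
    stop("read_length exceeds a sequence length")
  reads <- unlist(lapply(seqs, function(s) {
    L <- nchar(s)
    n <- round(coverage * L / read_length)
    starts <- floor(runif(n, 1, L - read_length + 2))
    substring(s, starts, starts + read_length - 1)
  }), use.names = FALSE)
  if (error_rate > 0 && length(reads) > 0) {
    total <- length(reads) * read_length
    n_err <- rbinom(1, total, error_rate)
    if (n_err > 0) {
      ri <- sample.int(length(reads), n_err, replace = TRUE)
      pi <- sample.int(read_length, n_err, replace = TRUE)
      bases <- c("A", "C", "G", "T")
      for (e in seq_len(n_err)) {
        old <- substr(reads[ri[e]], pi[e], pi[e])
        new <- sample(setdiff(bases, old), 1L)
        substr(reads[ri[e]], pi[e], pi[e]) <- new
      }
    }
  }
  structure(list(reads = reads, read_length = read_length,
                 coverage = coverage, error_rate = error_rate),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set:", length(x$reads), "reads x", x$read_length, "bp (",
      x$coverage, "x nominal, error", x$error_rate, ")\n")
  invisible(x)
}

#' Write a read set as FASTQ
#'
#' Constant quality (`I`, Q40) since the simulator models substitution
#' errors only.
#'
#' @param reads a `read_set` or character vector.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  if (inherits(reads, "read_set")) reads <- reads$reads
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- paste0("read_", seq_along(x))
  q <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = q)
  invisible(path)
}

#' Read sequences from FASTQ into a character vector
#'
#' @param path FASTQ file (optionally gzip-compressed).
#' @return Character vector of read sequences.
#' @export
read_fastq <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}
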