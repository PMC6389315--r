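# Independent oracle implementations used across tests.  These share no
# code with the package: reverse complement via chartr, k-mer counting
# via substring/table, alignment scoring re-derived from the declared
# model, genome reconstruction by sequential splicing.

oracle_revcomp <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

# brute-force canonical k-mer histogram
oracle_kmer_histogram <- function(seqs, k) {
  kmers <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  }))
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  rc <- oracle_revcomp(kmers)
  canon <- ifelse(kmers <= rc, kmers, rc)
  mult <- table(table(canon))
  data.frame(multiplicity = as.integer(names(mult)),
             count = as.integer(mult))
}

# step score of the declared alignment model, recomputed independently
oracle_step_score <- function(a, b, pi, pj, i, j, p) {
  dL <- (a[i] - a[pi]) - (b[j] - b[pj])
  span <- ((i - pi) + (j - pj)) / 2
  cost <- min(dL^2 / (2 * span * p$sizing_sd^2), p$max_step_cost)
  p$match_bonus - cost - p$miss_penalty * ((i - pi - 1) + (j - pj - 1))
}

# optimal alignment score via longest path on the explicit DAG (igraph,
# Bellman-Ford on negated weights); independent of the package's DP.
oracle_align_score_igraph <- function(a, b, p) {
  n <- length(a); m <- length(b)
  id <- function(i, j) (i - 1) * m + j
  from <- integer(0); to <- integer(0); w <- numeric(0)
  START <- n * m + 1; END <- n * m + 2
  for (i in 1:n) for (j in 1:m) {
    from <- c(from, START, id(i, j)); to <- c(to, id(i, j), END)
    w <- c(w, -p$match_bonus, 0)
  }
  for (i in 2:n) for (j in 2:m)
    for (pi in max(1, i - 1 - p$max_skip):(i - 1))
      for (pj in max(1, j - 1 - p$max_skip):(j - 1)) {
        from <- c(from, id(pi, pj)); to <- c(to, id(i, j))
        w <- c(w, -oracle_step_score(a, b, pi, pj, i, j, p))
      }
  g <- igraph::graph_from_edgelist(cbind(from, to))
  igraph::E(g)$weight <- w
  d <- igraph::distances(g, v = START, to = END, mode = "out",
                         algorithm = "bellman-ford")
  -as.numeric(d)
}

# exhaustive enumeration over every monotone matching (tiny maps only)
oracle_align_score_exhaustive <- function(a, b, p) {
  n <- length(a); m <- length(b)
  best <- -Inf
  chains <- list(list())
  extend <- function(chain) {
    last <- if (length(chain)) chain[[length(chain)]] else c(0, 0)
    score <- 0
    if (length(chain)) {
      score <- p$match_bonus
      if (length(chain) > 1)
        for (q in 2:length(chain)) {
          pr <- chain[[q - 1]]; cu <- chain[[q]]
          if (cu[1] - pr[1] - 1 > p$max_skip ||
              cu[2] - pr[2] - 1 > p$max_skip) return(NULL)
          score <- score +
            oracle_step_score(a, b, pr[1], pr[2], cu[1], cu[2], p)
        }
    }
    score
  }
  # enumerate all subsets of A indices and matching B index combinations
  for (k in 1:min(n, m)) {
    ia <- utils::combn(n, k, simplify = FALSE)
    ib <- utils::combn(m, k, simplify = FALSE)
    for (A in ia) for (B in ib) {
      sc <- extend(lapply(seq_len(k), function(q) c(A[q], B[q])))
      if (!is.null(sc)) best <- max(best, sc)
    }
  }
  best
}

# splice a truth table into a reference genome, chromosome by chromosome
oracle_apply_truth <- function(genome_B, truth) {
  out <- genome_B
  for (ch in names(genome_B)) {
    tt <- truth[truth$chromosome == ch, , drop = FALSE]
    if (nrow(tt) == 0) next
    tt <- tt[order(tt$ref_start, decreasing = TRUE), ]  # right to left
    s <- out[[ch]]
    for (i in seq_len(nrow(tt))) {
      left <- substr(s, 1, tt$ref_start[i])
      if (tt$type[i] == "INS") {
        right <- substr(s, tt$ref_start[i] + 1, nchar(s))
        s <- paste0(left, tt$content[i], right)
      } else {
        right <- substr(s, tt$ref_end[i] + 1, nchar(s))
        s <- paste0(left, right)
      }
    }
    out[[ch]] <- s
  }
  out
}

# small equal-length chromosome table for statistics tests
toy_chrom_table <- function(n = 16, len = 1e6, sg = c(0.25, 0.75)) {
  data.frame(chromosome = paste0("chr", seq_len(n)),
             length = rep(len, n),
             is_social = c(rep(FALSE, n - 1), TRUE),
             sg_start = c(rep(NA, n - 1), sg[1] * len),
             sg_end = c(rep(NA, n - 1), sg[2] * len))
}
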