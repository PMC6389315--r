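# Synthetic paired haploid genomes with planted structural variants.
# Coordinates are 0-based, half-open throughout (documented in writers).

#' Random DNA sequence
#'
#' @param n length in bp.
#' @return A single character string over A/C/G/T.
#' @export
random_dna <- function(n) {
  if (n == 0) return("")
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE)])
}

#' Specification of a synthetic genome pair
#'
#' Bundles and validates the parameters of the B/b genome pair generator:
#' a chromosome table with one social chromosome carrying a supergene
#' interval, the number of insertions and deletions distinguishing the b
#' genome from the B genome, the fraction of insertions directed into the
#' supergene interval, and the indel size distribution (log-uniform, with
#' a hard >= 3 kb floor matching the detection threshold used throughout).
#'
#' @param chrom_table chromosome table, see [fire_ant_chromosomes()].
#' @param n_insertions,n_deletions counts of planted indels (b relative
#'   to B; insertions make b longer).
#' @param insertion_bias fraction of insertions whose position is drawn
#'   inside the supergene interval; the remainder are uniform over the
#'   rest of the genome.
#' @param size_range two-element range of indel sizes in bp; sizes are
#'   drawn log-uniformly.  Minimum allowed is 3000.
#' @param repeat_families optional `data.frame(unit_length, n_copies)`;
#'   each family is planted as a tandem array shared by both genomes, and
#'   inserted DNA is then drawn from family units (so the b genome's
#'   extra content is repetitive), emulating the observation that the
#'   size difference is concentrated in repeats.
#' @param seed optional RNG seed for the generation step.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(chrom_table = fire_ant_chromosomes(0.01),
                        n_insertions = 163, n_deletions = 187,
                        insertion_bias = 0.32,
                        size_range = c(3e3, 1e5) * 0.01,
                        repeat_families = NULL, seed = NULL) {
  chrom_table <- validate_chrom_table(chrom_table)
  stopifnot(n_insertions >= 0, n_deletions >= 0,
            insertion_bias >= 0, insertion_bias <= 1,
            length(size_range) == 2L, size_range[1] <= size_range[2])
  min_indel <- 3000 * sum(chrom_table$length) / 350.94e6
  if (size_range[1] < min_indel * 0.999)
    stop("indel sizes below the 3 kb detection floor (scaled: ",
         round(min_indel), " bp) are not allowed")
  if (!is.null(repeat_families))
    stopifnot(is.data.frame(repeat_families),
              all(c("unit_length", "n_copies") %in% names(repeat_families)))
  structure(list(chrom_table = chrom_table,
                 n_insertions = n_insertions, n_deletions = n_deletions,
                 insertion_bias = insertion_bias, size_range = size_range,
                 repeat_families = repeat_families, seed = seed),
            class = "genome_spec")
}

#' Plant indel coordinates on a chromosome table
#'
#' Draws the coordinates and sizes of the structural differences between
#' a b and a B genome without materialising sequence: insertions fall
#' inside the supergene interval with probability `insertion_bias` and
#' uniformly (by length) over the remaining genome otherwise; deletions
#' fall uniformly by length over all chromosomes.  Sizes are log-uniform
#' over `size_range`.  Events never overlap on the reference genome.
#'
#' @param chrom_table chromosome table.
#' @param n_insertions,n_deletions event counts.
#' @param insertion_bias supergene-directed fraction of insertions.
#' @param size_range indel size range in bp (log-uniform).
#' @param seed optional RNG seed.
#' @return A `data.frame` truth table with columns `chromosome`, `type`
#'   (`"INS"`/`"DEL"`), `ref_start`, `ref_end` (B coordinates, 0-based
#'   half-open; zero-width for insertions), `alt_start`, `alt_end`
#'   (b coordinates), `size`, and `in_supergene`.
#' @export
plant_indels <- function(chrom_table, n_insertions, n_deletions,
                         insertion_bias = 0.32, size_range = c(3e3, 1e5),
                         seed = NULL) {
  chrom_table <- validate_chrom_table(chrom_table)
  if (!is.null(seed)) withr::local_seed(seed)
  soc <- chrom_table[chrom_table$is_social, ]
  sg_len <- soc$sg_end - soc$sg_start
  draw_size <- function(n)
    round(exp(runif(n, log(size_range[1]), log(size_range[2]))))

  n_tot <- n_insertions + n_deletions
  if (n_tot == 0L)
    return(data.frame(chromosome = character(), type = character(),
                      ref_start = numeric(), ref_end = numeric(),
                      alt_start = numeric(), alt_end = numeric(),
                      size = numeric(), in_supergene = logical()))

  in_sg <- if (n_insertions > 0) runif(n_insertions) < insertion_bias else logical()
  if (sum(in_sg) > sg_len)
    stop("supergene interval too small to host ", sum(in_sg), " insertions")

  # uniform-by-length placement over the genome minus the supergene span
  w_out <- chrom_table$length
  w_out[chrom_table$is_social] <- w_out[chrom_table$is_social] - sg_len
  place_ins <- function(inside) {
    if (inside) {
      list(chrom = soc$chromosome,
           pos = floor(runif(1, soc$sg_start, soc$sg_end)))
    } else {
      ci <- sample.int(nrow(chrom_table), 1L, prob = w_out)
      u <- floor(runif(1, 0, w_out[ci]))
      if (chrom_table$is_social[ci] && u >= soc$sg_start) u <- u + sg_len
      list(chrom = chrom_table$chromosome[ci], pos = u)
    }
  }
  place_del <- function(size) {
    ok <- chrom_table$length > size
    if (!any(ok)) stop("deletion size ", size, " exceeds every chromosome")
    ci <- sample.int(nrow(chrom_table), 1L, prob = chrom_table$length * ok)
    list(chrom = chrom_table$chromosome[ci],
         pos = floor(runif(1, 0, chrom_table$length[ci] - size)))
  }

  type <- c(rep("INS", n_insertions), rep("DEL", n_deletions))
  size <- draw_size(n_tot)
  chrom <- character(n_tot); start <- numeric(n_tot)
  spans <- list()  # per-chromosome occupied [start, end) spans on B
  for (i in seq_len(n_tot)) {
    for (attempt in seq_len(200L)) {
      p <- if (type[i] == "INS") place_ins(in_sg[i]) else place_del(size[i])
      s <- p$pos
      e <- if (type[i] == "DEL") p$pos + size[i] else p$pos + 1
      occ <- spans[[p$chrom]]
      if (is.null(occ) || !any(s < occ[, 2] & e > occ[, 1])) {
        spans[[p$chrom]] <- rbind(occ, c(s, e))
        chrom[i] <- p$chrom; start[i] <- s
        break
      }
      if (attempt == 200L)
        stop("could not place non-overlapping indels; genome too small")
    }
  }

  tt <- data.frame(chromosome = chrom, type = type,
                   ref_start = start,
                   ref_end = ifelse(type == "DEL", start + size, start),
                   size = size,
                   in_supergene = chrom == soc$chromosome &
                     start >= soc$sg_start & start < soc$sg_end,
                   stringsAsFactors = FALSE)
  tt <- tt[order(match(tt$chromosome, chrom_table$chromosome), tt$ref_start), ]
  rownames(tt) <- NULL
  # b coordinates: cumulative shift from upstream events on the same chromosome
  tt$alt_start <- NA_real_; tt$alt_end <- NA_real_
  for (ch in unique(tt$chromosome)) {
    idx <- which(tt$chromosome == ch)
    shift <- 0
    for (i in idx) {
      tt$alt_start[i] <- tt$ref_start[i] + shift
      if (tt$type[i] == "INS") {
        tt$alt_end[i] <- tt$alt_start[i] + tt$size[i]
        shift <- shift + tt$size[i]
      } else {
        tt$alt_end[i] <- tt$alt_start[i]
        shift <- shift - tt$size[i]
      }
    }
  }
  tt
}

#' Generate a B/b genome pair with planted indels
#'
#' Materialises the reference (B) genome as random sequence, optionally
#' plants shared tandem-repeat arrays, then derives the b genome by
#' applying the planted insertions and deletions from [plant_indels()].
#' The returned truth table is exhaustive: applying its edits to the B
#' genome reconstructs the b genome byte for byte.
#'
#' @param spec a [genome_spec()].
#' @return A list with `genome_B`, `genome_b` (named character vectors of
#'   chromosome sequences), `truth` (the truth table, with an added
#'   `content` column holding inserted/deleted sequence), and `spec`.
#' @export
generate_genome_pair <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  if (!is.null(spec$seed)) withr::local_seed(spec$seed)
  ct <- spec$chrom_table

  genome_B <- setNames(vapply(ct$length, random_dna, character(1)),
                       ct$chromosome)
  units <- character()
  if (!is.null(spec$repeat_families)) {
    for (f in seq_len(nrow(spec$repeat_families))) {
      ul <- spec$repeat_families$unit_length[f]
      nc <- spec$repeat_families$n_copies[f]
      unit <- random_dna(ul)
      units <- c(units, unit)
      arr <- strrep(unit, nc)
      ci <- sample.int(nrow(ct), 1L, prob = ct$length)
      if (nchar(arr) >= ct$length[ci])
        stop("repeat array larger than chromosome ", ct$chromosome[ci])
      at <- floor(runif(1, 0, ct$length[ci] - nchar(arr)))
      substr(genome_B[ci], at + 1, at + nchar(arr)) <- arr
    }
  }

  truth <- plant_indels(ct, spec$n_insertions, spec$n_deletions,
                        spec$insertion_bias, spec$size_range)
  ins_content <- function(size) {
    if (length(units) > 0) {
      u <- units[sample.int(length(units), 1L)]
      substr(strrep(u, ceiling(size / nchar(u))), 1, size)
    } else random_dna(size)
  }
  truth$content <- rep(NA_character_, nrow(truth))

  genome_b <- genome_B
  for (ch in names(genome_B)) {
    idx <- which(truth$chromosome == ch)
    if (length(idx) == 0L) next
    seq_B <- genome_B[[ch]]
    # assemble b as alternating kept pieces and edit pieces
    pieces <- character(0)
    cursor <- 0
    for (i in idx) {
      pieces <- c(pieces, substr(seq_B, cursor + 1, truth$ref_start[i]))
      if (truth$type[i] == "INS") {
        truth$content[i] <- ins_content(truth$size[i])
        pieces <- c(pieces, truth$content[i])
        cursor <- truth$ref_start[i]
      } else {
        truth$content[i] <- substr(seq_B, truth$ref_start[i] + 1,
                                   truth$ref_end[i])
        cursor <- truth$ref_end[i]
      }
    }
    pieces <- c(pieces, substr(seq_B, cursor + 1, nchar(seq_B)))
    genome_b[[ch]] <- paste(pieces, collapse = "")
  }

  list(genome_B = genome_B, genome_b = genome_b, truth = truth, spec = spec)
}

#' Write genome sequences as FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Write a truth/call table as BED-like TSV
#'
#' Coordinates are 0-based, half-open (BED convention); a header comment
#' records this.
#'
#' @param tt data.frame with at least `chromosome`, `ref_start`,
#'   `ref_end`, `type`, `size`.
#' @param path output file.
#' @param sample sample label stored in the last column.
#' @export
write_indel_tsv <- function(tt, path, sample = "b_vs_B") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 0-based, half-open", con)
  out <- data.frame(chrom = tt$chromosome, start = tt$ref_start,
                    end = tt$ref_end, type = tt$type, size_bp = tt$size,
                    sample = sample)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED-like indel TSV written by [write_indel_tsv()]
#'
#' @param path input file.
#' @return data.frame with columns `chromosome`, `ref_start`, `ref_end`,
#'   `type`, `size`, `sample`.
#' @export
read_indel_tsv <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  data.frame(chromosome = df$chrom, ref_start = df$start, ref_end = df$end,
             type = df$type, size = df$size_bp, sample = df$sample,
             stringsAsFactors = FALSE)
}
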