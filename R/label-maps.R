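# Ordered-label maps: the in-memory stand-in for optical (Bionano-style)
# restriction/nicking maps.  Positions are 0-based bp, strictly increasing.

#' Construct a label map
#'
#' @param map_id identifier.
#' @param positions strictly increasing 0-based label coordinates (bp).
#' @param length map length in bp (>= last position + 1).
#' @param chromosome chromosome id, or `NA` for unplaced maps.
#' @return Object of class `label_map`.
#' @export
label_map <- function(map_id, positions, length,
                      chromosome = NA_character_) {
  positions <- as.numeric(positions)
  if (is.unsorted(positions, strictly = TRUE))
    stop("label positions must be strictly increasing")
  if (length(positions) > 0 &&
      (positions[1] < 0 || positions[length(positions)] >= length))
    stop("labels must satisfy 0 <= position < length")
  structure(list(map_id = map_id, chromosome = chromosome,
                 positions = positions, length = as.numeric(length)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat("label_map", x$map_id,
      if (!is.na(x$chromosome)) paste0("(", x$chromosome, ")"),
      "-", length(x$positions), "labels over",
      format(x$length, big.mark = ","), "bp\n")
  invisible(x)
}

#' Digest a genome sequence into a label map
#'
#' Labels every occurrence of a recognition motif (exact match on the
#' given strand, as for a nicking enzyme), or -- when `density` is given
#' instead -- places labels as a uniform point process.  Optional noise
#' (interval sizing error, label misses, false labels) is applied through
#' [perturb_label_map()].  With all noise parameters zero and a motif,
#' the returned positions are exactly the 0-based motif match positions.
#'
#' @param genome a sequence (character string), or an integer length when
#'   using `density`.
#' @param motif recognition sequence, e.g. `"GCTCTTC"`.
#' @param density labels per bp, alternative to `motif`.
#' @param sizing_sd,miss_rate,false_rate noise parameters, see
#'   [perturb_label_map()].
#' @param map_id,chromosome identifiers for the resulting map.
#' @param seed optional RNG seed.
#' @return A [label_map()].
#' @export
digest_to_label_map <- function(genome, motif = NULL, density = NULL,
                                sizing_sd = 0, miss_rate = 0,
                                false_rate = 0, map_id = "map",
                                chromosome = NA_character_, seed = NULL) {
  if (is.null(motif) == is.null(density))
    stop("give exactly one of `motif` or `density`")
  if (!is.null(seed)) withr::local_seed(seed)
  if (!is.null(motif)) {
    stopifnot(is.character(genome), nchar(motif) > 0)
    L <- nchar(genome)
    hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(genome))
    pos <- Biostrings::start(hits) - 1
  } else {
    stopifnot(density > 0)
    L <- if (is.character(genome)) nchar(genome) else as.numeric(genome)
    n <- rpois(1, L * density)
    pos <- sort(unique(floor(runif(n, 0, L))))
  }
  m <- label_map(map_id, pos, L, chromosome)
  perturb_label_map(m, sizing_sd, miss_rate, false_rate)
}

#' Apply a noise model to a label map
#'
#' The minimal optical-map error model: each inter-label interval is
#' perturbed by Gaussian noise (sd `sizing_sd` bp, intervals floored at
#' 1 bp), each label is then lost independently with probability
#' `miss_rate`, and spurious labels appear as a Poisson process with
#' expectation `false_rate` per true label.  The returned map carries an
#' `origin` attribute giving, for each output label, the index of the
#' source label in the input map (`NA` for false labels) -- the ground
#' truth used to score alignment recovery.
#'
#' @param map a [label_map()].
#' @param sizing_sd interval sizing error sd in bp.
#' @param miss_rate per-label loss probability in \[0, 1\].
#' @param false_rate expected false labels per true label (>= 0).
#' @param seed optional RNG seed.
#' @return A perturbed [label_map()] with attribute `origin`.
#' @export
perturb_label_map <- function(map, sizing_sd = 0, miss_rate = 0,
                              false_rate = 0, seed = NULL) {
  stopifnot(inherits(map, "label_map"),
            miss_rate >= 0, miss_rate <= 1, false_rate >= 0, sizing_sd >= 0)
  if (!is.null(seed)) withr::local_seed(seed)
  pos <- map$positions
  n <- length(pos)
  len <- map$length
  origin <- seq_len(n)
  if (n > 0 && sizing_sd > 0) {
    d <- diff(c(0, pos))
    d <- pmax(1, d + rnorm(n, 0, sizing_sd))
    new_pos <- cumsum(d)
    len <- len + (new_pos[n] - pos[n])
    pos <- new_pos
  }
  if (n > 0 && miss_rate > 0) {
    keep <- runif(n) >= miss_rate
    pos <- pos[keep]; origin <- origin[keep]
  }
  if (false_rate > 0 && n > 0) {
    nf <- rpois(1, false_rate * n)
    if (nf > 0) {
      fp <- floor(runif(nf, 0, len))
      pos <- c(pos, fp); origin <- c(origin, rep(NA_integer_, nf))
    }
  }
  o <- order(pos)
  pos <- pos[o]; origin <- origin[o]
  dup <- duplicated(pos)
  pos <- pos[!dup]; origin <- origin[!dup]
  out <- label_map(map$map_id, pos, max(len, if (length(pos)) pos[length(pos)] + 1 else 1),
                   map$chromosome)
  attr(out, "origin") <- origin
  out
}

#' Write label maps as TSV
#'
#' One row per label; columns `map_id`, `chromosome`, `label_index`
#' (1-based), `position_bp` (0-based), `map_length_bp`.
#'
#' @param maps a `label_map` or list of them.
#' @param path output file.
#' @export
write_label_maps <- function(maps, path) {
  if (inherits(maps, "label_map")) maps <- list(maps)
  rows <- lapply(maps, function(m) {
    data.frame(map_id = m$map_id, chromosome = m$chromosome,
               label_index = seq_along(m$positions),
               position_bp = m$positions, map_length_bp = m$length)
  })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# positions: 0-based bp", con)
  write.table(do.call(rbind, rows), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read label maps written by [write_label_maps()]
#'
#' @param path input file.
#' @return A named list of [label_map()] objects.
#' @export
read_label_maps <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  out <- lapply(split(df, df$map_id), function(d) {
    d <- d[order(d$label_index), ]
    label_map(d$map_id[1], d$position_bp, d$map_length_bp[1],
              d$chromosome[1])
  })
  out[unique(df$map_id)]
}
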