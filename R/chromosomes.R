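#' Chromosome table for the fire ant optical reference
#'
#' Returns a 16-chromosome table matching the superscaffolded optical
#' genome used throughout the package: 350.94 Mb total, with the social
#' chromosome (chr16) spanning 29.61 Mb and carrying the supergene
#' interval at 7.7--28.6 Mb (20.9 Mb).  Lengths of chromosomes 1--15 are
#' not individually published at optical resolution; they are apportioned
#' deterministically on a linearly decreasing profile so that they sum to
#' the published non-social total (321.33 Mb).
#'
#' @param scale numeric scale factor applied to all coordinates.  Use
#'   e.g. `scale = 0.01` to obtain a miniature genome whose sequences can
#'   be materialised in memory while preserving all proportions.
#' @return A `data.frame` with columns `chromosome`, `length`,
#'   `is_social`, `sg_start`, `sg_end` (supergene interval, 0-based
#'   half-open; `NA` off the social chromosome).
#' @export
#' @examples
#' ct <- fire_ant_chromosomes()
#' sum(ct$length)                     # 350.94 Mb
#' ct[ct$is_social, ]
fire_ant_chromosomes <- function(scale = 1) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  non_social_total <- 350.94e6 - 29.61e6
  w <- (25:11) / sum(25:11)
  len <- c(round(non_social_total * w), 29.61e6)
  ct <- data.frame(
    chromosome = paste0("chr", 1:16),
    length     = round(len * scale),
    is_social  = c(rep(FALSE, 15), TRUE),
    sg_start   = c(rep(NA_real_, 15), round(7.7e6 * scale)),
    sg_end     = c(rep(NA_real_, 15), round(28.6e6 * scale)),
    stringsAsFactors = FALSE
  )
  validate_chrom_table(ct)
}

#' Validate a chromosome table
#'
#' Checks the invariants every downstream statistic relies on: positive
#' lengths, exactly one social chromosome, and a supergene interval lying
#' within its chromosome.
#'
#' @param ct data.frame with columns `chromosome`, `length`, `is_social`,
#'   and (on the social chromosome) `sg_start`, `sg_end`.
#' @return The validated table, invisibly unchanged.
#' @export
validate_chrom_table <- function(ct) {
  stopifnot(is.data.frame(ct))
  req <- c("chromosome", "length", "is_social")
  if (!all(req %in% names(ct)))
    stop("chromosome table needs columns: ", paste(req, collapse = ", "))
  if (any(ct$length <= 0)) stop("chromosome lengths must be > 0")
  if (sum(ct$is_social) != 1L)
    stop("exactly one social chromosome required")
  if (anyDuplicated(ct$chromosome))
    stop("duplicated chromosome ids")
  soc <- ct[ct$is_social, ]
  if (!is.null(ct$sg_start)) {
    if (is.na(soc$sg_start) || is.na(soc$sg_end))
      stop("social chromosome must carry a supergene interval")
    if (soc$sg_start < 0 || soc$sg_end > soc$length ||
        soc$sg_start >= soc$sg_end)
      stop("supergene interval must lie within the social chromosome")
  } else {
    stop("chromosome table needs sg_start/sg_end columns")
  }
  ct
}

#' Genome share of one chromosome
#'
#' Percentage of the total placed (superscaffolded) genome length carried
#' by one chromosome; the denominator excludes nothing because the table
#' itself only holds placed chromosomes.
#'
#' @param ct chromosome table (see [fire_ant_chromosomes()]).
#' @param chromosome chromosome id.
#' @return Percentage in \[0, 100\].
#' @export
genome_share <- function(ct, chromosome) {
  ct <- validate_chrom_table(ct)
  i <- match(chromosome, ct$chromosome)
  if (is.na(i)) stop("unknown chromosome: ", chromosome)
  100 * ct$length[i] / sum(ct$length)
}
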