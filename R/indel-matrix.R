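# Presence/absence indel matrices across individuals.  A locus is kept
# only when it is present in at least `min_carriers` individuals and has
# coverage information in every individual -- the filters under which
# absence is informative and distances need no missing-data handling.

new_indel_matrix <- function(values, covered, loci, samples) {
  stopifnot(is.matrix(values), all(dim(values) == dim(covered)),
            nrow(values) == nrow(loci), ncol(values) == nrow(samples))
  rownames(values) <- rownames(covered) <- loci$locus
  colnames(values) <- colnames(covered) <- samples$sample
  structure(list(values = values, covered = covered,
                 loci = loci, samples = samples),
            class = "indel_matrix")
}

#' @export
print.indel_matrix <- function(x, ...) {
  cat("indel_matrix:", nrow(x$values), "loci x", ncol(x$values),
      "samples (", sum(x$loci$partition == "supergene"), "supergene,",
      sum(x$loci$partition == "background"), "background )\n")
  invisible(x)
}

#' Generate a planted-structure indel matrix
#'
#' Emulates the six-individual (3 species x B/b variants) design:
#' background loci share presence/absence within species (each locus is
#' carried by a random proper subset of species), supergene loci share
#' alleles within supergene variant across species (most are carried by
#' the b individuals, reflecting insertion accumulation on the
#' nonrecombining variant).  Independent flips at rate `noise` and an
#' independent per-cell missing-coverage mask complete the model.
#'
#' @param n_species,n_per_species design; one B and one b individual per
#'   species.
#' @param n_background_loci,n_supergene_loci locus counts per partition.
#' @param noise per-cell flip probability.
#' @param missing_rate per-cell probability of lacking coverage.
#' @param chrom_table chromosome table used to draw locus coordinates.
#' @param prob_b_carrier probability a supergene locus is carried by the
#'   b class rather than the B class.
#' @param seed optional RNG seed.
#' @return An unfiltered `indel_matrix`; apply [filter_indel_matrix()]
#'   before distance computation.
#' @export
generate_indel_matrix <- function(n_species = 3, n_per_species = 2,
                                  n_background_loci = 60,
                                  n_supergene_loci = 40,
                                  noise = 0.02, missing_rate = 0.03,
                                  chrom_table = fire_ant_chromosomes(),
                                  prob_b_carrier = 0.75, seed = NULL) {
  stopifnot(n_per_species == 2, n_species >= 2)
  if (!is.null(seed)) withr::local_seed(seed)
  chrom_table <- validate_chrom_table(chrom_table)
  species <- c("invicta", "quinquecuspis", "richteri",
               paste0("species", seq_len(max(0, n_species - 3))))[1:n_species]
  samples <- data.frame(
    sample = paste(rep(species, each = 2), c("B", "b"), sep = "_"),
    species = rep(species, each = 2),
    variant = rep(c("B", "b"), n_species),
    stringsAsFactors = FALSE)
  n_loci <- n_background_loci + n_supergene_loci
  partition <- rep(c("background", "supergene"),
                   c(n_background_loci, n_supergene_loci))
  values <- matrix(0L, n_loci, nrow(samples))
  for (i in seq_len(n_background_loci)) {
    k <- sample.int(n_species - 1L, 1L)
    sp <- sample(species, k)
    values[i, samples$species %in% sp] <- 1L
  }
  for (i in seq_len(n_supergene_loci)) {
    cls <- if (runif(1) < prob_b_carrier) "b" else "B"
    values[n_background_loci + i, samples$variant == cls] <- 1L
  }
  if (noise > 0) {
    flip <- matrix(runif(length(values)) < noise, nrow(values))
    values[flip] <- 1L - values[flip]
  }
  covered <- matrix(runif(length(values)) >= missing_rate, nrow(values))

  soc <- chrom_table[chrom_table$is_social, ]
  bg_ct <- chrom_table[!chrom_table$is_social, ]
  bg_chrom <- sample(bg_ct$chromosome, n_background_loci, replace = TRUE,
                     prob = bg_ct$length)
  bg_start <- floor(runif(n_background_loci) *
                      (bg_ct$length[match(bg_chrom, bg_ct$chromosome)] - 2e4))
  sg_start <- floor(runif(n_supergene_loci, soc$sg_start, soc$sg_end - 2e4))
  width <- floor(runif(n_loci, 3e3, 2e4))
  loci <- data.frame(
    locus = sprintf("L%04d", seq_len(n_loci)),
    chromosome = c(bg_chrom, rep(soc$chromosome, n_supergene_loci)),
    start = c(bg_start, sg_start), stringsAsFactors = FALSE)
  loci$end <- loci$start + width
  loci$partition <- partition
  new_indel_matrix(values, covered, loci, samples)
}

#' Filter an indel matrix to shared, fully covered loci
#'
#' Keeps loci that are present in at least `min_carriers` individuals
#' and covered in all individuals.  Idempotent.
#'
#' @param x an `indel_matrix`.
#' @param min_carriers minimum number of carrier individuals; default 2.
#' @return A filtered `indel_matrix` (possibly with zero loci).
#' @export
filter_indel_matrix <- function(x, min_carriers = 2) {
  stopifnot(inherits(x, "indel_matrix"))
  keep <- rowSums(x$covered) == ncol(x$covered) &
    rowSums(x$values == 1L) >= min_carriers
  new_indel_matrix(x$values[keep, , drop = FALSE],
                   x$covered[keep, , drop = FALSE],
                   x$loci[keep, , drop = FALSE], x$samples)
}

#' Build an indel matrix from per-individual call sets
#'
#' Merges indel calls across individuals into loci by greedy reciprocal
#' interval overlap (a call joins a locus when each interval covers at
#' least `reciprocal` of the other), marks presence per individual,
#' derives coverage from per-individual coverage intervals (a locus is
#' covered when its interval lies within a covered interval, or when the
#' individual itself carries a call there), assigns each locus to the
#' supergene or background partition, and applies the
#' [filter_indel_matrix()] rules.
#'
#' @param call_sets named list (one element per individual) of call
#'   data.frames with columns `chromosome`, `ref_start`, `ref_end`,
#'   `type`.
#' @param coverage named list of data.frames with columns `chromosome`,
#'   `start`, `end` giving covered intervals per individual; `NULL`
#'   means full coverage everywhere.
#' @param samples data.frame with columns `sample`, `species`,
#'   `variant`; rownames of the matrix follow `sample`.
#' @param chrom_table chromosome table (partition assignment).
#' @param reciprocal reciprocal overlap fraction for merging.
#' @param min_carriers presence filter, see [filter_indel_matrix()].
#' @return A filtered `indel_matrix`; zero loci is a valid result.
#' @export
build_indel_matrix <- function(call_sets, coverage = NULL, samples,
                               chrom_table, reciprocal = 0.5,
                               min_carriers = 2) {
  stopifnot(is.list(call_sets), !is.null(names(call_sets)),
            all(samples$sample %in% names(call_sets)))
  chrom_table <- validate_chrom_table(chrom_table)
  pooled <- do.call(rbind, lapply(samples$sample, function(s) {
    cs <- call_sets[[s]]
    if (is.null(cs) || nrow(cs) == 0) return(NULL)
    data.frame(sample = s, chromosome = cs$chromosome,
               start = cs$ref_start, end = cs$ref_end, type = cs$type,
               stringsAsFactors = FALSE)
  }))
  n_s <- nrow(samples)
  if (is.null(pooled) || nrow(pooled) == 0) {
    empty <- matrix(integer(), 0, n_s)
    return(new_indel_matrix(empty, matrix(logical(), 0, n_s),
                            data.frame(locus = character(),
                                       chromosome = character(),
                                       start = numeric(), end = numeric(),
                                       partition = character()),
                            samples))
  }
  pooled$end <- pmax(pooled$end, pooled$start + 1)   # point insertions
  pooled <- pooled[order(pooled$chromosome, pooled$type, pooled$start), ]
  # greedy clustering within chromosome+type by reciprocal overlap with
  # the cluster representative (the first member)
  cl <- integer(nrow(pooled)); n_cl <- 0L
  rep_s <- numeric(); rep_e <- numeric(); rep_key <- character()
  for (i in seq_len(nrow(pooled))) {
    key <- paste(pooled$chromosome[i], pooled$type[i])
    s <- pooled$start[i]; e <- pooled$end[i]
    hit <- 0L
    cand <- which(rep_key == key)
    for (j in cand) {
      ov <- min(e, rep_e[j]) - max(s, rep_s[j])
      if (ov >= reciprocal * (e - s) &&
          ov >= reciprocal * (rep_e[j] - rep_s[j])) { hit <- j; break }
    }
    if (hit == 0L) {
      n_cl <- n_cl + 1L
      rep_s[n_cl] <- s; rep_e[n_cl] <- e; rep_key[n_cl] <- key
      hit <- n_cl
    }
    cl[i] <- hit
  }
  loci <- data.frame(
    locus = sprintf("L%04d", seq_len(n_cl)),
    chromosome = vapply(strsplit(rep_key, " "), `[`, character(1), 1L),
    start = rep_s, end = rep_e,
    type = vapply(strsplit(rep_key, " "), `[`, character(1), 2L),
    stringsAsFactors = FALSE)
  soc <- chrom_table[chrom_table$is_social, ]
  loci$partition <- ifelse(
    loci$chromosome == soc$chromosome &
      loci$start < soc$sg_end & loci$end > soc$sg_start,
    "supergene", "background")
  values <- matrix(0L, n_cl, n_s)
  for (i in seq_len(nrow(pooled)))
    values[cl[i], match(pooled$sample[i], samples$sample)] <- 1L
  covered <- matrix(TRUE, n_cl, n_s)
  if (!is.null(coverage)) {
    for (s in seq_len(n_s)) {
      cov <- coverage[[samples$sample[s]]]
      if (is.null(cov)) next
      covered[, s] <- vapply(seq_len(n_cl), function(l) {
        any(cov$chromosome == loci$chromosome[l] &
              cov$start <= loci$start[l] & cov$end >= loci$end[l])
      }, logical(1)) | values[, s] == 1L
    }
  }
  filter_indel_matrix(new_indel_matrix(values, covered, loci, samples),
                      min_carriers)
}

#' Write an indel matrix as TSV
#'
#' @param x an `indel_matrix`.
#' @param path output file.
#' @export
write_indel_matrix <- function(x, path) {
  df <- cbind(x$loci, as.data.frame(x$values))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
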