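# Reproduction experiments: each function re-runs one property-based
# study condition end to end at desk scale and returns the measured
# quantity.  These back the package's acceptance checks and give users a
# one-call way to re-derive the headline numbers.

#' Enrichment detection across planted-insertion replicates
#'
#' For each seed, plants the published event counts (163 insertions with
#' the supergene-directed bias calibrated so about a third land on the
#' social chromosome, 187 length-uniform deletions) on the full-scale
#' chromosome table, runs the enrichment Z machinery on the insertion
#' counts, and records whether the social chromosome -- and only the
#' social chromosome -- is Bonferroni-significant at `alpha`.
#'
#' @param n_seeds number of independent replicates.
#' @param n_insertions,n_deletions,insertion_bias generator settings.
#' @param alpha family-wise level.
#' @param seed base RNG seed.
#' @return List: `exact_rate` (fraction of seeds flagging exactly the
#'   social chromosome), `n_seeds`, and the per-seed logical vector.
#' @export
insertion_enrichment_experiment <- function(n_seeds = 100,
                                            n_insertions = 163,
                                            n_deletions = 187,
                                            insertion_bias = 0.32,
                                            alpha = 0.05, seed = 1) {
  ct <- fire_ant_chromosomes()
  soc <- ct$chromosome[ct$is_social]
  hits <- vapply(seq_len(n_seeds), function(i) {
    tt <- plant_indels(ct, n_insertions, n_deletions, insertion_bias,
                       seed = seed + i)
    ins <- tt[tt$type == "INS", ]
    counts <- table(factor(ins$chromosome, levels = ct$chromosome))
    r <- suppressWarnings(enrichment_zscores(as.numeric(counts), ct,
                                             alpha = alpha))
    flagged <- r$table$chromosome[r$table$enriched]
    identical(flagged, soc)
  }, logical(1))
  list(exact_rate = mean(hits), n_seeds = n_seeds, hits = hits)
}

#' Genome-size estimator recovery on synthetic read sets
#'
#' For each seed, simulates a random genome, draws reads at the given
#' coverage and error rate, builds the k-mer spectrum and estimates
#' genome size; returns the per-seed percent bias.
#'
#' @param n_seeds replicates.
#' @param genome_size true genome size in bp.
#' @param coverage fold coverage.
#' @param read_length read length in bp.
#' @param error_rate per-base substitution rate.
#' @param k k-mer length.
#' @param seed base RNG seed.
#' @return List: `bias_pct` (per-seed signed percent error),
#'   `median_abs_bias_pct`, `n_seeds`.
#' @export
genome_size_recovery_experiment <- function(n_seeds = 20,
                                            genome_size = 2e5,
                                            coverage = 30,
                                            read_length = 125,
                                            error_rate = 0.001, k = 21,
                                            seed = 1) {
  bias <- vapply(seq_len(n_seeds), function(i) {
    withr::local_seed(seed + i)
    g <- random_dna(genome_size)
    rs <- simulate_reads(g, coverage, read_length, error_rate)
    est <- estimate_genome_size(build_kmer_histogram(rs, k = k))
    100 * (est$genome_size - genome_size) / genome_size
  }, numeric(1))
  list(bias_pct = bias, median_abs_bias_pct = median(abs(bias)),
       n_seeds = n_seeds)
}

#' Coverage of the paired-comparison confidence interval
#'
#' Simulates replicate five-pair studies in which the b member of each
#' pair is larger by a true mean percentage with between-pair scatter,
#' and counts how often the two-sided 95% t interval covers the truth.
#'
#' @param n_rep replicate studies.
#' @param true_pct true mean percent difference.
#' @param sd_pct between-pair sd of the percent difference.
#' @param n_pairs pairs per study.
#' @param seed base RNG seed.
#' @return List: `covered` (count), `coverage` (fraction), `n_rep`.
#' @export
paired_ci_coverage_experiment <- function(n_rep = 100, true_pct = 3.6,
                                          sd_pct = 1, n_pairs = 5,
                                          seed = 1) {
  withr::local_seed(seed)
  covered <- 0L
  for (r in seq_len(n_rep)) {
    B <- runif(n_pairs, 4e8, 4.6e8)
    b <- B * (1 + rnorm(n_pairs, true_pct, sd_pct) / 100)
    pc <- paired_comparison(B, b)
    if (pc$ci95[1] <= true_pct && true_pct <= pc$ci95[2])
      covered <- covered + 1L
  }
  list(covered = covered, coverage = covered / n_rep, n_rep = n_rep)
}

#' Recovery of planted grouping structure by neighbour joining
#'
#' For each seed, generates a planted six-individual indel matrix,
#' filters it, infers background and supergene trees, and records
#' whether all species form clans on the background tree and both
#' variant classes form clans on the supergene tree.
#'
#' @param n_seeds replicates.
#' @param noise,missing_rate generator settings.
#' @param seed base RNG seed.
#' @return List: `species_rate`, `variant_rate`, `both_rate`, `n_seeds`.
#' @export
grouping_recovery_experiment <- function(n_seeds = 100, noise = 0.02,
                                         missing_rate = 0.03, seed = 1) {
  sp <- logical(n_seeds); va <- logical(n_seeds)
  for (i in seq_len(n_seeds)) {
    im <- generate_indel_matrix(noise = noise, missing_rate = missing_rate,
                                seed = seed + i)
    f <- filter_indel_matrix(im)
    bg <- infer_indel_tree(f, "background")
    sg <- infer_indel_tree(f, "supergene")
    sp[i] <- all(bg$grouping$is_clan)
    va[i] <- all(sg$grouping$is_clan)
  }
  list(species_rate = mean(sp), variant_rate = mean(va),
       both_rate = mean(sp & va), n_seeds = n_seeds)
}

# miniature four-chromosome table used by the optical-map experiments
miniature_chrom_table <- function(chrom_len = 6e5) {
  data.frame(chromosome = paste0("chr", 1:4),
             length = rep(chrom_len, 4),
             is_social = c(FALSE, FALSE, FALSE, TRUE),
             sg_start = c(NA, NA, NA, round(chrom_len / 6)),
             sg_end = c(NA, NA, NA, round(5 * chrom_len / 6)))
}

#' Reciprocal indel-call consistency on a noisy synthetic map pair
#'
#' Generates a miniature genome pair with planted indels, digests both
#' genomes into label maps with an optical-style noise model, aligns
#' every chromosome in both directions, calls indels, and measures the
#' fraction of calls recovered reciprocally.
#'
#' @param n_insertions,n_deletions planted events across the genome.
#' @param size_range indel sizes in bp (log-uniform).
#' @param motif labelling motif.
#' @param sizing_sd,miss_rate,false_rate map noise model.
#' @param max_skip aligner skip bound.
#' @param seed RNG seed.
#' @return List: `consistency`, `n_calls_ab`, `n_calls_ba`.
#' @export
reciprocal_recovery_experiment <- function(n_insertions = 24,
                                           n_deletions = 16,
                                           size_range = c(5e3, 2.5e4),
                                           motif = "GCTCTTC",
                                           sizing_sd = 150,
                                           miss_rate = 0.05,
                                           false_rate = 0.02,
                                           max_skip = 4, seed = 1) {
  withr::local_seed(seed)
  ct <- miniature_chrom_table()
  spec <- genome_spec(ct, n_insertions, n_deletions, insertion_bias = 0.4,
                      size_range = size_range)
  gp <- generate_genome_pair(spec)
  ab <- list(); ba <- list()
  for (ch in ct$chromosome) {
    mB <- digest_to_label_map(gp$genome_B[[ch]], motif = motif,
                              sizing_sd = sizing_sd, miss_rate = miss_rate,
                              false_rate = false_rate,
                              map_id = paste0(ch, "_B"), chromosome = ch)
    mb <- digest_to_label_map(gp$genome_b[[ch]], motif = motif,
                              sizing_sd = sizing_sd, miss_rate = miss_rate,
                              false_rate = false_rate,
                              map_id = paste0(ch, "_b"), chromosome = ch)
    ab[[ch]] <- call_indels(align_label_maps(mB, mb, sizing_sd = sizing_sd,
                                             max_skip = max_skip), mB, mb)
    ba[[ch]] <- call_indels(align_label_maps(mb, mB, sizing_sd = sizing_sd,
                                             max_skip = max_skip), mb, mB)
  }
  callsAB <- do.call(rbind, ab); callsBA <- do.call(rbind, ba)
  list(consistency = reciprocal_consistency(callsAB, callsBA),
       n_calls_ab = nrow(callsAB), n_calls_ba = nrow(callsBA))
}

#' Net overhang recovery of a planted tail excess
#'
#' Plants an unmatched tail of `excess_bp` on the b copy of the social
#' chromosome of a miniature genome pair (no internal indels), digests
#' and aligns all chromosomes, and measures the net per-chromosome
#' overhang excess.
#'
#' @param excess_bp planted tail excess in bp.
#' @param motif,sizing_sd,miss_rate,false_rate as in
#'   [reciprocal_recovery_experiment()].
#' @param seed RNG seed.
#' @return List: `net` (per-chromosome data.frame from
#'   [net_overhang_difference()]), `social_net_bp`, `excess_bp`,
#'   `relative_error`.
#' @export
overhang_recovery_experiment <- function(excess_bp = 6e4,
                                         motif = "GCTCTTC",
                                         sizing_sd = 150,
                                         miss_rate = 0.05,
                                         false_rate = 0.02, seed = 1) {
  withr::local_seed(seed)
  ct <- miniature_chrom_table()
  spec <- genome_spec(ct, 0, 0)
  gp <- generate_genome_pair(spec)
  soc <- ct$chromosome[ct$is_social]
  gp$genome_b[[soc]] <- paste0(gp$genome_b[[soc]], random_dna(excess_bp))
  oh <- list()
  for (ch in ct$chromosome) {
    mB <- digest_to_label_map(gp$genome_B[[ch]], motif = motif,
                              sizing_sd = sizing_sd, miss_rate = miss_rate,
                              false_rate = false_rate,
                              map_id = paste0(ch, "_B"), chromosome = ch)
    mb <- digest_to_label_map(gp$genome_b[[ch]], motif = motif,
                              sizing_sd = sizing_sd, miss_rate = miss_rate,
                              false_rate = false_rate,
                              map_id = paste0(ch, "_b"), chromosome = ch)
    al <- align_label_maps(mB, mb, sizing_sd = sizing_sd)
    oh[[ch]] <- call_overhangs(al, mB, mb, alignment_id = ch)
  }
  net <- net_overhang_difference(do.call(rbind, oh), ct)
  social_net <- net$net_bp[net$chromosome == soc]
  list(net = net, social_net_bp = social_net, excess_bp = excess_bp,
       relative_error = abs(social_net - excess_bp) / excess_bp)
}
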