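# Generators: planted indels, genome pairs, digests, reads, matrices.

test_that("insertion bias places insertions where requested", {
  ct <- fire_ant_chromosomes()
  tt <- plant_indels(ct, n_insertions = 10, n_deletions = 0,
                     insertion_bias = 1, seed = 11)
  expect_equal(nrow(tt), 10)
  expect_true(all(tt$in_supergene))
  expect_true(all(tt$chromosome == "chr16"))
  # bias honoured in expectation over many insertions
  tt2 <- plant_indels(ct, n_insertions = 2000, n_deletions = 0,
                      insertion_bias = 0.32, seed = 12)
  expect_gt(mean(tt2$in_supergene), 0.32 - 3 * sqrt(0.32 * 0.68 / 2000))
  expect_lt(mean(tt2$in_supergene), 0.32 + 3 * sqrt(0.32 * 0.68 / 2000))
})

test_that("deletions are spread by chromosome length, sizes respect the floor", {
  ct <- fire_ant_chromosomes()
  tt <- plant_indels(ct, n_insertions = 0, n_deletions = 3000, seed = 13)
  expect_true(all(tt$size >= 3000))
  # length-proportional placement: chi-square against length expectation
  counts <- table(factor(tt$chromosome, levels = ct$chromosome))
  e <- 3000 * ct$length / sum(ct$length)
  expect_lt(sum((counts - e)^2 / e), qchisq(0.999, 15))
})

test_that("zero planted indels gives identical genomes", {
  spec <- genome_spec(fire_ant_chromosomes(0.002), n_insertions = 0,
                      n_deletions = 0, seed = 1)
  gp <- generate_genome_pair(spec)
  expect_identical(gp$genome_B, gp$genome_b)
})

test_that("truth table is exhaustive: splicing reconstructs genome_b exactly", {
  spec <- genome_spec(fire_ant_chromosomes(0.002), n_insertions = 12,
                      n_deletions = 10, size_range = c(6, 200), seed = 42,
                      repeat_families = data.frame(unit_length = 25,
                                                   n_copies = 40))
  gp <- generate_genome_pair(spec)
  rebuilt <- oracle_apply_truth(gp$genome_B, gp$truth)
  expect_identical(rebuilt, gp$genome_b)
  # alt coordinates point at the inserted content in genome_b
  ins <- gp$truth[gp$truth$type == "INS", ]
  for (i in seq_len(nrow(ins)))
    expect_identical(substr(gp$genome_b[[ins$chromosome[i]]],
                            ins$alt_start[i] + 1, ins$alt_end[i]),
                     ins$content[i])
})

test_that("generators are deterministic under a fixed seed", {
  spec <- genome_spec(fire_ant_chromosomes(0.001), n_insertions = 5,
                      n_deletions = 5, size_range = c(3, 50), seed = 7)
  expect_identical(generate_genome_pair(spec), generate_genome_pair(spec))
  g <- random_dna(2000)
  r1 <- simulate_reads(g, 5, 50, 0.01, seed = 3)
  r2 <- simulate_reads(g, 5, 50, 0.01, seed = 3)
  expect_identical(r1, r2)
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(r1, f1); write_fastq(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("motif digestion finds exact 0-based match positions", {
  m <- digest_to_label_map("AAGCTAGCTT", motif = "GCT")
  expect_equal(m$positions, c(2, 6))
  expect_equal(m$length, 10)
  m2 <- perturb_label_map(m, miss_rate = 1)
  expect_length(m2$positions, 0)
})

test_that("density digestion and perturbation keep origin bookkeeping", {
  m <- digest_to_label_map(5e5, density = 1 / 5e3, seed = 21)
  expect_gt(length(m$positions), 50)
  noisy <- perturb_label_map(m, sizing_sd = 150, miss_rate = 0.1,
                             false_rate = 0.05, seed = 22)
  org <- attr(noisy, "origin")
  expect_equal(length(org), length(noisy$positions))
  surv <- org[!is.na(org)]
  expect_true(!is.unsorted(surv))
  # sizing noise is local: surviving labels stay near their source
  expect_lt(max(abs(noisy$positions[!is.na(org)] - m$positions[surv])),
            150 * 6 * sqrt(length(m$positions)))
})

test_that("read simulation hits target coverage and exactness without error", {
  g <- random_dna(1e5)
  rs <- simulate_reads(g, 30, 100, error_rate = 0, seed = 5)
  total <- sum(nchar(rs$reads))
  expect_lt(abs(total - 30 * 1e5) / (30 * 1e5), 0.03)
  idx <- sample(length(rs$reads), 20)
  for (r in rs$reads[idx]) expect_true(grepl(r, g, fixed = TRUE))
  expect_error(simulate_reads(g, 1, 1e6), "read_length")
})

test_that("planted indel matrix has the designed within-group structure", {
  im <- generate_indel_matrix(noise = 0, missing_rate = 0, seed = 9)
  v <- im$values
  sp <- im$samples$species
  for (s in unique(sp)) {
    pair <- which(sp == s)
    expect_equal(sum(v[im$loci$partition == "background", pair[1]] !=
                       v[im$loci$partition == "background", pair[2]]), 0)
  }
  bs <- which(im$samples$variant == "b")
  sg <- im$loci$partition == "supergene"
  expect_equal(sum(v[sg, bs[1]] != v[sg, bs[2]]), 0)
  expect_equal(sum(v[sg, bs[1]] != v[sg, bs[3]]), 0)
})

test_that("impossible placements raise explicit errors", {
  ct <- toy_chrom_table(4, 1e5, sg = c(0.5, 0.50002))
  expect_error(plant_indels(ct, n_insertions = 50, n_deletions = 0,
                            insertion_bias = 1, seed = 1),
               "supergene interval too small")
})
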