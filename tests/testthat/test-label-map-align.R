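# Dynamic-programming label-map alignment, indel and overhang calling.

mk_map <- function(pos, len, id = "m", chrom = "chr1")
  label_map(id, pos, len, chrom)

test_that("a map aligns to itself with every label matched and zero sizing error", {
  m <- mk_map(c(0, 5000, 12000, 20000, 31000), 35000)
  al <- align_label_maps(m, m)
  expect_equal(nrow(al$matched_pairs), 5)
  expect_equal(al$matched_pairs[, 1], al$matched_pairs[, 2])
  expect_equal(al$score, 5 * al$params$match_bonus)
  expect_error(align_label_maps(mk_map(c(1), 10), m), "at least 2")
})

test_that("a single planted insertion appears as one interval discrepancy", {
  a <- mk_map(seq(0, 90000, by = 10000), 1e5, "A")
  bpos <- a$positions
  bpos[bpos > 45000] <- bpos[bpos > 45000] + 5000   # +5 kb between labels 5,6
  b <- mk_map(bpos, 1e5 + 5000, "B")
  al <- align_label_maps(a, b)
  expect_equal(nrow(al$matched_pairs), 10)
  calls <- call_indels(al, a, b, min_size = 3000)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$type, "insertion")
  expect_equal(calls$size, 5000)
  expect_equal(calls$ref_start, 40000)
  expect_equal(calls$ref_end, 50000)
  # below the 3 kb floor: no call
  bpos2 <- a$positions
  bpos2[bpos2 > 45000] <- bpos2[bpos2 > 45000] + 2000
  al2 <- align_label_maps(a, mk_map(bpos2, 1e5 + 2000, "B2"))
  expect_equal(nrow(call_indels(al2, a, mk_map(bpos2, 1e5 + 2000, "B2"))), 0)
})

test_that("role swap converts insertions to deletions of equal size", {
  set.seed(31)
  a <- mk_map(sort(sample(1e5, 30)) - 1, 1e5, "A")
  bpos <- a$positions
  bpos[bpos > 50000] <- bpos[bpos > 50000] + 8000
  bpos <- bpos[bpos < 20000 | bpos > 25000]   # and drop a few labels
  b <- mk_map(bpos, 108000, "B")
  ab <- call_indels(align_label_maps(a, b), a, b)
  ba <- call_indels(align_label_maps(b, a), b, a)
  expect_equal(sort(ab$size[ab$type == "insertion"]),
               sort(ba$size[ba$type == "deletion"]))
})

test_that("DP score equals the independent DAG longest-path optimum", {
  skip_if_not_installed("igraph")
  set.seed(77)
  p <- list(sizing_sd = 150, miss_penalty = 3, max_skip = 2,
            match_bonus = 5, max_step_cost = 25)
  for (rep in 1:30) {
    n <- sample(6:12, 1); m <- sample(6:12, 1)
    a <- sort(runif(n, 0, 6e4)); b <- sort(runif(m, 0, 6e4))
    al <- align_label_maps(mk_map(a, 7e4, "a"), mk_map(b, 7e4, "b"),
                           sizing_sd = p$sizing_sd,
                           miss_penalty = p$miss_penalty,
                           max_skip = p$max_skip,
                           match_bonus = p$match_bonus,
                           max_step_cost = p$max_step_cost)
    expect_equal(al$score, oracle_align_score_igraph(a, b, p),
                 tolerance = 1e-8)
  }
})

test_that("DP score equals exhaustive enumeration on tiny maps", {
  set.seed(78)
  p <- list(sizing_sd = 150, miss_penalty = 3, max_skip = 2,
            match_bonus = 5, max_step_cost = 25)
  for (rep in 1:10) {
    n <- sample(3:5, 1); m <- sample(3:5, 1)
    a <- sort(runif(n, 0, 2e4)); b <- sort(runif(m, 0, 2e4))
    al <- align_label_maps(mk_map(a, 3e4, "a"), mk_map(b, 3e4, "b"),
                           sizing_sd = p$sizing_sd,
                           miss_penalty = p$miss_penalty,
                           max_skip = p$max_skip,
                           match_bonus = p$match_bonus,
                           max_step_cost = p$max_step_cost)
    expect_equal(al$score, oracle_align_score_exhaustive(a, b, p),
                 tolerance = 1e-8)
  }
})

test_that("re-noised self-alignment recovers at least 95% of label pairs", {
  m <- digest_to_label_map(1e6, density = 1 / 1e4, seed = 41)
  noisy <- perturb_label_map(m, sizing_sd = 150, seed = 42)
  org <- attr(noisy, "origin")
  al <- align_label_maps(m, noisy)
  correct <- sum(org[al$matched_pairs[, 2]] == al$matched_pairs[, 1],
                 na.rm = TRUE)
  expect_gte(correct / length(m$positions), 0.95)
})

test_that("no emitted call is ever smaller than min_size", {
  set.seed(55)
  sizes <- numeric(0)
  for (rep in 1:5) {
    m <- digest_to_label_map(3e5, density = 1 / 8e3)
    a <- perturb_label_map(m, sizing_sd = 150, miss_rate = 0.05,
                           false_rate = 0.03)
    b <- perturb_label_map(m, sizing_sd = 150, miss_rate = 0.05,
                           false_rate = 0.03)
    calls <- call_indels(align_label_maps(a, b), a, b, min_size = 3000)
    sizes <- c(sizes, calls$size)
  }
  expect_true(all(sizes >= 3000))
})

test_that("overhang records capture unaligned flank excess", {
  m <- mk_map(seq(0, 90000, by = 10000), 95000, "A", "chr9")
  al <- align_label_maps(m, m)
  oh <- call_overhangs(al, m, m)
  # symmetric flanks: nets cancel
  ct <- toy_chrom_table(16)
  ct$chromosome[9] <- "chr9"
  net <- net_overhang_difference(oh, ct)
  expect_true(all(net$net_bp == 0))
  # b map with a 50 kb unlabeled extra tail
  b <- mk_map(m$positions, 145000, "B", "chr9")
  al2 <- align_label_maps(m, b)
  oh2 <- call_overhangs(al2, m, b)
  right_b <- oh2[oh2$side == "right" & oh2$sample == "b", ]
  expect_equal(nrow(right_b), 1)
  expect_equal(right_b$length, 55000)   # tail + distance to last label
  net2 <- net_overhang_difference(oh2, ct)
  expect_equal(net2$net_bp[net2$chromosome == "chr9"], 50000)
})

test_that("reciprocal consistency is 1 for mirrored calls and 0 for disjoint", {
  ab <- data.frame(chromosome = "chr1", ref_start = c(1e4, 5e4),
                   ref_end = c(2e4, 6e4), qry_start = c(1e4, 5e4),
                   qry_end = c(2.5e4, 6e4),
                   type = c("insertion", "deletion"), size = c(5e3, 4e3))
  ba <- ab
  ba$type <- c("deletion", "insertion")
  ba[c("ref_start", "ref_end", "qry_start", "qry_end")] <-
    ab[c("qry_start", "qry_end", "ref_start", "ref_end")]
  expect_equal(reciprocal_consistency(ab, ba), 1)
  ba2 <- ba
  ba2$ref_start <- ba2$ref_start + 1e6; ba2$ref_end <- ba2$ref_end + 1e6
  ba2$qry_start <- ba2$qry_start + 1e6; ba2$qry_end <- ba2$qry_end + 1e6
  expect_equal(reciprocal_consistency(ab, ba2), 0)
  expect_warning(r <- reciprocal_consistency(ab[0, ], ba[0, ]), "empty")
  expect_equal(r, 1)
})
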