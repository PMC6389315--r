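# Presence/absence matrices, distances, NJ trees, clan tests.

test_that("filters drop singleton and under-covered loci and are idempotent", {
  im <- generate_indel_matrix(n_background_loci = 30, n_supergene_loci = 20,
                              noise = 0, missing_rate = 0, seed = 14)
  # singleton locus: present in exactly one individual
  im$values[1, ] <- c(1L, rep(0L, 5))
  # under-covered locus
  im$covered[2, 3] <- FALSE
  f <- filter_indel_matrix(im)
  expect_false("L0001" %in% rownames(f$values))
  expect_false("L0002" %in% rownames(f$values))
  expect_equal(nrow(f$values), 48)
  expect_identical(filter_indel_matrix(f), f)
})

test_that("distances satisfy metric basics", {
  im <- generate_indel_matrix(noise = 0, missing_rate = 0, seed = 15)
  f <- filter_indel_matrix(im)
  d <- as.matrix(indel_distances(f))
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d))
  # identical and complementary rows at the matrix level
  v <- rbind(c(1L, 1L, 0L), c(1L, 1L, 0L), c(0L, 0L, 1L))
  dd <- as.matrix(dist(t(cbind(v[, 1], v[, 1], 1L - v[, 1])),
                       method = "manhattan"))
  expect_equal(dd[1, 2], 0)
  expect_equal(dd[1, 3], 3)
})

test_that("triangle inequality holds over random presence matrices", {
  set.seed(16)
  for (rep in 1:1000) {
    v <- matrix(rbinom(30, 1, 0.5), 10, 3)
    d <- as.matrix(dist(t(v), method = "manhattan"))
    expect_lte(d[1, 3], d[1, 2] + d[2, 3])
  }
})

test_that("NJ reconstructs random additive 6-leaf trees exactly", {
  set.seed(17)
  for (rep in 1:20) {
    tr <- ape::rtree(6)
    tr$edge.length <- tr$edge.length + 0.1
    d <- cophenetic(tr)
    nj <- ape::nj(as.dist(d))
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(nj)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("three-leaf trees use the closed-form branch lengths", {
  v <- matrix(c(1L, 1L, 0L, 0L,
                1L, 0L, 1L, 0L,
                0L, 1L, 1L, 1L), nrow = 3, byrow = TRUE)
  loci <- data.frame(locus = paste0("L", 1:3), chromosome = "chr16",
                     start = c(8e6, 9e6, 10e6), end = c(8.1e6, 9.1e6, 10.1e6),
                     partition = "supergene")
  samples <- data.frame(sample = c("x", "y", "z", "w"),
                        species = c("a", "b", "c", "c"),
                        variant = c("B", "b", "B", "b"))
  im <- sbexpand:::new_indel_matrix(v, matrix(TRUE, 3, 4), loci, samples)
  d <- as.matrix(indel_distances(im))
  im3 <- sbexpand:::new_indel_matrix(v[, 1:3], matrix(TRUE, 3, 3),
                                     loci, samples[1:3, ])
  tre <- infer_indel_tree(im3, "supergene")
  bl <- tre$tree$edge.length
  m <- d[1:3, 1:3]
  expect_equal(sort(bl), sort(c((m[1,2] + m[1,3] - m[2,3]) / 2,
                                (m[1,2] + m[2,3] - m[1,3]) / 2,
                                (m[1,3] + m[2,3] - m[1,2]) / 2)))
})

test_that("planted structure is recovered: species on background, variant on supergene", {
  im <- generate_indel_matrix(noise = 0.02, missing_rate = 0.03, seed = 18)
  f <- filter_indel_matrix(im)
  bg <- infer_indel_tree(f, "background")
  expect_true(all(bg$grouping$is_clan))
  expect_equal(sort(bg$grouping$group),
               c("invicta", "quinquecuspis", "richteri"))
  sg <- infer_indel_tree(f, "supergene")
  expect_true(all(sg$grouping$is_clan))
  expect_equal(sort(sg$grouping$group), c("B", "b"))
  # Newick round-trips through ape
  expect_setequal(ape::read.tree(text = bg$newick)$tip.label,
                  bg$tree$tip.label)
})

test_that("degenerate all-zero distances yield a star tree and NA grouping", {
  v <- matrix(1L, 5, 6)
  loci <- data.frame(locus = paste0("L", 1:5), chromosome = "chr1",
                     start = 1:5 * 1e6, end = 1:5 * 1e6 + 1e4,
                     partition = "background")
  samples <- data.frame(
    sample = paste0("s", 1:6),
    species = rep(c("invicta", "quinquecuspis", "richteri"), each = 2),
    variant = rep(c("B", "b"), 3))
  im <- sbexpand:::new_indel_matrix(v, matrix(TRUE, 5, 6), loci, samples)
  tr <- infer_indel_tree(im, "background")
  expect_true(all(is.na(tr$grouping$is_clan)))
  expect_equal(length(tr$tree$tip.label), 6)
})

test_that("build_indel_matrix merges by reciprocal overlap and filters", {
  ct <- fire_ant_chromosomes()
  samples <- data.frame(
    sample = c("i_B", "i_b", "q_B", "q_b", "r_B", "r_b"),
    species = rep(c("invicta", "quinquecuspis", "richteri"), each = 2),
    variant = rep(c("B", "b"), 3))
  site <- function(ch, s, e, type = "insertion")
    data.frame(chromosome = ch, ref_start = s, ref_end = e, type = type)
  calls <- list(
    i_B = rbind(site("chr1", 1e6, 1.01e6), site("chr16", 8e6, 8.02e6)),
    i_b = rbind(site("chr1", 1.002e6, 1.012e6),          # ~80% reciprocal
                site("chr16", 8.001e6, 8.021e6)),
    q_B = site("chr2", 5e6, 5.01e6),                     # singleton: dropped
    q_b = site("chr16", 8.002e6, 8.019e6),
    r_B = site("chr5", 2e6, 2.01e6),
    r_b = site("chr5", 2.001e6, 2.009e6))
  m <- build_indel_matrix(calls, coverage = NULL, samples, ct)
  expect_equal(nrow(m$values), 3)
  expect_setequal(m$loci$partition, c("background", "supergene"))
  sg <- m$loci$partition == "supergene"
  expect_equal(sum(m$values[sg, ]), 3)      # i_B, i_b, q_b share the locus
  # coverage gap drops a locus
  cov <- setNames(lapply(samples$sample, function(s)
    data.frame(chromosome = ct$chromosome, start = 0, end = ct$length)),
    samples$sample)
  cov$r_B <- data.frame(chromosome = "chr1", start = 0, end = 1e5)
  m2 <- build_indel_matrix(calls, cov, samples, ct)
  # r_B has no coverage outside chr1[0,1e5): loci not carried by r_B go
  expect_true(all(m2$values[, "r_B"] == 1))
})
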