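# Wright-Fisher chromosome-length simulator.

test_that("zero rates leave the population untouched", {
  cfg <- sim_config(N = 10, T = 5, L0 = 1e5, F0 = 10, element_size = 500,
                    mu_ins = 0, mu_del = 0)
  pop <- new_population(cfg)
  withr::with_seed(1, {
    for (g in 1:5) pop <- next_generation(pop)
  })
  expect_true(all(vapply(pop$chroms, `[[`, numeric(1), "length") == 1e5))
  expect_true(all(pop$fitness == 1))
})

test_that("insertion bookkeeping shifts downstream elements exactly", {
  cfg <- sim_config(N = 2, L0 = 1e5, F0 = 4, element_size = 1000,
                    s_ins = 0.01)
  ch <- new_chromosome(cfg)
  el0 <- ch$el_start                    # 0, 25000, 50000, 75000
  ch2 <- apply_insertion(ch, 30000, 10000, cfg)
  expect_equal(ch2$length, 110000)
  expect_equal(ch2$el_start, c(el0[1:2], el0[3:4] + 10000))
  expect_equal(ch2$fitness, 1)          # landed outside elements
  # insertion inside an intact element disrupts it once
  ch3 <- apply_insertion(ch, 25500, 5000, cfg)
  expect_equal(ch3$fitness, 1 - 0.01)
  expect_false(ch3$intact[2])
  expect_equal(ch3$el_end[2] - ch3$el_start[2], 6000)  # stretched
  ch4 <- apply_insertion(ch3, 26000, 5000, cfg)        # second hit: free
  expect_equal(ch4$fitness, 1 - 0.01)
})

test_that("deletion handles containment, truncation and removal", {
  cfg <- sim_config(N = 2, L0 = 1e5, F0 = 4, element_size = 1000,
                    s_del = 0.1)
  ch <- new_chromosome(cfg)              # elements at 0, 25000, 50000, 75000
  d <- apply_deletion(ch, 24000, 30000, cfg)   # removes elements 2 and 3
  expect_equal(d$length, 70000)
  expect_equal(length(d$el_start), 2)
  expect_equal(d$el_start, c(0, 45000))
  expect_equal(d$fitness, (1 - 0.1)^2)
  # partial overlap truncates and costs once
  d2 <- apply_deletion(ch, 25500, 1000, cfg)
  expect_equal(d2$el_end[2] - d2$el_start[2], 500)
  expect_equal(d2$fitness, 0.9)
  expect_false(d2$intact[2])
})

test_that("fitness is multiplicative and matches the closed form", {
  cfg <- sim_config(N = 2, L0 = 1e6, F0 = 100, element_size = 1000,
                    s_del = 0.07)
  ch <- new_chromosome(cfg)
  k <- 12
  for (i in seq_len(k))
    ch <- apply_deletion(ch, ch$el_start[1], 1500, cfg)
  expect_equal(log(ch$fitness), k * log(1 - 0.07), tolerance = 1e-12)
})

test_that("event replay: length equals L0 + insertions - deletions exactly", {
  cfg <- sim_config(N = 2, L0 = 5e5, F0 = 50, element_size = 1000,
                    mu_ins = 3, mu_del = 3, ectopic_rate = 0.5,
                    s_ins = 0.01, s_del = 0.05, min_length = 1e4)
  ch <- new_chromosome(cfg)
  withr::with_seed(23, {
    for (i in 1:2000) ch <- mutate_chromosome(ch, cfg)
  })
  expect_equal(ch$length, cfg$L0 + ch$ins_bp - ch$del_bp)
  expect_gte(ch$length, cfg$min_length)
  if (length(ch$el_start)) {
    expect_true(all(ch$el_start >= 0 & ch$el_end <= ch$length))
    expect_true(all(diff(ch$el_start) >= 0))
  }
})

test_that("whole runs keep exact bookkeeping and are seed-reproducible", {
  cfg <- sim_config(N = 30, T = 120, L0 = 2e5, F0 = 20, element_size = 1000,
                    mu_ins = 0.3, mu_del = 0.3, s_ins = 0.01, s_del = 0.1)
  r1 <- run_scenario(config = cfg, replicates = 2, seed = 99)
  r2 <- run_scenario(config = cfg, replicates = 2, seed = 99)
  expect_identical(r1$trajectory, r2$trajectory)   # determinism
  expect_equal(nrow(r1$final), 2)
  expect_true(all(r1$trajectory$mean_length > 0))
})

test_that("neutral reproduction draws offspring uniformly", {
  cfg <- sim_config(N = 400, T = 1, L0 = 1e5, mu_ins = 0, mu_del = 0)
  pop <- new_population(cfg)
  withr::with_seed(31, {
    nxt <- next_generation(pop)
  })
  expect_length(nxt$chroms, 400)
  expect_true(all(nxt$fitness == 1))
})

test_that("fixation probability of a beneficial variant is about 2s", {
  # one parent at fitness 1 among N at 1 - s; WF haploid expectation
  # p_fix = (1 - exp(-2s)) / (1 - exp(-2Ns)) ~ 2s for small s
  run_fix <- function(s, N, reps) {
    cfg <- sim_config(N = N, T = 1, L0 = 1e4, mu_ins = 0, mu_del = 0)
    fixed <- 0L
    for (r in seq_len(reps)) {
      pop <- new_population(cfg)
      pop$fitness <- c(1, rep(1 - s, N - 1))
      n1 <- 1L
      for (g in seq_len(10 * N)) {
        pop <- next_generation(pop)
        n1 <- sum(pop$fitness == 1)
        if (n1 == 0L || n1 == N) break
      }
      if (n1 == N) fixed <- fixed + 1L
    }
    fixed
  }
  withr::with_seed(47, {
    for (s in c(0.05, 0.01)) {
      N <- 500; reps <- if (s == 0.05) 400 else 600
      p_exp <- (1 - exp(-2 * s)) / (1 - exp(-2 * N * s))
      fixed <- run_fix(s, N, reps)
      lo <- qbinom(5e-4, reps, p_exp); hi <- qbinom(1 - 5e-4, reps, p_exp)
      expect_gte(fixed, lo)
      expect_lte(fixed, hi)
    }
  })
})

test_that("growth slows as intact functional elements are lost", {
  cfg <- sim_config(N = 50, T = 4000, L0 = 2e5, F0 = 80,
                    element_size = 2000, mu_ins = 0.3, mu_del = 0.3,
                    ins_size = function(n) pmax(100, round(rexp(n, 1 / 2000))),
                    del_size = function(n) pmax(100, round(rexp(n, 1 / 2000))),
                    s_ins = 0.02, s_del = 0.3)
  res <- run_scenario(config = cfg, replicates = 3, record_every = 200,
                      seed = 53)
  tr <- res$trajectory
  epochs <- split(tr, tr$generation)
  gens <- sort(unique(tr$generation))
  mean_len <- vapply(epochs, function(e) mean(e$mean_length), numeric(1))
  mean_int <- vapply(epochs, function(e) mean(e$mean_intact), numeric(1))
  growth <- diff(mean_len[as.character(gens)])
  intact_at <- mean_int[as.character(gens)][-length(gens)]
  expect_lt(tail(mean_int, 1), 0.6 * mean_int[1])    # real degeneration
  expect_gt(cor(growth, intact_at), 0)               # growth tracks elements
})
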