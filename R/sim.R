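# Forward Wright-Fisher simulation of chromosome-length evolution.
#
# A chromosome is a length plus a set of non-overlapping functional
# element intervals, each intact or disrupted.  Fitness is multiplicative
# over incurred costs and is incurred once per element: after an element
# is disrupted, further hits to it are free ("removing the fitness cost
# of most mutations").  Length bookkeeping is exact: every applied event
# updates cumulative insertion/deletion counters so that
# length == L0 + ins_bp - del_bp holds at all times.

#' Create a founder chromosome
#'
#' @param config a [sim_config()].
#' @return Object of class `sim_chromosome`: `length`, element interval
#'   vectors `el_start`/`el_end` (0-based half-open, non-overlapping),
#'   `intact`, `fitness`, and the exact event counters `ins_bp`,
#'   `del_bp`, `n_floored`.
#' @export
new_chromosome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  F0 <- config$F0
  if (F0 > 0) {
    gap <- config$L0 / F0
    el_start <- round((seq_len(F0) - 1) * gap)
    el_end <- el_start + config$element_size
  } else {
    el_start <- numeric(0); el_end <- numeric(0)
  }
  structure(list(length = config$L0, el_start = el_start, el_end = el_end,
                 intact = rep(TRUE, F0), fitness = 1,
                 ins_bp = 0, del_bp = 0, n_floored = 0L),
            class = "sim_chromosome")
}

#' Apply one insertion to a chromosome
#'
#' Inserts `size` bp of neutral DNA at `pos` (0-based, in `[0, length]`):
#' downstream element coordinates shift right; an intact element strictly
#' containing the position is disrupted at cost `s_ins` and stretched by
#' the insert; otherwise the neutral-insertion cost applies.
#'
#' @param chrom a `sim_chromosome`.
#' @param pos insertion position.
#' @param size insertion size in bp (> 0).
#' @param config a [sim_config()].
#' @return The updated chromosome.
#' @export
apply_insertion <- function(chrom, pos, size, config) {
  stopifnot(size > 0, pos >= 0, pos <= chrom$length)
  inside <- chrom$el_start < pos & chrom$el_end > pos
  after <- chrom$el_start >= pos & !inside
  chrom$el_start[after] <- chrom$el_start[after] + size
  chrom$el_end[after | inside] <- chrom$el_end[after | inside] + size
  if (any(inside & chrom$intact)) {
    chrom$fitness <- chrom$fitness * (1 - config$s_ins)^sum(inside & chrom$intact)
    chrom$intact[inside] <- FALSE
  } else if (config$s_neutral_ins > 0) {
    chrom$fitness <- chrom$fitness * (1 - config$s_neutral_ins)
  }
  chrom$length <- chrom$length + size
  chrom$ins_bp <- chrom$ins_bp + size
  chrom
}

#' Apply one deletion to a chromosome
#'
#' Removes the span `[pos, pos + size)`.  Elements fully inside are
#' removed; partially overlapped elements are truncated; every intact
#' element touched costs `s_del` once and is marked disrupted.  The
#' caller guarantees the span fits (`pos + size <= length`) and that the
#' result respects the configured minimum length.
#'
#' @inheritParams apply_insertion
#' @return The updated chromosome.
#' @export
apply_deletion <- function(chrom, pos, size, config) {
  stopifnot(size > 0, pos >= 0, pos + size <= chrom$length)
  del_end <- pos + size
  touched <- chrom$el_start < del_end & chrom$el_end > pos
  shift <- function(x) ifelse(x <= pos, x, pmax(pos, x - size))
  ns <- shift(chrom$el_start); ne <- shift(chrom$el_end)
  n_cost <- sum(touched & chrom$intact)
  if (n_cost > 0) {
    chrom$fitness <- chrom$fitness * (1 - config$s_del)^n_cost
    chrom$intact[touched] <- FALSE
  } else if (config$s_neutral_del > 0) {
    chrom$fitness <- chrom$fitness * (1 - config$s_neutral_del)
  }
  keep <- ne > ns
  chrom$el_start <- ns[keep]; chrom$el_end <- ne[keep]
  chrom$intact <- chrom$intact[keep]
  chrom$length <- chrom$length - size
  chrom$del_bp <- chrom$del_bp + size
  chrom
}

# Apply pre-drawn event counts; events are interleaved in random order.
apply_events <- function(chrom, config, n_ins, n_del, n_ect) {
  types <- c(rep.int(1L, n_ins), rep.int(2L, n_del), rep.int(3L, n_ect))
  if (length(types) > 1L) types <- types[sample.int(length(types))]
  for (ty in types) {
    if (ty == 1L) {
      size <- config$ins_size(1L)
      pos <- floor(runif(1) * (chrom$length + 1))
      chrom <- apply_insertion(chrom, min(pos, chrom$length), size, config)
    } else {
      size <- if (ty == 2L) config$del_size(1L) else config$ectopic_size(1L)
      avail <- chrom$length - config$min_length
      if (size > avail) {                 # floor the chromosome length
        chrom$n_floored <- chrom$n_floored + 1L
        size <- avail
      }
      if (size > 0) {
        pos <- floor(runif(1) * (chrom$length - size + 1))
        chrom <- apply_deletion(chrom, pos, size, config)
      }
    }
  }
  chrom
}

#' Mutate a chromosome for one generation
#'
#' Draws Poisson event counts for the insertion, deletion, and ectopic
#' channels and applies the events in random order.  Deletion sizes are
#' floored at `length - min_length` (the event is logged in
#' `n_floored`), and deletion start positions are uniform over the
#' positions where the span fits, so applied sizes are exact.
#'
#' @param chrom a `sim_chromosome`.
#' @param config a [sim_config()].
#' @return The mutated chromosome.
#' @export
mutate_chromosome <- function(chrom, config) {
  f <- if (config$per_bp) chrom$length / config$L0 else 1
  apply_events(chrom, config,
               rpois(1, config$mu_ins * f),
               rpois(1, config$mu_del * f),
               rpois(1, config$ectopic_rate * f))
}

#' Fitness of a chromosome
#'
#' Multiplicative over incurred costs, maintained incrementally by the
#' mutation operators; an untouched chromosome has fitness 1.
#'
#' @param chrom a `sim_chromosome`.
#' @return Value in (0, 1\].
#' @export
chromosome_fitness <- function(chrom) chrom$fitness

#' Create a founder population
#'
#' @param config a [sim_config()].
#' @return Object of class `sim_population`: list with `chroms` (list of
#'   N chromosomes) and `fitness` (numeric vector).
#' @export
new_population <- function(config) {
  ch <- new_chromosome(config)
  structure(list(chroms = rep(list(ch), config$N),
                 fitness = rep(1, config$N), config = config),
            class = "sim_population")
}

#' Advance a population by one Wright-Fisher generation
#'
#' Draws N offspring with replacement, parent probability proportional
#' to fitness, then mutates each offspring.
#'
#' @param pop a `sim_population`.
#' @param config a [sim_config()]; defaults to the population's own.
#' @return The next-generation `sim_population`.
#' @export
next_generation <- function(pop, config = pop$config) {
  N <- config$N
  idx <- sample.int(N, N, replace = TRUE, prob = pop$fitness)
  chroms <- pop$chroms[idx]
  fitness <- pop$fitness[idx]
  f <- if (config$per_bp)
    vapply(chroms, `[[`, numeric(1), "length") / config$L0 else rep(1, N)
  n_i <- rpois(N, config$mu_ins * f)
  n_d <- rpois(N, config$mu_del * f)
  n_e <- rpois(N, config$ectopic_rate * f)
  hit <- which(n_i + n_d + n_e > 0L)
  for (i in hit) {
    chroms[[i]] <- apply_events(chroms[[i]], config, n_i[i], n_d[i], n_e[i])
    fitness[i] <- chroms[[i]]$fitness
  }
  structure(list(chroms = chroms, fitness = fitness, config = config),
            class = "sim_population")
}

population_stats <- function(pop) {
  len <- vapply(pop$chroms, `[[`, numeric(1), "length")
  intact <- vapply(pop$chroms, function(c) sum(c$intact), numeric(1))
  c(mean_length = mean(len), median_length = median(len),
    mean_intact = mean(intact), mean_fitness = mean(pop$fitness))
}

#' Verify exact length bookkeeping for every chromosome
#'
#' Checks `length == L0 + ins_bp - del_bp` (event-log replay) and the
#' element invariants (sorted, non-overlapping, within bounds) for every
#' individual.
#'
#' @param pop a `sim_population`.
#' @return `TRUE` invisibly; stops on any violation.
#' @export
check_length_bookkeeping <- function(pop) {
  L0 <- pop$config$L0
  for (ch in pop$chroms) {
    if (abs(ch$length - (L0 + ch$ins_bp - ch$del_bp)) > 1e-6)
      stop("length bookkeeping violated")
    if (length(ch$el_start)) {
      if (any(ch$el_start < 0) || any(ch$el_end > ch$length))
        stop("element outside chromosome bounds")
      if (any(diff(ch$el_start) < 0) ||
          any(head(ch$el_end, -1) > tail(ch$el_start, -1)))
        stop("elements overlap or are unsorted")
    }
  }
  invisible(TRUE)
}

#' Run a simulation scenario across replicates
#'
#' Simulates `replicates` independent populations for `config$T`
#' generations each, recording per-generation population summaries, and
#' reports the mean final length change with a two-sided sign test
#' across replicates.
#'
#' @param scenario regime name passed to [scenario_preset()], or `NULL`
#'   when `config` is given directly.
#' @param config optional [sim_config()] overriding the preset.
#' @param replicates number of independent replicates.
#' @param record_every trajectory recording stride in generations.
#' @param seed optional RNG seed.
#' @return Object of class `sim_trajectory`: `trajectory` (data.frame
#'   `replicate`, `generation`, `mean_length`, `median_length`,
#'   `mean_intact`, `mean_fitness`), `final` (per-replicate final mean
#'   length), `summary` (mean change, sign-test p), `config`,
#'   `scenario`.
#' @export
run_scenario <- function(scenario = c("expansion", "drift", "shrinkage"),
                         config = NULL, replicates = 20,
                         record_every = 25, seed = NULL) {
  if (is.null(config)) {
    scenario <- match.arg(scenario)
    config <- scenario_preset(scenario)
  } else {
    scenario <- if (is.character(scenario) && length(scenario) == 1)
      scenario else "custom"
    stopifnot(inherits(config, "sim_config"))
  }
  if (!is.null(seed)) withr::local_seed(seed)
  traj <- vector("list", replicates)
  final <- numeric(replicates)
  for (r in seq_len(replicates)) {
    pop <- new_population(config)
    gens <- unique(c(seq(0, config$T, by = record_every), config$T))
    rows <- matrix(NA_real_, length(gens), 4)
    gi <- 1L
    rows[gi, ] <- population_stats(pop)
    for (g in seq_len(config$T)) {
      pop <- next_generation(pop, config)
      if (g %in% gens) {
        gi <- gi + 1L
        rows[gi, ] <- population_stats(pop)
      }
    }
    check_length_bookkeeping(pop)
    traj[[r]] <- data.frame(replicate = r, generation = gens,
                            mean_length = rows[, 1],
                            median_length = rows[, 2],
                            mean_intact = rows[, 3],
                            mean_fitness = rows[, 4])
    final[r] <- rows[nrow(rows), 1]
  }
  n_up <- sum(final > config$L0)
  structure(list(
    trajectory = do.call(rbind, traj),
    final = data.frame(replicate = seq_len(replicates),
                       final_mean_length = final),
    summary = list(
      L0 = config$L0,
      mean_final_length = mean(final),
      mean_change = mean(final) - config$L0,
      n_replicates = replicates, n_increased = n_up,
      sign_test_p = binom.test(n_up, replicates, 0.5)$p.value),
    config = config, scenario = scenario
  ), class = "sim_trajectory")
}

#' @export
print.sim_trajectory <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "sim_trajectory (%s): %d replicates x %d generations\n",
    x$scenario, s$n_replicates, x$config$T))
  cat(sprintf(
    "  mean final length %.0f (L0 = %.0f, change %+.0f bp); %d/%d increased, sign-test p = %s\n",
    s$mean_final_length, s$L0, s$mean_change, s$n_increased,
    s$n_replicates, format.pval(s$sign_test_p)))
  invisible(x)
}
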