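# Configuration for the forward Wright-Fisher simulation of a population
# of haploid individuals each carrying one nonrecombining chromosome.
# Event counts are Poisson per chromosome per generation (rates are
# length-independent by default); a per-bp mode rescales rates by
# current length relative to L0, since length-proportional rates change
# the long-run dynamics.

#' Simulation configuration
#'
#' @param N population size (haploid individuals, >= 2).
#' @param T generations to simulate.
#' @param L0 initial chromosome length in bp.
#' @param F0 initial number of functional elements, evenly spaced.
#' @param element_size extent of each functional element in bp.
#' @param mu_ins,mu_del per-chromosome per-generation insertion and
#'   deletion event rates.
#' @param ins_size,del_size size distributions: functions `n ->` sizes in
#'   bp.  Defaults are exponential with mean 5 kb, floored at 100 bp.
#' @param s_ins fitness cost of an insertion landing inside an intact
#'   functional element (the element is thereby disrupted).
#' @param s_del fitness cost per intact functional element removed or
#'   disrupted by a deletion.
#' @param s_neutral_ins,s_neutral_del costs of events touching only
#'   non-functional DNA (default 0).
#' @param ectopic_rate rate of an additional large-deletion channel
#'   (ectopic-recombination-like events).
#' @param ectopic_size size distribution for ectopic deletions.
#' @param per_bp logical; if `TRUE`, event rates scale with current
#'   length relative to `L0`.
#' @param min_length floor on chromosome length in bp; deletions are
#'   truncated so the chromosome never shrinks below it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(N = 200, T = 1000, L0 = 1e6, F0 = 0,
                       element_size = 2000,
                       mu_ins = 0.1, mu_del = 0.1,
                       ins_size = NULL, del_size = NULL,
                       s_ins = 0, s_del = 0,
                       s_neutral_ins = 0, s_neutral_del = 0,
                       ectopic_rate = 0, ectopic_size = NULL,
                       per_bp = FALSE, min_length = 1000) {
  stopifnot(N >= 2, T >= 0, L0 > 0, F0 >= 0,
            mu_ins >= 0, mu_del >= 0, ectopic_rate >= 0,
            s_ins >= 0, s_ins < 1, s_del >= 0, s_del < 1,
            s_neutral_ins >= 0, s_neutral_ins < 1,
            s_neutral_del >= 0, s_neutral_del < 1,
            min_length > 0, min_length <= L0)
  default_size <- function(mean_bp)
    function(n) pmax(100, round(stats::rexp(n, 1 / mean_bp)))
  if (F0 > 0 && L0 / F0 < element_size)
    stop("functional elements do not fit: need L0 / F0 >= element_size")
  structure(list(
    N = N, T = T, L0 = L0, F0 = F0, element_size = element_size,
    mu_ins = mu_ins, mu_del = mu_del,
    ins_size = if (is.null(ins_size)) default_size(5000) else ins_size,
    del_size = if (is.null(del_size)) default_size(5000) else del_size,
    s_ins = s_ins, s_del = s_del,
    s_neutral_ins = s_neutral_ins, s_neutral_del = s_neutral_del,
    ectopic_rate = ectopic_rate,
    ectopic_size = if (is.null(ectopic_size)) default_size(10000) else ectopic_size,
    per_bp = per_bp, min_length = min_length
  ), class = "sim_config")
}

#' Scenario presets for the three qualitative regimes
#'
#' * `expansion`: deletions carry a much higher fitness cost than
#'   insertions and intact functional elements are abundant, so
#'   insertions fix preferentially and mean chromosome length grows.
#' * `drift`: no functional elements and no costs; insertion and
#'   deletion channels are symmetric, so length performs an unbiased
#'   random walk.
#' * `shrinkage`: as `drift` plus an ectopic large-deletion channel,
#'   so mean length declines.
#'
#' Preset parameter values are this package's own calibration of the
#' regimes (population size 200, event rates 0.1 per chromosome per
#' generation, event sizes with 5 kb mean); the claims tested against
#' them are directional, not quantitative.
#'
#' @param scenario one of `"expansion"`, `"drift"`, `"shrinkage"`.
#' @param ... overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
scenario_preset <- function(scenario = c("expansion", "drift", "shrinkage"),
                            ...) {
  scenario <- match.arg(scenario)
  args <- switch(scenario,
    expansion = list(N = 200, T = 2000, L0 = 1e6, F0 = 200,
                     element_size = 2000, mu_ins = 0.1, mu_del = 0.1,
                     s_ins = 0.005, s_del = 0.05),
    drift     = list(N = 200, T = 1000, L0 = 1e6, F0 = 0,
                     mu_ins = 0.1, mu_del = 0.1),
    shrinkage = list(N = 200, T = 1000, L0 = 1e6, F0 = 0,
                     mu_ins = 0.1, mu_del = 0.1, ectopic_rate = 0.05)
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}
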