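# Pairwise alignment of ordered-label maps by dynamic programming.
#
# Scoring (maximised): each matched label pair after the first adds
#   match_bonus - min(dL^2 / (2 * m * sizing_sd^2), max_step_cost)
#              - miss_penalty * (labels skipped in the step)
# where dL is the difference of the two matched inter-label intervals and
# m the mean number of elementary intervals spanned (interval sizing noise
# is additive across spanned intervals, so the variance scales with m).
# The first matched pair contributes match_bonus.  End gaps are free
# (semi-global), so unaligned flanks fall out naturally as overhangs.
# The per-step cost cap keeps a single large indel from truncating the
# alignment: the step is paid a bounded penalty and matching resumes.
# Ties are broken toward fewer skipped labels, then the earlier index.

#' Align two label maps by dynamic programming
#'
#' Computes the optimal monotone, non-crossing matching of the two label
#' sequences under the interval-sizing likelihood score described in the
#' package vignette.  Both maps need at least two labels.
#'
#' @param mapA,mapB [label_map()] objects (A is the reference).
#' @param sizing_sd expected interval sizing error sd in bp.
#' @param miss_penalty score penalty per skipped label.
#' @param max_skip maximum labels skippable between consecutive matches.
#' @param match_bonus score reward per matched label pair.
#' @param max_step_cost cap on the sizing cost of a single step; steps
#'   spanning a large indel pay this bounded cost (just above one match
#'   bonus), so crossing an indel stays worthwhile whenever matching
#'   continues beyond it, while local sizing noise (cost about 1) is
#'   still discriminated.
#' @return Object of class `map_alignment`: `matched_pairs` (two-column
#'   matrix of 1-based label indices in A and B), `score`, and the
#'   unaligned flank lengths `prefix_A`, `suffix_A`, `prefix_B`,
#'   `suffix_B` in bp.
#' @export
align_label_maps <- function(mapA, mapB, sizing_sd = 150,
                             miss_penalty = 3, max_skip = 3,
                             match_bonus = 5, max_step_cost = 6) {
  stopifnot(inherits(mapA, "label_map"), inherits(mapB, "label_map"),
            sizing_sd > 0, max_skip >= 0)
  a <- mapA$positions; b <- mapB$positions
  n <- length(a); m <- length(b)
  if (n < 2 || m < 2) stop("both maps need at least 2 labels")

  S <- matrix(match_bonus, n, m)       # best score ending with (i, j) matched
  PI <- matrix(0L, n, m); PJ <- matrix(0L, n, m)
  eps <- 1e-9
  for (i in 2:n) {
    pis <- max(1L, i - 1L - max_skip):(i - 1L)
    da <- a[i] - a[pis]
    ska <- i - pis - 1L
    for (j in 2:m) {
      pjs <- max(1L, j - 1L - max_skip):(j - 1L)
      db <- b[j] - b[pjs]
      skb <- j - pjs - 1L
      dL <- outer(da, db, `-`)
      span <- (outer(i - pis, j - pjs, `+`)) / 2
      cost <- pmin(dL^2 / (2 * span * sizing_sd^2), max_step_cost)
      skips <- outer(ska, skb, `+`)
      cand <- S[pis, pjs, drop = FALSE] + match_bonus - cost -
        miss_penalty * skips
      # tie-break: fewer skips, then earlier reference index, then earlier query
      ord <- order(as.vector(skips),
                   rep(rev(seq_along(pis)), times = length(pjs)),
                   rep(rev(seq_along(pjs)), each = length(pis)))
      cv <- as.vector(cand)[ord]
      best <- ord[which(cv >= max(cv) - eps)[1L]]
      mx <- as.vector(cand)[best]
      if (mx >= match_bonus - eps) {
        S[i, j] <- mx
        bi <- (best - 1L) %% length(pis) + 1L
        bj <- (best - 1L) %/% length(pis) + 1L
        PI[i, j] <- pis[bi]; PJ[i, j] <- pjs[bj]
      }
    }
  }

  # end-cell ties break toward the longer alignment (larger i + j)
  ends <- which(S >= max(S) - eps, arr.ind = TRUE)
  end <- ends[order(-(ends[, 1] + ends[, 2]), ends[, 1])[1L], ]
  pairs <- matrix(NA_integer_, 0L, 2L)
  i <- end[1L]; j <- end[2L]
  while (i > 0L) {
    pairs <- rbind(c(i, j), pairs)
    pi0 <- PI[i, j]; pj0 <- PJ[i, j]
    i <- pi0; j <- pj0
  }
  colnames(pairs) <- c("A", "B")
  structure(list(
    matched_pairs = pairs,
    score = S[end[1L], end[2L]],
    prefix_A = a[pairs[1L, 1L]],
    suffix_A = mapA$length - a[pairs[nrow(pairs), 1L]],
    prefix_B = b[pairs[1L, 2L]],
    suffix_B = mapB$length - b[pairs[nrow(pairs), 2L]],
    params = list(sizing_sd = sizing_sd, miss_penalty = miss_penalty,
                  max_skip = max_skip, match_bonus = match_bonus,
                  max_step_cost = max_step_cost)
  ), class = "map_alignment")
}

#' @export
print.map_alignment <- function(x, ...) {
  cat("map_alignment:", nrow(x$matched_pairs), "matched pairs, score",
      round(x$score, 2), "\n")
  invisible(x)
}

#' Call large indels from a map alignment
#'
#' For each pair of consecutive matched label pairs, the difference of
#' the spanned intervals on the two maps is compared; when it reaches
#' `min_size` (default 3 kb, the optical detection floor) one call is
#' emitted.  The call is an insertion when the query (b) interval is
#' longer, a deletion when shorter.  The position is the flanking matched
#' interval on the reference map -- optical resolution does not localise
#' breakpoints within an interval.  Adjacent calls are not merged.
#'
#' @param alignment a [align_label_maps()] result.
#' @param mapA,mapB the aligned maps (A = reference sample B).
#' @param min_size minimum absolute interval difference in bp.
#' @param source_pair label recorded with each call.
#' @return data.frame with columns `chromosome`, `ref_start`, `ref_end`
#'   (reference map, 0-based half-open), `qry_start`, `qry_end` (query
#'   map), `type` (`"insertion"`/`"deletion"`), `size`, `source_pair`.
#' @export
call_indels <- function(alignment, mapA, mapB, min_size = 3000,
                        source_pair = "b_vs_B") {
  stopifnot(inherits(alignment, "map_alignment"))
  p <- alignment$matched_pairs
  out <- list()
  if (nrow(p) >= 2) {
    a <- mapA$positions; b <- mapB$positions
    for (k in seq_len(nrow(p) - 1L)) {
      dA <- a[p[k + 1L, 1L]] - a[p[k, 1L]]
      dB <- b[p[k + 1L, 2L]] - b[p[k, 2L]]
      delta <- dB - dA
      if (abs(delta) >= min_size) {
        out[[length(out) + 1L]] <- data.frame(
          chromosome = mapA$chromosome,
          ref_start = a[p[k, 1L]], ref_end = a[p[k + 1L, 1L]],
          qry_start = b[p[k, 2L]], qry_end = b[p[k + 1L, 2L]],
          type = if (delta > 0) "insertion" else "deletion",
          size = abs(delta), source_pair = source_pair,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(chromosome = character(), ref_start = numeric(),
                      ref_end = numeric(), qry_start = numeric(),
                      qry_end = numeric(), type = character(),
                      size = numeric(), source_pair = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Call unaligned overhangs from a map alignment
#'
#' Emits one record per non-empty unaligned flank: the span from a map
#' end to its outermost matched label.  Overhangs capture excess or
#' divergent sequence invisible to interval-difference indel calling.
#' The net per-chromosome excess in the b sample is
#' `sum(b overhangs) - sum(B overhangs)` (see
#' [net_overhang_difference()]).
#'
#' @param alignment a [align_label_maps()] result.
#' @param mapA,mapB the aligned maps.
#' @param samples labels for the two maps; defaults `c(A = "B", B = "b")`
#'   (map A comes from the B individual).
#' @param alignment_id identifier recorded with each record.
#' @return data.frame with columns `chromosome`, `alignment_id`, `side`
#'   (`"left"`/`"right"`), `length`, `sample`.
#' @export
call_overhangs <- function(alignment, mapA, mapB,
                           samples = c(A = "B", B = "b"),
                           alignment_id = "aln") {
  stopifnot(inherits(alignment, "map_alignment"))
  rec <- function(side, len, sample)
    data.frame(chromosome = mapA$chromosome, alignment_id = alignment_id,
               side = side, length = len, sample = sample,
               stringsAsFactors = FALSE)
  out <- list()
  if (alignment$prefix_A > 0) out <- c(out, list(rec("left",  alignment$prefix_A, samples[["A"]])))
  if (alignment$suffix_A > 0) out <- c(out, list(rec("right", alignment$suffix_A, samples[["A"]])))
  if (alignment$prefix_B > 0) out <- c(out, list(rec("left",  alignment$prefix_B, samples[["B"]])))
  if (alignment$suffix_B > 0) out <- c(out, list(rec("right", alignment$suffix_B, samples[["B"]])))
  if (length(out) == 0L)
    return(data.frame(chromosome = character(), alignment_id = character(),
                      side = character(), length = numeric(),
                      sample = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Reciprocal consistency of two indel call sets
#'
#' Fraction of indel sites recovered in both alignment directions.  A
#' call from the A-vs-B direction is recovered when some call from the
#' B-vs-A direction has the opposite type, the same chromosome, and
#' reciprocally overlapping coordinates (each call's reference interval
#' overlaps the other call's query interval).  The fraction is the
#' symmetric recovery over the union of both call sets.
#'
#' @param callsAB,callsBA call tables from [call_indels()] with roles
#'   swapped.
#' @return Fraction in \[0, 1\]; `1` with a warning when both sets are
#'   empty.
#' @export
reciprocal_consistency <- function(callsAB, callsBA) {
  nA <- nrow(callsAB); nB <- nrow(callsBA)
  if (nA + nB == 0L) {
    warning("both call sets empty; consistency defined as 1")
    return(1)
  }
  swap <- c(insertion = "deletion", deletion = "insertion")
  overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
  # widen zero-width intervals by 1 bp so point insertions can overlap
  w <- function(s, e) list(s = s, e = pmax(e, s + 1))
  recovered <- function(x, y) {
    vapply(seq_len(nrow(x)), function(i) {
      cand <- y$chromosome == x$chromosome[i] &
        y$type == swap[[x$type[i]]]
      if (!any(cand)) return(FALSE)
      xr <- w(x$ref_start[i], x$ref_end[i]); xq <- w(x$qry_start[i], x$qry_end[i])
      yr <- w(y$ref_start[cand], y$ref_end[cand])
      yq <- w(y$qry_start[cand], y$qry_end[cand])
      any(overlaps(xq$s, xq$e, yr$s, yr$e) & overlaps(xr$s, xr$e, yq$s, yq$e))
    }, logical(1))
  }
  hits <- 0
  if (nA > 0) hits <- hits + sum(recovered(callsAB, callsBA))
  if (nB > 0) hits <- hits + sum(recovered(callsBA, callsAB))
  hits / (nA + nB)
}
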