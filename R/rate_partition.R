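#' Randomly pair rate posterior samples with stochastic maps
#'
#' When the two lists have equal length the pairing is a uniform random
#' permutation (without replacement); when lengths differ, the longer list
#' is permuted and the shorter sampled uniformly with replacement, giving
#' `max(length(rate_maps), length(area_maps))` pairs. The index pairing is
#' recorded in the result.
#'
#' @param rate_maps list of [rate_map()]s.
#' @param area_maps list of stochastic maps ([sample_maps()]).
#' @param seed integer seed.
#' @return list of `list(rates =, areas =, rate_idx =, area_idx =)`.
#' @export
pair_samples <- function(rate_maps, area_maps, seed = 1L) {
  if (!length(rate_maps) || !length(area_maps)) {
    stop("empty sample list", call. = FALSE)
  }
  set.seed(seed)
  n <- max(length(rate_maps), length(area_maps))
  ri <- if (length(rate_maps) == n) sample.int(n) else
    sample.int(length(rate_maps), n, replace = TRUE)
  ai <- if (length(area_maps) == n) sample.int(n) else
    sample.int(length(area_maps), n, replace = TRUE)
  lapply(seq_len(n), function(i) {
    list(rates = rate_maps[[ri[i]]], areas = area_maps[[ai[i]]],
         rate_idx = ri[i], area_idx = ai[i])
  })
}

#' Segment branches by joint (area, rate) regime
#'
#' Each branch is cut at every change-point of either map, and every
#' resulting interval is then subdivided into equal sub-pieces so that no
#' segment exceeds `max_frac` times the root height. Segments carry the
#' constant (area, rate) pair of their interval.
#'
#' @param tree the `phylo` both maps tile.
#' @param rates a [rate_map()].
#' @param areas a stochastic map.
#' @param max_frac maximum segment duration as a fraction of root height.
#' @return data.frame `child`, `start_age`, `end_age`, `duration`, `area`, `rate`.
#' @export
segment_branches <- function(tree, rates, areas, max_frac = 0.02) {
  H <- root_age(tree)
  check_same_tiling(rates, areas, tree)
  max_len <- max_frac * H
  out <- vector("list", length(unique(rates$child)))
  oi <- 0
  for (child in unique(rates$child)) {
    rp <- rates[rates$child == child, , drop = FALSE]
    ap <- areas[areas$child == child, , drop = FALSE]
    cuts <- sort(unique(c(rp$start_age, rp$end_age, ap$start_age, ap$end_age)),
                 decreasing = TRUE)
    # merge nearly identical cut points
    cuts <- cuts[c(TRUE, -diff(cuts) > 1e-12)]
    segs <- NULL
    for (ci in seq_len(length(cuts) - 1)) {
      s <- cuts[ci]; e <- cuts[ci + 1]
      mid <- (s + e) / 2
      rate <- rp$rate[rp$start_age >= mid - 1e-12 & rp$end_age <= mid + 1e-12][1]
      area <- ap$state[ap$start_age >= mid - 1e-12 & ap$end_age <= mid + 1e-12][1]
      nsub <- max(1L, ceiling((s - e) / max_len - 1e-12))
      bounds <- seq(s, e, length.out = nsub + 1)
      segs <- rbind(segs, data.frame(
        child = child, start_age = bounds[-length(bounds)],
        end_age = bounds[-1], area = area, rate = rate))
    }
    oi <- oi + 1
    out[[oi]] <- segs
  }
  segs <- do.call(rbind, out)
  segs$duration <- segs$start_age - segs$end_age
  segs
}

check_same_tiling <- function(rates, areas, tree, tol = 1e-9) {
  b1 <- sort(unique(rates$child)); b2 <- sort(unique(areas$child))
  if (!identical(b1, b2) || !setequal(b1, tree$edge[, 2])) {
    stop("rate map and area map do not tile the same tree", call. = FALSE)
  }
  invisible(TRUE)
}

# per-area duration-weighted mean rate of one segment table, optionally
# restricted to an age window [hi, lo]
area_means <- function(segs, window = NULL, weighted = TRUE) {
  if (!is.null(window)) {
    hi <- window[1]; lo <- window[2]
    s <- pmin(segs$start_age, hi)
    e <- pmax(segs$end_age, lo)
    keep <- s - e > 1e-15
    segs <- segs[keep, , drop = FALSE]
    segs$duration <- (s - e)[keep]
  }
  if (!nrow(segs)) return(numeric(0))
  w <- if (weighted) segs$duration else rep(1, nrow(segs))
  vapply(split(seq_len(nrow(segs)), segs$area), function(idx) {
    sum(segs$rate[idx] * w[idx]) / sum(w[idx])
  }, numeric(1))
}

#' Diversification-rate summary by ancestral area
#'
#' For each (rate sample, area map) pairing, branches are segmented with
#' [segment_branches()] and each area receives the duration-weighted mean
#' net rate of its segments, both overall and restricted to each of
#' `n_windows` equal time windows (segments are split at window
#' boundaries). Across pairings the mean and the 2.5%/97.5% quantiles are
#' reported. Duration weighting makes the summary invariant to subdivision
#' finer than `max_frac` (an unweighted mode is available for comparison).
#' Areas with zero total duration in a window are absent from that window's
#' rows, not reported as zero.
#'
#' @param pairings output of [pair_samples()].
#' @param tree the `phylo`.
#' @param n_windows number of equal time windows (20 in typical use).
#' @param max_frac passed to [segment_branches()].
#' @param weighted duration weighting (default) or plain segment averaging.
#' @return `list(overall =, windows =)` data.frames with `area`, (`window`,
#'   `start_age`, `end_age`,) `mean`, `q2.5`, `q97.5`, `n_pairings`.
#' @export
summarize_by_area <- function(pairings, tree, n_windows = 20, max_frac = 0.02,
                              weighted = TRUE) {
  H <- root_age(tree)
  wins <- lapply(seq_len(n_windows), function(w)
    c(H - (w - 1) * H / n_windows, H - w * H / n_windows))
  per_overall <- list(); per_win <- list()
  for (i in seq_along(pairings)) {
    segs <- segment_branches(tree, pairings[[i]]$rates, pairings[[i]]$areas,
                             max_frac = max_frac)
    per_overall[[i]] <- area_means(segs, weighted = weighted)
    per_win[[i]] <- lapply(wins, function(w) area_means(segs, w, weighted))
  }
  summ <- function(values_by_pairing) {
    areas <- sort(unique(unlist(lapply(values_by_pairing, names))))
    do.call(rbind, lapply(areas, function(a) {
      v <- unlist(lapply(values_by_pairing, function(x) x[as.character(a)]))
      v <- v[!is.na(v)]
      data.frame(area = as.integer(a), mean = mean(v),
                 q2.5 = stats::quantile(v, 0.025, type = 7, names = FALSE),
                 q97.5 = stats::quantile(v, 0.975, type = 7, names = FALSE),
                 n_pairings = length(v))
    }))
  }
  windows <- do.call(rbind, lapply(seq_len(n_windows), function(w) {
    s <- summ(lapply(per_win, `[[`, w))
    if (is.null(s) || !nrow(s)) return(NULL)
    cbind(window = w, start_age = wins[[w]][1], end_age = wins[[w]][2], s)
  }))
  list(overall = summ(per_overall), windows = windows)
}
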