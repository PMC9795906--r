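#' Stochastic character maps of area histories
#'
#' A stochastic map is one sampled realization of the full area history on
#' every branch, consistent with the tip data and the fitted equal-rates
#' model. Maps are stored as data.frames of pieces `(child, state,
#' start_age, end_age)`, pieces ordered old to young on each branch,
#' adjacent pieces differing in state, and the first state of each branch
#' equal to the last state of its parent branch.
#'
#' Sampling is in two stages: (1) joint node states drawn root-to-tips from
#' the conditional distribution given the tip data (reusing the pruning
#' partials), then (2) each branch's internal history drawn from the CTMC
#' conditioned on its endpoint states by uniformization. With dominating
#' rate `Lambda = k q` the uniformized jump chain of the equal-rates model
#' is uniform over all `k` states (including self-jumps), so the number of
#' virtual jumps N given endpoints (a, b) has
#' `P(N = n) proportional to Pois(n; Lambda t) * (1/k)` for `n >= 1` (and
#' `[a == b]` for `n = 0`), virtual states are iid uniform with the last
#' fixed at `b`, and jump times are sorted uniforms; self-jumps are then
#' discarded.
#'
#' @param tree a `phylo`.
#' @param tips named list of area sets (see [prune_loglik()]).
#' @param model a fitted [area_model()].
#' @param n_maps number of maps.
#' @param seed integer seed for the whole batch.
#' @return list of maps; each a data.frame with attributes `map_id`, `seed`,
#'   plus a `node_states` integer vector (sampled state at every node).
#' @export
sample_maps <- function(tree, tips, model, n_maps = 100, seed = 1L) {
  set.seed(seed)
  k <- model$k; q <- model$q
  tipm <- tip_partials(tips, k, tree)
  pr <- prune_internal(tree, tipm, model)
  ntip <- ape::Ntip(tree); ntot <- ntip + tree$Nnode
  bl <- branch_lengths_by_child(tree)
  ages <- node_ages(tree)
  par <- parent_of(tree)
  root <- root_node(tree)
  pre_edges <- tree$edge[order(-ages[tree$edge[, 2]]), , drop = FALSE]
  lapply(seq_len(n_maps), function(m) {
    states <- integer(ntot)
    w <- root_prior_vec(model, pr$partial[, root]) * pr$partial[, root]
    states[root] <- sample.int(k, 1, prob = w)
    for (i in seq_len(nrow(pre_edges))) {
      p <- pre_edges[i, 1]; v <- pre_edges[i, 2]
      e <- exp(-k * q * bl[v])
      prow <- rep((1 - e) / k, k); prow[states[p]] <- prow[states[p]] + e
      w <- prow * pr$partial[, v]
      states[v] <- sample.int(k, 1, prob = w)
    }
    pieces <- vector("list", nrow(pre_edges))
    for (i in seq_len(nrow(pre_edges))) {
      p <- pre_edges[i, 1]; v <- pre_edges[i, 2]
      path <- sample_branch_path(q, k, bl[v], states[p], states[v])
      a0 <- ages[p]
      pieces[[i]] <- data.frame(
        child = v, state = path$states,
        start_age = a0 - path$t_start, end_age = a0 - path$t_end)
      # snap the last piece onto the node age exactly
      pieces[[i]]$end_age[nrow(pieces[[i]])] <- ages[v]
    }
    map <- do.call(rbind, pieces)
    attr(map, "map_id") <- m
    attr(map, "seed") <- seed
    attr(map, "node_states") <- states
    class(map) <- c("stochastic_map", "data.frame")
    map
  })
}

#' Endpoint-conditioned path of the equal-rates chain (uniformization)
#'
#' Samples one path of duration `t` starting in `a` and ending in `b`.
#' Exported mainly so the sampler can be validated against a rejection
#' oracle on small cases.
#'
#' @param q,k model parameters; `t` duration; `a,b` endpoint states.
#' @param t,a,b see above.
#' @return `list(states, t_start, t_end)`: consecutive visited states with
#'   segment times measured forward from the branch's older end; adjacent
#'   states differ; `states[1] == a`, last `== b`.
#' @export
sample_branch_path <- function(q, k, t, a, b) {
  lam <- k * q * t
  if (t <= 0 || q <= 0) {
    if (a != b) stop("impossible endpoint pair on zero-length branch", call. = FALSE)
    return(list(states = a, t_start = 0, t_end = t))
  }
  # P(N = n | a, b) ~ Pois(n; lam) * (n == 0 ? [a == b] : 1/k)
  nmax <- max(20, ceiling(lam + 10 * sqrt(lam) + 10))
  wn <- stats::dpois(0:nmax, lam) / k
  wn[1] <- if (a == b) stats::dpois(0, lam) else 0
  n <- sample.int(nmax + 1, 1, prob = wn) - 1L
  if (n == 0) return(list(states = a, t_start = 0, t_end = t))
  times <- sort(stats::runif(n, 0, t))
  virt <- c(if (n > 1) sample.int(k, n - 1, replace = TRUE), b)
  seq_states <- c(a, virt)
  keep <- c(TRUE, seq_states[-1] != seq_states[-length(seq_states)])
  states <- seq_states[keep]
  starts <- c(0, times)[keep]
  ends <- c(starts[-1], t)
  list(states = states, t_start = starts, t_end = ends)
}

#' Count dispersal events between areas across maps
#'
#' A dispersal event is a state change i -> j somewhere on the tree; each
#' map yields one count per ordered pair, summarized across maps by mean,
#' median and the 2.5%/97.5% quantiles (linear interpolation between order
#' statistics, R quantile type 7).
#'
#' @param maps list of maps from [sample_maps()].
#' @param k number of areas (inferred from the maps when missing).
#' @return data.frame `from`, `to`, `mean`, `median`, `q2.5`, `q97.5`.
#' @export
count_dispersals <- function(maps, k = NULL) {
  if (!length(maps)) stop("no maps", call. = FALSE)
  if (is.null(k)) k <- max(vapply(maps, function(m) max(m$state), numeric(1)))
  counts <- vapply(maps, function(m) {
    tab <- matrix(0, k, k)
    ev <- map_events(m)
    if (nrow(ev)) for (r in seq_len(nrow(ev))) {
      tab[ev$from[r], ev$to[r]] <- tab[ev$from[r], ev$to[r]] + 1
    }
    as.vector(tab)
  }, numeric(k * k))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = k * k)
  idx <- expand.grid(from = seq_len(k), to = seq_len(k))
  keep <- idx$from != idx$to
  data.frame(
    from = idx$from[keep], to = idx$to[keep],
    mean = rowMeans(counts)[keep],
    median = apply(counts, 1, stats::median)[keep],
    q2.5 = apply(counts, 1, stats::quantile, probs = 0.025, type = 7)[keep],
    q97.5 = apply(counts, 1, stats::quantile, probs = 0.975, type = 7)[keep])
}

# events of one map: state changes along branches, dated at the age where
# the new state begins
map_events <- function(map) {
  out <- NULL
  for (child in unique(map$child)) {
    p <- map[map$child == child, , drop = FALSE]
    p <- p[order(-p$start_age), , drop = FALSE]
    if (nrow(p) > 1) {
      out <- rbind(out, data.frame(
        from = p$state[-nrow(p)], to = p$state[-1],
        age = p$start_age[-1]))
    }
  }
  if (is.null(out)) data.frame(from = integer(0), to = integer(0),
                               age = numeric(0)) else out
}

#' Filter the dispersal network to well-supported edges
#'
#' Keeps the ordered pairs whose 2.5% quantile of counts across maps
#' exceeds zero (i.e. the 95% quantile range excludes zero).
#'
#' @param summary output of [count_dispersals()].
#' @return the kept rows of `summary`.
#' @export
filter_network <- function(summary) {
  summary[summary$q2.5 > 0, , drop = FALSE]
}

#' Immigration/emigration through time per focal area
#'
#' Partitions `[root age, 0]` into `n_windows` equal spans; every dispersal
#' event is assigned to the window containing the age at which the new
#' state begins (events exactly on a boundary go to the older window).
#' Immigration into an area counts events with that destination, emigration
#' events with that source; medians and 95% quantile ranges are taken
#' across maps.
#'
#' @param maps list of maps from [sample_maps()].
#' @param tree the `phylo` the maps live on (for the root age).
#' @param n_windows number of equal time windows.
#' @param focal_areas integer vector of area states to summarize.
#' @return data.frame `area`, `window` (1 = oldest), `start_age`, `end_age`,
#'   `direction` (`immigration`/`emigration`), `median`, `q2.5`, `q97.5`.
#' @export
dispersal_time_windows <- function(maps, tree, n_windows = 10, focal_areas) {
  H <- root_age(tree)
  width <- H / n_windows
  win_of <- function(age) {
    w <- ceiling((H - age) / width - 1e-12)
    pmin(pmax(w, 1L), n_windows)
  }
  out <- NULL
  for (a in focal_areas) {
    imm <- matrix(0, n_windows, length(maps))
    emi <- matrix(0, n_windows, length(maps))
    for (mi in seq_along(maps)) {
      ev <- map_events(maps[[mi]])
      if (!nrow(ev)) next
      w <- win_of(ev$age)
      for (r in seq_len(nrow(ev))) {
        if (ev$to[r] == a) imm[w[r], mi] <- imm[w[r], mi] + 1
        if (ev$from[r] == a) emi[w[r], mi] <- emi[w[r], mi] + 1
      }
    }
    for (dir in c("immigration", "emigration")) {
      m <- if (dir == "immigration") imm else emi
      out <- rbind(out, data.frame(
        area = a, window = seq_len(n_windows),
        start_age = H - (seq_len(n_windows) - 1) * width,
        end_age = H - seq_len(n_windows) * width,
        direction = dir,
        median = apply(m, 1, stats::median),
        q2.5 = apply(m, 1, stats::quantile, probs = 0.025, type = 7),
        q97.5 = apply(m, 1, stats::quantile, probs = 0.975, type = 7)))
    }
  }
  out
}

#' Serialize maps to TSV
#' @param maps list of maps.
#' @param path output TSV.
#' @export
write_maps <- function(maps, path) {
  rows <- do.call(rbind, lapply(maps, function(m) {
    cbind(map_id = attr(m, "map_id"), as.data.frame(m))
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read maps from TSV
#' @param path TSV from [write_maps()].
#' @export
read_maps <- function(path) {
  rows <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(split(rows, rows$map_id), function(m) {
    map <- m[, c("child", "state", "start_age", "end_age")]
    attr(map, "map_id") <- m$map_id[1]
    class(map) <- c("stochastic_map", "data.frame")
    map
  })
}
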