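#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. Defaults describe
#' the stated test world: a moderately sized clade (`n_tips = 200`) under a
#' birth--death process with `lambda = 0.3`, `mu = 0.1` events/Myr, areas
#' evolving under an equal-rates Markov process with `q_true = 0.05` over
#' `k = 9` areas, 10% polymorphic and 10% missing tips, and barcode-like
#' sequence families of ~1% intra-family divergence.
#'
#' @param n_tips number of extant tips to stop at.
#' @param birth_rate,death_rate birth/death rates (events/Myr), `lambda > mu >= 0`.
#' @param rate_shift_spec list of shifts, each `list(time=, new_lambda=, new_mu=)`:
#'   at `time` (forward from the origin) one random extant lineage and all of
#'   its descendants switch to the new rates.
#' @param mk_rate true area transition rate `q` (per Myr, per ordered pair).
#' @param n_areas number of areas `k >= 2`.
#' @param polymorphic_fraction,missing_fraction tip fractions made polymorphic
#'   (true state plus one random extra) or missing (empty set); must sum to <= 1.
#' @param seq_divergence_spec list of families, each
#'   `list(family_size=, sub_prob=)` (per-site substitution probability).
#' @param rng_seed integer seed; all generator randomness flows through it.
#' @export
sim_config <- function(n_tips = 200, birth_rate = 0.3, death_rate = 0.1,
                       rate_shift_spec = list(), mk_rate = 0.05, n_areas = 9,
                       polymorphic_fraction = 0.1, missing_fraction = 0.1,
                       seq_divergence_spec = list(list(family_size = 10, sub_prob = 0.01)),
                       rng_seed = 1L) {
  stopifnot(birth_rate > death_rate, death_rate >= 0, mk_rate > 0,
            n_areas >= 2, polymorphic_fraction >= 0, missing_fraction >= 0)
  if (polymorphic_fraction + missing_fraction > 1) {
    stop("polymorphic_fraction + missing_fraction > 1", call. = FALSE)
  }
  structure(list(n_tips = n_tips, birth_rate = birth_rate,
                 death_rate = death_rate, rate_shift_spec = rate_shift_spec,
                 mk_rate = mk_rate, n_areas = n_areas,
                 polymorphic_fraction = polymorphic_fraction,
                 missing_fraction = missing_fraction,
                 seq_divergence_spec = seq_divergence_spec,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' Simulate a birth--death tree with optional rate shifts
#'
#' Forward (Gillespie) simulation from two root lineages, stopping when the
#' extant lineage count reaches `n_tips` (simple stop-at-n; no GSA-style
#' correction, which is fine for generator-scale testing but not for
#' inference about tree priors). Extinct lineages are pruned. Rate shifts
#' move one random extant lineage (and descendants) to new rates at the
#' stated time. If all lineages die the simulation retries, up to
#' `max_retries`.
#'
#' @param config a [sim_config()].
#' @param max_retries retries on total extinction.
#' @return `list(tree = phylo, rates = rate_map, shift_nodes = integer)`:
#'   `rates` records the true per-branch net rate (lambda - mu) including
#'   shifts, as pieces split at shift times.
#' @export
sim_bd_tree <- function(config, max_retries = 100) {
  set.seed(config$rng_seed)
  for (try in seq_len(max_retries)) {
    res <- sim_bd_once(config)
    if (!is.null(res)) return(res)
  }
  stop("all lineages went extinct in ", max_retries, " attempts", call. = FALSE)
}

sim_bd_once <- function(config) {
  lam0 <- config$birth_rate; mu0 <- config$death_rate
  shifts <- config$rate_shift_spec
  shift_times <- vapply(shifts, function(s) s$time, numeric(1))
  if (length(shifts)) {
    ord <- order(shift_times); shifts <- shifts[ord]; shift_times <- shift_times[ord]
  }
  # lineage bookkeeping: id, parent id, birth time, regime, alive, death time
  n_alloc <- 4 * config$n_tips + 8
  parent <- integer(n_alloc); btime <- numeric(n_alloc); dtime <- rep(NA_real_, n_alloc)
  regime <- integer(n_alloc); alive <- logical(n_alloc)
  reg_lam <- lam0; reg_mu <- mu0           # regime 1 = base
  shift_node <- integer(0)                 # lineage at which each shift starts
  parent[1:2] <- 0L; btime[1:2] <- 0; regime[1:2] <- 1L; alive[1:2] <- TRUE
  nlin <- 2L; t <- 0; next_shift <- if (length(shifts)) 1L else 0L
  repeat {
    ext <- which(alive[seq_len(nlin)])
    if (!length(ext)) return(NULL)
    if (length(ext) >= config$n_tips) break
    lams <- reg_lam[regime[ext]]; mus <- reg_mu[regime[ext]]
    tot <- sum(lams) + sum(mus)
    dt <- stats::rexp(1, tot)
    if (next_shift > 0 && next_shift <= length(shifts) &&
        t + dt >= shift_times[next_shift]) {
      t <- shift_times[next_shift]
      s <- shifts[[next_shift]]
      tgt <- ext[sample.int(length(ext), 1)]
      reg_lam <- c(reg_lam, s$new_lambda); reg_mu <- c(reg_mu, s$new_mu)
      # split the target lineage at the shift time so the regime change has
      # an exact change-point on its branch: end it, start a single child
      alive[tgt] <- FALSE; dtime[tgt] <- NA  # not a death: single descendant
      nlin <- nlin + 1L
      parent[nlin] <- tgt; btime[nlin] <- t; regime[nlin] <- length(reg_lam)
      alive[nlin] <- TRUE
      shift_node <- c(shift_node, nlin)
      next_shift <- next_shift + 1L
      next
    }
    t <- t + dt
    w <- sample.int(length(ext), 1, prob = lams + mus)
    lin <- ext[w]
    p_birth <- reg_lam[regime[lin]] / (reg_lam[regime[lin]] + reg_mu[regime[lin]])
    if (stats::runif(1) < p_birth) {
      # speciation: lineage ends, two children start
      alive[lin] <- FALSE
      for (j in 1:2) {
        nlin <- nlin + 1L
        if (nlin > length(parent)) {
          parent <- c(parent, integer(n_alloc)); btime <- c(btime, numeric(n_alloc))
          dtime <- c(dtime, rep(NA_real_, n_alloc)); regime <- c(regime, integer(n_alloc))
          alive <- c(alive, logical(n_alloc))
        }
        parent[nlin] <- lin; btime[nlin] <- t; regime[nlin] <- regime[lin]
        alive[nlin] <- TRUE
      }
    } else {
      alive[lin] <- FALSE; dtime[lin] <- t
    }
  }
  build_sim_tree(seq_len(nlin), parent, btime, dtime, alive, regime,
                 reg_lam, reg_mu, t, shift_node)
}

# assemble a phylo + true rate map from the lineage table
build_sim_tree <- function(ids, parent, btime, dtime, alive, regime,
                           reg_lam, reg_mu, t_end, shift_node) {
  child_of <- split(ids, factor(parent[ids], levels = ids))
  # keep lineages with extant descendants
  keep <- logical(length(ids))
  keep[alive[ids]] <- TRUE
  for (i in ids[order(btime[ids], decreasing = TRUE)]) {
    kids <- child_of[[as.character(i)]]
    if (length(kids) && any(keep[kids])) keep[i] <- TRUE
  }
  if (sum(keep & alive[ids]) < 2) return(NULL)
  # collapse: surviving lineage chains with single surviving child merge
  # build edges among "real" nodes: lineages whose parent link splits
  surv <- ids[keep]
  kids_surv <- lapply(child_of, function(k) k[keep[k]])
  is_tip <- alive[surv]
  # final tree assembled recursively as a Newick string: tips = extant
  # lineages, internal nodes = surviving lineages with >=2 surviving
  # children; single-surviving-child chains (pruned or shift points)
  # collapse into one branch
  lab <- character(max(ids)); lab[surv[is_tip]] <- paste0("t", seq_len(sum(is_tip)))
  seg <- new.env(); seg$pieces <- list(); seg$k <- 0L
  # build(i) describes the subtree hanging from lineage i: `node` is the
  # Newick of the node ending lineage i's branch (without branch length),
  # `blen` the length of the branch above it (chains collapse into it),
  # `leafref` the leftmost descendant tip label (addresses the branch later)
  build_leafref <- function(i) {
    while (!alive[i]) i <- kids_surv[[as.character(i)]][1]
    lab[i]
  }
  build <- function(i) {
    kids <- kids_surv[[as.character(i)]]
    start <- btime[i]
    if (alive[i]) {
      node_str <- lab[i]; end <- t_end; leafref <- lab[i]
    } else if (length(kids) >= 2) {
      parts <- lapply(kids, build)
      node_str <- paste0("(", paste(vapply(parts, function(p)
        paste0(p$node, ":", format(p$blen, digits = 15)), ""), collapse = ","), ")")
      end <- btime[kids[1]]
      leafref <- build_leafref(kids[1])
    } else if (length(kids) == 1) {
      # chain (pruned split or shift point): extend the child branch upward
      sub <- build(kids[[1]])
      seg$k <- seg$k + 1L
      seg$pieces[[seg$k]] <- data.frame(
        tip_path = sub$leafref, t0 = start, t1 = btime[kids[[1]]],
        rate = reg_lam[regime[i]] - reg_mu[regime[i]])
      return(list(node = sub$node, blen = sub$blen + (btime[kids[[1]]] - start),
                  leafref = sub$leafref))
    } else stop("pruned lineage reached")
    seg$k <- seg$k + 1L
    seg$pieces[[seg$k]] <- data.frame(
      tip_path = leafref, t0 = start, t1 = end,
      rate = reg_lam[regime[i]] - reg_mu[regime[i]])
    list(node = node_str, blen = end - start, leafref = leafref)
  }
  roots <- ids[parent[ids] == 0 & keep]
  if (length(roots) == 2) {
    parts <- lapply(roots, build)
    nwk <- paste0("(", paste(vapply(parts, function(p)
      paste0(p$node, ":", format(p$blen, digits = 15)), ""), collapse = ","), ");")
  } else {
    # one side died: root is the earliest split of the surviving side
    sub <- build(roots[[1]])
    nwk <- paste0(sub$node, ";")
  }
  tr <- ape::read.tree(text = nwk)
  pieces_raw <- do.call(rbind, seg$pieces)
  # translate (leafref, t0, t1) segments into per-branch rate pieces; ages
  # run backward from t_end (= the present)
  H <- root_age(tr)
  ages <- node_ages(tr)
  par_tr <- parent_of(tr)
  pieces <- NULL
  for (r in seq_len(nrow(pieces_raw))) {
    a0 <- t_end - pieces_raw$t0[r]; a1 <- t_end - pieces_raw$t1[r] # older, younger
    if (a1 >= H - 1e-9) next  # segment above the crown root (pruned stem)
    v <- match(pieces_raw$tip_path[r], tr$tip.label)
    # walk up from the reference tip to the branch spanning [a1, a0]:
    # the child node v with ages[v] <= a1 and parent age >= a0
    while (!is.na(par_tr[v]) && ages[par_tr[v]] < a0 - 1e-9) v <- par_tr[v]
    if (is.na(par_tr[v])) next   # numeric sliver above the root
    pieces <- rbind(pieces, data.frame(child = v,
                                       start_age = min(a0, ages[par_tr[v]]),
                                       end_age = max(a1, ages[v]),
                                       rate = pieces_raw$rate[r]))
  }
  # snap tiny numeric gaps to the branch ends
  pieces <- snap_pieces(pieces, tr)
  list(tree = tr, rates = rate_map(pieces, tr),
       n_shifts = length(shift_node))
}

snap_pieces <- function(pieces, tr, tol = 1e-7) {
  ages <- node_ages(tr); par <- parent_of(tr)
  out <- NULL
  for (child in unique(pieces$child)) {
    p <- pieces[pieces$child == child, , drop = FALSE]
    p <- p[order(-p$start_age), , drop = FALSE]
    p$start_age[1] <- ages[par[child]]
    p$end_age[nrow(p)] <- ages[child]
    if (nrow(p) > 1) p$start_age[-1] <- p$end_age[-nrow(p)]
    keep <- p$start_age - p$end_age > 1e-12
    # zero-length branches (stop-at-n newborn tips) keep one degenerate piece
    if (!any(keep)) keep[1] <- TRUE
    out <- rbind(out, p[keep, , drop = FALSE])
  }
  out
}

#' Simulate tip areas under the equal-rates Markov process
#'
#' Draws the root state uniformly, evolves states down every branch under
#' the equal-rates chain (total exit rate `(k-1) q`, new state uniform among
#' the others), then degrades a random tip subset to polymorphic (true state
#' plus one random extra) and another to missing (empty set).
#'
#' @param tree a `phylo`.
#' @param q transition rate per ordered pair of distinct areas.
#' @param k number of areas.
#' @param polymorphic_fraction,missing_fraction tip fractions; sum must be <= 1.
#' @param seed integer seed.
#' @return list with `tips` (named list of integer area sets, possibly empty),
#'   `true_tip_states`, `true_node_states` (integer vectors by node id), and
#'   `n_events` (true total number of state changes on the tree).
#' @export
sim_mk_tips <- function(tree, q, k, polymorphic_fraction = 0,
                        missing_fraction = 0, seed = 1L) {
  stopifnot(q >= 0, k >= 2)
  if (polymorphic_fraction + missing_fraction > 1) {
    stop("polymorphic_fraction + missing_fraction > 1", call. = FALSE)
  }
  set.seed(seed)
  ntip <- ape::Ntip(tree); ntot <- ntip + tree$Nnode
  state <- integer(ntot)
  root <- root_node(tree)
  state[root] <- sample.int(k, 1)
  bl <- branch_lengths_by_child(tree)
  # preorder: parents before children
  ord <- tree$edge[order(-node_ages(tree)[tree$edge[, 2]]), , drop = FALSE]
  n_events <- 0L
  for (i in seq_len(nrow(ord))) {
    p <- ord[i, 1]; v <- ord[i, 2]
    s <- state[p]; t_rem <- bl[v]
    if (q > 0) {
      repeat {
        w <- stats::rexp(1, (k - 1) * q)
        if (w >= t_rem) break
        t_rem <- t_rem - w
        s_new <- sample.int(k - 1, 1); if (s_new >= s) s_new <- s_new + 1L
        s <- s_new; n_events <- n_events + 1L
      }
    }
    state[v] <- s
  }
  tips <- lapply(seq_len(ntip), function(i) state[i])
  n_poly <- round(polymorphic_fraction * ntip)
  n_miss <- round(missing_fraction * ntip)
  pick <- sample.int(ntip, n_poly + n_miss)
  for (i in seq_len(n_poly)) {
    v <- pick[i]
    extra <- sample.int(k - 1, 1); if (extra >= state[v]) extra <- extra + 1L
    tips[[v]] <- sort(c(state[v], extra))
  }
  for (i in seq_len(n_miss)) tips[[pick[n_poly + i]]] <- integer(0)
  names(tips) <- tree$tip.label
  list(tips = tips, true_tip_states = state[seq_len(ntip)],
       true_node_states = state[(ntip + 1):ntot], n_events = n_events)
}

#' Simulate sequence families with controlled divergence
#'
#' Each family is founded by a random centroid sequence which every member
#' copies with independent per-site substitutions (to a uniformly chosen
#' different base). Members are truncated by 0--2 bases so the centroid is
#' always the longest family member. Indels and rate heterogeneity are not
#' modelled.
#'
#' @param centroid_length bases per centroid.
#' @param family_spec list of `list(family_size=, sub_prob=)`.
#' @param seed integer seed.
#' @param centroid_divergence optional per-site substitution probability
#'   between centroids: when set, centroids of families 2, 3, ... are
#'   mutated copies of family 1's centroid at this rate (controlled
#'   inter-family divergence); when `NULL` centroids are independent random
#'   sequences.
#' @return list with `seqs` (data.frame `id`, `sequence`, `length`) and
#'   `true_labels` (integer family index per sequence).
#' @export
sim_sequence_family <- function(centroid_length, family_spec, seed = 1L,
                                centroid_divergence = NULL) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  seqs <- NULL; labels <- integer(0)
  cen1 <- NULL
  for (f in seq_along(family_spec)) {
    spec <- family_spec[[f]]
    if (f == 1 || is.null(centroid_divergence)) {
      cen <- sample(bases, centroid_length, replace = TRUE)
      if (f == 1) cen1 <- cen
    } else {
      cen <- cen1
      hit <- stats::runif(centroid_length) < centroid_divergence
      if (any(hit)) {
        cen[hit] <- vapply(cen[hit], function(b) sample(setdiff(bases, b), 1), "")
      }
    }
    ids <- paste0("f", f, "_s", seq_len(spec$family_size))
    for (m in seq_len(spec$family_size)) {
      s <- cen
      if (m > 1 && spec$sub_prob > 0) {
        hit <- stats::runif(centroid_length) < spec$sub_prob
        if (any(hit)) {
          s[hit] <- vapply(s[hit], function(b) sample(setdiff(bases, b), 1), "")
        }
      }
      if (m > 1) {
        drop <- sample(0:1, 1)
        if (drop > 0) s <- s[seq_len(length(s) - drop)]
      }
      seqs <- rbind(seqs, data.frame(id = ids[m], sequence = paste(s, collapse = ""),
                                     length = length(s), stringsAsFactors = FALSE))
      labels <- c(labels, f)
    }
  }
  list(seqs = seqs, true_labels = labels)
}

#' Simulate metadata records with known true areas
#'
#' Builds per-sequence metadata for a set of OTU tips with known true areas,
#' exercising every branch of the assignment cascade: a fraction of records
#' carry only an unambiguous country, a fraction only coordinates, a
#' fraction only a manual area code, and the rest nothing (unassignable).
#'
#' @param otu_areas named list: OTU id -> integer/character area codes (true).
#' @param scheme an [area_scheme()]; records are generated consistent with it.
#' @param p_country,p_coords,p_manual route fractions (remainder unassigned).
#' @param seed integer seed.
#' @return data.frame in [read_metadata()] layout plus `true_area`.
#' @export
sim_metadata <- function(otu_areas, scheme, p_country = 0.5, p_coords = 0.2,
                         p_manual = 0.2, seed = 1L) {
  stopifnot(p_country + p_coords + p_manual <= 1)
  set.seed(seed)
  # invert the country table to countries mapping to exactly one area
  cn <- names(scheme$country_table)
  uniq <- cn[vapply(scheme$country_table, length, integer(1)) == 1]
  area_of <- vapply(scheme$country_table[uniq], `[[`, "", 1)
  recs <- NULL
  i <- 0
  for (otu in names(otu_areas)) {
    for (area in otu_areas[[otu]]) {
      i <- i + 1
      u <- stats::runif(1)
      row <- data.frame(sequence_id = paste0("seq", i), otu_id = otu,
                        country = NA_character_, lat = NA_real_, lon = NA_real_,
                        manual_area = NA_character_, introduced = NA,
                        true_area = area, stringsAsFactors = FALSE)
      if (u < p_country) {
        cands <- uniq[area_of == area]
        if (length(cands)) row$country <- sample(cands, 1)
        else u <- p_country + 1e-9  # no country for this area: use coordinates
      }
      if (is.na(row$country) && u < p_country + p_coords + 1e-8) {
        pt <- polygon_interior_point(scheme$polygons[[area]])
        row$lat <- pt[2]; row$lon <- pt[1]
      }
      if (is.na(row$country) && is.na(row$lat) &&
          u < p_country + p_coords + p_manual + 2e-8) {
        row$manual_area <- area
      }
      recs <- rbind(recs, row)
    }
  }
  recs
}

# a representative interior point of the first ring (centroid of vertices,
# valid for the convex synthetic polygons used in tests)
polygon_interior_point <- function(poly) {
  ring <- poly[[1]][[1]]
  c(mean(ring[, 1]), mean(ring[, 2]))
}
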