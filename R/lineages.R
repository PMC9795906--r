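#' Extract focal-area lineages from marginal ancestral estimates
#'
#' A lineage for a focal area is a maximal connected set of tree nodes
#' (tips and internals) whose relative likelihood for that area exceeds
#' `threshold`. Tip "marginals" are the indicator of the observed area set
#' split equally across a polymorphic tip's areas; internal nodes use the
#' supplied marginals. The stem age of a lineage is the age of the parent
#' of the set's shallowest node; the crown age is the age of that shallowest
#' node, defined only when the set contains two or more tips. With
#' `threshold >= 0.5` no node can pass for two areas at once, so lineages of
#' different areas are node-disjoint; lower thresholds would break that
#' uniqueness and are rejected.
#'
#' @param tree a `phylo` (ages from [node_ages()]).
#' @param marginals matrix from [marginal_ancestral()] (rows = all nodes).
#' @param tips named list of observed area sets (for the tip rows).
#' @param focal_areas integer vector of area states.
#' @param threshold relative-likelihood cutoff, `>= 0.5`.
#' @return data.frame: `lineage_id`, `focal_area`, `n_otus`, `is_clade`,
#'   `root_node`, `stem_age_rel`, `crown_age_rel` (`NA` for single-OTU
#'   lineages and for a lineage containing the tree root's stem).
#' @export
find_focal_lineages <- function(tree, marginals, tips, focal_areas,
                                threshold = 0.5) {
  if (threshold < 0.5) {
    stop("threshold must be >= 0.5 (guarantees area-disjoint lineages)",
         call. = FALSE)
  }
  ntip <- ape::Ntip(tree); ntot <- ntip + tree$Nnode
  ages <- node_ages(tree)
  par <- parent_of(tree)
  prob <- marginals
  for (i in seq_len(ntip)) {
    s <- tips[[tree$tip.label[i]]]
    v <- numeric(ncol(marginals))
    if (length(s)) v[s] <- 1 / length(s)
    prob[i, ] <- v
  }
  out <- NULL; lid <- 0
  for (a in focal_areas) {
    pass <- prob[, a] > threshold
    if (!any(pass)) next
    # connected components of the passing node set in the tree graph
    comp <- rep(0L, ntot); cid <- 0
    for (v in which(pass)) {
      if (comp[v]) next
      cid <- cid + 1
      stack <- v; comp[v] <- cid
      while (length(stack)) {
        u <- stack[[1]]; stack <- stack[-1]
        nb <- c(par[u], tree$edge[tree$edge[, 1] == u, 2])
        nb <- nb[!is.na(nb)]
        nb <- nb[pass[nb] & comp[nb] == 0]
        comp[nb] <- cid
        stack <- c(stack, nb)
      }
    }
    for (ci in seq_len(cid)) {
      members <- which(comp == ci)
      mtips <- members[members <= ntip]
      # the unique rootmost member: its parent is outside the set (robust to
      # zero-length branches, unlike taking the max age)
      rootmost <- members[is.na(par[members]) | !(par[members] %in% members)]
      root_of_set <- rootmost[1]
      stem <- if (is.na(par[root_of_set])) NA_real_ else ages[par[root_of_set]]
      crown <- if (length(mtips) >= 2) ages[root_of_set] else NA_real_
      lid <- lid + 1
      out <- rbind(out, data.frame(
        lineage_id = lid, focal_area = a, n_otus = length(mtips),
        is_clade = length(mtips) > 1, root_node = root_of_set,
        stem_age_rel = stem, crown_age_rel = crown))
    }
  }
  if (is.null(out)) {
    out <- data.frame(lineage_id = integer(0), focal_area = integer(0),
                      n_otus = integer(0), is_clade = logical(0),
                      root_node = integer(0), stem_age_rel = numeric(0),
                      crown_age_rel = numeric(0))
  }
  out
}

#' Per-area lineage table with calibrated ages
#'
#' For each focal area: number of lineages, number of clades (> 1 OTU), and
#' the oldest crown and stem ages as `"point (low-high)"` strings (Myr,
#' half-up to 0.1, whole numbers without decimals); em dash when no clade
#' exists in the area.
#'
#' @param lineages output of [find_focal_lineages()].
#' @param calib a [calibration_spec()].
#' @param area_names optional names for the `focal_area` codes.
#' @export
tabulate_lineages <- function(lineages, calib = calibration_spec(),
                              area_names = NULL) {
  areas <- sort(unique(lineages$focal_area))
  rows <- lapply(areas, function(a) {
    l <- lineages[lineages$focal_area == a, , drop = FALSE]
    crowns <- l$crown_age_rel[!is.na(l$crown_age_rel)]
    stems <- l$stem_age_rel[!is.na(l$stem_age_rel)]
    data.frame(
      area = if (is.null(area_names)) as.character(a) else area_names[[as.character(a)]],
      n_lineages = nrow(l),
      n_clades = sum(l$is_clade),
      oldest_crown = if (length(crowns)) format_age_triple(max(crowns), calib) else "—",
      oldest_stem = if (length(stems)) format_age_triple(max(stems), calib) else "—",
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Geological event windows
#'
#' @param name window name.
#' @param start_age,end_age window bounds in Ma, `start_age >= end_age >= 0`
#'   (equal for a point event).
#' @export
event_window <- function(name, start_age, end_age = start_age) {
  stopifnot(start_age >= end_age, end_age >= 0)
  list(name = name, start_age = start_age, end_age = end_age)
}

#' Read event windows from YAML
#'
#' Format: a list of `{name:, start_age:, end_age:}` entries (end_age
#' optional for point events).
#' @param path YAML file.
#' @export
read_event_windows <- function(path) {
  lapply(yaml::read_yaml(path), function(e) {
    event_window(e$name, e$start_age,
                 if (is.null(e$end_age)) e$start_age else e$end_age)
  })
}

#' The default geological event windows
#'
#' South America--Antarctica split (50 Ma, point), boreotropical conditions
#' (Palaeocene--Eocene, taken as 66--33.9 Ma), rapid northern Andean uplift
#' (8--5 Ma), Panama isthmus biotic interchange (from 20 Ma to the present).
#' @export
default_event_windows <- function() {
  read_event_windows(system.file("extdata", "events.yaml", package = "mkareas"))
}

#' Lineage ages versus geological events
#'
#' For each lineage and each of its stem/crown ages, reports whether the
#' calibrated age interval `[low, high]` intersects each event window.
#'
#' @param lineages output of [find_focal_lineages()].
#' @param events list of [event_window()]s.
#' @param calib a [calibration_spec()].
#' @return long data.frame `lineage_id`, `which_age`, `age_low`, `age_high`,
#'   `event`, `overlaps`.
#' @export
event_overlap <- function(lineages, events, calib = calibration_spec()) {
  out <- NULL
  for (i in seq_len(nrow(lineages))) {
    for (which_age in c("stem", "crown")) {
      rel <- if (which_age == "stem") lineages$stem_age_rel[i] else
        lineages$crown_age_rel[i]
      if (is.na(rel)) next
      lo <- rel * calib$low; hi <- rel * calib$high
      for (e in events) {
        out <- rbind(out, data.frame(
          lineage_id = lineages$lineage_id[i], which_age = which_age,
          age_low = lo, age_high = hi, event = e$name,
          overlaps = lo <= e$start_age && hi >= e$end_age))
      }
    }
  }
  out
}
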