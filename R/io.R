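#' Read a FASTA file of nucleotide sequences
#'
#' Minimal strict FASTA reader: records are returned in file order, sequences
#' are upper-cased and validated against the IUPAC nucleotide alphabet
#' (`ACGTRYSWKMBDHVN`); gaps are not allowed and empty sequences are an error.
#'
#' @param path FASTA file path.
#' @return a data.frame with columns `id`, `sequence`, `length`.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!length(lines) || !hdr[1]) stop("not a FASTA file: ", path, call. = FALSE)
  grp <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, "", collapse = "")
  # headers with no sequence lines drop out of split(); restore as empty
  all_ids <- as.character(seq_along(ids))
  seqs <- seqs[match(all_ids, names(seqs))]
  seqs[is.na(seqs)] <- ""
  seqs <- toupper(seqs)
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  }
  bad <- grepl("[^ACGTRYSWKMBDHVN]", seqs)
  if (any(bad)) {
    stop("non-IUPAC characters in record(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  data.frame(id = ids, sequence = unname(seqs), length = nchar(seqs),
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#' @param seqs data.frame with `id` and `sequence` columns.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  writeLines(paste0(">", seqs$id, "\n", seqs$sequence), path)
  invisible(path)
}

#' Read per-sequence metadata
#'
#' Tab-separated with columns `sequence_id`, `otu_id`, `country`, `lat`,
#' `lon`, `manual_area`, `introduced` (all but `sequence_id` optional; empty
#' strings become `NA`). Coordinates are validated to lie in
#' `[-90, 90] x [-180, 180]`.
#'
#' @param path TSV file path.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!"sequence_id" %in% names(md)) {
    stop("metadata must have a sequence_id column", call. = FALSE)
  }
  for (col in c("otu_id", "country", "manual_area")) {
    if (!col %in% names(md)) md[[col]] <- NA_character_
  }
  for (col in c("lat", "lon")) {
    if (!col %in% names(md)) md[[col]] <- NA_real_
    md[[col]] <- as.numeric(md[[col]])
  }
  if (!"introduced" %in% names(md)) md$introduced <- NA
  md$introduced <- as.logical(md$introduced)
  ok_lat <- is.na(md$lat) | (md$lat >= -90 & md$lat <= 90)
  ok_lon <- is.na(md$lon) | (md$lon >= -180 & md$lon <= 180)
  if (!all(ok_lat & ok_lon)) {
    stop("coordinates out of range for sequence(s): ",
         paste(md$sequence_id[!(ok_lat & ok_lon)], collapse = ", "),
         call. = FALSE)
  }
  md
}

# ---- per-branch rate maps -------------------------------------------------

#' Construct a rate map from per-branch pieces
#'
#' A rate map is a data.frame of piecewise-constant net diversification rates
#' with columns `child` (the branch's child node id), `start_age` (older end),
#' `end_age` (younger end) and `rate`. Pieces must tile every branch of
#' `tree` exactly. Negative rates are allowed but flagged with a warning.
#'
#' @param pieces data.frame with columns `child`, `start_age`, `end_age`, `rate`.
#' @param tree the `phylo` the map lives on.
#' @export
rate_map <- function(pieces, tree) {
  stopifnot(all(c("child", "start_age", "end_age", "rate") %in% names(pieces)))
  pieces <- pieces[order(pieces$child, -pieces$start_age), , drop = FALSE]
  validate_tiling(pieces, tree, what = "rate map")
  if (any(pieces$rate < 0)) {
    warning("rate map contains negative net rates; kept as given")
  }
  structure(pieces, class = c("rate_map", "data.frame"))
}

# shared tiling validation for rate maps and stochastic maps
validate_tiling <- function(pieces, tree, what = "map", tol = 1e-9) {
  ages <- node_ages(tree)
  par <- parent_of(tree)
  for (child in unique(pieces$child)) {
    p <- pieces[pieces$child == child, , drop = FALSE]
    if (is.na(par[child])) stop(what, ": branch id ", child, " is the root", call. = FALSE)
    older <- ages[par[child]]
    younger <- ages[child]
    if (any(p$start_age < p$end_age)) {
      stop(what, ": piece with start_age < end_age on branch ", child, call. = FALSE)
    }
    if (abs(p$start_age[1] - older) > tol ||
        abs(p$end_age[nrow(p)] - younger) > tol ||
        (nrow(p) > 1 && any(abs(p$end_age[-nrow(p)] - p$start_age[-1]) > tol))) {
      stop(what, ": pieces do not tile branch ", child,
           " (branch spans [", format(older), ", ", format(younger), "])",
           call. = FALSE)
    }
  }
  missing <- setdiff(tree$edge[, 2], unique(pieces$child))
  if (length(missing)) {
    stop(what, ": branches without pieces: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(pieces)
}

# resolve branch identifiers given as tip labels, node numbers, or "node123"
resolve_branch_id <- function(id, tree) {
  ntot <- ape::Ntip(tree) + tree$Nnode
  out <- suppressWarnings(as.integer(id))
  lab <- match(id, tree$tip.label)
  out[!is.na(lab)] <- lab[!is.na(lab)]
  m <- grepl("^node([0-9]+)$", id)
  out[m] <- as.integer(sub("^node", "", id[m]))
  if (any(is.na(out)) || any(out < 1 | out > ntot)) {
    stop("branch id(s) not in tree: ",
         paste(unique(id[is.na(out) | out < 1 | out > ntot]), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Read a per-branch diversification rate table
#'
#' Plain TSV with columns `branch_id`, `start_age`, `end_age`, `rate`.
#' `branch_id` is a tip label, a node number, or `node<N>`; each row is one
#' constant-rate piece on that branch. Branches absent from the table inherit
#' the rate of the nearest ancestral branch (the piece adjoining the shared
#' node). Pieces must tile each listed branch; gaps or pieces outside the
#' branch extent are errors.
#'
#' @param path TSV path.
#' @param tree the `phylo` the table refers to.
#' @return a [rate_map()].
#' @export
read_rate_table <- function(path, tree) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("branch_id", "start_age", "end_age", "rate") %in% names(tab)))
  tab$child <- resolve_branch_id(as.character(tab$branch_id), tree)
  fill_rate_pieces(tab[, c("child", "start_age", "end_age", "rate")], tree)
}

# complete a partial piece table: unlisted branches inherit the nearest
# ancestral regime (rate at the parent branch's youngest piece)
fill_rate_pieces <- function(pieces, tree) {
  ages <- node_ages(tree)
  par <- parent_of(tree)
  listed <- unique(pieces$child)
  root <- root_node(tree)
  # process branches root-down so ancestors are always filled first
  ord <- order(-ages[tree$edge[, 2]])
  out <- pieces
  for (child in tree$edge[ord, 2]) {
    if (child %in% listed) next
    anc <- par[child]
    rate <- NA_real_
    while (!is.na(anc) && anc != root) {
      p <- out[out$child == anc, , drop = FALSE]
      if (nrow(p)) { rate <- p$rate[which.min(p$end_age)]; break }
      anc <- par[anc]
    }
    if (is.na(rate) && !is.na(anc) && anc == root) {
      # root's other child branches may be listed; fall back to oldest piece overall
      p <- out[out$child %in% tree$edge[tree$edge[, 1] == root, 2], , drop = FALSE]
      if (nrow(p)) rate <- p$rate[which.max(p$start_age)]
    }
    if (is.na(rate)) {
      stop("no ancestral regime to inherit for branch ", child, call. = FALSE)
    }
    out <- rbind(out, data.frame(child = child, start_age = ages[par[child]],
                                 end_age = ages[child], rate = rate))
    listed <- c(listed, child)
  }
  rate_map(out, tree)
}

#' Read a BAMM-style event data file
#'
#' Accepts the event-data CSV written by BAMM-type diversification samplers:
#' columns `generation`, `leftchild`, `rightchild`, `abstime`, `lambdainit`,
#' `lambdashift`, `muinit` (and optionally `mushift`, ignored beyond constant
#' mu). Each generation is one posterior sample. An event placed on the
#' branch subtending the MRCA of `leftchild`/`rightchild` (equal when a tip)
#' starts a new regime inherited by all descendant branches until overridden;
#' the speciation rate decays or grows as `lambda(t) = lambda0 * exp(z t)`
#' with `t` the time since the event. The returned rate maps discretise each
#' branch at `n_slices` equal slices with the net rate evaluated at slice
#' midpoints.
#'
#' @param path CSV path.
#' @param tree the `phylo` (ages backward from tips; `abstime` forward from root).
#' @param n_slices slices per branch for the exponential-rate discretisation.
#' @return list of [rate_map()], one per generation.
#' @export
read_bamm_events <- function(path, tree, n_slices = 5) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("generation", "leftchild", "rightchild", "abstime",
            "lambdainit", "lambdashift", "muinit")
  stopifnot(all(need %in% names(ev)))
  H <- root_age(tree)
  ages <- node_ages(tree)
  par <- parent_of(tree)
  lapply(split(ev, ev$generation), function(g) {
    # locate each event's node
    g$node <- vapply(seq_len(nrow(g)), function(i) {
      l <- g$leftchild[i]; r <- g$rightchild[i]
      if (is.na(r) || r == "" || identical(l, r)) {
        resolve_branch_id(l, tree)
      } else {
        ape::getMRCA(tree, c(l, r))
      }
    }, integer(1))
    g$event_age <- H - g$abstime      # backward age of the event
    pieces <- NULL
    # regime applying at the top (older end) of each branch: nearest event at
    # or above it; root events have abstime <= 0 age >= H
    for (ei in seq_len(nrow(tree$edge))) {
      child <- tree$edge[ei, 2]
      older <- ages[par[child]]; younger <- ages[child]
      # candidate events: on this branch, or governing an ancestor
      govern <- function(node, age) {
        # most recent event on/above `node` older than `age`
        best <- NULL
        v <- node
        repeat {
          onb <- g[g$node == v & g$event_age >= age - 1e-12, , drop = FALSE]
          if (nrow(onb)) {
            best <- onb[which.min(onb$event_age), , drop = FALSE]
            break
          }
          if (is.na(par[v])) {
            rootev <- g[g$event_age >= ages[v] - 1e-12, , drop = FALSE]
            if (nrow(rootev)) best <- rootev[which.min(rootev$event_age), , drop = FALSE]
            break
          }
          age <- ages[v]  # climbing: from here on any ancestor event is older
          v <- par[v]
        }
        best
      }
      cuts <- sort(unique(c(older, younger,
                            g$event_age[g$node == child &
                                        g$event_age < older & g$event_age > younger])),
                   decreasing = TRUE)
      for (ci in seq_len(length(cuts) - 1)) {
        s <- cuts[ci]; e <- cuts[ci + 1]
        sub <- seq(s, e, length.out = n_slices + 1)
        reg <- govern(child, s - 1e-12)
        if (is.null(reg)) stop("no governing event for branch ", child, call. = FALSE)
        mids <- (sub[-1] + sub[-length(sub)]) / 2
        tmid <- reg$event_age - mids   # forward time since the event
        lam <- reg$lambdainit * exp(reg$lambdashift * tmid)
        pieces <- rbind(pieces, data.frame(
          child = child, start_age = sub[-length(sub)], end_age = sub[-1],
          rate = lam - reg$muinit))
      }
    }
    rate_map(pieces, tree)
  })
}
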