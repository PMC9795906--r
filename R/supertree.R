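#' Calibration with uncertainty
#'
#' A point age with a low/high range (Myr) used to convert relative node
#' ages (root crown age = 1) to absolute time. The default is a 60 Myr crown
#' calibration with a 57--64 Myr range.
#'
#' @param point,low,high ages in Myr, `low <= point <= high`, all > 0.
#' @export
calibration_spec <- function(point = 60, low = 57, high = 64) {
  stopifnot(low > 0, low <= point, point <= high)
  structure(list(point = point, low = low, high = high),
            class = "calibration_spec")
}

#' Collapse poorly supported splits into polytopies
#'
#' Builds the constraint topology: every internal branch whose support is
#' below `min_support` is collapsed into a polytomy; branch lengths are
#' dropped. Internal nodes without a support value are treated as below the
#' threshold (with a message). The root is never collapsed.
#'
#' @param tree a `phylo` with `node.support` (see [read_newick()]).
#' @param min_support threshold in `[0, 1]`; splits at or above it survive.
#' @return a topology-only `phylo` (no branch lengths).
#' @export
constraint_from_support <- function(tree, min_support = 0.7) {
  sup <- tree$node.support
  if (is.null(sup)) sup <- rep(NA_real_, tree$Nnode)
  if (anyNA(sup[-1])) {
    message(sum(is.na(sup[-1])), " internal node(s) without support treated as unsupported")
  }
  ntip <- ape::Ntip(tree)
  # edge whose child is internal node i (node id ntip+i) is collapsible
  keep_node <- c(TRUE, !is.na(sup[-1]) & sup[-1] >= min_support)  # index = node - ntip
  tr <- tree
  tr$edge.length <- rep(1, nrow(tr$edge))
  collapse <- which(!keep_node) + ntip
  collapse <- setdiff(collapse, root_node(tree))
  if (length(collapse)) {
    # zero out collapsible internal edges, then di2multi
    kill <- tr$edge[, 2] %in% collapse
    tr$edge.length[kill] <- 0
    tr <- ape::di2multi(tr, tol = 1e-9)
  }
  tr$edge.length <- NULL
  tr$node.support <- NULL
  tr$node.label <- NULL
  tr
}

#' Graft a calibrated subclade tree into a backbone
#'
#' Both trees must be ultrametric with root (crown) age 1. The backbone MRCA
#' of the shared tips defines the clade to replace; that clade (crown age
#' `c` in backbone units) is excised and the subtree inserted in its place
#' with all subtree branch lengths multiplied by `c`, so the subtree's
#' root lands exactly at the replaced crown node. The stem branch above the
#' clade is untouched and the resulting tree is ultrametric with root age 1.
#'
#' Shared tips are matched through an explicit two-column mapping, never by
#' fuzzy name matching. Tips of the backbone clade that are not listed as
#' shared are simply replaced along with the clade.
#'
#' @param backbone ultrametric `phylo`, root age 1.
#' @param subtree ultrametric `phylo`, root age 1 (renormalized with a
#'   message when its root age differs by more than 1e-6).
#' @param shared_tips data.frame with columns `backbone`, `subtree` naming
#'   the matched tips.
#' @return the grafted `phylo`, root age 1.
#' @export
graft <- function(backbone, subtree, shared_tips) {
  stopifnot(is.data.frame(shared_tips),
            all(c("backbone", "subtree") %in% names(shared_tips)))
  if (abs(root_age(backbone) - 1) > 1e-6) {
    stop("backbone root age must be 1", call. = FALSE)
  }
  miss_b <- setdiff(shared_tips$backbone, backbone$tip.label)
  if (length(miss_b)) stop("shared tips missing from backbone: ",
                           paste(miss_b, collapse = ", "), call. = FALSE)
  miss_s <- setdiff(shared_tips$subtree, subtree$tip.label)
  if (length(miss_s)) stop("subtree missing shared tip(s): ",
                           paste(miss_s, collapse = ", "), call. = FALSE)
  sub_root_age <- root_age(subtree)
  if (abs(sub_root_age - 1) > 1e-6) {
    message("subtree root age ", format(sub_root_age), " normalized to 1")
  }
  subtree$edge.length <- subtree$edge.length / sub_root_age
  shared_b <- shared_tips$backbone
  if (length(shared_b) == 1) {
    mrca <- match(shared_b, backbone$tip.label)
  } else {
    mrca <- ape::getMRCA(backbone, shared_b)
  }
  clade_tips <- backbone$tip.label[tips_under(backbone, mrca)]
  intruders <- setdiff(clade_tips, shared_b)
  if (length(intruders)) {
    stop("shared tips are not monophyletic in the backbone; intruding tips: ",
         paste(intruders, collapse = ", "), call. = FALSE)
  }
  crown <- node_ages(backbone)[mrca]
  if (crown <= 1e-12) {
    stop("replaced clade has zero crown age (need >= 2 shared tips spanning a clade)",
         call. = FALSE)
  }
  sub_scaled <- subtree
  sub_scaled$edge.length <- sub_scaled$edge.length * crown
  sub_scaled$node.label <- NULL
  if (length(clade_tips) == 1) {
    placeholder <- clade_tips
    bb2 <- backbone
  } else {
    placeholder <- clade_tips[1]
    bb2 <- ape::drop.tip(backbone, setdiff(clade_tips, placeholder))
  }
  # attach the subtree root on the placeholder's terminal branch at age
  # `crown`, then remove the placeholder (collapses the degree-2 node);
  # the placeholder is renamed first so a same-named subtree tip survives
  ph_idx <- match(placeholder, bb2$tip.label)
  placeholder <- ".mkareas_graft_placeholder."
  bb2$tip.label[ph_idx] <- placeholder
  grafted <- ape::bind.tree(bb2, sub_scaled, where = ph_idx, position = crown)
  grafted <- ape::drop.tip(grafted, placeholder)
  grafted$node.support <- NULL
  grafted$node.label <- NULL
  validate_tree(grafted)
  grafted
}

#' Flag conspicuously long terminal branches
#'
#' A stand-in for the visual long-branch screen used in barcode supertree
#' assembly: flags tips whose terminal branch exceeds `factor` times the
#' median terminal branch length, sorted by decreasing excess.
#'
#' @param tree a `phylo`.
#' @param factor multiplier on the median terminal branch length.
#' @return character vector of tip labels (possibly empty).
#' @export
flag_long_branches <- function(tree, factor = 10) {
  ntip <- ape::Ntip(tree)
  term <- tree$edge.length[match(seq_len(ntip), tree$edge[, 2])]
  med <- stats::median(term)
  excess <- term / med
  hit <- which(is.finite(excess) & excess > factor)
  hit <- hit[order(-excess[hit])]
  tree$tip.label[hit]
}

#' Scale a relative tree to absolute time under calibration uncertainty
#'
#' Multiplies every branch length (hence every node age) of a unit-root
#' ultrametric tree by the low, point and high calibration ages.
#'
#' @param tree ultrametric `phylo` with root age 1 (tolerance 1e-6).
#' @param calib a [calibration_spec()].
#' @return `list(low =, point =, high =)` of `phylo`s, plus an `ages`
#'   data.frame (`node`, `age_rel`, `age_low`, `age_point`, `age_high`, Myr).
#' @export
scale_absolute <- function(tree, calib = calibration_spec()) {
  if (abs(root_age(tree) - 1) > 1e-6) {
    stop("tree root age must be 1 (relative calibration)", call. = FALSE)
  }
  mk <- function(f) { t2 <- tree; t2$edge.length <- t2$edge.length * f; t2 }
  rel <- node_ages(tree)
  list(low = mk(calib$low), point = mk(calib$point), high = mk(calib$high),
       ages = data.frame(node = seq_along(rel), age_rel = rel,
                         age_low = rel * calib$low,
                         age_point = rel * calib$point,
                         age_high = rel * calib$high))
}

#' Format an age triple the way summary tables print it
#'
#' Rounds half-up to 0.1 Myr, drops the decimal when the rounded value is
#' whole, and prints `"point (low-high)"` with an en dash.
#'
#' @param rel relative age (root = 1).
#' @param calib a [calibration_spec()].
#' @export
format_age_triple <- function(rel, calib = calibration_spec()) {
  v <- round_half_up(rel * c(calib$low, calib$point, calib$high), 1)
  s <- vapply(v, function(x) {
    if (abs(x - round(x)) < 1e-9) format(round(x)) else format(x, nsmall = 1)
  }, "")
  paste0(s[2], " (", s[1], "–", s[3], ")")
}

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
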