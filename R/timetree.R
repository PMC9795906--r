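#' Time-calibrated trees
#'
#' `mkareas` passes trees between pipeline stages as ape `phylo` objects with
#' two light extensions: an optional `node.support` vector (one value per
#' internal node, in `[0, 1]`, `NA` when absent) and node ages measured
#' *backward* from the tips (age 0 = present), obtained with [node_ages()].
#' Branch lengths are in relative units (root crown age = 1) or absolute Myr
#' depending on the stage; the object itself is agnostic.
#'
#' @name timetree
NULL

#' Read a Newick tree with validation
#'
#' Parses a Newick file (or string), stores internal-node labels that look
#' numeric as per-node support values, and validates the basic tree
#' invariants: single root, non-negative branch lengths, unique tip labels.
#' Support values in `(1, 100]` are interpreted as percentages and rescaled
#' to `[0, 1]` with a warning.
#'
#' @param path path to a Newick file, or a Newick string containing `";"`.
#' @param expect_ultrametric if `TRUE`, verify that all root-to-tip path
#'   lengths agree within `1e-8 *` root age and error otherwise, reporting
#'   the maximum deviation.
#' @return an ape `phylo` with an extra `node.support` numeric vector
#'   (length `Nnode`, `NA` where no support was present).
#' @export
read_newick <- function(path, expect_ultrametric = FALSE) {
  txt <- if (grepl(";", path, fixed = TRUE)) path else {
    paste(readLines(path, warn = FALSE), collapse = "")
  }
  tr <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) NULL
  )
  if (is.null(tr) || !inherits(tr, "phylo")) {
    # locate the first structurally suspicious character for the report
    bad <- regexpr("[^A-Za-z0-9_.:,;()\\[\\]' \t\n|-]", txt)
    stop("malformed Newick near character offset ",
         if (bad > 0) bad else nchar(txt), call. = FALSE)
  }
  if (is.null(tr$edge.length)) {
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  validate_tree(tr)
  tr$node.support <- parse_support(tr$node.label, tr$Nnode)
  if (expect_ultrametric) {
    dev <- ultrametric_deviation(tr)
    tol <- 1e-8 * max(node_depths(tr))
    if (dev > tol) {
      stop("tree is not ultrametric: max root-to-tip deviation ",
           format(dev), " exceeds tolerance ", format(tol), call. = FALSE)
    }
  }
  tr
}

parse_support <- function(labels, nnode) {
  sup <- rep(NA_real_, nnode)
  if (is.null(labels)) return(sup)
  suppressWarnings(num <- as.numeric(labels))
  sup[!is.na(num)] <- num[!is.na(num)]
  if (any(sup > 1, na.rm = TRUE)) {
    if (any(sup < 0 | sup > 100, na.rm = TRUE)) {
      stop("node support values outside [0, 100]", call. = FALSE)
    }
    warning("support values in (1, 100] rescaled to [0, 1]")
    sup <- sup / 100
  }
  sup
}

validate_tree <- function(tr) {
  stopifnot(inherits(tr, "phylo"))
  if (anyDuplicated(tr$tip.label)) {
    stop("tip labels are not unique", call. = FALSE)
  }
  if (any(tr$edge.length < 0)) {
    stop("negative branch lengths", call. = FALSE)
  }
  # exactly one root: one node that never appears as a child
  nodes <- seq_len(ape::Ntip(tr) + tr$Nnode)
  parentless <- setdiff(nodes, tr$edge[, 2])
  if (length(parentless) != 1L) {
    stop("tree does not have exactly one root", call. = FALSE)
  }
  invisible(tr)
}

#' Write a tree to Newick, preserving support values
#'
#' @param tree a `phylo`, optionally with `node.support`.
#' @param path output file; if `NULL` the Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @export
write_newick <- function(tree, path = NULL, digits = 12) {
  if (!is.null(tree$node.support)) {
    lab <- ifelse(is.na(tree$node.support), "",
                  format(tree$node.support, trim = TRUE, digits = 12))
    tree$node.label <- lab
  }
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

# distance of every node from the root, in branch-length units
node_depths <- function(tr) {
  ape::node.depth.edgelength(tr)
}

#' Node ages (backward from the tips)
#'
#' Ages are measured from the present: on an ultrametric tree every tip has
#' age 0 and the root has the crown age. On non-ultrametric trees the age of
#' a node is `max tip depth - node depth` (tips may then have nonzero age).
#'
#' @param tree a `phylo`.
#' @return numeric vector indexed by node id (`1..Ntip` tips, then internals).
#' @export
node_ages <- function(tree) {
  d <- node_depths(tree)
  max(d) - d
}

#' Root (crown) age of a tree
#' @param tree a `phylo`.
#' @export
root_age <- function(tree) {
  max(node_depths(tree))
}

ultrametric_deviation <- function(tr) {
  d <- node_depths(tr)[seq_len(ape::Ntip(tr))]
  max(d) - min(d)
}

is_ultrametric_tol <- function(tr, tol = 1e-8) {
  ultrametric_deviation(tr) <= tol * max(node_depths(tr))
}

root_node <- function(tr) ape::Ntip(tr) + 1L

# children of each node as a list (polytomy-safe), index = node id
children_list <- function(tr) {
  n <- ape::Ntip(tr) + tr$Nnode
  ch <- vector("list", n)
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1]
    ch[[p]] <- c(ch[[p]], tr$edge[i, 2])
  }
  ch
}

# postorder of internal+tip node ids (children before parents)
postorder_nodes <- function(tr) {
  tr <- ape::reorder.phylo(tr, "postorder")
  unique(as.vector(t(tr$edge[, c(2, 1)])))
}

# edge length subtending each node (NA for root), index = child node id
branch_lengths_by_child <- function(tr) {
  n <- ape::Ntip(tr) + tr$Nnode
  bl <- rep(NA_real_, n)
  bl[tr$edge[, 2]] <- tr$edge.length
  bl
}

parent_of <- function(tr) {
  n <- ape::Ntip(tr) + tr$Nnode
  p <- rep(NA_integer_, n)
  p[tr$edge[, 2]] <- tr$edge[, 1]
  p
}

#' Tips descending from a node
#' @keywords internal
tips_under <- function(tr, node) {
  ntip <- ape::Ntip(tr)
  if (node <= ntip) return(node)
  ch <- children_list(tr)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v <= ntip) out <- c(out, v) else stack <- c(stack, ch[[v]])
  }
  sort(out)
}
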