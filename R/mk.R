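#' The equal-rates Markov (Mk) area model
#'
#' One free parameter: the transition rate `q` between any ordered pair of
#' distinct areas (per unit branch length). The rate matrix has off-diagonal
#' entries `q` and diagonal `-(k-1) q`; its stationary distribution is
#' uniform `1/k`.
#'
#' @param q transition rate, `> 0`.
#' @param k number of areas, `>= 2`.
#' @param root_prior `"uniform"` (= the stationary distribution; default) or
#'   `"fitzjohn"` (likelihood-proportional root weighting).
#' @export
area_model <- function(q, k, root_prior = c("uniform", "fitzjohn")) {
  stopifnot(q > 0, k >= 2)
  structure(list(q = q, k = as.integer(k), root_prior = match.arg(root_prior)),
            class = "area_model")
}

#' Transition probabilities of the equal-rates chain
#'
#' Closed form: `P_ii(t) = 1/k + ((k-1)/k) exp(-k q t)` and
#' `P_ij(t) = 1/k - (1/k) exp(-k q t)` for `i != j`. Rows sum to 1; at
#' `t = 0` the matrix is the identity and as `t -> Inf` every entry tends to
#' `1/k`.
#'
#' @param q rate, `k` number of states, `t` elapsed time `>= 0`.
#' @param k,t see above.
#' @return a `k x k` stochastic matrix.
#' @export
transition_prob <- function(q, k, t) {
  if (t < 0) stop("t must be >= 0", call. = FALSE)
  e <- exp(-k * q * t)
  p_off <- (1 - e) / k
  m <- matrix(p_off, k, k)
  diag(m) <- 1 / k + (k - 1) / k * e
  m
}

# apply P(t_j) to column j of x without building matrices:
# P(t) %*% v = e^{-kqt} v + (1 - e^{-kqt}) (sum(v)/k) * 1
# `t` is scalar or one value per column of x.
p_times <- function(q, k, t, x) {
  e <- exp(-k * q * t)
  if (length(e) == 1) e <- rep(e, ncol(x))
  s <- colSums(x) / k
  x * rep(e, each = nrow(x)) + rep(s * (1 - e), each = nrow(x))
}

# tip partial-likelihood matrix: k x ntip indicator columns (all ones when
# the area set is empty = missing)
tip_partials <- function(tips, k, tree) {
  missing_tip <- setdiff(tree$tip.label, names(tips))
  if (length(missing_tip)) {
    stop("tip(s) absent from the assignment table: ",
         paste(missing_tip, collapse = ", "), call. = FALSE)
  }
  ntip <- ape::Ntip(tree)
  m <- matrix(0, k, ntip)
  for (i in seq_len(ntip)) {
    s <- tips[[tree$tip.label[i]]]
    if (length(s) == 0) m[, i] <- 1 else {
      if (any(s < 1 | s > k)) stop("area state out of range at tip ",
                                   tree$tip.label[i], call. = FALSE)
      m[s, i] <- 1
    }
  }
  m
}

# Felsenstein pruning; returns per-node scaled partials, per-node log scale
# factors, and the total log-likelihood. Polytomy-safe.
prune_internal <- function(tree, tipm, model) {
  k <- model$k; q <- model$q
  ntip <- ape::Ntip(tree); ntot <- ntip + tree$Nnode
  bl <- branch_lengths_by_child(tree)
  ch <- children_list(tree)
  partial <- matrix(0, k, ntot)
  partial[, seq_len(ntip)] <- tipm
  logscale <- numeric(ntot)
  po <- ape::reorder.phylo(tree, "postorder")
  inner <- unique(po$edge[, 1])          # postorder: children before parents
  for (v in inner) {
    kids <- ch[[v]]
    lifted <- p_times(q, k, bl[kids], partial[, kids, drop = FALSE])
    vec <- apply(lifted, 1, prod)
    sc <- sum(vec)
    if (sc <= 0) {
      partial[, v] <- 0
      logscale[v] <- -Inf + sum(logscale[kids])
    } else {
      partial[, v] <- vec / sc
      logscale[v] <- log(sc) + sum(logscale[kids])
    }
  }
  root <- root_node(tree)
  pr <- root_prior_vec(model, partial[, root])
  ll <- log(sum(pr * partial[, root])) + logscale[root]
  list(partial = partial, logscale = logscale, loglik = ll,
       lifted_cache = NULL)
}

root_prior_vec <- function(model, root_partial) {
  if (model$root_prior == "fitzjohn") {
    s <- sum(root_partial)
    if (s > 0) root_partial / s else rep(1 / model$k, model$k)
  } else {
    rep(1 / model$k, model$k)
  }
}

#' Log-likelihood of tip areas under the Mk model (pruning)
#'
#' Felsenstein pruning with per-node rescaling (safe on thousands of tips).
#' Polymorphic tips enter as indicator vectors over their observed areas;
#' missing tips (empty set) as all-ones vectors, i.e. the likelihood is
#' integrated over all states a multiple-state or missing tip may occupy.
#' The root is combined with a uniform `1/k` weighting (the model's
#' stationary distribution) unless the model says `"fitzjohn"`.
#'
#' @param tree a `phylo`.
#' @param tips named list (by tip label) of integer area-state sets in
#'   `1..k`; empty = missing.
#' @param model an [area_model()].
#' @return the log-likelihood (scalar).
#' @export
prune_loglik <- function(tree, tips, model) {
  tipm <- tip_partials(tips, model$k, tree)
  prune_internal(tree, tipm, model)$loglik
}

#' Maximum-likelihood estimate of the Mk rate
#'
#' Bounded 1-D maximization of [prune_loglik()] over `q` (golden-section on
#' `log q`). Warns when fewer than two tips carry informative
#' (non-missing) states or all observed tips share one state; flags an
#' optimum within 1% of a bound.
#'
#' @param tree a `phylo`.
#' @param tips named list of area sets (see [prune_loglik()]).
#' @param k number of areas.
#' @param bounds search interval for `q`.
#' @param root_prior passed to [area_model()].
#' @return `list(q_hat, loglik, at_bound, convergence)`.
#' @export
fit_rate <- function(tree, tips, k, bounds = c(1e-8, 1e3),
                     root_prior = "uniform") {
  nonmiss <- Filter(length, tips)
  if (!length(nonmiss)) stop("all tips missing; rate not identifiable", call. = FALSE)
  singles <- unique(unlist(nonmiss[lengths(nonmiss) == 1]))
  if (length(nonmiss) < 2 || length(singles) <= 1 && all(lengths(nonmiss) == 1)) {
    warning("fewer than two informative, non-identical tip states; ",
            "q is weakly identified")
  }
  tipm <- tip_partials(tips, k, tree)
  nll <- function(logq) {
    -prune_internal(tree, tipm, area_model(exp(logq), k, root_prior))$loglik
  }
  opt <- stats::optimize(nll, interval = log(bounds), tol = 1e-10)
  q_hat <- exp(opt$minimum)
  at_bound <- q_hat / bounds[1] < 1.01 || bounds[2] / q_hat < 1.01
  if (at_bound) warning("q_hat at a search bound: ", format(q_hat))
  list(q_hat = q_hat, loglik = -opt$objective, at_bound = at_bound,
       convergence = list(bounds = bounds, tol = 1e-8))
}

#' Marginal ancestral areas (relative likelihoods) at every node
#'
#' Up--down algorithm: the upward (pruning) pass conditions each node on the
#' tips below it; the downward pass propagates the root weighting and the
#' contributions of the rest of the tree, so every internal node gets its
#' marginal posterior over the `k` areas given *all* tip data. Vectors are
#' normalized to sum to 1. Tip rows carry the tip's own conditional
#' distribution (probability 1 on a single observed state).
#'
#' @param tree a `phylo`.
#' @param tips named list of area sets.
#' @param model an [area_model()].
#' @return matrix `(Ntip + Nnode) x k` of relative likelihoods, rows
#'   indexed by node id.
#' @export
marginal_ancestral <- function(tree, tips, model) {
  k <- model$k; q <- model$q
  tipm <- tip_partials(tips, k, tree)
  pr <- prune_internal(tree, tipm, model)
  ntip <- ape::Ntip(tree); ntot <- ntip + tree$Nnode
  bl <- branch_lengths_by_child(tree)
  ch <- children_list(tree)
  root <- root_node(tree)
  above <- matrix(0, k, ntot)    # message arriving at each node from above
  above[, root] <- root_prior_vec(model, pr$partial[, root])
  # preorder: parents before children
  pre <- rev(unique(ape::reorder.phylo(tree, "postorder")$edge[, 1]))
  for (v in pre) {
    kids <- ch[[v]]
    lifted <- p_times(q, k, bl[kids], pr$partial[, kids, drop = FALSE])
    for (j in seq_along(kids)) {
      others <- lifted[, -j, drop = FALSE]
      prod_oth <- if (ncol(others)) apply(others, 1, prod) else rep(1, k)
      msg <- above[, v] * prod_oth
      # P is symmetric for the equal-rates model: P^T = P
      down <- p_times(q, k, bl[kids[j]], matrix(msg, ncol = 1))[, 1]
      s <- sum(down)
      above[, kids[j]] <- if (s > 0) down / s else rep(1 / k, k)
    }
  }
  marg <- above * pr$partial
  marg <- t(marg)
  rs <- rowSums(marg)
  rs[rs == 0] <- 1
  marg <- marg / rs
  rownames(marg) <- c(tree$tip.label, paste0("node", (ntip + 1):ntot))
  marg
}
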