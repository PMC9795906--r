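# Independent oracles used to validate the package's fast paths.
# Deliberately written in a different style from the implementation.

# matrix exponential of the explicit equal-rates rate matrix, by
# eigendecomposition (the rate matrix is symmetric)
oracle_transition_prob <- function(q, k, t) {
  Q <- matrix(q, k, k); diag(Q) <- -(k - 1) * q
  es <- eigen(Q, symmetric = TRUE)
  es$vectors %*% diag(exp(es$values * t)) %*% t(es$vectors)
}

# brute-force tree likelihood: sum over all joint internal-node states
oracle_tree_loglik <- function(tree, tips, q, k) {
  ntip <- ape::Ntip(tree); nint <- tree$Nnode
  bl <- tree$edge.length
  edge <- tree$edge
  tipm <- lapply(tree$tip.label, function(l) {
    s <- tips[[l]]
    v <- rep(0, k); if (length(s)) v[s] <- 1 else v[] <- 1
    v
  })
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nint)))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    states <- grid[g, ]
    p <- 1 / k  # uniform root prior
    for (e in seq_len(nrow(edge))) {
      a <- states[edge[e, 1] - ntip]
      P <- oracle_transition_prob(q, k, bl[e])
      child <- edge[e, 2]
      if (child <= ntip) {
        p <- p * sum(P[a, ] * tipm[[child]])
      } else {
        p <- p * P[a, states[child - ntip]]
      }
    }
    total <- total + p
  }
  log(total)
}

# brute-force marginals: joint enumeration, then per-node sums
oracle_marginals <- function(tree, tips, q, k) {
  ntip <- ape::Ntip(tree); nint <- tree$Nnode
  bl <- tree$edge.length; edge <- tree$edge
  tipm <- lapply(tree$tip.label, function(l) {
    s <- tips[[l]]
    v <- rep(0, k); if (length(s)) v[s] <- 1 else v[] <- 1
    v
  })
  Ps <- lapply(seq_len(nrow(edge)), function(e) oracle_transition_prob(q, k, bl[e]))
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nint)))
  marg <- matrix(0, nint, k)
  for (g in seq_len(nrow(grid))) {
    states <- grid[g, ]
    p <- 1 / k
    for (e in seq_len(nrow(edge))) {
      a <- states[edge[e, 1] - ntip]
      child <- edge[e, 2]
      p <- p * if (child <= ntip) sum(Ps[[e]][a, ] * tipm[[child]])
      else Ps[[e]][a, states[child - ntip]]
    }
    for (v in seq_len(nint)) marg[v, states[v]] <- marg[v, states[v]] + p
  }
  marg / rowSums(marg)
}

# alignment identity by memoized recursion over (i, j, state); same scoring
# and tie preference (match/mismatch > gap-in-b > gap-in-a) as the package
oracle_identity <- function(a, b, gap_open = -2, gap_extend = -1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  memo <- array(NA_real_, c(n + 1, m + 1, 3))
  sc <- function(i, j, st) {
    if (!is.na(memo[i + 1, j + 1, st])) return(memo[i + 1, j + 1, st])
    val <- if (i == 0 && j == 0) {
      if (st == 1) 0 else NEG
    } else if (st == 1) {
      if (i == 0 || j == 0) NEG
      else max(sc(i - 1, j - 1, 1), sc(i - 1, j - 1, 2), sc(i - 1, j - 1, 3)) +
        (if (av[i] == bv[j]) 1 else -1)
    } else if (st == 2) {
      if (i == 0) NEG
      else max(sc(i - 1, j, 1) + gap_open, sc(i - 1, j, 2) + gap_extend,
               sc(i - 1, j, 3) + gap_open)
    } else {
      if (j == 0) NEG
      else max(sc(i, j - 1, 1) + gap_open, sc(i, j - 1, 3) + gap_extend,
               sc(i, j - 1, 2) + gap_open)
    }
    memo[i + 1, j + 1, st] <<- val
    val
  }
  for (st in 1:3) sc(n, m, st)
  # traceback with the fixed preference order
  i <- n; j <- m
  vals <- c(sc(n, m, 1), sc(n, m, 2), sc(n, m, 3))
  st <- which.max(vals)
  cols <- 0; matches <- 0
  while (i > 0 || j > 0) {
    cols <- cols + 1
    if (st == 1) {
      if (av[i] == bv[j]) matches <- matches + 1
      prev <- memo[i + 1, j + 1, 1] - (if (av[i] == bv[j]) 1 else -1)
      i <- i - 1; j <- j - 1
      if (i == 0 && j == 0) break
      st <- if (abs(sc(i, j, 1) - prev) < 1e-9) 1
      else if (abs(sc(i, j, 2) - prev) < 1e-9) 2 else 3
    } else if (st == 2) {
      cur <- memo[i + 1, j + 1, 2]
      i <- i - 1
      st <- if (abs(sc(i, j, 1) + gap_open - cur) < 1e-9) 1
      else if (abs(sc(i, j, 2) + gap_extend - cur) < 1e-9) 2 else 3
    } else {
      cur <- memo[i + 1, j + 1, 3]
      j <- j - 1
      st <- if (abs(sc(i, j, 1) + gap_open - cur) < 1e-9) 1
      else if (abs(sc(i, j, 3) + gap_extend - cur) < 1e-9) 3 else 2
    }
  }
  matches / cols
}

# the greedy clustering procedure, written naively over all pairs
oracle_greedy <- function(seqs, threshold, accept_mode = "first") {
  ord <- order(-nchar(seqs$sequence), seq_len(nrow(seqs)))
  centroid_rows <- integer(0)
  cl <- integer(nrow(seqs))
  for (i in ord) {
    ids <- vapply(centroid_rows, function(cr)
      pairwise_identity(seqs$sequence[i], seqs$sequence[cr]), numeric(1))
    ok <- which(ids >= threshold)
    if (length(ok)) {
      cl[i] <- if (accept_mode == "first") ok[1] else ok[which.max(ids[ok])]
    } else {
      centroid_rows <- c(centroid_rows, i)
      cl[i] <- length(centroid_rows)
    }
  }
  list(cluster = cl, centroid_rows = centroid_rows)
}

# rejection sampler for endpoint-conditioned 2-state equal-rates paths:
# forward-simulate from a, keep paths that end in b; returns event count
oracle_conditioned_events <- function(q, k, t, a, b, n_draws, max_tries = 1e7) {
  out <- integer(0); tries <- 0
  while (length(out) < n_draws && tries < max_tries) {
    tries <- tries + 1
    s <- a; tt <- 0; nev <- 0
    repeat {
      w <- stats::rexp(1, (k - 1) * q)
      if (tt + w > t) break
      tt <- tt + w
      ns <- sample.int(k - 1, 1); if (ns >= s) ns <- ns + 1L
      s <- ns; nev <- nev + 1
    }
    if (s == b) out <- c(out, nev)
  }
  out
}

# random ultrametric tree with root age 1 (coalescent-ish shape)
random_unit_tree <- function(n) {
  tr <- ape::rcoal(n)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  tr
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, p) {
  v <- strsplit(s, "")[[1]]
  hit <- stats::runif(length(v)) < p
  if (any(hit)) {
    v[hit] <- vapply(v[hit], function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
  }
  paste(v, collapse = "")
}
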