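# helpers: constant-rate map and single-state area map over a whole tree
uniform_rate_map <- function(tree, rate) {
  ages <- node_ages(tree)
  rate_map(data.frame(child = tree$edge[, 2],
                      start_age = ages[tree$edge[, 1]],
                      end_age = ages[tree$edge[, 2]], rate = rate), tree)
}

uniform_area_map <- function(tree, state) {
  ages <- node_ages(tree)
  m <- data.frame(child = tree$edge[, 2], state = state,
                  start_age = ages[tree$edge[, 1]],
                  end_age = ages[tree$edge[, 2]])
  class(m) <- c("stochastic_map", "data.frame")
  m
}

test_that("pair_samples permutes or resamples depending on lengths", {
  r <- lapply(1:5, function(i) i); a <- lapply(1:5, function(i) i * 10)
  p <- pair_samples(r, a, seed = 3)
  expect_equal(length(p), 5)
  expect_setequal(vapply(p, `[[`, numeric(1), "rate_idx"), 1:5)
  expect_setequal(vapply(p, `[[`, numeric(1), "area_idx"), 1:5)

  p2 <- pair_samples(r[1:3], a, seed = 4)
  expect_equal(length(p2), 5)
  expect_true(all(vapply(p2, `[[`, numeric(1), "rate_idx") %in% 1:3))
  p2b <- pair_samples(r[1:3], a, seed = 4)
  expect_identical(vapply(p2, `[[`, numeric(1), "rate_idx"),
                   vapply(p2b, `[[`, numeric(1), "rate_idx"))
  expect_error(pair_samples(list(), a), "empty")
})

test_that("segmentation respects change-points and the max length", {
  # branch of length 0.05 within a unit-height tree
  tr2 <- read_newick("((A:0.05,B:0.05):0.95,C:1);")
  rm <- uniform_rate_map(tr2, 0.2)
  am <- uniform_area_map(tr2, 1L)
  segs <- segment_branches(tr2, rm, am, max_frac = 0.02)
  sa <- segs[segs$child == 1, ]
  expect_equal(nrow(sa), 3)              # ceil(0.05 / 0.02)
  expect_equal(sa$duration, rep(0.05 / 3, 3), tolerance = 1e-12)
  # conservation over the whole tree
  expect_equal(sum(segs$duration), sum(tr2$edge.length), tolerance = 1e-9)

  # a mid-branch area change is respected exactly
  am2 <- am
  long_branch <- 3L  # tip C, length 1
  am2 <- am2[am2$child != long_branch, ]
  am2 <- rbind(am2, data.frame(child = long_branch, state = c(1L, 2L),
                               start_age = c(1, 0.5), end_age = c(0.5, 0)))
  class(am2) <- c("stochastic_map", "data.frame")
  segs2 <- segment_branches(tr2, rm, am2, max_frac = 0.25)
  sc <- segs2[segs2$child == long_branch, ]
  expect_true(any(abs(sc$start_age - 0.5) < 1e-12))
  expect_equal(sort(unique(sc$area)), c(1L, 2L))
  expect_equal(sum(sc$duration), 1, tolerance = 1e-12)

  # mismatched trees error
  tr3 <- read_newick("(A:1,B:1);")
  expect_error(segment_branches(tr3, rm, am), "same tree")
})

test_that("per-area means weight by duration and aggregate over windows", {
  # one branch half in A at rate 0.4, half in B at rate 0.2
  tr <- read_newick("(A:1,B:1);")
  ages <- node_ages(tr)
  rm <- rate_map(data.frame(child = c(1L, 1L, 2L),
                            start_age = c(1, 0.5, 1),
                            end_age = c(0.5, 0, 0),
                            rate = c(0.4, 0.2, 0.3)), tr)
  am <- data.frame(child = c(1L, 1L, 2L), state = c(1L, 2L, 3L),
                   start_age = c(1, 0.5, 1), end_age = c(0.5, 0, 0))
  class(am) <- c("stochastic_map", "data.frame")
  pairing <- list(list(rates = rm, areas = am))
  s <- summarize_by_area(pairing, tr, n_windows = 4)
  expect_equal(s$overall$mean[s$overall$area == 1], 0.4)
  expect_equal(s$overall$mean[s$overall$area == 2], 0.2)
  expect_equal(s$overall$mean[s$overall$area == 3], 0.3)
  # pooled duration-weighted overall of areas 1+2 = 0.3 by hand
  segs <- segment_branches(tr, rm, am, 0.02)
  ab <- segs[segs$area %in% 1:2, ]
  expect_equal(sum(ab$rate * ab$duration) / sum(ab$duration), 0.3)

  # windowed summaries aggregate back to the overall mean
  w <- s$windows
  for (a in 1:3) {
    wa <- w[w$area == a, ]
    segs_a <- segs[segs$area == a, ]
    dur_w <- vapply(seq_len(nrow(wa)), function(i) {
      s0 <- pmin(segs_a$start_age, wa$start_age[i])
      e0 <- pmax(segs_a$end_age, wa$end_age[i])
      sum(pmax(s0 - e0, 0))
    }, numeric(1))
    expect_equal(sum(wa$mean * dur_w) / sum(dur_w),
                 s$overall$mean[s$overall$area == a], tolerance = 1e-9)
  }
})

test_that("summaries are invariant to finer subdivision", {
  set.seed(33)
  tr <- random_unit_tree(10)
  rm <- uniform_rate_map(tr, 0.25)
  # alternating-area map: per branch, one or two pieces
  ages <- node_ages(tr); par <- mkareas:::parent_of(tr)
  rows <- lapply(tr$edge[, 2], function(ch) {
    s0 <- ages[par[ch]]; e0 <- ages[ch]
    if ((s0 - e0) > 0.3) {
      mid <- (s0 + e0) / 2
      data.frame(child = ch, state = c(1L, 2L), start_age = c(s0, mid),
                 end_age = c(mid, e0))
    } else data.frame(child = ch, state = 1L, start_age = s0, end_age = e0)
  })
  am <- do.call(rbind, rows)
  class(am) <- c("stochastic_map", "data.frame")
  pairing <- list(list(rates = rm, areas = am))
  s_coarse <- summarize_by_area(pairing, tr, n_windows = 5, max_frac = 0.02)
  s_fine <- summarize_by_area(pairing, tr, n_windows = 5, max_frac = 0.002)
  expect_equal(s_fine$overall$mean, s_coarse$overall$mean, tolerance = 1e-9)
  expect_equal(s_fine$windows$mean, s_coarse$windows$mean, tolerance = 1e-9)
  # one-area tree: per-area mean equals the plain duration-weighted branch mean
  am1 <- uniform_area_map(tr, 1L)
  rm_var <- rate_map(data.frame(child = tr$edge[, 2],
                                start_age = ages[tr$edge[, 1]],
                                end_age = ages[tr$edge[, 2]],
                                rate = runif(nrow(tr$edge), 0.1, 0.5)), tr)
  s1 <- summarize_by_area(list(list(rates = rm_var, areas = am1)), tr, 5)
  bl <- tr$edge.length
  expect_equal(s1$overall$mean, sum(rm_var$rate * (rm_var$start_age - rm_var$end_age)) /
                 sum(bl), tolerance = 1e-9)
})

test_that("two-regime recovery brackets the true rate ratio", {
  # a clade with true net rate 2x the background; deterministic area map
  # (clade = area 2) paired with noisy rate samples
  set.seed(43)
  bd <- sim_bd_tree(sim_config(
    n_tips = 80, birth_rate = 0.3, death_rate = 0,
    rate_shift_spec = list(list(time = 2, new_lambda = 0.6, new_mu = 0)),
    rng_seed = 43))
  tr <- bd$tree
  truth <- bd$rates
  am <- truth
  am$state <- ifelse(abs(truth$rate - 0.6) < 1e-9, 2L, 1L)
  am <- am[, c("child", "state", "start_age", "end_age")]
  # merge adjacent same-state pieces is unnecessary for segmentation
  class(am) <- c("stochastic_map", "data.frame")
  rate_samples <- lapply(1:100, function(i) {
    rs <- truth
    rs$rate <- rs$rate * exp(rnorm(nrow(rs), 0, 0.1))
    rs
  })
  pairings <- pair_samples(rate_samples, rep(list(am), 100), seed = 44)
  s <- summarize_by_area(pairings, tr, n_windows = 5)
  m1 <- s$overall[s$overall$area == 1, ]
  m2 <- s$overall[s$overall$area == 2, ]
  expect_gt(nrow(m1), 0); expect_gt(nrow(m2), 0)
  # ratio of mean rates near 2, bracketed by propagating the 95% bounds
  expect_gt(m2$mean / m1$mean, 2 * 0.8)
  expect_lt(m2$mean / m1$mean, 2 * 1.2)
  expect_true(m2$q2.5 / m1$q97.5 < 2 && m2$q97.5 / m1$q2.5 > 2)
})
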