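test_that("outlier screen removes only trials beyond the SD margin", {
  # identical points: zero variance, nothing exceeds the margin
  sc <- screen_outliers(rep(0.1, 30), rep(0.3, 30))
  expect_equal(sc$removed, 0L)

  # tight scatter plus one gross onset outlier: exactly that trial removed
  set.seed(2)
  on <- seq(0.09, 0.11, length.out = 30)   # inliers within ~1.7 SD
  off <- seq(0.29, 0.31, length.out = 30)
  on[17] <- 0.2                            # > 5 SD away after inclusion
  sc <- screen_outliers(on, off)
  expect_equal(sc$removed, 1L)
  expect_false(sc$kept[17])

  # four points on a square: all deviations equal (1.5 SD), none removed
  sq <- screen_outliers(c(0, 0, 1, 1), c(0, 1, 0, 1))
  expect_equal(sq$removed, 0L)

  # fewer than 3 trials passes through untouched
  expect_message(s2 <- screen_outliers(c(0, 1), c(1, 2)), "skipped")
  expect_equal(s2$removed, 0L)
})

test_that("outlier screen never removes more than 10% of trials", {
  set.seed(3)
  on <- c(rnorm(40, 0, 0.01), rnorm(10, 0.5, 0.01))  # 20% far mass
  off <- on + 0.2
  sc <- screen_outliers(on, off)
  expect_lte(sc$removed, 5L)
})

test_that("burst summaries are the sample moments", {
  s <- summarize_burst("b", c(0, 0.1), c(0.2, 0.3))
  expect_equal(s$X, 0.05)
  expect_equal(s$Y, 0.25)
  expect_equal(s$sX, sd(c(0, 0.1)))
  expect_equal(s$sX, 0.0707, tolerance = 1e-3)
  expect_equal(s$rho, 1.0)

  # degenerate: zero variance defines rho = 0
  s0 <- summarize_burst("c", rep(0.1, 5), rep(0.3, 5))
  expect_equal(unlist(s0[c("sX", "sY", "rho")]), c(sX = 0, sY = 0, rho = 0))

  # translation equivariance
  set.seed(4)
  on <- rnorm(20, 0.1, 0.03); off <- rnorm(20, 0.3, 0.03)
  a <- summarize_burst("a", on, off)
  b <- summarize_burst("a", on + 0.1, off + 0.1)
  expect_equal(b$X, a$X + 0.1)
  expect_equal(b$Y, a$Y + 0.1)
  expect_equal(b$sX, a$sX)
  expect_equal(b$rho, a$rho)

  expect_error(summarize_burst("d", 0.1, 0.2), "insufficient")
})

test_that("adjacency criterion matches the worked rectangle-overlap cases", {
  a <- make_stats("a", 0, 0.10, 0.04, 0.04)
  b <- make_stats("b", 0.10, 0.20, 0.04, 0.04)
  expect_equal(adjacency_q(a, b), 0.04 * sqrt(2) * 2 - 0.1 * sqrt(2), tolerance = 1e-12)
  expect_lt(adjacency_q(a, b), 0)  # -0.028: not adjacent

  a2 <- make_stats("a", 0, 0.10, 0.06, 0.06)
  b2 <- make_stats("b", 0.10, 0.20, 0.06, 0.06)
  expect_gt(adjacency_q(a2, b2), 0)  # +0.028: adjacent
  expect_equal(adjacency_q(a2, b2), 0.12 * sqrt(2) - 0.1 * sqrt(2), tolerance = 1e-12)

  # identical centroids are adjacent by convention
  expect_identical(adjacency_q(a, make_stats("c", 0, 0.10, 0.01, 0.01)), Inf)
})

test_that("adjacency criterion equals the 16-sign brute-force oracle", {
  set.seed(5)
  for (i in 1:1000) {
    p <- random_stats_pair()
    expect_equal(adjacency_q(p$a, p$b), brute_force_q(p$a, p$b), tolerance = 1e-12)
  }
})

test_that("adjacency criterion is symmetric, translation-invariant, scale-equivariant", {
  set.seed(6)
  for (i in 1:200) {
    p <- random_stats_pair()
    q <- adjacency_q(p$a, p$b)
    expect_equal(adjacency_q(p$b, p$a), q, tolerance = 1e-12)
    shift <- runif(2, -5, 5)
    at <- p$a; at$X <- at$X + shift[1]; at$Y <- at$Y + shift[2]
    bt <- p$b; bt$X <- bt$X + shift[1]; bt$Y <- bt$Y + shift[2]
    expect_equal(adjacency_q(at, bt), q, tolerance = 1e-9)
    lam <- runif(1, 0.1, 10)
    as <- lapply(p$a, `*`, lam); bs <- lapply(p$b, `*`, lam)
    expect_equal(adjacency_q(as, bs), lam * q, tolerance = 1e-9)
  }
})

test_that("adjacency matrix encodes pairwise overlap with a true diagonal", {
  solo <- build_adjacency(make_stats("a", 0, 0.1, 0.01, 0.01))
  expect_identical(dim(solo), c(1L, 1L))
  expect_true(solo[1, 1])

  far <- make_stats(c("a", "b", "c"), c(0, 0.4, 0.8), c(0.1, 0.5, 0.9),
                    0.01, 0.01)
  B <- build_adjacency(far)
  expect_identical(sum(B), 3L)  # diagonal only

  # chain: A-B and B-C overlap (gap 0.0707 < SD span 0.0849), A-C does not
  chain <- make_stats(c("A", "B", "C"), c(0, 0.05, 0.10), c(0.2, 0.25, 0.30),
                      0.03, 0.03)
  Bc <- build_adjacency(chain)
  expect_true(Bc["A", "B"] && Bc["B", "C"])
  expect_false(Bc["A", "C"])

  expect_error(build_adjacency(make_stats(c("x", "x"), c(0, 1), c(0.1, 1.1), 0.01, 0.01)),
               "duplicate")
})

test_that("equivalence classes are the transitive closure of adjacency", {
  chain <- make_stats(c("A", "B", "C"), c(0, 0.05, 0.10), c(0.2, 0.25, 0.30),
                      0.03, 0.03)
  cls <- equivalence_classes(build_adjacency(chain))
  expect_equal(length(unique(cls)), 1L)  # one class by transitivity

  empty <- diag(5) > 0
  dimnames(empty) <- list(letters[1:5], letters[1:5])
  expect_equal(unname(equivalence_classes(empty)), 1:5)  # all singletons
})

test_that("equivalence classes match a graph-traversal oracle on random graphs", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(2:20, 1)
    A <- matrix(runif(n * n) < 0.15, n, n)
    A[lower.tri(A)] <- FALSE
    diag(A) <- TRUE
    dimnames(A) <- list(paste0("b", seq_len(n)), paste0("b", seq_len(n)))
    got <- equivalence_classes(A)
    want <- bfs_components(A)
    expect_true(same_partition(got, want))
  }
})

test_that("clusters are numbered by ascending mean onset with deterministic ties", {
  st <- make_stats(c("p", "q", "r"), c(0.3, -0.1, 0.1), c(0.5, 0.1, 0.3),
                   0.01, 0.01)
  sol <- order_clusters(stats::setNames(1:3, c("p", "q", "r")), st)
  expect_equal(vapply(sol$clusters, function(cl) cl$members, character(1)),
               c("q", "r", "p"))
  expect_equal(vapply(sol$clusters, `[[`, integer(1), "id"), 1:3)

  # tie in mean onset: lexicographic first member label breaks it
  tie <- make_stats(c("zed", "ant"), c(0.2, 0.2), c(0.4, 0.6), 0.01, 0.01)
  sol2 <- order_clusters(stats::setNames(1:2, c("zed", "ant")), tie)
  expect_equal(sol2$clusters[[1]]$members, "ant")
})

test_that("unconstrained clustering is invariant to input order", {
  cfg <- figure2_config()
  st <- summarize_bursts(generate_burst_dataset(cfg, seed = 9)$bursts |>
                           (\(b) b[b$condition == "unobstructed", ])())
  ref <- membership(cluster_bursts(st))
  set.seed(10)
  for (i in 1:5) {
    perm <- st[sample(nrow(st)), ]
    class(perm) <- c("burst_stats", "data.frame")
    expect_identical(membership(cluster_bursts(perm)), ref)
  }
})

test_that("pooled cluster statistics equal moments of the concatenated trials", {
  set.seed(12)
  t1 <- list(on = rnorm(30, 0.1, 0.02), off = rnorm(30, 0.3, 0.02))
  t2 <- list(on = rnorm(45, 0.12, 0.03), off = rnorm(45, 0.31, 0.03))
  st <- rbind(summarize_burst("a", t1$on, t1$off),
              summarize_burst("b", t2$on, t2$off))
  class(st) <- c("burst_stats", "data.frame")
  sol <- order_clusters(list(c("a", "b")), st)
  pooled <- sol$clusters[[1]]$pooled
  on <- c(t1$on, t2$on); off <- c(t1$off, t2$off)
  expect_equal(pooled$X, mean(on), tolerance = 1e-12)
  expect_equal(pooled$sX, sd(on), tolerance = 1e-12)
  expect_equal(pooled$sY, sd(off), tolerance = 1e-12)
  expect_equal(pooled$rho, cor(on, off), tolerance = 1e-12)
  expect_equal(pooled$n, 75L)
  # centroid is the unweighted mean of member centroids
  expect_equal(unname(sol$clusters[[1]]$centroid["X"]),
               mean(c(mean(t1$on), mean(t2$on))), tolerance = 1e-12)
})

test_that("stage-2 candidates need two overlaps to join a multi-member cluster", {
  # stage-1 cluster of three mutually adjacent members (SD span 0.0566)
  prim <- make_stats(c("m1", "m2", "m3"), c(0.10, 0.11, 0.13),
                     c(0.30, 0.31, 0.33), 0.02, 0.02)
  # candidate adjacent to m2 (gap 0.0495) and m3 (0.0212) but not m1 (0.0636)
  add_in <- make_stats("x1", 0.145, 0.345, 0.02, 0.02)
  expect_lt(adjacency_q(add_in, prim[1, ]), 0)
  sol <- cluster_two_stage(prim, add_in)
  expect_equal(length(sol$clusters), 1L)
  expect_true("x1" %in% sol$clusters[[1]]$members)

  # candidate overlapping only m3 -> stays out as its own cluster
  add_out <- make_stats("x2", 0.15, 0.35, 0.005, 0.005)
  expect_gt(adjacency_q(add_out, prim[3, ]), 0)
  expect_lt(adjacency_q(add_out, prim[2, ]), 0)
  sol2 <- cluster_two_stage(prim, add_out)
  expect_equal(length(sol2$clusters), 2L)
  expect_equal(sol2$clusters[[2]]$members, "x2")

  # a singleton stage-1 cluster admits on one overlap
  prim_s <- make_stats("solo", 0.5, 0.7, 0.02, 0.02)
  add_s <- make_stats("x3", 0.52, 0.72, 0.02, 0.02)
  sol3 <- cluster_two_stage(prim_s, add_s)
  expect_equal(length(sol3$clusters), 1L)

  # no additional bursts: identical to stage 1
  sol4 <- cluster_two_stage(prim, prim[0, ])
  expect_identical(membership(sol4), membership(cluster_bursts(prim)))

  expect_error(cluster_two_stage(prim, prim[1, ]), "disjoint")
})

test_that("constrained assignment keeps reference membership and routes novel bursts", {
  cfg <- figure2_config()
  d <- generate_burst_dataset(cfg, seed = 13)
  bt <- d$bursts
  st_u <- summarize_bursts(bt[bt$condition == "unobstructed", ])
  ref <- cluster_bursts(st_u)

  # idempotence: condition data = reference data
  same <- assign_constrained(st_u, ref)
  expect_identical(membership(same), membership(ref))
  expect_equal(same$clusters[[2]]$pooled, ref$clusters[[2]]$pooled)

  # constant phase shift leaves membership unchanged, centroids shifted
  shifted <- st_u
  shifted$X <- shifted$X + 0.07
  shifted$Y <- shifted$Y + 0.07
  class(shifted) <- c("burst_stats", "data.frame")
  sh <- assign_constrained(shifted, ref)
  expect_identical(membership(sh), membership(ref))
  expect_equal(sh$clusters[[1]]$centroid, ref$clusters[[1]]$centroid + 0.07)

  # trail condition: every planted novel burst lands in its planted cluster
  st_t <- summarize_bursts(bt[bt$condition == "trail", ])
  ct <- assign_constrained(st_t, ref)
  mem <- membership(ct)
  for (nv in which(cfg$novel$condition == "trail")) {
    expect_equal(unname(mem[cfg$novel$label[nv]]), cfg$novel$cluster[nv])
  }
  # known labels unchanged despite the trail phase shifts
  common <- intersect(names(mem), names(membership(ref)))
  expect_identical(mem[common], membership(ref)[common])
})

test_that("novel burst joins the cluster with most adjacent members", {
  # cluster 1: three tight members around (0.1, 0.3); cluster 2: one at (0.4, 0.6)
  st <- make_stats(c("a1", "a2", "a3", "b1"),
                   c(0.10, 0.11, 0.12, 0.40),
                   c(0.30, 0.31, 0.32, 0.60), 0.02, 0.02)
  ref <- cluster_bursts(st)
  expect_equal(length(ref$clusters), 2L)
  cond <- rbind(st, make_stats("new", 0.13, 0.33, 0.02, 0.02))
  class(cond) <- c("burst_stats", "data.frame")
  sol <- assign_constrained(cond, ref)
  expect_equal(unname(membership(sol)["new"]), 1L)

  # adjacent to nothing: nearest centroid with a warning
  cond2 <- rbind(st, make_stats("far", 0.9, 0.95, 0.001, 0.001))
  class(cond2) <- c("burst_stats", "data.frame")
  expect_warning(sol2 <- assign_constrained(cond2, ref), "nearest centroid")
  expect_equal(unname(membership(sol2)["far"]), 2L)
})

test_that("centroid distance is the Euclidean phase-plane norm", {
  c1 <- list(centroid = c(X = 0, Y = 0))
  c2 <- list(centroid = c(X = 0.3, Y = 0.4))
  expect_equal(centroid_distance(c1, c2), 0.5)
  expect_equal(centroid_distance(c2, c1), 0.5)
  expect_equal(centroid_distance(c1, c1), 0)
})

test_that("well-separated planted clusters are recovered exactly", {
  cfg <- figure2_config()
  for (seed in 1:5) {
    d <- generate_burst_dataset(cfg, seed = seed, conditions = "unobstructed")
    st <- summarize_bursts(d$bursts)
    mem <- membership(cluster_bursts(st))
    truth <- d$truth$partition[names(mem)]
    expect_equal(mclust::adjustedRandIndex(mem, truth), 1.0)
  }
})
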