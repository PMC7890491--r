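test_that("network construction respects occupancy and the threshold", {
  gaps <- matrix(c(0, 50, 120,
                   50, 0, 200,
                   120, 200, 0), 3, byrow = TRUE)
  # no occupied patches: empty graph
  snap <- build_network(rep(FALSE, 3), gaps, D = 100)
  expect_equal(igraph::vcount(snap$graph), 0)
  expect_equal(network_length(snap), 0)

  # boundary convention: gap == D is linked
  snap <- build_network(c(TRUE, TRUE, FALSE), gaps, D = 50)
  expect_equal(igraph::ecount(snap$graph), 1)
  expect_equal(igraph::E(snap$graph)$gap, 50)

  # only occupied patches are nodes
  snap <- build_network(c(TRUE, FALSE, TRUE), gaps, D = 150)
  expect_setequal(snap$ids, c("1", "3"))
  expect_equal(igraph::ecount(snap$graph), 1)

  # 5-patch toy: edge set equals the exhaustive pairwise threshold check
  set.seed(17)
  for (rep in 1:20) {
    n <- 5
    xy <- matrix(runif(2 * n, 0, 100), ncol = 2)
    g <- as.matrix(dist(xy))
    D <- runif(1, 10, 80)
    occ <- runif(n) < 0.7
    snap <- build_network(occ, g, D)
    el <- igraph::as_edgelist(snap$graph)
    got <- if (nrow(el)) paste(pmin(el[, 1], el[, 2]),
                               pmax(el[, 1], el[, 2])) else character()
    idx <- which(occ)
    want <- character()
    for (a in idx) for (b in idx) if (a < b && g[a, b] <= D)
      want <- c(want, paste(a, b))
    expect_setequal(got, want)
  }
})

test_that("degree and betweenness match exhaustive oracles", {
  # path graph a-b-c: b bridges the single (a,c) pair
  gaps <- matrix(c(0, 10, 30,
                   10, 0, 10,
                   30, 10, 0), 3, byrow = TRUE)
  snap <- build_network(rep(TRUE, 3), gaps, D = 15)
  expect_equal(unname(node_degree(snap)), c(1, 2, 1))
  expect_equal(unname(node_betweenness(snap)), c(0, 1, 0))

  # complete graph: all degrees n-1, all betweenness 0
  snap <- build_network(rep(TRUE, 4), matrix(5, 4, 4) - diag(5, 4), D = 10)
  expect_equal(unname(node_degree(snap)), rep(3, 4))
  expect_equal(unname(node_betweenness(snap)), rep(0, 4))

  # random graphs: degree equals adjacency row sums, betweenness equals
  # brute-force shortest-path enumeration
  set.seed(23)
  for (rep in 1:30) {
    n <- sample(3:6, 1)
    adj <- matrix(FALSE, n, n)
    adj[upper.tri(adj)] <- runif(n * (n - 1) / 2) < 0.5
    adj <- adj | t(adj)
    gaps <- ifelse(adj, 5, 1e9); diag(gaps) <- 0
    snap <- build_network(rep(TRUE, n), gaps, D = 10)
    expect_equal(unname(node_degree(snap)), rowSums(adj))
    expect_equal(unname(node_betweenness(snap)), betweenness_bf(adj),
                 tolerance = 1e-12)
  }
})

test_that("network length is the weighted diameter across components", {
  # single edge
  g1 <- matrix(c(0, 42, 42, 0), 2)
  expect_equal(network_length(build_network(c(TRUE, TRUE), g1, D = 50)), 42)
  # path with gaps 3 and 4: diameter 7
  gp <- matrix(c(0, 3, 1e6,
                 3, 0, 4,
                 1e6, 4, 0), 3, byrow = TRUE)
  expect_equal(network_length(build_network(rep(TRUE, 3), gp, D = 5)), 7)
  # fragmented: maximum over components, or largest component only
  gf <- matrix(1e6, 5, 5); diag(gf) <- 0
  gf[1, 2] <- gf[2, 1] <- 9                 # component {1,2}: diameter 9
  gf[3, 4] <- gf[4, 3] <- 2                 # component {3,4,5}: diameter 5
  gf[4, 5] <- gf[5, 4] <- 3
  snap <- build_network(rep(TRUE, 5), gf, D = 10)
  expect_equal(network_length(snap, fragmented = "max"), 9)
  expect_equal(network_length(snap, fragmented = "largest"), 5)

  # brute-force Floyd-Warshall on random weighted toys
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    xy <- matrix(runif(2 * n, 0, 100), ncol = 2)
    g <- as.matrix(dist(xy))
    D <- runif(1, 20, 90)
    snap <- build_network(rep(TRUE, n), g, D)
    W <- ifelse(g <= D, g, 0); diag(W) <- 0
    d_bf <- floyd_warshall(W)
    want <- if (any(is.finite(d_bf) & d_bf > 0))
      max(d_bf[is.finite(d_bf)]) else 0
    expect_equal(network_length(snap), want, tolerance = 1e-9)
  }
})

test_that("edge sets and lengths are monotone in the dispersal threshold", {
  set.seed(41)
  n <- 12
  xy <- matrix(runif(2 * n, 0, 200), ncol = 2)
  g <- as.matrix(dist(xy))
  occ <- rep(TRUE, n)
  prev_edges <- character(); prev_k <- 0
  for (D in c(20, 50, 90, 150, 400)) {
    snap <- build_network(occ, g, D)
    el <- igraph::as_edgelist(snap$graph)
    edges <- if (nrow(el)) paste(pmin(el[, 1], el[, 2]),
                                 pmax(el[, 1], el[, 2])) else character()
    expect_true(all(prev_edges %in% edges))
    k <- mean(node_degree(snap))
    expect_gte(k, prev_k)
    prev_edges <- edges; prev_k <- k
  }
})

test_that("the NLDC is a valid exceedance curve", {
  # constant series: all mass at one length
  cc <- nldc(rep(5000, 10))
  expect_equal(unique(cc$length), 5000)
  expect_equal(cc$exceedance, (1:10) / 11)

  # strictly increasing series: k-th largest has exceedance k/(n+1)
  cv <- nldc(seq(100, 1000, by = 100))
  expect_equal(cv$length, seq(1000, 100, by = -100))
  expect_equal(cv$exceedance, (1:10) / 11)

  # survival-curve validity on random series
  set.seed(51)
  r <- nldc(rexp(200, 1 / 3000))
  expect_true(all(diff(r$length) <= 0))
  expect_true(all(diff(r$exceedance) > 0))
  expect_true(all(r$exceedance > 0 & r$exceedance < 1))
  expect_error(nldc(numeric()), "at least one")
})
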