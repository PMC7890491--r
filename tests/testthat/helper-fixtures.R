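# Shared fixtures and independent oracles used across the test files.

# small homogeneous landscape, explicit attributes
toy_landscape <- function(n = 4, spacing = 300, A_max = 5000, h_max = 1.5,
                          p = 2, ca_ratio = 2) {
  xy <- expand.grid(x = spacing * (0:(ceiling(sqrt(n)) - 1)),
                    y = spacing * (0:(ceiling(sqrt(n)) - 1)))[1:n, ]
  wetlandscape(data.frame(id = paste0("t", seq_len(n)),
                          x = xy$x + 50, y = xy$y + 50,
                          A_max = A_max, h_max = h_max, p = p,
                          ca_ratio = ca_ratio),
               extent = c(spacing * ceiling(sqrt(n)) + 100,
                          spacing * ceiling(sqrt(n)) + 100))
}

# bypasses validation, to write deliberately malformed tables
wetlandscape_unchecked <- function(df, extent) {
  structure(df, extent = extent, class = c("wetlandscape", "data.frame"))
}

# hydrology held exactly constant (no fluxes), stages at h0
constant_hydro <- function(landscape, t_days, h0 = "full") {
  f <- forcing_series(rep(0, t_days), 0)
  simulate_hydrology(landscape, f, hydro_params(k_leak = 0, pet_coeff = 0),
                     h0 = h0)
}

# --- independent graph oracles (no igraph) ------------------------------

# all simple paths between a and b in adjacency matrix `adj`
all_simple_paths_bf <- function(adj, a, b) {
  n <- nrow(adj)
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == b) { out[[length(out) + 1L]] <<- path; return(invisible()) }
    for (w in which(adj[v, ])) if (!w %in% path) walk(c(path, w))
  }
  walk(a)
  out
}

# shortest-path betweenness by exhaustive path enumeration (hop counts,
# even split among equally short paths, endpoints excluded)
betweenness_bf <- function(adj) {
  n <- nrow(adj)
  beta <- numeric(n)
  if (n < 3) return(beta)
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    paths <- all_simple_paths_bf(adj, a, b)
    if (!length(paths)) next
    lens <- vapply(paths, length, 1L)
    sp <- paths[lens == min(lens)]
    for (pth in sp) {
      inner <- setdiff(pth, c(a, b))
      beta[inner] <- beta[inner] + 1 / length(sp)
    }
  }
  beta
}

# all-pairs weighted shortest paths, Floyd-Warshall
floyd_warshall <- function(W) {
  n <- nrow(W)
  d <- W
  d[d == 0] <- Inf
  d[W > 0] <- W[W > 0]
  diag(d) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# power iteration, independent route to the leading eigenvalue
power_lambda <- function(M, iters = 10000, tol = 1e-14) {
  n <- nrow(M)
  if (n == 0 || max(M) == 0) return(0)
  v <- rep(1 / sqrt(n), n)
  lam <- 0
  for (i in seq_len(iters)) {
    w <- M %*% v
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v2 <- as.vector(w / nw)
    lam2 <- as.numeric(t(v2) %*% M %*% v2)
    if (abs(lam2 - lam) < tol * max(abs(lam2), 1)) return(lam2)
    v <- v2; lam <- lam2
  }
  lam
}
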