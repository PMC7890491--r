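test_that("colonization and extinction rates evaluate the model formulas", {
  gaps <- matrix(c(0, 150, 150, 0), 2)
  tr <- species_traits(e = 2e-4, c = 1.5, D = 100)
  # no occupied neighbours
  expect_equal(colonization_rate(1, c(0, 0), c(1, 1), gaps, tr), 0)
  # one occupied neighbour at d = 1.5 D with unit suitability
  expect_equal(colonization_rate(1, c(0, 1), c(1, 1), gaps, tr),
               1.5 * exp(-1.5), tolerance = 1e-12)
  # occupied neighbour at zero gap, S = 1, c = 1
  tr1 <- species_traits(e = 0, c = 1, D = 100)
  g0 <- matrix(0, 2, 2)
  expect_equal(colonization_rate(1, c(0, 1), c(1, 1), g0, tr1), 1)
  # the focal patch never colonizes itself
  expect_equal(colonization_rate(1, c(1, 0), c(1, 1), gaps, tr1), 0)

  expect_equal(extinction_rate(1, tr), 2e-4)
  expect_equal(extinction_rate(0.5, tr), 4e-4)
  expect_identical(extinction_rate(0, tr), Inf)

  expect_equal(event_probability(0), 0)
  expect_equal(event_probability(Inf), 1)
  expect_equal(event_probability(0.1, 1), 1 - exp(-0.1), tolerance = 1e-14)
  expect_error(event_probability(-1), ">= 0")
})

test_that("landscape matrix and metapopulation capacity match closed forms", {
  expect_equal(metapopulation_capacity(matrix(0, 3, 3)), 0)
  expect_equal(metapopulation_capacity(matrix(0, 1, 1)), 0)

  # all-zero suitability gives the zero matrix
  g <- matrix(c(0, 100, 100, 0), 2)
  expect_equal(landscape_matrix(c(0, 0), g, 200), matrix(0, 2, 2))

  # two patches: off-diagonal S^2 exp(-d/D), eigenvalues +/- m12
  S <- 0.8; d <- 120; D <- 200
  M <- landscape_matrix(c(S, S), g * (d / 100), D)
  m12 <- S^2 * exp(-d / D)
  expect_equal(M[1, 2], m12, tolerance = 1e-14)
  expect_equal(metapopulation_capacity(M), m12, tolerance = 1e-12)

  # random symmetric non-negative matrices against an independent
  # power-iteration oracle
  set.seed(12)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    A <- matrix(runif(n * n), n); M <- (A + t(A)) / 2; diag(M) <- 0
    expect_equal(metapopulation_capacity(M), power_lambda(M),
                 tolerance = 1e-10)
  }
  expect_error(metapopulation_capacity(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("persistence condition implements the mean-field criterion", {
  tr <- species_traits(e = 2e-4, c = 1.5, D = 100)
  expect_equal(tr$e / tr$c, 2e-4 / 1.5)
  expect_false(persistence_condition(0, tr))
  expect_true(persistence_condition(2e-4 / 1.5 + 1e-9, tr))
  expect_false(persistence_condition(2e-4 / 1.5 - 1e-9, tr))
  expect_true(persistence_condition(0.5, species_traits(e = 0, c = 1, D = 1)))
  expect_false(persistence_condition(10, species_traits(e = 1, c = 0, D = 1)))
  expect_true(is.na(persistence_condition(1, species_traits(0, 0, 1))))
})

test_that("the occupancy chain freezes, absorbs and empties correctly", {
  n <- 5
  K <- exp(-matrix(runif(n * n, 0, 300), n) / 100); K <- (K + t(K)) / 2
  diag(K) <- 0
  S <- rep(1, n)
  P <- matrix(c(TRUE, FALSE), n, 4)

  # e = c = 0: the chain is frozen
  set.seed(1)
  expect_identical(step_occupancy(P, S, K, species_traits(0, 0, 1)), P)

  # S = 0 everywhere: everything goes extinct in one step
  set.seed(1)
  expect_false(any(step_occupancy(P, rep(0, n), K, species_traits(1, 1, 1))))

  # global extinction is absorbing
  set.seed(1)
  empty <- matrix(FALSE, n, 4)
  expect_identical(step_occupancy(empty, S, K, species_traits(1e-3, 2, 100)),
                   empty)

  # single isolated patch: extinction time is geometric with mean 1/P_E
  tr <- species_traits(e = 0.05, c = 0, D = 1)
  p_e <- event_probability(extinction_rate(1, tr))
  set.seed(42)
  n_real <- 5000
  P1 <- matrix(TRUE, 1, n_real)
  tmax <- 400
  t_ext <- rep(NA_real_, n_real)
  for (t in 1:tmax) {
    P1 <- step_occupancy(P1, 1, matrix(0, 1, 1), tr)
    t_ext[is.na(t_ext) & !P1[1, ]] <- t
  }
  expect_true(all(!is.na(t_ext)))
  se <- sqrt((1 - p_e) / p_e^2 / n_real)
  expect_lt(abs(mean(t_ext) - 1 / p_e), 3 * se)
})

test_that("ensemble runs are reproducible and statistics well-formed", {
  L <- toy_landscape(6)
  hy <- constant_hydro(L, 60)
  tr <- species_traits(e = 0.01, c = 0.5, D = 300)
  a <- run_dspom(L, hy, tr, n_realizations = 10, seed = 5,
                 record_states = TRUE)
  b <- run_dspom(L, hy, tr, n_realizations = 10, seed = 5,
                 record_states = TRUE)
  expect_identical(a$states, b$states)
  expect_identical(a$omega, b$omega)
  expect_true(all(a$omega >= 0 & a$omega <= 1))
  expect_equal(a$omega, rowMeans(a$occ_frac))
  expect_true(a$f_S >= 0 && a$f_S <= 1)
  expect_length(a$lambda, 60)
  expect_true(all(a$lambda >= 0))
})

test_that("occupancy is monotone in time for one-way chains", {
  L <- toy_landscape(6)
  hy <- constant_hydro(L, 80)
  # e = 0: occupancy can only grow, realization by realization
  grow <- run_dspom(L, hy, species_traits(e = 0, c = 0.05, D = 300),
                    n_realizations = 8, p0 = 0.3, seed = 9)
  expect_true(all(apply(grow$occ_frac, 2, function(z) all(diff(z) >= 0))))
  # c = 0: occupancy can only shrink
  shrink <- run_dspom(L, hy, species_traits(e = 0.02, c = 0, D = 300),
                      n_realizations = 8, seed = 9)
  expect_true(all(apply(shrink$occ_frac, 2, function(z) all(diff(z) <= 0))))
})

test_that("f_S responds to traits in the expected direction", {
  L <- toy_landscape(9)
  hy <- constant_hydro(L, 300)
  # common random numbers across trait values
  fs_by_e <- sapply(c(0.02, 0.2), function(e)
    run_dspom(L, hy, species_traits(e = e, c = 0.1, D = 300),
              n_realizations = 40, seed = 31)$f_S)
  expect_true(diff(fs_by_e) <= 0)
  fs_by_c <- sapply(c(0.01, 0.5), function(cc)
    run_dspom(L, hy, species_traits(e = 0.1, c = cc, D = 300),
              n_realizations = 40, seed = 31)$f_S)
  expect_true(diff(fs_by_c) >= 0)
})

test_that("static and dynamic engines coincide under constant hydrology", {
  L <- toy_landscape(5)
  hy <- constant_hydro(L, 50, h0 = 0.9)
  tr <- species_traits(e = 0.01, c = 0.8, D = 300)
  dyn <- run_dspom(L, hy, tr, n_realizations = 6, seed = 77,
                   record_states = TRUE)
  sta <- run_static_spom(L, hy, tr, n_realizations = 6, seed = 77,
                         record_states = TRUE)
  expect_identical(dyn$states, sta$states)
  expect_identical(dyn$occ_frac, sta$occ_frac)
  expect_equal(dyn$lambda, sta$lambda, tolerance = 1e-12)
  expect_true(all(abs(diff(sta$lambda)) == 0))
})

test_that("dispersal distance can be resolved from the landscape NND", {
  L <- toy_landscape(4)
  g <- gap_matrix(L, L$A_max)
  expect_equal(resolve_dispersal(L, 1.5), 1.5 * nnd(g))
  expect_error(resolve_dispersal(toy_landscape(1), 1.5), "fewer than 2")
})
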