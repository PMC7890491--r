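#' Species traits
#'
#' Fixed life-history traits of a focal species: extinction coefficient
#' \code{e} (the local extinction rate on patch i is \code{e / S_i}),
#' colonization coefficient \code{c} and dispersal distance \code{D} of the
#' exponential kernel \code{exp(-d/D)}.
#'
#' @param e extinction coefficient (d^-1 per unit suitability), >= 0.
#' @param c colonization coefficient (d^-1 per unit suitability), >= 0.
#' @param D dispersal distance (m), > 0.
#' @return Object of class \code{"species_traits"}.
#' @export
species_traits <- function(e = 2e-4, c = 1.5, D = 500) {
  if (e < 0) stop("species_traits: extinction coefficient e must be >= 0")
  if (c < 0) stop("species_traits: colonization coefficient c must be >= 0")
  if (!(D > 0)) stop("species_traits: dispersal distance D must be > 0")
  structure(list(e = e, c = c, D = D), class = "species_traits")
}

#' Colonization rate of one patch
#'
#' \code{C_i = c * sum_{j != i} exp(-d_ij / D) S_j p_j}: occupied neighbours
#' contribute suitability-weighted propagules discounted by the exponential
#' dispersal kernel. Zero when no neighbour is occupied.
#'
#' @param i focal patch index.
#' @param p occupancy vector (0/1 or logical).
#' @param S suitabilities (>= 0).
#' @param gaps gap-distance matrix (m).
#' @param traits a [species_traits()].
#' @return Colonization rate (d^-1).
#' @export
colonization_rate <- function(i, p, S, gaps, traits) {
  w <- exp(-gaps[i, ] / traits$D) * S * as.numeric(p)
  w[i] <- 0
  traits$c * sum(w)
}

#' Extinction rate of one patch
#'
#' \code{E_i = e / S_i}: extinction is inversely proportional to the
#' suitability. \code{S_i = 0} is a defined limit, not an error: the rate is
#' infinite and the patch goes extinct with probability 1 at the next step.
#'
#' @param S_i suitability (>= 0); vectorized.
#' @param traits a [species_traits()].
#' @return Extinction rate (d^-1), possibly \code{Inf}.
#' @export
extinction_rate <- function(S_i, traits) {
  ifelse(S_i > 0, traits$e / S_i, Inf)
}

#' Probability of at least one event in a time step
#'
#' Exponential survival: \code{1 - exp(-rate * dt)}, in \code{[0, 1]};
#' infinite rates give probability 1.
#'
#' @param rate event rate (d^-1), >= 0 or \code{Inf}; vectorized.
#' @param dt time step (d), > 0.
#' @return Probability in \code{[0, 1]}.
#' @export
event_probability <- function(rate, dt = 1) {
  if (any(rate < 0, na.rm = TRUE)) stop("rate must be >= 0")
  ifelse(is.infinite(rate), 1, -expm1(-rate * dt))
}

#' Landscape matrix
#'
#' \code{m_ij = exp(-d_ij / D) S_i S_j} for \code{i != j}, zero diagonal:
#' symmetric and non-negative. Its leading eigenvalue is the metapopulation
#' capacity.
#'
#' @param S suitabilities.
#' @param gaps gap-distance matrix (m).
#' @param D dispersal distance (m).
#' @return n x n symmetric non-negative matrix.
#' @export
landscape_matrix <- function(S, gaps, D) {
  M <- exp(-gaps / D) * outer(S, S)
  diag(M) <- 0
  M
}

#' Metapopulation capacity
#'
#' The leading eigenvalue of the landscape matrix; it summarizes the amount
#' of habitat and its spatial configuration, and enters the deterministic
#' persistence condition \code{lambda_max > e/c}.
#'
#' @param M symmetric non-negative matrix from [landscape_matrix()].
#' @param tol symmetry tolerance (absolute, relative to \code{max(|M|)}).
#' @return \code{lambda_max} (>= 0 for a non-negative symmetric matrix with
#'   zero diagonal).
#' @export
metapopulation_capacity <- function(M, tol = 1e-8) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("M must be square")
  scale <- max(abs(M), 1e-300)
  if (max(abs(M - t(M))) > tol * scale)
    stop("M must be symmetric")
  if (nrow(M) == 0L) return(0)
  max(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
}

#' Deterministic persistence condition
#'
#' Mean-field criterion \code{lambda_max > e/c}: the global-extinction
#' equilibrium is unstable iff the leading eigenvalue of the Jacobian
#' \code{c M - e I} is positive. Stochastic realizations near the threshold
#' can still go extinct through demographic stochasticity.
#'
#' @param lambda_max metapopulation capacity.
#' @param traits a [species_traits()].
#' @return \code{TRUE}/\code{FALSE}, or \code{NA} when \code{c = e = 0}
#'   (indeterminate).
#' @export
persistence_condition <- function(lambda_max, traits) {
  if (traits$c == 0) {
    if (traits$e == 0) return(NA)
    return(FALSE)
  }
  lambda_max > traits$e / traits$c
}

#' One synchronous update of the occupancy chain
#'
#' Advances every realization one step of the discrete-time Markov chain:
#' each unoccupied patch is colonized with probability
#' \code{1 - exp(-C_i dt)} and each occupied patch goes extinct with
#' probability \code{1 - exp(-E_i dt)}, all rates evaluated from the state
#' at time t (synchronous update). Patches with zero suitability can never
#' be colonized and, if occupied, go extinct with probability 1.
#'
#' Consumes \code{n * n_real} uniforms from R's RNG stream in patch-major
#' order.
#'
#' @param P n x n_real logical occupancy matrix (patches x realizations).
#' @param S suitability vector.
#' @param K dispersal kernel matrix \code{exp(-d/D)} with zero diagonal.
#' @param traits a [species_traits()].
#' @param dt time step (d).
#' @return Updated occupancy matrix.
#' @export
step_occupancy <- function(P, S, K, traits, dt = 1) {
  P <- as.matrix(P)
  n <- nrow(P); n_real <- ncol(P)
  crate <- traits$c * (K %*% (S * P))        # n x n_real colonization rates
  p_col <- -expm1(-crate * dt)
  p_col[S == 0, ] <- 0                       # unsuitable patches stay empty
  p_ext <- event_probability(extinction_rate(S, traits), dt)
  U <- matrix(stats::runif(n * n_real), n, n_real)
  (P & (U >= p_ext)) | (!P & (U < p_col))
}

# Shared chain engine for the static and dynamic models. Suitability and
# kernel providers are functions of the day index; the static model passes
# constants, so both engines consume the RNG identically and degenerate to
# the same trajectories under time-constant hydrology.
run_chain <- function(n, T_days, S_fun, K_fun, traits, dt, n_real,
                      p0, seed, record_capacity, record_states, D) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  S1 <- S_fun(1L)
  P <- init_occupancy(S1, n, n_real, p0)
  occ_frac <- matrix(0, T_days, n_real)
  lambda <- if (record_capacity) numeric(T_days) else NULL
  states <- if (record_states) array(FALSE, c(T_days, n, n_real)) else NULL
  for (t in seq_len(T_days)) {
    S <- S_fun(t)
    K <- K_fun(t)
    if (record_capacity)
      lambda[t] <- metapopulation_capacity(K * outer(S, S))
    P <- step_occupancy(P, S, K, traits, dt)
    occ_frac[t, ] <- colMeans(P)
    if (record_states) states[t, , ] <- P
  }
  list(occ_frac = occ_frac, lambda = lambda, states = states, final = P)
}

init_occupancy <- function(S, n, n_real, p0) {
  if (is.character(p0) && p0 == "all") {
    matrix(rep(S > 0, n_real), n, n_real)
  } else if (is.numeric(p0) && length(p0) == 1L && p0 > 0 && p0 <= 1) {
    matrix(stats::runif(n * n_real) < p0, n, n_real) & (S > 0)
  } else {
    stop("p0 must be \"all\" or a fraction in (0, 1]")
  }
}

finish_ensemble <- function(res, traits, dt, n_real, suitability, s_ref) {
  omega <- rowMeans(res$occ_frac)
  sigma_omega <- apply(res$occ_frac, 1, stats::sd)
  structure(list(occ_frac = res$occ_frac, omega = omega,
                 sigma_omega = sigma_omega,
                 f_S = mean(colSums(res$final) > 0),
                 lambda = res$lambda, states = res$states,
                 final = res$final, traits = traits, dt = dt,
                 n_realizations = n_real, suitability = suitability,
                 s_ref = s_ref),
            class = "spom_run")
}

#' @export
print.spom_run <- function(x, ...) {
  cat(sprintf("spom_run: %d days x %d realizations (suitability: %s)\n",
              nrow(x$occ_frac), x$n_realizations, x$suitability))
  cat(sprintf("  mean omega %.3f, f_S = %.2f", mean(x$omega), x$f_S))
  if (!is.null(x$lambda) && length(x$lambda) > 1)
    cat(sprintf(", lambda_max in [%.3g, %.3g]",
                min(x$lambda), max(x$lambda)))
  cat("\n")
  invisible(x)
}

suitability_matrix <- function(hydro, suitability) {
  switch(suitability,
         area = hydro$A,
         shallow = hydro$A_shallow,
         intermediate = hydro$A_int,
         deep = hydro$A_deep,
         stop("unknown suitability rule: ", suitability))
}

#' Run the dynamic stochastic patch occupancy model
#'
#' Couples a precomputed hydrologic simulation to the occupancy chain: each
#' day the patch suitabilities \code{S_i(t)} (wetted or depth-zone area,
#' normalized by \code{s_ref}) and perimeter-to-perimeter gap distances
#' \code{d_ij(t)} are refreshed, the metapopulation capacity
#' \code{lambda_max(t)} is recorded (it is deterministic given the
#' hydrology), and every Monte-Carlo realization advances one step.
#'
#' @param landscape a [wetlandscape()].
#' @param hydro a \code{hydro_series} from [simulate_hydrology()].
#' @param traits a [species_traits()].
#' @param n_realizations Monte-Carlo ensemble size (100 is a typical
#'   choice for occupancy statistics).
#' @param dt time step (d).
#' @param p0 initial occupancy rule: \code{"all"} (every suitable patch
#'   occupied) or a Bernoulli fraction in (0, 1].
#' @param suitability which area series defines \code{S_i(t)}:
#'   \code{"area"} (total wetted area), \code{"shallow"},
#'   \code{"intermediate"} or \code{"deep"} depth-zone area.
#' @param s_ref normalization reference (m^2) making suitability
#'   dimensionless; default \code{mean(A_max)} over the landscape.
#' @param seed integer seed; the full ensemble is reproducible.
#' @param record_capacity record \code{lambda_max(t)} daily.
#' @param record_states keep the full binary occupancy array
#'   (days x patches x realizations); memory-hungry, off by default.
#' @return Object of class \code{"spom_run"} with elements \code{occ_frac}
#'   (days x realizations occupied fractions), \code{omega} (ensemble mean
#'   occupancy per day), \code{sigma_omega} (between-realization sd),
#'   \code{f_S} (fraction of realizations with at least one occupied patch
#'   on the final day), \code{lambda} (capacity series) and \code{final}
#'   (final occupancy matrix).
#' @export
run_dspom <- function(landscape, hydro, traits, n_realizations = 100,
                      dt = 1, p0 = "all", suitability = "area",
                      s_ref = NULL, seed = NULL,
                      record_capacity = TRUE, record_states = FALSE) {
  stopifnot(inherits(landscape, "wetlandscape"),
            inherits(hydro, "hydro_series"), n_realizations >= 1)
  n <- nrow(landscape)
  T_days <- nrow(hydro$A)
  if (is.null(s_ref)) s_ref <- mean(landscape$A_max)
  S_mat <- suitability_matrix(hydro, suitability) / s_ref
  cd <- as.matrix(stats::dist(cbind(landscape$x, landscape$y)))
  K_fun <- function(t) {
    g <- gap_matrix(landscape, hydro$A[t, ], centre_dist = cd)
    K <- exp(-g / traits$D); diag(K) <- 0
    K
  }
  res <- run_chain(n, T_days, function(t) S_mat[t, ], K_fun, traits, dt,
                   n_realizations, p0, seed, record_capacity,
                   record_states, traits$D)
  finish_ensemble(res, traits, dt, n_realizations, suitability, s_ref)
}

#' Run the static stochastic patch occupancy model
#'
#' The classical static counterpart: wetted areas are frozen at their
#' per-wetland time means over the hydrologic simulation, giving constant
#' suitabilities, gap distances and a single metapopulation capacity; the
#' chain mechanics are otherwise identical to [run_dspom()] (the two consume
#' random numbers identically, so under time-constant hydrology they produce
#' the same seeded trajectories).
#'
#' @inheritParams run_dspom
#' @return A \code{"spom_run"}; \code{lambda} is the constant capacity
#'   (also replicated to a daily series for comparability).
#' @export
run_static_spom <- function(landscape, hydro, traits, n_realizations = 100,
                            dt = 1, p0 = "all", suitability = "area",
                            s_ref = NULL, seed = NULL,
                            record_states = FALSE) {
  stopifnot(inherits(landscape, "wetlandscape"),
            inherits(hydro, "hydro_series"), n_realizations >= 1)
  n <- nrow(landscape)
  T_days <- nrow(hydro$A)
  if (is.null(s_ref)) s_ref <- mean(landscape$A_max)
  S_bar <- colMeans(suitability_matrix(hydro, suitability)) / s_ref
  A_bar <- colMeans(hydro$A)
  cd <- as.matrix(stats::dist(cbind(landscape$x, landscape$y)))
  g <- gap_matrix(landscape, A_bar, centre_dist = cd)
  K <- exp(-g / traits$D); diag(K) <- 0
  lambda0 <- metapopulation_capacity(K * outer(S_bar, S_bar))
  res <- run_chain(n, T_days, function(t) S_bar, function(t) K, traits, dt,
                   n_realizations, p0, seed, FALSE, record_states, traits$D)
  res$lambda <- rep(lambda0, T_days)
  out <- finish_ensemble(res, traits, dt, n_realizations, suitability, s_ref)
  out$lambda_static <- lambda0
  out
}

#' Resolve a dispersal distance given relative to the landscape NND
#'
#' The dispersal distance may be stated as a multiple of the mean
#' nearest-neighbour gap distance (\code{D/NND}); the NND is evaluated with
#' every wetland at its maximum area. Returns the absolute distance in
#' metres.
#'
#' @param landscape a [wetlandscape()].
#' @param D_over_NND ratio (e.g. 1.5).
#' @return Absolute dispersal distance (m).
#' @export
resolve_dispersal <- function(landscape, D_over_NND) {
  g <- gap_matrix(landscape, landscape$A_max)
  base <- nnd(g)
  if (is.na(base)) stop("NND undefined: landscape has fewer than 2 wetlands")
  if (base == 0) stop("NND is zero at maximum areas; supply D in metres")
  D_over_NND * base
}
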