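#' Hydrologic parameters
#'
#' Flux coefficients of the per-wetland daily water balance: the net of
#' precipitation falling over the wetland and its contributing area, minus
#' evapotranspiration over the wetted area, minus a linear groundwater
#' leakage proportional to the wetted area.
#'
#' @param k_leak groundwater exchange rate (cm d^-1; positive = loss to
#'   shallow groundwater).
#' @param pet_coeff multiplier applied to PET over the wetted area
#'   (dimensionless, >= 0).
#' @return Object of class \code{"hydro_params"}.
#' @export
hydro_params <- function(k_leak = 0.1, pet_coeff = 1) {
  if (pet_coeff < 0) stop("pet_coeff must be >= 0")
  structure(list(k_leak = k_leak, pet_coeff = pet_coeff),
            class = "hydro_params")
}

#' Power-law stage--area--volume bathymetry
#'
#' Wetted area as a function of stage follows
#' \code{A(h) = A_max * min(1, h/h_max)^(2/p)}; the stored volume is its
#' integral \code{V(h) = A_max * h_max * (h/h_max)^(2/p + 1) / (2/p + 1)}
#' for \code{h <= h_max}, with \code{dV/dh = A(h)}. \code{p = 2} gives a
#' cone-like basin (area linear in stage).
#'
#' Arguments are vectorized over wetlands and stages.
#'
#' @param A_max,h_max,p bathymetry parameters (or a \code{wetlandscape} row).
#' @param h stage (m), >= 0.
#' @return Area in m^2 (\code{stage_to_area}), volume in m^3
#'   (\code{stage_to_volume}), or stage in m (\code{volume_to_stage}).
#' @export
stage_to_area <- function(h, A_max, h_max, p) {
  if (any(h < 0)) stop("stage h must be >= 0")
  A_max * pmin(1, h / h_max)^(2 / p)
}

#' @rdname stage_to_area
#' @param V stored volume (m^3).
#' @export
stage_to_volume <- function(h, A_max, h_max, p) {
  if (any(h < 0)) stop("stage h must be >= 0")
  if (any(h > h_max + 1e-12)) stop("stage h must be <= h_max")
  ex <- 2 / p + 1
  A_max * h_max * pmin(1, h / h_max)^ex / ex
}

#' @rdname stage_to_area
#' @export
volume_to_stage <- function(V, A_max, h_max, p) {
  ex <- 2 / p + 1
  V_full <- A_max * h_max / ex
  h_max * pmin(1, pmax(0, V / V_full))^(1 / ex)
}

#' Concentric depth-zone areas
#'
#' Splits the wetted area at stage \code{h} into three concentric annular
#' micro-habitats by local water depth: shallow (< 30 cm), intermediate
#' (30--80 cm) and deep (> 80 cm). The area with local depth exceeding
#' \code{d} equals \code{A(h - d)} for \code{d < h}, so the three zone areas
#' telescope exactly to the total wetted area. At \code{h = 0.8} m the deep
#' zone has zero area (deep means strictly greater than 80 cm).
#'
#' @inheritParams stage_to_area
#' @param shallow_depth,deep_depth zone boundaries (m).
#' @return A list with numeric components \code{shallow}, \code{intermediate},
#'   \code{deep} (m^2), summing to \code{stage_to_area(h, ...)}.
#' @export
zone_areas <- function(h, A_max, h_max, p,
                       shallow_depth = 0.3, deep_depth = 0.8) {
  A_tot <- stage_to_area(h, A_max, h_max, p)
  A_ge_shallow <- ifelse(h > shallow_depth,
                         stage_to_area(pmax(h - shallow_depth, 0), A_max, h_max, p), 0)
  A_deep <- ifelse(h > deep_depth,
                   stage_to_area(pmax(h - deep_depth, 0), A_max, h_max, p), 0)
  list(shallow = A_tot - A_ge_shallow,
       intermediate = A_ge_shallow - A_deep,
       deep = A_deep)
}

#' One daily water-balance step
#'
#' Updates the stored volume to
#' \code{V(h) + P*(A(h) + ca_ratio*A_max) - pet_coeff*PET*A(h) - k_leak*A(h)}
#' with rainfall/PET/leakage depths converted cm to m. When losses exceed
#' storage the wetland dries (volume floored at 0, actual losses reduced
#' accordingly); when the updated volume exceeds capacity the excess spills and
#' the stage is capped at \code{h_max}. Spilled water leaves the system
#' (wetlands are hydrologically independent).
#'
#' Vectorized over wetlands.
#'
#' @param h current stage (m).
#' @param rain_cm,pet_cm daily depths (cm).
#' @param A_max,h_max,p,ca_ratio wetland parameters.
#' @param params a [hydro_params()].
#' @return List with \code{h} (next stage, m), \code{spill} (m^3),
#'   \code{inflow}, \code{et}, \code{leak} (actual fluxes, m^3), so that
#'   \code{V(h_next) - V(h) = inflow - et - leak - spill} exactly.
#' @export
step_water_balance <- function(h, rain_cm, pet_cm, A_max, h_max, p, ca_ratio,
                               params = hydro_params()) {
  A <- stage_to_area(h, A_max, h_max, p)
  V <- stage_to_volume(h, A_max, h_max, p)
  inflow <- rain_cm / 100 * (A + ca_ratio * A_max)
  et_pot <- params$pet_coeff * pet_cm / 100 * A
  leak_pot <- params$k_leak / 100 * A
  avail <- V + inflow
  loss_pot <- et_pot + leak_pot
  # proportional curtailment when potential losses would empty the wetland
  scale <- ifelse(loss_pot > avail & loss_pot > 0, avail / loss_pot, 1)
  et <- et_pot * scale
  leak <- leak_pot * scale
  V_new <- avail - et - leak
  ex <- 2 / p + 1
  V_full <- A_max * h_max / ex
  spill <- pmax(0, V_new - V_full)
  V_new <- pmin(V_new, V_full)
  list(h = volume_to_stage(V_new, A_max, h_max, p),
       spill = spill, inflow = inflow, et = et, leak = leak)
}

#' Simulate the wetlandscape water balance
#'
#' Applies [step_water_balance()] daily and independently to every wetland,
#' recording stage, wetted area, equivalent radius and the three depth-zone
#' areas, plus a cumulative flux ledger for mass-balance checks.
#'
#' @param landscape a [wetlandscape()].
#' @param forcing a [forcing_series()].
#' @param params a [hydro_params()].
#' @param h0 initial stage rule: \code{"full"} (all wetlands at
#'   \code{h_max}, the default), \code{"half"} (half of \code{h_max}), a
#'   single number (m, capped at each wetland's \code{h_max}) or a numeric
#'   vector of per-wetland stages.
#' @return Object of class \code{"hydro_series"}: list with T x n matrices
#'   \code{h}, \code{A}, \code{r}, \code{A_shallow}, \code{A_int},
#'   \code{A_deep} (state at the end of each day), the initial stage
#'   \code{h0}, per-wetland cumulative fluxes \code{inflow}, \code{et},
#'   \code{leak}, \code{spill} (m^3) and the landscape.
#' @export
simulate_hydrology <- function(landscape, forcing, params = hydro_params(),
                               h0 = "full") {
  stopifnot(inherits(landscape, "wetlandscape"))
  n <- nrow(landscape)
  T_days <- nrow(forcing)
  A_max <- landscape$A_max; h_max <- landscape$h_max
  p <- landscape$p; ca <- landscape$ca_ratio
  h <- if (is.character(h0)) {
    switch(match.arg(h0, c("full", "half")),
           full = h_max, half = h_max / 2)
  } else if (length(h0) == 1L) {
    pmin(as.numeric(h0), h_max)
  } else {
    stopifnot(length(h0) == n)
    as.numeric(h0)
  }
  h_init <- h
  H <- matrix(0, T_days, n); A <- matrix(0, T_days, n)
  Ash <- matrix(0, T_days, n); Ain <- matrix(0, T_days, n)
  Adp <- matrix(0, T_days, n)
  tot <- list(inflow = numeric(n), et = numeric(n),
              leak = numeric(n), spill = numeric(n))
  for (t in seq_len(T_days)) {
    st <- step_water_balance(h, forcing$rain[t], forcing$pet[t],
                             A_max, h_max, p, ca, params)
    h <- st$h
    tot$inflow <- tot$inflow + st$inflow
    tot$et <- tot$et + st$et
    tot$leak <- tot$leak + st$leak
    tot$spill <- tot$spill + st$spill
    H[t, ] <- h
    A[t, ] <- stage_to_area(h, A_max, h_max, p)
    z <- zone_areas(h, A_max, h_max, p)
    Ash[t, ] <- z$shallow; Ain[t, ] <- z$intermediate; Adp[t, ] <- z$deep
  }
  structure(list(h = H, A = A, r = sqrt(A / pi),
                 A_shallow = Ash, A_int = Ain, A_deep = Adp,
                 h0 = h_init, inflow = tot$inflow, et = tot$et,
                 leak = tot$leak, spill = tot$spill,
                 landscape = landscape),
            class = "hydro_series")
}

#' @export
print.hydro_series <- function(x, ...) {
  cat(sprintf("hydro_series: %d days x %d wetlands\n",
              nrow(x$h), ncol(x$h)))
  cat(sprintf("  mean A*(t) = %.3f\n",
              mean(rowSums(x$A) / sum(x$landscape$A_max))))
  invisible(x)
}

#' Mass-balance closure of a hydrologic simulation
#'
#' Checks that the change in total stored volume equals accumulated
#' inflow minus evapotranspiration, leakage and spill.
#'
#' @param hydro a \code{hydro_series}.
#' @return Relative closure error (dimensionless).
#' @export
mass_balance_error <- function(hydro) {
  L <- hydro$landscape
  V0 <- sum(stage_to_volume(hydro$h0, L$A_max, L$h_max, L$p))
  VT <- sum(stage_to_volume(hydro$h[nrow(hydro$h), ], L$A_max, L$h_max, L$p))
  net <- sum(hydro$inflow) - sum(hydro$et) - sum(hydro$leak) - sum(hydro$spill)
  denom <- max(sum(hydro$inflow), V0, 1)
  abs((VT - V0) - net) / denom
}

#' Write a hydrologic state series as a long-format table
#'
#' Columns \code{day}, \code{wetland_id}, \code{h}, \code{A},
#' \code{A_shallow}, \code{A_int}, \code{A_deep}; tab-delimited.
#'
#' @param hydro a \code{hydro_series}.
#' @param path file path.
#' @export
write_hydro_series <- function(hydro, path) {
  n <- ncol(hydro$h); T_days <- nrow(hydro$h)
  df <- data.frame(
    day = rep(seq_len(T_days), each = n),
    wetland_id = rep(hydro$landscape$id, T_days),
    h = as.vector(t(hydro$h)),
    A = as.vector(t(hydro$A)),
    A_shallow = as.vector(t(hydro$A_shallow)),
    A_int = as.vector(t(hydro$A_int)),
    A_deep = as.vector(t(hydro$A_deep)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
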