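#' Perimeter-to-perimeter gap distance between two circular patches
#'
#' \code{max(0, ||x_i - x_j|| - r_i - r_j)} with equivalent radii
#' \code{r = sqrt(A/pi)}. Shrinking either area never decreases the gap;
#' patches with zero area reduce to points.
#'
#' @param x1,y1,x2,y2 centre coordinates (m).
#' @param A1,A2 wetted areas (m^2), >= 0.
#' @return Gap distance (m).
#' @export
gap_distance <- function(x1, y1, x2, y2, A1, A2) {
  if (any(A1 < 0) || any(A2 < 0)) stop("areas must be >= 0")
  pmax(0, sqrt((x1 - x2)^2 + (y1 - y2)^2) - sqrt(A1 / pi) - sqrt(A2 / pi))
}

#' Pairwise gap-distance matrix
#'
#' Symmetric matrix of perimeter-to-perimeter distances for one day's wetted
#' areas. Dry patches (A = 0) keep their centre coordinates and enter with
#' radius 0; they are removed from the occupancy dynamics by zero
#' suitability, not from the distance matrix, so the matrix shape is
#' time-constant.
#'
#' @param landscape a [wetlandscape()].
#' @param areas wetted areas (m^2) for each wetland; defaults to
#'   \code{A_max}.
#' @param centre_dist optional precomputed centre-to-centre distance matrix.
#' @return n x n symmetric matrix (m) with zero diagonal.
#' @export
gap_matrix <- function(landscape, areas = landscape$A_max,
                       centre_dist = NULL) {
  if (is.null(centre_dist))
    centre_dist <- as.matrix(stats::dist(cbind(landscape$x, landscape$y)))
  r <- sqrt(pmax(areas, 0) / pi)
  g <- centre_dist - outer(r, r, "+")
  g[g < 0] <- 0
  diag(g) <- 0
  dimnames(g) <- NULL
  g
}

#' Mean nearest-neighbour gap distance
#'
#' Mean over patches of the minimum gap distance to any other patch. By
#' default only currently wet patches (area > 0) are considered, both as
#' focal patches and as neighbours; with fewer than two such patches the
#' statistic is undefined and \code{NA} is returned.
#'
#' @param gaps gap matrix from [gap_matrix()].
#' @param wet logical vector marking wet patches (default all).
#' @return NND in metres, or \code{NA_real_}.
#' @export
nnd <- function(gaps, wet = rep(TRUE, nrow(gaps))) {
  idx <- which(wet)
  if (length(idx) < 2) return(NA_real_)
  g <- gaps[idx, idx, drop = FALSE]
  diag(g) <- Inf
  mean(apply(g, 1, min))
}

#' Normalized total wetted area A*
#'
#' Ratio of the day's total wetted area to the landscape's total maximum
#' area; 1 when every wetland is full, 0 when all are dry.
#'
#' @param areas wetted areas (m^2).
#' @param A_T_max total maximum area \code{sum(A_max)} (m^2).
#' @return Dimensionless value in \code{[0, 1]}.
#' @export
a_star <- function(areas, A_T_max) {
  sum(areas) / A_T_max
}

#' Ratio of spatial coefficients of variation of area and gap distance
#'
#' \code{r_CV = CV(areas) / CV(gaps)} where both CVs (sd/mean) are taken
#' across the landscape cross-section at one time: areas over wet patches,
#' gaps over the distinct wet-patch pairs. Values above 1 mean area
#' heterogeneity contributes more than spacing heterogeneity to landscape
#' suitability. Undefined (\code{NA}) with fewer than two wet patches.
#'
#' @param areas wetted areas (m^2).
#' @param gaps gap matrix (m).
#' @param wet logical wet-patch mask (default area > 0).
#' @return Dimensionless ratio, or \code{NA_real_}.
#' @export
r_cv <- function(areas, gaps, wet = areas > 0) {
  idx <- which(wet)
  if (length(idx) < 2) return(NA_real_)
  a <- areas[idx]
  g <- gaps[idx, idx][upper.tri(gaps[idx, idx])]
  cv_a <- stats::sd(a) / mean(a)
  cv_g <- stats::sd(g) / mean(g)
  if (cv_a == 0) return(0)
  if (!is.finite(cv_g) || cv_g == 0) return(NA_real_)
  cv_a / cv_g
}

#' Daily landscape-level statistics
#'
#' Per-day normalized total area A*, mean nearest-neighbour gap distance and
#' the area/gap CV ratio, computed from a hydrologic simulation. Days on
#' which a statistic is undefined (fewer than two wet patches) carry
#' \code{NA}, never a silent zero.
#'
#' @param hydro a \code{hydro_series}.
#' @param wet_only if \code{TRUE} (default) NND and r_CV use only wet
#'   patches; if \code{FALSE} all patches enter with their current (possibly
#'   zero) radius.
#' @return Data frame with columns \code{day}, \code{A_star}, \code{NND},
#'   \code{r_CV}.
#' @export
landscape_stats <- function(hydro, wet_only = TRUE) {
  L <- hydro$landscape
  A_T_max <- sum(L$A_max)
  cd <- as.matrix(stats::dist(cbind(L$x, L$y)))
  T_days <- nrow(hydro$A)
  out <- data.frame(day = seq_len(T_days), A_star = NA_real_,
                    NND = NA_real_, r_CV = NA_real_)
  for (t in seq_len(T_days)) {
    areas <- hydro$A[t, ]
    g <- gap_matrix(L, areas, centre_dist = cd)
    wet <- if (wet_only) areas > 0 else rep(TRUE, length(areas))
    out$A_star[t] <- a_star(areas, A_T_max)
    out$NND[t] <- nnd(g, wet)
    out$r_CV[t] <- r_cv(areas, g, wet)
  }
  out
}
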