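#' Construct a wetlandscape
#'
#' A wetlandscape is an ordered collection of depressional wetlands, each
#' represented as an equivalent circle (radius \code{sqrt(A/pi)}) with a
#' power-law stage--area bathymetry. All downstream quantities of the
#' occupancy model (wetted areas, perimeter-to-perimeter gap distances) are
#' computed from this circular approximation.
#'
#' @param wetlands data frame with columns \code{id} (unique identifier),
#'   \code{x}, \code{y} (planar position, m), \code{A_max} (maximum wetted
#'   area, m^2), \code{h_max} (stage at which \code{A_max} is reached, m),
#'   \code{p} (bathymetry shape exponent, dimensionless) and \code{ca_ratio}
#'   (ratio of contributing area to \code{A_max}, dimensionless).
#' @param extent numeric length-2, domain width and height in metres. All
#'   wetland centres must lie inside \code{[0, extent[1]] x [0, extent[2]]}.
#'
#' @return An object of class \code{"wetlandscape"}: the validated data frame
#'   with an \code{extent} attribute.
#' @export
wetlandscape <- function(wetlands, extent) {
  wetlands <- as.data.frame(wetlands)
  validate_wetlands(wetlands)
  extent <- as.numeric(extent)
  if (length(extent) != 2L || any(!is.finite(extent)) || any(extent <= 0))
    stop("'extent' must be two positive numbers (width, height) in metres")
  if (nrow(wetlands) > 0) {
    inside <- wetlands$x >= 0 & wetlands$x <= extent[1] &
      wetlands$y >= 0 & wetlands$y <= extent[2]
    if (!all(inside))
      stop("wetland centre(s) outside the domain: id ",
           paste(wetlands$id[!inside], collapse = ", "))
  }
  structure(wetlands, extent = extent, class = c("wetlandscape", "data.frame"))
}

validate_wetlands <- function(w, rows = NULL) {
  needed <- c("id", "x", "y", "A_max", "h_max", "p", "ca_ratio")
  missing_cols <- setdiff(needed, names(w))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(w) == 0) return(invisible(w))
  if (is.null(rows)) rows <- seq_len(nrow(w))
  bad <- function(cond, what) {
    if (any(cond))
      stop(what, " (row ", rows[which(cond)[1]], ", id ",
           w$id[which(cond)[1]], ")")
  }
  bad(duplicated(w$id), "duplicate wetland id")
  for (col in c("x", "y", "A_max", "h_max", "p", "ca_ratio"))
    bad(!is.finite(as.numeric(w[[col]])), paste0("non-finite ", col))
  bad(w$A_max <= 0, "A_max must be > 0")
  bad(w$h_max <= 0, "h_max must be > 0")
  bad(w$p <= 0, "bathymetry exponent p must be > 0")
  bad(w$ca_ratio < 0, "ca_ratio must be >= 0")
  invisible(w)
}

#' @export
print.wetlandscape <- function(x, ...) {
  ext <- attr(x, "extent")
  cat(sprintf("wetlandscape: %d wetlands over %.0f x %.0f m (%.1f km^-2)\n",
              nrow(x), ext[1], ext[2],
              nrow(x) / (prod(ext) / 1e6)))
  cat(sprintf("  total A_max %.3f km^2, mean A_max %.0f m^2\n",
              sum(x$A_max) / 1e6, mean(x$A_max)))
  invisible(x)
}

#' Generate a synthetic wetlandscape
#'
#' Places wetland centres uniformly at random inside a rectangular domain,
#' subject to a minimum centre-to-centre separation enforced by rejection
#' sampling, and draws per-wetland maximum areas, maximum stages and
#' bathymetry shape exponents from configurable laws. Two archetypes can be
#' produced through [archetype_params()]: a dense, heterogeneous prairie
#' pothole-like landscape (about 30 wetlands per km^2) and a sparse,
#' homogeneous playa-like landscape (about 1 wetland per km^2).
#'
#' @param n_patches number of wetlands (>= 0).
#' @param extent numeric length-2 domain size (m).
#' @param area_law law for \code{A_max}: either
#'   \code{list(type = "lognormal", meanlog =, sdlog =)} or
#'   \code{list(type = "fixed", value =)}. Areas in m^2.
#' @param h_max_law law for the maximum stage (m), same format.
#' @param bathymetry_law law for the shape exponent \code{p}:
#'   \code{list(type = "uniform", min =, max =)} or
#'   \code{list(type = "fixed", value =)}.
#' @param ca_ratio contributing-area-to-A_max ratio (same for all wetlands).
#' @param min_centre_separation minimum distance between any two centres (m).
#' @param seed integer seed; identical seeds give identical landscapes.
#' @param max_tries rejection-sampling attempts per wetland before failing.
#'
#' @return A [wetlandscape()].
#' @export
generate_wetlandscape <- function(n_patches,
                                  extent = c(10000, 10000),
                                  area_law = list(type = "lognormal",
                                                  meanlog = log(12500),
                                                  sdlog = 1),
                                  h_max_law = list(type = "lognormal",
                                                   meanlog = log(1.2),
                                                   sdlog = 0.3),
                                  bathymetry_law = list(type = "uniform",
                                                        min = 1, max = 3),
                                  ca_ratio = 3,
                                  min_centre_separation = 0,
                                  seed = NULL,
                                  max_tries = 200L) {
  if (n_patches < 0) stop("n_patches must be >= 0")
  extent <- as.numeric(extent)
  if (any(extent <= 0)) stop("extent must be positive")
  if (n_patches * pi * (min_centre_separation / 2)^2 >= prod(extent))
    stop("infeasible packing: n_patches * pi * (min_centre_separation/2)^2 ",
         "exceeds the domain area")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- as.integer(n_patches)
  if (n == 0L) {
    return(wetlandscape(data.frame(id = character(), x = numeric(),
                                   y = numeric(), A_max = numeric(),
                                   h_max = numeric(), p = numeric(),
                                   ca_ratio = numeric()), extent))
  }
  x <- numeric(n); y <- numeric(n)
  placed <- 0L
  while (placed < n) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cx <- stats::runif(1, 0, extent[1])
      cy <- stats::runif(1, 0, extent[2])
      if (placed == 0L ||
          min((x[1:placed] - cx)^2 + (y[1:placed] - cy)^2) >=
            min_centre_separation^2) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not satisfy min_centre_separation = ",
           min_centre_separation, " m after ", max_tries,
           " attempts (placed ", placed, " of ", n, " wetlands)")
    placed <- placed + 1L
    x[placed] <- cx; y[placed] <- cy
  }
  draw <- function(law, n) {
    switch(law$type,
           lognormal = stats::rlnorm(n, law$meanlog, law$sdlog),
           fixed = rep(law$value, n),
           uniform = stats::runif(n, law$min, law$max),
           stop("unknown law type: ", law$type))
  }
  wetlandscape(data.frame(
    id = sprintf("w%04d", seq_len(n)),
    x = x, y = y,
    A_max = draw(area_law, n),
    h_max = draw(h_max_law, n),
    p = draw(bathymetry_law, n),
    ca_ratio = rep(ca_ratio, n)
  ), extent)
}

#' Parameter presets for the two wetlandscape archetypes
#'
#' Returns a full argument list for [generate_wetlandscape()] emulating the
#' landscape-level statistics of two contrasting US wetlandscape types:
#' \describe{
#'   \item{dense}{prairie-pothole-like: ~30 wetlands per km^2, total maximum
#'     wetted area ~38 km^2 per 100 km^2 (mean \code{A_max} ~12,700 m^2),
#'     strongly heterogeneous areas (lognormal, sdlog = 1).}
#'   \item{sparse}{playa-like: ~1 wetland per km^2, total maximum area
#'     ~5 km^2 per 100 km^2 (mean \code{A_max} = 50,000 m^2), homogeneous
#'     areas (sdlog = 0.3) and near-parabolic bathymetry.}
#' }
#' Only landscape-level statistics are emulated; per-wetland attributes are
#' synthetic draws. \code{extent} rescales the domain while preserving the
#' archetype's density.
#'
#' @param archetype "dense" or "sparse".
#' @param extent domain size (m); the patch count is density times area.
#' @param seed integer seed passed through.
#' @return A named list of arguments for [generate_wetlandscape()].
#' @export
archetype_params <- function(archetype = c("dense", "sparse"),
                             extent = c(10000, 10000), seed = NULL) {
  archetype <- match.arg(archetype)
  area_km2 <- prod(extent) / 1e6
  if (archetype == "dense") {
    mean_area <- 38e6 / 3000   # A_T,MAX 38 km^2 spread over 3000 wetlands
    list(n_patches = round(30 * area_km2), extent = extent,
         area_law = list(type = "lognormal",
                         meanlog = log(mean_area) - 0.5, sdlog = 1),
         h_max_law = list(type = "lognormal",
                          meanlog = log(1.2), sdlog = 0.3),
         bathymetry_law = list(type = "uniform", min = 1, max = 3),
         ca_ratio = 3, min_centre_separation = 60, seed = seed)
  } else {
    mean_area <- 5e6 / 100     # A_T,MAX 5 km^2 spread over 100 wetlands
    list(n_patches = round(1 * area_km2), extent = extent,
         area_law = list(type = "lognormal",
                         meanlog = log(mean_area) - 0.3^2 / 2, sdlog = 0.3),
         h_max_law = list(type = "lognormal",
                          meanlog = log(1.0), sdlog = 0.15),
         bathymetry_law = list(type = "uniform", min = 1.8, max = 2.2),
         ca_ratio = 3, min_centre_separation = 300, seed = seed)
  }
}

#' Read / write a wetlandscape table
#'
#' Plain-text tab-delimited format, UTF-8, one row per wetland with header
#' \code{id x y A_max h_max p ca_ratio}; lines beginning \code{#} are
#' comments. The domain extent is stored in a comment line
#' \code{# extent_m: <width> <height>}. \code{read_wetlandscape(write_wetlandscape(L))}
#' reproduces \code{L} to decimal-text precision (15 significant digits).
#'
#' @param path file path.
#' @param landscape a [wetlandscape()].
#' @return \code{read_wetlandscape} returns a [wetlandscape()];
#'   \code{write_wetlandscape} returns \code{path} invisibly.
#' @export
read_wetlandscape <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  ext_line <- grep("^#\\s*extent_m:", lines, value = TRUE)
  if (!length(ext_line))
    stop("missing '# extent_m: <width> <height>' comment line in ", path)
  extent <- as.numeric(strsplit(sub("^#\\s*extent_m:\\s*", "", ext_line[1]),
                                "\\s+")[[1]])
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          colClasses = c(id = "character"),
                          stringsAsFactors = FALSE)
  # data rows start after the header line; report 1-based data row numbers
  validate_wetlands(df)
  wetlandscape(df, extent)
}

#' @rdname read_wetlandscape
#' @export
write_wetlandscape <- function(landscape, path) {
  stopifnot(inherits(landscape, "wetlandscape"))
  ext <- attr(landscape, "extent")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("# wetlandscape table: one row per wetland",
               "# units: x,y,h_max in m; A_max in m^2; p, ca_ratio dimensionless",
               sprintf("# extent_m: %.15g %.15g", ext[1], ext[2])), con)
  df <- as.data.frame(landscape)
  for (col in c("x", "y", "A_max", "h_max", "p", "ca_ratio"))
    df[[col]] <- sprintf("%.15g", df[[col]])
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
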