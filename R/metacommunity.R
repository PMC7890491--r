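#' A species with a water-depth habitat niche
#'
#' Species occupying one of the three concentric depth zones within each
#' wetland: shallow (< 30 cm), intermediate (30--80 cm) or deep (> 80 cm)
#' water. Its suitability on a patch is that zone's area.
#'
#' @param label species label (e.g. "A", "B", "C").
#' @param zone \code{"shallow"}, \code{"intermediate"} or \code{"deep"}.
#' @param traits a [species_traits()].
#' @return Object of class \code{"niche_species"}.
#' @export
niche_species <- function(label, zone = c("shallow", "intermediate", "deep"),
                          traits = species_traits()) {
  zone <- match.arg(zone)
  stopifnot(inherits(traits, "species_traits"))
  structure(list(label = label, zone = zone, traits = traits),
            class = "niche_species")
}

zone_seed_offset <- c(shallow = 1L, intermediate = 2L, deep = 3L)

#' Run a neutral metacommunity of depth-niche species
#'
#' Runs fully independent dynamic occupancy chains for several species,
#' each with suitability given by its depth-zone area series (no species
#' interactions). Every species draws from its own RNG stream, derived from
#' the master seed by the species' zone (seed + 1000 * zone index), so
#' results are reproducible and independent of the order in which species
#' are listed.
#'
#' @param landscape a [wetlandscape()].
#' @param hydro a \code{hydro_series} (zone areas are taken from it).
#' @param species list of [niche_species()].
#' @param n_realizations Monte-Carlo ensemble size per species.
#' @param seed master integer seed.
#' @param ... further arguments passed to [run_dspom()] (e.g. \code{p0},
#'   \code{s_ref}, \code{record_states}).
#' @return Named list (by species label), each element a list with the
#'   species object, its \code{spom_run} (\code{run}), \code{mean_omega},
#'   and per-realization \code{extinction_day} (first day with no occupied
#'   patch, \code{NA} if the realization survives) with ensemble median
#'   \code{median_extinction_day}.
#' @export
run_metacommunity <- function(landscape, hydro, species,
                              n_realizations = 100, seed = NULL, ...) {
  stopifnot(length(species) >= 1,
            all(vapply(species, inherits, TRUE, "niche_species")))
  out <- list()
  for (sp in species) {
    sp_seed <- if (is.null(seed)) NULL else
      as.integer(seed) + 1000L * zone_seed_offset[[sp$zone]]
    run <- run_dspom(landscape, hydro, sp$traits,
                     n_realizations = n_realizations,
                     suitability = sp$zone, seed = sp_seed, ...)
    ext_day <- apply(run$occ_frac == 0, 2, function(z)
      if (any(z)) which(z)[1] else NA_integer_)
    out[[sp$label]] <- list(
      species = sp, run = run,
      mean_omega = mean(run$omega),
      extinction_day = ext_day,
      median_extinction_day = stats::median(ext_day, na.rm = TRUE))
  }
  out
}
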