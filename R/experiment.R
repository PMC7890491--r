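#' Read a run configuration
#'
#' YAML key/value configuration describing one experiment end-to-end:
#' landscape source (file or generator), forcing source (file or generator),
#' hydrologic parameters, species traits, chain parameters, network
#' threshold and the experiment kind. See [validate_config()] for the
#' schema.
#'
#' @param path YAML file path.
#' @return The configuration list, classed \code{"run_config"}.
#' @export
read_run_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

#' Validate a run configuration
#'
#' Checks the configuration schema and invariants without running anything:
#' required sections, an explicit seed, valid species traits and positive
#' sizes. Returns the resolved configuration (defaults filled in) and, on
#' failure, stops with a message naming the offending field.
#'
#' @param cfg a configuration list (from [read_run_config()] or built in
#'   code).
#' @return The resolved configuration, invisibly-classed
#'   \code{"run_config"}; defaulted fields are listed in
#'   \code{attr(, "defaulted")}.
#' @export
validate_config <- function(cfg) {
  defaulted <- character()
  need <- function(name) {
    if (is.null(cfg[[name]]))
      stop("config error: missing required field '", name, "'")
  }
  default <- function(name, value) {
    if (is.null(cfg[[name]])) {
      cfg[[name]] <<- value
      defaulted <<- c(defaulted, name)
    }
  }
  need("seed")
  if (!is.numeric(cfg$seed)) stop("config error: 'seed' must be an integer")
  default("experiment", "dspom")
  if (!cfg$experiment %in%
        c("dspom", "static", "sensitivity-grid", "metacommunity"))
    stop("config error: unknown experiment kind '", cfg$experiment, "'")
  need("landscape")
  if (is.null(cfg$landscape$file)) {
    if (is.null(cfg$landscape$archetype) && is.null(cfg$landscape$n_patches))
      stop("config error: landscape needs 'file', 'archetype' or generator",
           " parameters ('n_patches', 'extent', ...)")
  }
  need("forcing")
  if (is.null(cfg$forcing$file)) {
    if (is.null(cfg$forcing$alpha) || is.null(cfg$forcing$lambda))
      stop("config error: generated forcing needs 'alpha' and 'lambda'")
    if (cfg$forcing$alpha <= 0)
      stop("config error: forcing 'alpha' must be > 0")
    if (is.null(cfg$forcing$et) && is.null(cfg$forcing$monthly_temp))
      stop("config error: forcing needs 'et' (constant, cm/d) or",
           " 'monthly_temp' + 'latitude' for Thornthwaite PET")
  }
  default("t_days", 365L)
  if (cfg$t_days < 1) stop("config error: 't_days' must be >= 1")
  need("traits")
  tr <- cfg$traits
  if (is.null(tr$e) || tr$e < 0)
    stop("config error: traits 'e' violates species_traits invariant e >= 0")
  if (is.null(tr$c) || tr$c < 0)
    stop("config error: traits 'c' violates species_traits invariant c >= 0")
  if (is.null(tr$D) && is.null(tr$D_over_NND))
    stop("config error: traits need 'D' (m) or 'D_over_NND'")
  default("hydro", list(k_leak = 0.1, pet_coeff = 1))
  default("n_realizations", 100L)
  default("dt", 1)
  default("p0", "all")
  default("suitability", "area")
  if (cfg$experiment == "sensitivity-grid") {
    if (is.null(cfg$grid) ||
        is.null(cfg$grid$parameter) || is.null(cfg$grid$values) ||
        !cfg$grid$parameter %in% c("e", "c", "alpha", "lambda"))
      stop("config error: sensitivity-grid needs grid: {parameter: e|c|",
           "alpha|lambda, values: [...]} (optionally parameter2/values2)")
  }
  structure(cfg, defaulted = defaulted, class = "run_config")
}

build_landscape_from_config <- function(cfg) {
  lc <- cfg$landscape
  if (!is.null(lc$file)) return(read_wetlandscape(lc$file))
  if (!is.null(lc$archetype)) {
    args <- archetype_params(lc$archetype,
                             extent = if (is.null(lc$extent)) c(10000, 10000)
                                      else as.numeric(lc$extent),
                             seed = cfg$seed)
    if (!is.null(lc$n_patches)) args$n_patches <- lc$n_patches
    return(do.call(generate_wetlandscape, args))
  }
  generate_wetlandscape(
    n_patches = lc$n_patches,
    extent = if (is.null(lc$extent)) c(10000, 10000) else as.numeric(lc$extent),
    min_centre_separation = if (is.null(lc$min_centre_separation)) 0
                            else lc$min_centre_separation,
    seed = cfg$seed)
}

build_forcing_from_config <- function(cfg) {
  fc <- cfg$forcing
  if (!is.null(fc$file))
    return(read_forcing(fc$file, pet = fc$et))
  rain <- generate_rainfall(fc$alpha, fc$lambda, cfg$t_days,
                            seed = cfg$seed + 1L)
  pet <- if (!is.null(fc$et)) fc$et
         else thornthwaite_pet(fc$monthly_temp, fc$latitude, cfg$t_days)
  forcing_series(rain, pet)
}

resolve_traits <- function(cfg, landscape) {
  tr <- cfg$traits
  D <- if (!is.null(tr$D)) tr$D else resolve_dispersal(landscape, tr$D_over_NND)
  species_traits(e = tr$e, c = tr$c, D = D)
}

#' Run a configured experiment
#'
#' Executes the experiment named in the configuration end-to-end and writes
#' plain-text tab-delimited outputs plus a YAML manifest echoing every
#' resolved parameter and seed (any output table is regenerable from its
#' manifest alone). Experiment kinds:
#' \describe{
#'   \item{dspom}{dynamic run: \code{omega.tsv} (day, omega, sigma_omega),
#'     \code{capacity.tsv}, \code{landscape_stats.tsv},
#'     \code{network_metrics.tsv} and \code{nldc.tsv} (network metrics
#'     follow realization 1).}
#'   \item{static}{same outputs from the static model (constant capacity).}
#'   \item{sensitivity-grid}{fraction of surviving metapopulations
#'     \code{f_S} over a 1- or 2-parameter lattice (\code{fs_grid.tsv}),
#'     for both the static and dynamic model.}
#'   \item{metacommunity}{per-species occupancy/capacity summaries
#'     (\code{metacommunity.tsv}).}
#' }
#'
#' @param cfg a validated configuration (list or \code{run_config}).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory results and the paths of
#'   the written tables.
#' @export
run_experiment <- function(cfg, out_dir) {
  cfg <- validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  landscape <- build_landscape_from_config(cfg)
  forcing <- build_forcing_from_config(cfg)
  hp <- hydro_params(k_leak = cfg$hydro$k_leak,
                     pet_coeff = cfg$hydro$pet_coeff)
  hydro <- simulate_hydrology(landscape, forcing, hp)
  traits <- resolve_traits(cfg, landscape)
  paths <- character()
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  results <- list(landscape = landscape, traits = traits)
  chain_seed <- cfg$seed + 2L

  if (cfg$experiment %in% c("dspom", "static")) {
    run <- if (cfg$experiment == "dspom")
      run_dspom(landscape, hydro, traits, cfg$n_realizations, cfg$dt,
                cfg$p0, cfg$suitability, seed = chain_seed,
                record_states = TRUE)
    else
      run_static_spom(landscape, hydro, traits, cfg$n_realizations, cfg$dt,
                      cfg$p0, cfg$suitability, seed = chain_seed,
                      record_states = TRUE)
    emit(data.frame(day = seq_along(run$omega), omega = run$omega,
                    sigma_omega = run$sigma_omega), "omega.tsv")
    emit(data.frame(day = seq_along(run$lambda), lambda_max = run$lambda),
         "capacity.tsv")
    emit(landscape_stats(hydro), "landscape_stats.tsv")
    nm <- network_metrics_series(run, hydro)
    emit(nm, "network_metrics.tsv")
    emit(nldc(nm$L), "nldc.tsv")
    results$run <- run
    results$network_metrics <- nm
    results$f_S <- run$f_S
  } else if (cfg$experiment == "sensitivity-grid") {
    g <- cfg$grid
    v1 <- as.numeric(g$values)
    v2 <- if (is.null(g$values2)) NA else as.numeric(g$values2)
    p2 <- g$parameter2
    rows <- list()
    for (a in v1) for (b in (if (is.null(p2)) NA else v2)) {
      cfg2 <- unclass(cfg)
      set_par <- function(cfg2, par, val) {
        if (par %in% c("e", "c")) cfg2$traits[[par]] <- val
        else cfg2$forcing[[par]] <- val
        cfg2
      }
      cfg2 <- set_par(cfg2, g$parameter, a)
      if (!is.null(p2)) cfg2 <- set_par(cfg2, p2, b)
      forcing2 <- build_forcing_from_config(cfg2)
      hydro2 <- simulate_hydrology(landscape, forcing2, hp)
      traits2 <- resolve_traits(cfg2, landscape)
      dyn <- run_dspom(landscape, hydro2, traits2, cfg$n_realizations,
                       cfg$dt, cfg$p0, cfg$suitability, seed = chain_seed,
                       record_capacity = FALSE)
      sta <- run_static_spom(landscape, hydro2, traits2, cfg$n_realizations,
                             cfg$dt, cfg$p0, cfg$suitability,
                             seed = chain_seed)
      rows[[length(rows) + 1L]] <-
        data.frame(parameter = g$parameter, value = a,
                   parameter2 = if (is.null(p2)) NA_character_ else p2,
                   value2 = b, f_S_dynamic = dyn$f_S, f_S_static = sta$f_S)
    }
    fs <- do.call(rbind, rows)
    emit(fs, "fs_grid.tsv")
    results$fs_grid <- fs
  } else if (cfg$experiment == "metacommunity") {
    sp <- list(niche_species("A", "shallow", traits),
               niche_species("B", "intermediate", traits),
               niche_species("C", "deep", traits))
    mc <- run_metacommunity(landscape, hydro, sp, cfg$n_realizations,
                            seed = chain_seed, p0 = cfg$p0)
    tab <- do.call(rbind, lapply(mc, function(z)
      data.frame(species = z$species$label, zone = z$species$zone,
                 mean_omega = z$mean_omega, f_S = z$run$f_S,
                 median_extinction_day = z$median_extinction_day,
                 mean_lambda_max = mean(z$run$lambda))))
    emit(tab, "metacommunity.tsv")
    results$metacommunity <- mc
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("dspom")),
    experiment = cfg$experiment,
    seed = cfg$seed,
    chain_seed = chain_seed,
    t_days = cfg$t_days,
    n_realizations = cfg$n_realizations,
    dt = cfg$dt, p0 = cfg$p0, suitability = cfg$suitability,
    traits = list(e = traits$e, c = traits$c, D = traits$D),
    hydro = cfg$hydro,
    landscape = utils::modifyList(
      cfg$landscape,
      list(n = nrow(landscape),
           extent = as.numeric(attr(landscape, "extent")))),
    forcing = cfg$forcing,
    defaulted_fields = attr(cfg, "defaulted"),
    outputs = basename(paths))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(c(results, list(paths = paths,
                            manifest = file.path(out_dir, "manifest.yaml"))))
}
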