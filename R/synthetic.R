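# Seeded generator of synthetic per-tap observations. Real per-tap tables for
# the study system are not published, so analyses are exercised on synthetic
# data with the reported statistical structure: total bacteria (log10 16S
# rRNA gene copies) increasing linearly with HRT at a calibrated population
# R-squared, Fe increasing with HRT at a calibrated correlation, and Zn/Cu
# leaching set by pipe and tap materials.

#' Parameters of the synthetic tap-water generator
#'
#' @param intercept_16s Log10 16S rRNA gene copies per litre at zero HRT.
#' @param slope_16s Log10 copies gained per hour of HRT.
#' @param target_r2_16s Population R-squared of the HRT to log10-16S relation
#'   (noise is calibrated to hit it); in (0, 1).
#' @param intercept_fe Fe concentration at zero HRT, mg/L.
#' @param slope_fe Fe gained per hour of HRT, mg/L per hour.
#' @param target_r_fe Population Pearson correlation of HRT with Fe; in
#'   (-1, 1), non-zero whenever `slope_fe` is.
#' @param zn_mean_by_material Named vector of mean Zn (mg/L) by horizontal
#'   pipe material; galvanized linings shed Zn, plastics do not.
#' @param cu_mean_by_material Named vector of mean Cu (mg/L) by tap material;
#'   brass fittings shed Cu.
#' @param metal_sdlog Log-scale SD of the lognormal metal concentrations.
#' @param seed Master seed; every random stream (demands, tap choice, 16S
#'   noise, Fe noise, metals) derives its own substream from it.
#' @return A `generator_params` list.
#' @export
generator_params <- function(intercept_16s = 2.5, slope_16s = 0.35,
                             target_r2_16s = 0.63,
                             intercept_fe = 0.01, slope_fe = 0.004,
                             target_r_fe = 0.79,
                             zn_mean_by_material = c("galvanized-steel" = 0.40,
                                                     "polypropylene" = 0.10),
                             cu_mean_by_material = c("brass" = 0.069,
                                                     "stainless-steel" = 0.005),
                             metal_sdlog = 0.5, seed = 1L) {
  if (!(target_r2_16s > 0 && target_r2_16s < 1)) {
    stop_swss("calibration", "target_r2_16s must lie strictly in (0, 1)")
  }
  if (!(target_r_fe > -1 && target_r_fe < 1) ||
      (slope_fe != 0 && target_r_fe == 0)) {
    stop_swss("calibration",
              "target_r_fe must lie in (-1, 1) and be non-zero when slope_fe is")
  }
  structure(list(intercept_16s = intercept_16s, slope_16s = slope_16s,
                 target_r2_16s = target_r2_16s,
                 intercept_fe = intercept_fe, slope_fe = slope_fe,
                 target_r_fe = target_r_fe,
                 zn_mean_by_material = zn_mean_by_material,
                 cu_mean_by_material = cu_mean_by_material,
                 metal_sdlog = metal_sdlog, seed = as.integer(seed)),
            class = "generator_params")
}

# Deterministic per-stream substream seeds below 2^31, so the master seed
# alone fixes every random draw of a run.
derive_seed <- function(master, stream) {
  offsets <- c(demands = 101L, bands = 157L, taps = 211L,
               sixteen_s = 307L, fe = 401L, metals = 503L)
  if (!stream %in% names(offsets)) stop_swss("config", sprintf("unknown stream '%s'", stream))
  s <- (as.double(master) * 48271 + offsets[[stream]]) %% 2147483629
  as.integer(max(s, 1))
}

#' Draw per-floor demands from consumption bands
#'
#' Emulates building-management consumption records: each floor is assigned
#' to a low (1--5 t/month) or high (10--14 t/month) utilisation band and its
#' monthly consumption is drawn uniformly within the band, then converted to
#' m^3/s with [demand_from_monthly()].
#'
#' @param floors Vector of floor indices.
#' @param band_assignment Character vector (`"low"`/`"high"`), recycled to
#'   the floors.
#' @param seed Integer seed; the draw is reproducible.
#' @return Data frame with `floor`, `band`, `tonnes_per_month`, `demand`.
#' @export
sample_demands <- function(floors, band_assignment, seed) {
  if (length(floors) == 0L) stop_swss("invalid_input", "no floors to draw demands for")
  bands <- rep_len(as.character(band_assignment), length(floors))
  if (!all(bands %in% c("low", "high"))) {
    stop_swss("invalid_input", "bands must be 'low' or 'high'")
  }
  set.seed(seed)
  lo <- ifelse(bands == "low", 1, 10)
  hi <- ifelse(bands == "low", 5, 14)
  t_month <- stats::runif(length(floors), lo, hi)
  data.frame(floor = as.integer(floors), band = bands,
             tonnes_per_month = t_month,
             demand = demand_from_monthly(t_month),
             stringsAsFactors = FALSE)
}

#' Noise level that hits a target population R-squared
#'
#' For a response `slope * x + Normal(0, sd)` the population R-squared is
#' `slope^2 Var(x) / (slope^2 Var(x) + sd^2)`; inverting gives
#' `sd = sqrt(slope^2 Var(x) (1 - R2) / R2)`.
#'
#' @param slope Linear signal slope (response units per unit of `x`).
#' @param x_values Predictor values whose variance defines the signal spread.
#' @param target_r2 Desired population R-squared, in (0, 1).
#' @return Standard deviation of the required Gaussian noise.
#' @export
calibrate_noise_sd <- function(slope, x_values, target_r2) {
  if (!(is.numeric(target_r2) && length(target_r2) == 1L &&
        target_r2 > 0 && target_r2 < 1)) {
    stop_swss("calibration", "target_r2 must lie strictly in (0, 1)")
  }
  v <- stats::var(x_values)
  if (!is.finite(v) || v <= 0) {
    stop_swss("calibration", "predictor values are constant; cannot calibrate noise")
  }
  sqrt(slope^2 * v * (1 - target_r2) / target_r2)
}

mean_for_material <- function(table, material, what) {
  if (!material %in% names(table)) {
    stop_swss("config", sprintf("no %s mean for material '%s'", what, material))
  }
  table[[material]]
}

#' Generate synthetic per-tap observations
#'
#' Draws one observation per tap on a building's served floors: the tap's
#' HRT from the plug-flow model, log10 16S rRNA gene copies and Fe as linear
#' functions of HRT (in hours) plus Gaussian noise calibrated to the target
#' association strengths, and Zn/Cu as lognormal draws around the means for
#' the building's pipe and tap materials. Fully deterministic per seed.
#'
#' @param topology A valid [building_topology()].
#' @param params A [generator_params()].
#' @param n_taps Number of taps, assigned to served floors with replacement;
#'   `NULL` samples every served floor exactly once.
#' @param resample_demands If `TRUE` (default), floor demands are redrawn
#'   from the consumption bands before computing HRT, emulating a fresh
#'   month of utilisation records; if `FALSE` the topology's stored demands
#'   are used as-is.
#' @return Data frame of tap observations: `building`, `floor`,
#'   `functional_area`, `supply_label`, `consumption_band`, `hrt_s`,
#'   `hrt_h`, `log10_16s`, `fe`, `zn`, `cu`.
#' @export
generate_observations <- function(topology, params = generator_params(),
                                  n_taps = NULL, resample_demands = TRUE) {
  stopifnot(inherits(params, "generator_params"))
  if (resample_demands) {
    served <- sort(unique(unlist(lapply(topology$zones, function(z) {
      zone_floor_indices(topology, z)
    }))))
    set.seed(derive_seed(params$seed, "bands"))
    bands <- sample(c("low", "high"), length(served), replace = TRUE)
    dem <- sample_demands(served, bands, derive_seed(params$seed, "demands"))
    i <- match(dem$floor, topology$floors$index)
    topology$floors$demand[i] <- dem$demand
    band_of <- stats::setNames(dem$band, dem$floor)
  } else {
    t_month <- topology$floors$demand * 2592000
    band_of <- stats::setNames(
      ifelse(t_month <= 5, "low", ifelse(t_month >= 10, "high", "mid")),
      topology$floors$index)
  }
  prof <- hrt_profile(topology)
  ok <- prof[prof$status == "ok", , drop = FALSE]
  if (nrow(ok) == 0L) {
    stop_swss("generation", "every served floor is stagnant; nothing to sample")
  }
  if (is.null(n_taps)) {
    taps <- ok
  } else {
    set.seed(derive_seed(params$seed, "taps"))
    taps <- ok[sample.int(nrow(ok), n_taps, replace = TRUE), , drop = FALSE]
  }
  hrt_h <- taps$hrt_h

  sd_16s <- calibrate_noise_sd(params$slope_16s, hrt_h, params$target_r2_16s)
  set.seed(derive_seed(params$seed, "sixteen_s"))
  log10_16s <- params$intercept_16s + params$slope_16s * hrt_h +
    stats::rnorm(nrow(taps), 0, sd_16s)

  sd_fe <- calibrate_noise_sd(params$slope_fe, hrt_h, params$target_r_fe^2)
  set.seed(derive_seed(params$seed, "fe"))
  fe <- pmax(0, params$intercept_fe + params$slope_fe * hrt_h +
               stats::rnorm(nrow(taps), 0, sd_fe))

  zn_mu <- mean_for_material(params$zn_mean_by_material, topology$pipe_material, "Zn")
  cu_mu <- mean_for_material(params$cu_mean_by_material, topology$tap_material, "Cu")
  set.seed(derive_seed(params$seed, "metals"))
  sdl <- params$metal_sdlog
  zn <- stats::rlnorm(nrow(taps), log(zn_mu) - sdl^2 / 2, sdl)
  cu <- stats::rlnorm(nrow(taps), log(cu_mu) - sdl^2 / 2, sdl)

  data.frame(building = taps$building, floor = taps$floor,
             functional_area = topology$functional_area,
             supply_label = taps$supply_label,
             consumption_band = unname(band_of[as.character(taps$floor)]),
             hrt_s = taps$hrt_s, hrt_h = hrt_h,
             log10_16s = log10_16s, fe = fe, zn = zn, cu = cu,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write observations as CSV with a parameter sidecar
#'
#' @param obs Output of [generate_observations()].
#' @param path CSV path; generator parameters are echoed to `<path>.params.yaml`
#'   for provenance.
#' @param params The [generator_params()] used, or `NULL` to skip the sidecar.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path, params = NULL) {
  atomic_write(path, function(tmp) utils::write.csv(obs, tmp, row.names = FALSE))
  if (!is.null(params)) {
    side <- paste0(path, ".params.yaml")
    atomic_write(side, function(tmp) {
      yaml::write_yaml(lapply(unclass(params), function(x) {
        if (is.null(names(x))) unname(x) else as.list(x)
      }), tmp)
    })
  }
  invisible(path)
}

#' Reference building layouts of the studied architectural complex
#'
#' Two ready-made topologies mirroring the studied high-rise pair. The
#' office tower (34 storeys) has its inlet tank two levels underground, a
#' mechanical floor with a break tank on the 23rd storey, a gravity
#' down-feed zone over floors 6--23 fed from the mechanical floor
#' (`swss-first`), and a pumped upper zone over floors 24--34 fed via the
#' break tank from the top of the building (`swss-second`); floors 1--2 are
#' mains-direct and floors 3--5 (a non-operational shopping mall) carry no
#' demand. The residential tower (45 storeys) has its mechanical floor and
#' break tank on the 30th storey, zones 3--30 and 31--45, and mains-direct
#' floors 1--2.
#'
#' Geometry and operating defaults (per-storey height 3 m, 50-mm standpipes,
#' 25-mm horizontal lines of 10 m, tank residence times of 4 h, uniform
#' 7.5 t/month demand) are stated assumptions, editable in the config
#' written by [cmd_build_example()].
#'
#' @return `office_topology()` / `residential_topology()`: one
#'   [building_topology()]; `study_layout_fixtures()`: a named list with
#'   both.
#' @export
office_topology <- function() {
  mk <- function(idx, label, t_month) {
    floor_spec(idx, monthly_demand = t_month, supply_label = label)
  }
  floors <- rbind(
    do.call(rbind, lapply(1:5, mk, label = "mains-direct", t_month = 0)),
    do.call(rbind, lapply(6:23, mk, label = "swss-first", t_month = 7.5)),
    do.call(rbind, lapply(24:34, mk, label = "swss-second", t_month = 7.5)))
  building_topology(
    name = "office",
    floors = floors,
    tanks = list(tank_spec("T1", -2L, 14400), tank_spec("T2", 23L, 14400)),
    zones = list(
      zone_spec("office-low", "T1", entry_floor = 23L,
                served_floors = c(6L, 23L), upstream_tanks = "T1"),
      zone_spec("office-high", "T2", entry_floor = 34L,
                served_floors = c(24L, 34L), upstream_tanks = c("T1", "T2"))),
    functional_area = "office",
    pipe_material = "galvanized-steel", tap_material = "stainless-steel")
}

#' @rdname office_topology
#' @export
residential_topology <- function() {
  mk <- function(idx, label, t_month) {
    floor_spec(idx, monthly_demand = t_month, supply_label = label)
  }
  floors <- rbind(
    do.call(rbind, lapply(1:2, mk, label = "mains-direct", t_month = 0)),
    do.call(rbind, lapply(3:30, mk, label = "swss-first", t_month = 7.5)),
    do.call(rbind, lapply(31:45, mk, label = "swss-second", t_month = 7.5)))
  building_topology(
    name = "residential",
    floors = floors,
    tanks = list(tank_spec("T1", -2L, 14400), tank_spec("T3", 30L, 14400)),
    zones = list(
      zone_spec("res-low", "T1", entry_floor = 30L,
                served_floors = c(3L, 30L), upstream_tanks = "T1"),
      zone_spec("res-high", "T3", entry_floor = 45L,
                served_floors = c(31L, 45L), upstream_tanks = c("T1", "T3"))),
    functional_area = "residence",
    pipe_material = "polypropylene", tap_material = "brass")
}

#' @rdname office_topology
#' @export
study_layout_fixtures <- function() {
  list(office = office_topology(), residential = residential_topology())
}
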