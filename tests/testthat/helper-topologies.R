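# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# Diameter giving an exact target segment volume at unit length.
diameter_for_volume <- function(volume, length = 1) {
  sqrt(4 * volume / (pi * length))
}

# One tank, one zone of `n_floors` floors with uniform geometry and demand.
toy_single_zone <- function(n_floors = 2, demand = 1e-6, vs = 2e-6,
                            tank_hrt = 0, horizontal_length = 0,
                            first_floor = 6L, tank_floor = NULL) {
  idx <- seq(first_floor, first_floor + n_floors - 1L)
  ds <- diameter_for_volume(vs)
  floors <- do.call(rbind, lapply(idx, function(i) {
    floor_spec(i, height = 1, demand = demand, standpipe_diameter = ds,
               horizontal_diameter = 0.02, horizontal_length = horizontal_length,
               supply_label = "swss-first")
  }))
  tank_floor <- if (is.null(tank_floor)) first_floor - 1L else tank_floor
  building_topology(
    name = "toy", floors = floors,
    tanks = list(tank_spec("T1", tank_floor, tank_hrt)),
    zones = list(zone_spec("z", "T1", entry_floor = max(idx),
                           served_floors = range(idx))),
    defaults = list(height = 1, standpipe_diameter = ds))
}

# Randomised valid topology: 1-3 stacked zones chained through break tanks,
# heterogeneous per-floor geometry and demand. Used for the oracle-
# equivalence property suite.
random_topology <- function(seed) {
  set.seed(seed)
  n_zones <- sample(1:3, 1)
  inlet_floor <- sample(-3:0, 1)
  lo <- sample(2:5, 1)
  zone_sizes <- sample(2:6, n_zones, replace = TRUE)
  floors <- list()
  tanks <- list(tank_spec("T1", inlet_floor, stats::runif(1, 0, 8 * 3600)))
  zones <- list()
  upstream <- "T1"
  start <- lo
  for (z in seq_len(n_zones)) {
    idx <- seq(start, start + zone_sizes[z] - 1L)
    for (i in idx) {
      floors[[length(floors) + 1L]] <- floor_spec(
        i, height = stats::runif(1, 2.5, 4),
        monthly_demand = stats::runif(1, 1, 14),
        standpipe_diameter = stats::runif(1, 0.03, 0.08),
        horizontal_diameter = stats::runif(1, 0.015, 0.03),
        horizontal_length = stats::runif(1, 0, 15),
        supply_label = if (z == 1) "swss-first" else "swss-second")
    }
    zones[[z]] <- zone_spec(paste0("z", z), upstream[length(upstream)],
                            entry_floor = max(idx), served_floors = range(idx),
                            upstream_tanks = upstream)
    if (z < n_zones) {
      tid <- paste0("T", z + 1L)
      tanks[[length(tanks) + 1L]] <- tank_spec(tid, max(idx),
                                               stats::runif(1, 0, 8 * 3600))
      upstream <- c(upstream, tid)
    }
    start <- max(idx) + 1L
  }
  building_topology(name = paste0("random-", seed),
                    floors = do.call(rbind, floors),
                    tanks = tanks, zones = zones)
}

# Office fixture with every demand multiplied by `c_factor`.
scale_demands <- function(topology, c_factor) {
  topology$floors$demand <- topology$floors$demand * c_factor
  topology
}
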