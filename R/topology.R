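# Building-topology data model for a high-rise secondary water supply system
# (SWSS): floors with pipe geometry and demand, storage tanks, and gravity
# down-feed supply zones. All hydraulics downstream assume steady plug flow.

SUPPLY_LABELS <- c("mains-direct", "swss-first", "swss-second")

#' Internal volume of a cylindrical pipe segment
#'
#' Computes the water volume held by a pipe of circular cross-section,
#' \eqn{V = (\pi/4) d^2 L}. This is the per-storey standpipe volume
#' (`Vs`) when `length` is the storey height, and the horizontal supply-line
#' volume (`Vh`) when `length` is the on-floor run to the tap.
#'
#' @param diameter Internal pipe diameter in metres. Must be positive.
#' @param length Segment length in metres. Must be non-negative.
#' @return Volume in cubic metres. Vectorised over both arguments.
#' @examples
#' segment_volume(0.05, 3)      # one storey of 50-mm standpipe
#' segment_volume(0.025, 4.074) # ~2 L of 25-mm supply line
#' @export
segment_volume <- function(diameter, length) {
  if (!is.numeric(diameter) || !is.numeric(length)) {
    stop_swss("invalid_geometry", "diameter and length must be numeric")
  }
  if (any(!is.finite(diameter)) || any(diameter <= 0)) {
    stop_swss("invalid_geometry", "pipe diameter must be positive and finite")
  }
  if (any(!is.finite(length)) || any(length < 0)) {
    stop_swss("invalid_geometry", "pipe length must be non-negative and finite")
  }
  (pi / 4) * diameter^2 * length
}

#' Convert a monthly water consumption to a volumetric flow rate
#'
#' Bridges consumption figures reported in tonnes per month (as in building
#' management records, e.g. the 1--5 and 10--14 t/month bands) to the
#' m\eqn{^3} s\eqn{^{-1}} demand rate the retention-time model uses.
#' Water density is taken as 1 t = 1 m\eqn{^3} and a month as 30 days
#' (2,592,000 s).
#'
#' @param tonnes_per_month Consumption in tonnes per month; non-negative.
#' @param seconds_per_month Length of the accounting month in seconds.
#' @return Demand in cubic metres per second. Vectorised.
#' @examples
#' demand_from_monthly(2.592)  # 1e-6 m^3/s
#' @export
demand_from_monthly <- function(tonnes_per_month, seconds_per_month = 2592000) {
  if (!is.numeric(tonnes_per_month) || any(!is.finite(tonnes_per_month)) ||
      any(tonnes_per_month < 0)) {
    stop_swss("invalid_demand", "monthly consumption must be non-negative and finite")
  }
  tonnes_per_month / seconds_per_month
}

#' Specify one floor of a building
#'
#' @param index Signed integer storey number; negative values are underground.
#' @param height Per-storey standpipe rise in metres.
#' @param demand Average water consumption rate in m^3/s. Give exactly one of
#'   `demand` or `monthly_demand`.
#' @param monthly_demand Average consumption in tonnes per month; converted
#'   with [demand_from_monthly()].
#' @param standpipe_diameter Riser internal diameter in metres.
#' @param horizontal_diameter On-floor supply-line diameter in metres.
#' @param horizontal_length On-floor supply-line length in metres.
#' @param supply_label One of `"mains-direct"`, `"swss-first"`,
#'   `"swss-second"`.
#' @return One-row data frame; rbind rows to build the `floors` table of
#'   [building_topology()].
#' @export
floor_spec <- function(index, height = 3, demand = NULL, monthly_demand = NULL,
                       standpipe_diameter = 0.05, horizontal_diameter = 0.025,
                       horizontal_length = 10,
                       supply_label = "swss-first") {
  if (is.null(demand) == is.null(monthly_demand)) {
    stop_swss("invalid_demand",
              sprintf("floor %s: give exactly one of demand or monthly_demand", index))
  }
  if (is.null(demand)) demand <- demand_from_monthly(monthly_demand)
  data.frame(index = as.integer(index), height = height, demand = demand,
             standpipe_diameter = standpipe_diameter,
             horizontal_diameter = horizontal_diameter,
             horizontal_length = horizontal_length,
             supply_label = supply_label, stringsAsFactors = FALSE)
}

#' Specify a storage tank
#'
#' @param id Short tank name, e.g. `"T1"`.
#' @param floor_index Storey where the tank sits (negative = underground).
#' @param hrt Regulated storage (residence) time in seconds.
#' @return A `swss_tank` list.
#' @export
tank_spec <- function(id, floor_index, hrt) {
  stopifnot(is.character(id), length(id) == 1L)
  if (!is.numeric(hrt) || length(hrt) != 1L || !is.finite(hrt) || hrt < 0) {
    stop_swss("invalid_tank", sprintf("tank %s: hrt must be a non-negative number", id))
  }
  structure(list(id = id, floor_index = as.integer(floor_index), hrt = hrt),
            class = "swss_tank")
}

#' Specify a gravity down-feed supply zone
#'
#' A zone is a contiguous block of floors fed from one tank: water is pumped
#' up to `entry_floor` and flows down the standpipe to the served floors.
#'
#' @param id Short zone name.
#' @param source_tank Id of the tank this zone draws from (the last element
#'   of `upstream_tanks`).
#' @param entry_floor Storey where water enters the down-feed (mechanical
#'   floor or top floor); must be at least the highest served floor.
#' @param served_floors Inclusive integer range `c(lo, hi)` of served storeys.
#' @param upstream_tanks Ordered tank ids traversed from the network inlet to
#'   this zone.
#' @return A `swss_zone` list.
#' @export
zone_spec <- function(id, source_tank, entry_floor, served_floors,
                      upstream_tanks = source_tank) {
  stopifnot(is.character(id), length(id) == 1L, length(served_floors) == 2L)
  served <- as.integer(served_floors)
  structure(list(id = id, source_tank = source_tank,
                 entry_floor = as.integer(entry_floor),
                 served_floors = served,
                 upstream_tanks = as.character(upstream_tanks)),
            class = "swss_zone")
}

#' Assemble a building topology
#'
#' @param name Building name.
#' @param floors Data frame of floor rows from [floor_spec()].
#' @param tanks List of [tank_spec()] objects.
#' @param zones List of [zone_spec()] objects.
#' @param functional_area Label for observations generated on this building,
#'   e.g. `"office"` or `"residence"`.
#' @param pipe_material Horizontal-pipe material, controls synthetic Zn
#'   leaching (e.g. `"galvanized-steel"`, `"polypropylene"`).
#' @param tap_material Tap/fitting material, controls synthetic Cu leaching
#'   (e.g. `"brass"`, `"stainless-steel"`).
#' @param defaults Geometry used for storeys a riser traverses that have no
#'   row in `floors` (basement and service levels): a list with `height` and
#'   `standpipe_diameter`.
#' @return A `building_topology` object.
#' @seealso [validate_topology()], [hrt_profile()]
#' @export
building_topology <- function(name, floors, tanks, zones,
                              functional_area = "office",
                              pipe_material = "galvanized-steel",
                              tap_material = "stainless-steel",
                              defaults = list(height = 3, standpipe_diameter = 0.05)) {
  tanks <- if (inherits(tanks, "swss_tank")) list(tanks) else tanks
  zones <- if (inherits(zones, "swss_zone")) list(zones) else zones
  names(tanks) <- vapply(tanks, `[[`, "", "id")
  names(zones) <- vapply(zones, `[[`, "", "id")
  structure(list(name = name, floors = floors, tanks = tanks, zones = zones,
                 functional_area = functional_area,
                 pipe_material = pipe_material, tap_material = tap_material,
                 defaults = defaults),
            class = "building_topology")
}

#' @export
print.building_topology <- function(x, ...) {
  cat(sprintf("<building_topology> %s (%s)\n", x$name, x$functional_area))
  cat(sprintf("  floors: %d (storeys %d..%d)\n", nrow(x$floors),
              min(x$floors$index), max(x$floors$index)))
  for (tk in x$tanks) {
    cat(sprintf("  tank %s @ floor %d, hrt %.0f s\n", tk$id, tk$floor_index, tk$hrt))
  }
  for (z in x$zones) {
    cat(sprintf("  zone %s: floors %d..%d, entry %d, via %s\n", z$id,
                z$served_floors[1], z$served_floors[2], z$entry_floor,
                paste(z$upstream_tanks, collapse = " > ")))
  }
  invisible(x)
}

# Look up a floor row; NULL if the storey has no entry.
floor_row <- function(topology, index) {
  i <- match(index, topology$floors$index)
  if (is.na(i)) NULL else topology$floors[i, , drop = FALSE]
}

# Per-storey standpipe volume Vs for storey `index`, falling back to the
# topology defaults for basement/service storeys absent from the floors table.
storey_volume <- function(topology, index) {
  fr <- floor_row(topology, index)
  if (is.null(fr)) {
    segment_volume(topology$defaults$standpipe_diameter, topology$defaults$height)
  } else {
    segment_volume(fr$standpipe_diameter, fr$height)
  }
}

# Zone that serves `index`, or NULL (mains-direct / unserved floor).
zone_of_floor <- function(topology, index) {
  for (z in topology$zones) {
    if (index >= z$served_floors[1] && index <= z$served_floors[2]) return(z)
  }
  NULL
}

# All floor indices of a zone that have a row in the floors table.
zone_floor_indices <- function(topology, zone) {
  idx <- topology$floors$index
  sort(idx[idx >= zone$served_floors[1] & idx <= zone$served_floors[2]])
}

#' Cumulative demand carried by a down-feed segment
#'
#' In a gravity down-feed zone the standpipe segment at storey `floor_j`
#' delivers water to every served floor at or below `floor_j`, so it carries
#' their summed demand. This is the denominator of each down-feed travel-time
#' term.
#'
#' @param topology A [building_topology()].
#' @param zone A zone of the topology (object or id).
#' @param floor_j Storey within the zone's served range.
#' @return Cumulative demand in m^3/s.
#' @export
downstream_demand <- function(topology, zone, floor_j) {
  zone <- resolve_zone(topology, zone)
  if (floor_j < zone$served_floors[1] || floor_j > zone$served_floors[2]) {
    stop_swss("out_of_zone",
              sprintf("floor %d is outside zone %s (%d..%d)", floor_j, zone$id,
                      zone$served_floors[1], zone$served_floors[2]))
  }
  idx <- zone_floor_indices(topology, zone)
  sum(topology$floors$demand[topology$floors$index %in% idx[idx <= floor_j]])
}

resolve_zone <- function(topology, zone) {
  if (inherits(zone, "swss_zone")) return(zone)
  z <- topology$zones[[zone]]
  if (is.null(z)) stop_swss("unknown_zone", sprintf("no zone '%s'", zone))
  z
}

resolve_tank <- function(topology, tank) {
  if (inherits(tank, "swss_tank")) return(tank)
  tk <- topology$tanks[[tank]]
  if (is.null(tk)) stop_swss("unknown_tank", sprintf("no tank '%s'", tank))
  tk
}

# Zones whose supply path passes through the given tank.
zones_fed_by <- function(topology, tank_id) {
  Filter(function(z) tank_id %in% z$upstream_tanks, topology$zones)
}

#' Total flow through the riser leaving a tank
#'
#' The riser out of a tank carries the summed average demand of every floor
#' ultimately fed from that tank, whether directly or via downstream tanks.
#'
#' @param topology A [building_topology()].
#' @param tank A tank of the topology (object or id).
#' @return Flow in m^3/s.
#' @export
riser_flow <- function(topology, tank) {
  tank <- resolve_tank(topology, tank)
  zs <- zones_fed_by(topology, tank$id)
  if (length(zs) == 0L) {
    stop_swss("dangling_tank", sprintf("tank %s feeds no zone", tank$id))
  }
  floors <- unique(unlist(lapply(zs, function(z) zone_floor_indices(topology, z))))
  sum(topology$floors$demand[topology$floors$index %in% floors])
}

#' Validate a building topology
#'
#' Checks every structural invariant of the data model and returns the
#' violations as text rather than raising, so configuration errors can be
#' reported together.
#'
#' @param topology A [building_topology()].
#' @return Character vector of violation descriptions; empty when valid.
#' @export
validate_topology <- function(topology) {
  v <- character(0)
  fl <- topology$floors
  req <- c("index", "height", "demand", "standpipe_diameter",
           "horizontal_diameter", "horizontal_length", "supply_label")
  missing_cols <- setdiff(req, names(fl))
  if (length(missing_cols) > 0) {
    return(sprintf("floors table lacks columns: %s", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(fl$index)) {
    v <- c(v, sprintf("duplicate floor indices: %s",
                      paste(unique(fl$index[duplicated(fl$index)]), collapse = ", ")))
  }
  bad <- fl$index[fl$height <= 0]
  if (length(bad)) v <- c(v, sprintf("non-positive storey height at floors: %s", paste(bad, collapse = ", ")))
  bad <- fl$index[fl$standpipe_diameter <= 0 | fl$horizontal_diameter <= 0]
  if (length(bad)) v <- c(v, sprintf("non-positive pipe diameter at floors: %s", paste(bad, collapse = ", ")))
  bad <- fl$index[fl$horizontal_length < 0]
  if (length(bad)) v <- c(v, sprintf("negative horizontal length at floors: %s", paste(bad, collapse = ", ")))
  bad <- fl$index[fl$demand < 0]
  if (length(bad)) v <- c(v, sprintf("negative demand at floors: %s", paste(bad, collapse = ", ")))
  bad <- fl$index[!fl$supply_label %in% SUPPLY_LABELS]
  if (length(bad)) v <- c(v, sprintf("unknown supply label at floors: %s", paste(bad, collapse = ", ")))

  for (tk in topology$tanks) {
    if (tk$hrt < 0) v <- c(v, sprintf("tank %s has negative hrt", tk$id))
  }

  assignment <- list()
  inlets <- character(0)
  for (z in topology$zones) {
    if (z$served_floors[1] > z$served_floors[2]) {
      v <- c(v, sprintf("zone %s has an empty served-floor range", z$id))
      next
    }
    if (z$entry_floor < z$served_floors[2]) {
      v <- c(v, sprintf("zone %s entry floor %d below its top served floor %d",
                        z$id, z$entry_floor, z$served_floors[2]))
    }
    for (tid in unique(c(z$source_tank, z$upstream_tanks))) {
      if (is.null(topology$tanks[[tid]])) {
        v <- c(v, sprintf("zone %s references missing tank '%s'", z$id, tid))
      }
    }
    if (length(z$upstream_tanks) == 0L) {
      v <- c(v, sprintf("zone %s has no upstream tank chain", z$id))
    } else {
      if (z$upstream_tanks[length(z$upstream_tanks)] != z$source_tank) {
        v <- c(v, sprintf("zone %s: upstream chain does not end at source tank %s",
                          z$id, z$source_tank))
      }
      inlets <- c(inlets, z$upstream_tanks[1])
    }
    served <- seq(z$served_floors[1], z$served_floors[2])
    absent <- setdiff(served, fl$index)
    if (length(absent)) {
      v <- c(v, sprintf("zone %s serves floors with no floor entry: %s",
                        z$id, paste(absent, collapse = ", ")))
    }
    for (k in intersect(served, fl$index)) {
      key <- as.character(k)
      assignment[[key]] <- c(assignment[[key]], z$id)
    }
  }
  multi <- names(assignment)[vapply(assignment, length, 0L) > 1L]
  for (k in multi) {
    v <- c(v, sprintf("floor %s belongs to more than one zone (%s)",
                      k, paste(assignment[[k]], collapse = ", ")))
  }
  if (length(unique(inlets)) > 1L) {
    v <- c(v, sprintf("zones disagree on the network inlet tank: %s",
                      paste(unique(inlets), collapse = ", ")))
  }
  served_any <- as.integer(names(assignment))
  mains <- fl$index[fl$supply_label == "mains-direct"]
  overlap <- intersect(mains, served_any)
  if (length(overlap)) {
    v <- c(v, sprintf("mains-direct floors assigned to a zone: %s",
                      paste(overlap, collapse = ", ")))
  }
  swss <- fl$index[fl$supply_label %in% c("swss-first", "swss-second") & fl$demand > 0]
  orphans <- setdiff(swss, served_any)
  if (length(orphans)) {
    v <- c(v, sprintf("SWSS-labelled floors in no zone: %s", paste(orphans, collapse = ", ")))
  }
  v
}

# Classed error helper: every package error carries class swsshrt_<what>.
stop_swss <- function(what, msg) {
  stop(structure(class = c(paste0("swsshrt_", what), "swsshrt_error",
                           "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
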