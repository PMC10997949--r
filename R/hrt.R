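# Analytic plug-flow hydraulic retention time (HRT) per tap, with component
# breakdown, plus an independent parcel-tracking oracle. A tap's HRT is the
# sum of (i) regulated storage in every tank on its supply path, (ii) travel
# up the pumped riser legs, (iii) travel down the gravity down-feed standpipe,
# and (iv) travel along the on-floor horizontal line. Each pipe segment
# contributes volume / steady flow, where the flow is the summed average
# demand of every floor the segment delivers to.

#' Travel time up a pumped riser leg
#'
#' Time for water to rise from a tank to the storey where its zone's
#' down-feed begins. Each traversed storey contributes its own standpipe
#' volume; the leg carries the total demand of every floor ultimately fed
#' from the tank, so for uniform geometry the time is
#' \eqn{N \cdot V_s / Q_{riser}} over \eqn{N} storeys.
#'
#' @param topology A [building_topology()].
#' @param tank Tank object or id; the leg starts at this tank's floor.
#' @param entry_floor Storey where the leg ends (down-feed entry or the next
#'   tank's floor).
#' @return Seconds.
#' @export
riser_travel_time <- function(topology, tank, entry_floor) {
  tank <- resolve_tank(topology, tank)
  q <- riser_flow(topology, tank)
  if (q <= 0) {
    stop_swss("stagnant_riser", sprintf("riser from tank %s carries no flow", tank$id))
  }
  if (entry_floor <= tank$floor_index) return(0)
  storeys <- seq(tank$floor_index + 1L, entry_floor)
  sum(vapply(storeys, function(s) storey_volume(topology, s), 0)) / q
}

#' Travel time down a gravity down-feed to a tap's storey
#'
#' Sums, over each storey from the tap's floor up to the zone's down-feed
#' entry, that storey's standpipe volume divided by the cumulative demand the
#' segment carries ([downstream_demand()]). Storeys above the top served
#' floor (when the entry floor is higher) carry the whole zone's demand.
#'
#' @param topology A [building_topology()].
#' @param zone Zone object or id.
#' @param floor_k Served storey of the tap.
#' @return Seconds.
#' @export
downfeed_travel_time <- function(topology, zone, floor_k) {
  zone <- resolve_zone(topology, zone)
  if (floor_k < zone$served_floors[1] || floor_k > zone$served_floors[2]) {
    stop_swss("out_of_zone",
              sprintf("floor %d not served by zone %s", floor_k, zone$id))
  }
  total <- 0
  for (j in seq(floor_k, zone$entry_floor)) {
    q <- downstream_demand(topology, zone, min(j, zone$served_floors[2]))
    if (q <= 0) {
      stop_swss("stagnant_segment",
                sprintf("down-feed segment at floor %d of zone %s carries no flow",
                        j, zone$id))
    }
    total <- total + storey_volume(topology, j) / q
  }
  total
}

# Ordered riser legs for a zone: one per upstream tank, ending at the next
# tank's floor (inter-tank leg) or at the zone's down-feed entry (last leg).
riser_legs <- function(topology, zone) {
  chain <- lapply(zone$upstream_tanks, resolve_tank, topology = topology)
  lapply(seq_along(chain), function(m) {
    to <- if (m < length(chain)) chain[[m + 1L]]$floor_index else zone$entry_floor
    list(tank = chain[[m]], to = to)
  })
}

#' Hydraulic retention time at one tap
#'
#' @param topology A [building_topology()].
#' @param floor_k Storey of the tap; must be served by a zone.
#' @return A list with `floor`, `zone`, the four components in seconds
#'   (`tank_s`, `riser_s`, `downfeed_s`, `horizontal_s`), their sum `hrt_s`,
#'   and `status` (`"ok"`, or `"stagnant"` with `hrt_s = NA` when some
#'   traversed segment or the tap itself carries no flow).
#' @export
tap_hrt <- function(topology, floor_k) {
  fr <- floor_row(topology, floor_k)
  if (!is.null(fr) && fr$supply_label == "mains-direct") {
    stop_swss("unmodeled_floor",
              sprintf("floor %d is supplied directly by the mains; its water age is not modelled",
                      floor_k))
  }
  zone <- zone_of_floor(topology, floor_k)
  if (is.null(zone) || is.null(fr)) {
    stop_swss("unmodeled_floor", sprintf("floor %d is not served by any zone", floor_k))
  }
  tank_s <- sum(vapply(zone$upstream_tanks,
                       function(id) resolve_tank(topology, id)$hrt, 0))
  out <- list(floor = floor_k, zone = zone$id, tank_s = tank_s,
              riser_s = NA_real_, downfeed_s = NA_real_,
              horizontal_s = NA_real_, hrt_s = NA_real_, status = "stagnant")
  ok <- tryCatch({
    out$riser_s <- sum(vapply(riser_legs(topology, zone), function(leg) {
      riser_travel_time(topology, leg$tank, leg$to)
    }, 0))
    out$downfeed_s <- downfeed_travel_time(topology, zone, floor_k)
    if (fr$demand <= 0) {
      stop_swss("stagnant_tap", sprintf("tap at floor %d has zero demand", floor_k))
    }
    out$horizontal_s <- segment_volume(fr$horizontal_diameter, fr$horizontal_length) /
      fr$demand
    TRUE
  }, swsshrt_stagnant_riser = function(e) FALSE,
     swsshrt_stagnant_segment = function(e) FALSE,
     swsshrt_stagnant_tap = function(e) FALSE)
  if (ok) {
    out$hrt_s <- out$tank_s + out$riser_s + out$downfeed_s + out$horizontal_s
    out$status <- "ok"
  }
  out
}

#' Per-floor HRT profile of a building
#'
#' @param topology A valid [building_topology()].
#' @return Data frame with one row per served floor: `building`, `floor`,
#'   `zone`, `supply_label`, the four HRT components and total in seconds,
#'   the total in hours, and a `status` column. Stagnant floors carry `NA`
#'   times and status `"stagnant"`.
#' @export
hrt_profile <- function(topology) {
  violations <- validate_topology(topology)
  if (length(violations) > 0) {
    stop_swss("invalid_topology",
              paste(c("invalid topology:", violations), collapse = "\n  "))
  }
  served <- sort(unique(unlist(lapply(topology$zones, function(z) {
    zone_floor_indices(topology, z)
  }))))
  rows <- lapply(served, function(k) {
    h <- tap_hrt(topology, k)
    data.frame(building = topology$name, floor = k, zone = h$zone,
               supply_label = floor_row(topology, k)$supply_label,
               tank_s = h$tank_s, riser_s = h$riser_s,
               downfeed_s = h$downfeed_s, horizontal_s = h$horizontal_s,
               hrt_s = h$hrt_s, hrt_h = h$hrt_s / 3600, status = h$status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write an HRT profile as CSV
#'
#' Undefined (stagnant) rows keep their status label and empty time fields.
#'
#' @param profile Output of [hrt_profile()].
#' @param path Output path (written atomically).
#' @return `path`, invisibly.
#' @export
write_hrt_profile <- function(profile, path) {
  atomic_write(path, function(tmp) {
    utils::write.csv(profile, tmp, row.names = FALSE, na = "")
  })
  invisible(path)
}

# Physical supply path to a tap as an ordered list of elements:
# tanks (dwell time) and pipe segments (volume, length, flow, area).
# Built directly from the topology's geometry, independently of the closed-
# form travel-time expressions, so the parcel oracle exercises the same
# hydraulics through different code.
parcel_path <- function(topology, floor_k) {
  fr <- floor_row(topology, floor_k)
  zone <- zone_of_floor(topology, floor_k)
  if (is.null(zone) || is.null(fr)) {
    stop_swss("unmodeled_floor", sprintf("floor %d is not served by any zone", floor_k))
  }
  path <- list()
  pipe_el <- function(storey, flow) {
    f <- floor_row(topology, storey)
    d <- if (is.null(f)) topology$defaults$standpipe_diameter else f$standpipe_diameter
    h <- if (is.null(f)) topology$defaults$height else f$height
    list(type = "pipe", length = h, area = (pi / 4) * d^2,
         volume = segment_volume(d, h), flow = flow)
  }
  chain <- lapply(zone$upstream_tanks, resolve_tank, topology = topology)
  for (m in seq_along(chain)) {
    tk <- chain[[m]]
    path[[length(path) + 1L]] <- list(type = "tank", dwell = tk$hrt)
    to <- if (m < length(chain)) chain[[m + 1L]]$floor_index else zone$entry_floor
    q <- riser_flow(topology, tk)
    if (to > tk$floor_index) {
      for (s in seq(tk$floor_index + 1L, to)) {
        path[[length(path) + 1L]] <- pipe_el(s, q)
      }
    }
  }
  for (j in rev(seq(floor_k, zone$entry_floor))) {
    q <- downstream_demand(topology, zone, min(j, zone$served_floors[2]))
    path[[length(path) + 1L]] <- pipe_el(j, q)
  }
  dh <- fr$horizontal_diameter
  path[[length(path) + 1L]] <- list(type = "pipe", length = fr$horizontal_length,
                                    area = (pi / 4) * dh^2,
                                    volume = segment_volume(dh, fr$horizontal_length),
                                    flow = fr$demand)
  path
}

#' Parcel-tracking oracle for a tap's HRT
#'
#' Follows one parcel of water from the inlet tank to the tap along the
#' physical supply path: it dwells in each tank for the tank's regulated
#' residence time, then moves through every pipe segment at the plug-flow
#' velocity (flow / cross-section area). With `dt = NULL` each segment is
#' crossed in exactly volume/flow (event-based, matches the analytic
#' [tap_hrt()] to machine precision); with a positive `dt` the parcel is
#' advanced in fixed time steps and the crossing time is the first whole
#' step count that clears the segment, an O(dt)-accurate discretisation.
#'
#' @param topology A [building_topology()].
#' @param floor_k Served storey of the tap.
#' @param dt Time step in seconds, or `NULL` for the event-based variant.
#' @return Elapsed time in seconds.
#' @export
simulate_parcel_oracle <- function(topology, floor_k, dt = NULL) {
  path <- parcel_path(topology, floor_k)
  for (el in path) {
    if (el$type == "pipe" && el$flow <= 0) {
      stop_swss("stagnant_segment", "parcel reached a segment with no flow")
    }
  }
  t_total <- 0
  for (el in path) {
    if (el$type == "tank") {
      t_total <- t_total + el$dwell
    } else if (el$length > 0) {
      if (is.null(dt)) {
        t_total <- t_total + el$volume / el$flow
      } else {
        stopifnot(dt > 0)
        v <- el$flow / el$area
        t_total <- t_total + ceiling((el$length / v) / dt - 1e-12) * dt
      }
    }
  }
  t_total
}
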