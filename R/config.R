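# Structured-text (YAML/JSON) serialisation of building topologies.
# Schema: building -> name, functional_area, pipe_material, tap_material,
# defaults {height, standpipe_diameter}, floors [...], tanks [...], zones [...].
# Each floor gives exactly one of `demand` (m^3/s) or `monthly_demand`
# (t/month); tank residence times are `hrt_s`.

#' Read a building topology from a YAML or JSON config
#'
#' @param path File path; `.json` is parsed with jsonlite, anything else
#'   with yaml.
#' @return A validated [building_topology()]; raises an aggregated error if
#'   the config fails [validate_topology()].
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop_swss("io", sprintf("no such config: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  topology_from_list(cfg)
}

# Build a topology from the parsed config list; shared by YAML and JSON.
topology_from_list <- function(cfg, validate = TRUE) {
  b <- cfg$building
  if (is.null(b)) stop_swss("config", "config has no 'building' section")
  defaults <- list(height = b$defaults$height %||% 3,
                   standpipe_diameter = b$defaults$standpipe_diameter %||% 0.05)
  floors <- do.call(rbind, lapply(b$floors, function(f) {
    floor_spec(index = f$index,
               height = f$height %||% defaults$height,
               demand = f$demand,
               monthly_demand = f$monthly_demand,
               standpipe_diameter = f$standpipe_diameter %||% defaults$standpipe_diameter,
               horizontal_diameter = f$horizontal_diameter %||% 0.025,
               horizontal_length = f$horizontal_length %||% 10,
               supply_label = f$supply_label %||% "swss-first")
  }))
  tanks <- lapply(b$tanks, function(t) tank_spec(t$id, t$floor_index, t$hrt_s))
  zones <- lapply(b$zones, function(z) {
    zone_spec(z$id, z$source_tank, z$entry_floor,
              unlist(z$served_floors),
              unlist(z$upstream_tanks %||% z$source_tank))
  })
  topo <- building_topology(name = b$name %||% "building",
                            floors = floors, tanks = tanks, zones = zones,
                            functional_area = b$functional_area %||% "office",
                            pipe_material = b$pipe_material %||% "galvanized-steel",
                            tap_material = b$tap_material %||% "stainless-steel",
                            defaults = defaults)
  if (validate) {
    violations <- validate_topology(topo)
    if (length(violations) > 0) {
      stop_swss("invalid_topology",
                paste(c("invalid topology config:", violations), collapse = "\n  "))
    }
  }
  topo
}

#' Write a building topology as an editable YAML config
#'
#' Round-trips through [read_topology()] to an equivalent topology.
#'
#' @param topology A [building_topology()].
#' @param path Output path (written atomically).
#' @return `path`, invisibly.
#' @export
write_topology <- function(topology, path) {
  fl <- topology$floors
  floors <- lapply(seq_len(nrow(fl)), function(i) {
    list(index = fl$index[i], height = fl$height[i], demand = fl$demand[i],
         standpipe_diameter = fl$standpipe_diameter[i],
         horizontal_diameter = fl$horizontal_diameter[i],
         horizontal_length = fl$horizontal_length[i],
         supply_label = fl$supply_label[i])
  })
  tanks <- lapply(unname(topology$tanks), function(t) {
    list(id = t$id, floor_index = t$floor_index, hrt_s = t$hrt)
  })
  zones <- lapply(unname(topology$zones), function(z) {
    list(id = z$id, source_tank = z$source_tank, entry_floor = z$entry_floor,
         served_floors = z$served_floors, upstream_tanks = z$upstream_tanks)
  })
  cfg <- list(building = list(name = topology$name,
                              functional_area = topology$functional_area,
                              pipe_material = topology$pipe_material,
                              tap_material = topology$tap_material,
                              defaults = topology$defaults,
                              floors = floors, tanks = tanks, zones = zones))
  atomic_write(path, function(tmp) yaml::write_yaml(cfg, tmp))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write via a temp file in the target directory + atomic rename, so a failed
# run never leaves a partial output behind.
atomic_write <- function(path, writer) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop_swss("io", sprintf("cannot write %s", path))
  invisible(path)
}
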