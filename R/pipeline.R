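# Configuration-driven pipeline chaining topology -> HRT -> synthetic
# observations -> association analysis, with a structured run log. All
# outputs are plain text (CSV / YAML), written atomically, and byte-
# reproducible from (config, seed, package version).

#' Load a pipeline run configuration
#'
#' A run config is YAML/JSON with fields: `topology` (path to a building
#' config), `out_dir`, `seed` (required for any stochastic stage),
#' `permutations` (B for the permutation test, default 999), `n_taps`
#' (optional tap count), `generator` (overrides for [generator_params()]),
#' `pairs` (list of two-element `[x, y]` column pairs to associate), and
#' `digits` (report formatting).
#'
#' @param config Path to a YAML/JSON file, or an equivalent named list.
#' @return A `run_config` list with defaults filled in.
#' @export
run_config <- function(config) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop_swss("io", sprintf("no such config: %s", config))
    if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  } else {
    config
  }
  if (is.null(cfg$topology)) stop_swss("config", "run config needs a 'topology' path")
  cfg$out_dir <- cfg$out_dir %||% "."
  cfg$permutations <- as.integer(cfg$permutations %||% 999L)
  cfg$digits <- as.integer(cfg$digits %||% 3L)
  cfg$pairs <- cfg$pairs %||% list(c("hrt_h", "log10_16s"),
                                   c("hrt_h", "fe"),
                                   c("log10_16s", "zn"))
  cfg$source_path <- if (is.character(config)) config else NA_character_
  structure(cfg, class = "run_config")
}

config_generator_params <- function(cfg) {
  if (is.null(cfg$seed)) {
    stop_swss("config", "a seed is required when stochastic stages run")
  }
  over <- cfg$generator %||% list()
  over$seed <- cfg$seed
  do.call(generator_params, over)
}

#' Write a ready-made building config to edit
#'
#' @param which `"office"` or `"residential"`.
#' @param out_path Destination YAML path.
#' @return `out_path`, invisibly.
#' @export
cmd_build_example <- function(which, out_path) {
  topo <- switch(which,
                 office = office_topology(),
                 residential = residential_topology(),
                 stop_swss("usage", "which must be 'office' or 'residential'"))
  write_topology(topo, out_path)
}

#' Validate a building config and report violations
#'
#' @param topology_path Path to a building config.
#' @return Character vector of violations (empty when valid).
#' @export
cmd_validate <- function(topology_path) {
  cfg <- if (grepl("\\.json$", topology_path, ignore.case = TRUE)) {
    jsonlite::read_json(topology_path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(topology_path)
  }
  validate_topology(topology_from_list(cfg, validate = FALSE))
}

#' Compute and write an HRT profile
#'
#' @param topology_path Path to a building config.
#' @param out_path Destination CSV.
#' @return The profile data frame, invisibly.
#' @export
cmd_compute_hrt <- function(topology_path, out_path) {
  topo <- read_topology(topology_path)
  prof <- hrt_profile(topo)
  write_hrt_profile(prof, out_path)
  invisible(prof)
}

#' Generate and write synthetic tap observations
#'
#' @param cfg A [run_config()] (or path/list coercible to one).
#' @param out_path Destination CSV; defaults to `observations.csv` under the
#'   config's output directory.
#' @return The observations data frame, invisibly.
#' @export
cmd_simulate <- function(cfg, out_path = NULL) {
  cfg <- run_config(cfg)
  params <- config_generator_params(cfg)
  topo <- read_topology(cfg$topology)
  obs <- generate_observations(topo, params, n_taps = cfg$n_taps)
  out_path <- out_path %||% file.path(cfg$out_dir, "observations.csv")
  write_observations(obs, out_path, params = params)
  invisible(obs)
}

#' Run association analyses over configured variable pairs
#'
#' @param obs Observations data frame or path to an observations CSV.
#' @param pairs List of two-element `c(x, y)` column-name pairs.
#' @param B Permutations for each p-value.
#' @param seed Integer seed.
#' @param out_path Optional YAML destination for the report.
#' @return List of `swss_association` results, invisibly when written.
#' @export
cmd_associate <- function(obs, pairs, B = 999L, seed = 1L, out_path = NULL) {
  if (is.character(obs)) obs <- utils::read.csv(obs)
  res <- lapply(pairs, function(p) associate(obs, p[[1]], p[[2]], B = B, seed = seed))
  if (!is.null(out_path)) {
    atomic_write(out_path, function(tmp) {
      yaml::write_yaml(lapply(res, unclass), tmp)
    })
    return(invisible(res))
  }
  res
}

#' Run the full pipeline
#'
#' Reads the building config, writes the HRT profile, generates synthetic
#' observations, runs every configured association, and writes a structured
#' run log with the package version, seed, input hash and output hashes.
#' Rerunning with the same config and seed reproduces every file
#' byte-for-byte.
#'
#' @param cfg A [run_config()] (or path/list coercible to one).
#' @return Named list with `profile`, `observations`, `associations`,
#'   `files`, invisibly.
#' @export
cmd_full_run <- function(cfg) {
  cfg <- run_config(cfg)
  params <- config_generator_params(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  topo <- read_topology(cfg$topology)

  prof_path <- file.path(cfg$out_dir, "hrt_profile.csv")
  prof <- hrt_profile(topo)
  write_hrt_profile(prof, prof_path)

  obs_path <- file.path(cfg$out_dir, "observations.csv")
  obs <- generate_observations(topo, params, n_taps = cfg$n_taps)
  write_observations(obs, obs_path, params = params)

  assoc_path <- file.path(cfg$out_dir, "associations.yaml")
  res <- cmd_associate(obs, cfg$pairs, B = cfg$permutations,
                       seed = cfg$seed, out_path = assoc_path)

  files <- c(profile = prof_path, observations = obs_path,
             associations = assoc_path)
  log_path <- file.path(cfg$out_dir, "run_log.yaml")
  atomic_write(log_path, function(tmp) {
    yaml::write_yaml(list(
      package = "swsshrt",
      version = as.character(utils::packageVersion("swsshrt")),
      seed = cfg$seed,
      permutations = cfg$permutations,
      topology = cfg$topology,
      topology_md5 = unname(tools::md5sum(cfg$topology)),
      outputs = lapply(stats::setNames(as.list(files), names(files)),
                       function(p) list(path = p, md5 = unname(tools::md5sum(p))))
    ), tmp)
  })
  invisible(list(profile = prof, observations = obs,
                 associations = res, files = c(files, log = log_path)))
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands: `build-example`, `validate`,
#' `compute-hrt`, `simulate`, `associate`, `full-run`. Installed as the
#' executable script `exec/swsshrt`; call as e.g.
#' `swsshrt full-run --config run.yaml`.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
swss_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: swsshrt <command> [flags]",
    "  build-example --which office|residential --out FILE",
    "  validate      --topology FILE",
    "  compute-hrt   --topology FILE --out FILE",
    "  simulate      --config FILE [--seed N] [--out FILE]",
    "  associate     --config FILE [--seed N] [--permutations B]",
    "  full-run      --config FILE [--seed N] [--permutations B] [--out DIR]",
    sep = "\n")
  status <- tryCatch({
    if (length(args) == 0L) stop_swss("usage", usage)
    cmd <- args[[1]]
    flags <- parse_flags(args[-1])
    load_cfg <- function() {
      if (is.null(flags$config)) stop_swss("usage", "--config is required")
      cfg <- run_config(flags$config)
      if (!is.null(flags$seed)) cfg$seed <- as.integer(flags$seed)
      if (!is.null(flags$permutations)) cfg$permutations <- as.integer(flags$permutations)
      if (!is.null(flags$out)) cfg$out_dir <- flags$out
      cfg
    }
    switch(cmd,
      "build-example" = {
        if (is.null(flags$which) || is.null(flags$out)) {
          stop_swss("usage", "build-example needs --which and --out")
        }
        cmd_build_example(flags$which, flags$out)
        message(sprintf("wrote %s topology to %s", flags$which, flags$out))
      },
      "validate" = {
        if (is.null(flags$topology)) stop_swss("usage", "validate needs --topology")
        v <- cmd_validate(flags$topology)
        if (length(v) > 0) {
          message(paste(c("topology violations:", paste(" -", v)), collapse = "\n"))
          return(invisible(1L))
        }
        message("topology is valid")
      },
      "compute-hrt" = {
        if (is.null(flags$topology) || is.null(flags$out)) {
          stop_swss("usage", "compute-hrt needs --topology and --out")
        }
        prof <- cmd_compute_hrt(flags$topology, flags$out)
        message(sprintf("wrote %d rows to %s", nrow(prof), flags$out))
      },
      "simulate" = {
        cfg <- load_cfg()
        obs <- cmd_simulate(cfg)
        message(sprintf("wrote %d observations under %s", nrow(obs), cfg$out_dir))
      },
      "associate" = {
        cfg <- load_cfg()
        obs_path <- file.path(cfg$out_dir, "observations.csv")
        res <- cmd_associate(obs_path, cfg$pairs, B = cfg$permutations,
                             seed = cfg$seed %||% 1L,
                             out_path = file.path(cfg$out_dir, "associations.yaml"))
        for (r in res) print(r)
      },
      "full-run" = {
        cfg <- load_cfg()
        out <- cmd_full_run(cfg)
        message(paste(sprintf("wrote %s", out$files), collapse = "\n"))
      },
      stop_swss("usage", paste0("unknown command '", cmd, "'\n", usage)))
    0L
  }, swsshrt_error = function(e) {
    message(conditionMessage(e))
    1L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(as.integer(status))
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop_swss("usage", sprintf("unexpected argument '%s'", a))
    key <- substring(a, 3)
    if (key == "verbose") {
      flags$verbose <- TRUE
      i <- i + 1L
    } else {
      if (i == length(args)) stop_swss("usage", sprintf("flag --%s needs a value", key))
      flags[[key]] <- args[[i + 1L]]
      i <- i + 2L
    }
  }
  flags
}
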