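# Configuration files, parameter/dataset serialization, run manifests.

rg_config_schema <- function() {
  list(
    plant = list(total_mass_kg = 74.5, height_m = 1.80,
                 gravity_mps2 = 9.81, dt_s = 5e-4),
    episode = list(t_max_s = 50, fall_height_m = 0.9, record_dt_s = 0.01,
                   transient_s = 10),
    cma = list(sigma0 = 0.01, n_seeds = 20, improve_tol = 1e-5,
               improve_window = 500, max_gen = 3000),
    smf = list(n_key = 30, d_reg = 3, grid_min_mps = 0.5,
               grid_max_mps = 3.5, grid_step_mps = 0.025),
    schedule = list(v_a_mps = 0.05, settle_s = 20, quantum_mps = 0.025))
}

check_units_by_suffix <- function(section, key, value) {
  positive <- c("_s", "_m", "_kg", "_mps", "_mps2")
  for (suf in positive) {
    if (endsWith(key, suf)) {
      if (!is.numeric(value) || !isTRUE(value > 0))
        stop(sprintf("validation error: '%s$%s' (%s) must be a positive number",
                     section, key, sub("^_", "", suf)))
      return(invisible(TRUE))
    }
  }
  invisible(TRUE)
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration, checks it against the known schema (unknown
#' keys and missing sections are named validation errors), fills defaults
#' (e.g. `t_max_s` 50, `sigma0` 0.01, `grid_step_mps` 0.025), and checks
#' units by key suffix (`_s`, `_m`, `_kg`, `_mps`, `_mps2` entries must be
#' positive numbers).
#'
#' @param path Path to the YAML file.
#' @return Object of class `rg_config` (validated nested list).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  validate_config(raw)
}

#' Validate a configuration list against the schema
#' @param raw Nested configuration list.
#' @return Object of class `rg_config` with defaults filled.
#' @export
validate_config <- function(raw) {
  schema <- rg_config_schema()
  unknown_sections <- setdiff(names(raw), names(schema))
  if (length(unknown_sections))
    stop("validation error: unknown section(s): ",
         paste(unknown_sections, collapse = ", "))
  cfg <- schema
  for (sec in names(raw)) {
    unknown <- setdiff(names(raw[[sec]]), names(schema[[sec]]))
    if (length(unknown))
      stop(sprintf("validation error: unknown key(s) in '%s': %s", sec,
                   paste(unknown, collapse = ", ")))
    for (key in names(raw[[sec]])) {
      val <- raw[[sec]][[key]]
      check_units_by_suffix(sec, key, val)
      cfg[[sec]][[key]] <- val
    }
  }
  if (!isTRUE(cfg$episode$t_max_s > 0))
    stop("validation error: 'episode$t_max_s' must be > 0")
  if (!isTRUE(cfg$cma$sigma0 > 0))
    stop("validation error: 'cma$sigma0' must be > 0")
  if (!cfg$smf$d_reg %in% 1:3)
    stop("validation error: 'smf$d_reg' must be 1, 2 or 3")
  structure(cfg, class = "rg_config")
}

#' Save a configuration to YAML
#' @param cfg An `rg_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Write a parameter vector to CSV
#'
#' Single-row CSV with the canonical headered columns
#' (`kL_<target>_<source>`, `kF_<target>_<source>`, `c_<muscle>`).
#'
#' @param p An `rg_params` or named canonical vector.
#' @param path Output path.
#' @param cm Connection matrix (needed when `p` is an unnamed vector).
#' @return `path`, invisibly.
#' @export
write_params_csv <- function(p, path, cm = NULL) {
  if (inherits(p, "rg_params")) {
    v <- encode_params(p)
  } else {
    v <- as.numeric(p)
    names(v) <- if (!is.null(cm)) param_names(cm) else names(p)
  }
  if (is.null(names(v))) stop("parameter vector must be named (or give cm)")
  df <- as.data.frame(as.list(v), check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a parameter vector from CSV
#' @param path CSV path (single row, canonical columns).
#' @param cm Connection matrix to decode against.
#' @return An `rg_params`.
#' @export
read_params_csv <- function(path, cm = build_connection_matrix()) {
  df <- read.csv(path, check.names = FALSE)
  if (nrow(df) != 1) stop("parameter CSV must have exactly one row")
  want <- param_names(cm)
  if (!all(want %in% names(df)))
    stop("parameter CSV is missing canonical columns")
  decode_params(as.numeric(df[1, want]), cm)
}

#' Write/read a parameter set as JSON
#' @param p An `rg_params`.
#' @param path File path.
#' @return `path` (write) or an `rg_params` (read).
#' @export
write_params_json <- function(p, path) {
  stopifnot(inherits(p, "rg_params"))
  jsonlite::write_json(list(kL = p$kL, kF = p$kF, c = p$c), path,
                       digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_params_json
#' @param cm Connection matrix to attach on read.
#' @export
read_params_json <- function(path, cm = build_connection_matrix()) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  reflex_params(x$kL, x$kF, x$c, cm)
}

#' Write a speed dataset to CSV
#'
#' Canonical parameter columns plus `v_act`, `stable` and provenance
#' columns (`seed`, `gen`, `direction`).
#'
#' @param ds An `rg_speed_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(ds, path) {
  stopifnot(inherits(ds, "rg_speed_dataset"))
  df <- cbind(as.data.frame(ds$params, check.names = FALSE),
              v_act = ds$v_act, stable = ds$stable, ds$provenance)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a speed dataset from CSV
#' @param path CSV path written by [write_dataset_csv()].
#' @return An `rg_speed_dataset`.
#' @export
read_dataset_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  meta <- c("v_act", "stable", "seed", "gen", "direction")
  pcols <- setdiff(names(df), meta)
  new_speed_dataset(as.matrix(df[, pcols, drop = FALSE]), df$v_act,
                    df[, intersect(c("seed", "gen", "direction"),
                                   names(df)), drop = FALSE])
}

#' Export episode trajectories to CSV
#'
#' Time, generalized coordinates/velocities, total CoM, per-MTU
#' activation/force/CE length/stimulation and per-point contact forces.
#'
#' @param ep An `rg_episode`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_episode_csv <- function(ep, path) {
  stopifnot(inherits(ep, "rg_episode"))
  qn <- ep$dof_names
  df <- data.frame(t = ep$t, check.names = FALSE)
  add <- function(m, prefix) {
    m <- as.matrix(m)
    colnames(m) <- paste0(prefix, seq_len(ncol(m)))
    cbind(df, m)
  }
  q <- ep$q; colnames(q) <- qn
  qd <- ep$qd; colnames(qd) <- paste0("d_", qn)
  df <- cbind(df, q, qd, com_x = ep$com[, 1], com_y = ep$com[, 2])
  if (ncol(ep$act)) {
    df <- add(ep$act, "act_"); df <- add(ep$force, "force_")
    df <- add(ep$lce, "lce_"); df <- add(ep$stim, "stim_")
  }
  if (ncol(ep$contact_normal)) {
    df <- add(ep$contact_normal, "fn_")
    df <- add(ep$contact_tangential, "ft_")
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records configuration paths with content hashes, RNG seeds, the stage
#' list, the package version and a timestamp, so identical manifests
#' reproduce identical deterministic outputs.
#'
#' @param out_dir Output directory (created if needed); the manifest is
#'   written as `manifest.json` inside it.
#' @param config_paths Character vector of input configuration files.
#' @param seeds Named list/vector of every RNG seed used.
#' @param stages Character vector of pipeline stages run.
#' @return The manifest list, invisibly.
#' @export
run_manifest <- function(out_dir, config_paths = character(0), seeds = list(),
                         stages = character(0)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hashes <- if (length(config_paths))
    as.list(tools::md5sum(config_paths)) else list()
  man <- list(tool = "reflexgait",
              version = as.character(utils::packageVersion("reflexgait")),
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              config_paths = as.list(config_paths),
              config_md5 = hashes,
              seeds = as.list(seeds),
              stages = as.list(stages),
              out_dir = out_dir)
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(man)
}
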