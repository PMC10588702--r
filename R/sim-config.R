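# Simulation configuration: a single YAML document holding the fixture (or
# mesh path), force and solver parameters, colliders, interaction script,
# step count and output settings. All physics defaults live here, not in
# code paths; unknown keys are rejected so typos fail loudly.

sim_config_defaults <- function() {
  list(
    fixture = list(type = "phantom", subdivision = 3L,
                   kidney_scale = c(0.055, 0.035, 0.030),
                   tumor_fraction = 0.35,
                   tumor_direction = c(1, 0.35, 0.25)),
    mesh = NULL,
    forces = list(k_spring = 50, damping = 0.5, pressure = 0,
                  offset_magnitude = 0, offset_mode = "inward-normal",
                  dt = 0.01),
    solver = list(iterations = 4L, k_str = 0.9, k_bend = 0.5,
                  break_mode = "relative", break_threshold = 0.4,
                  breakable = FALSE),
    colliders = list(planes = list()),
    interaction = NULL,
    steps = 100L,
    seed = 1L,
    frame_stride = 0L,
    metrics_stride = 1L)
}

#' Build a simulation configuration
#'
#' Merges user settings over the documented defaults (see the package
#' vignette for the full table) and validates every invariant. Unknown keys
#' at any level are rejected.
#'
#' @param ... named top-level settings (`fixture`, `mesh`, `forces`,
#'   `solver`, `colliders`, `interaction`, `steps`, `seed`,
#'   `frame_stride`, `metrics_stride`).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(...) {
  user <- list(...)
  cfg <- merge_config(sim_config_defaults(), user, path = "")
  res <- check_config(cfg)
  bad <- res$check[!res$pass]
  if (length(bad) > 0L)
    stop(sprintf("invalid configuration: %s", paste(bad, collapse = "; ")))
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read config '%s'", path))
  y <- yaml::read_yaml(path)
  do.call(sim_config, y)
}

merge_config <- function(def, user, path) {
  unknown <- setdiff(names(user), names(def))
  if (length(unknown) > 0L)
    stop(sprintf("unknown configuration key(s): %s",
                 paste0(path, unknown, collapse = ", ")))
  for (k in names(user)) {
    if (is.list(def[[k]]) && is.list(user[[k]]) &&
        !is.null(names(def[[k]])) && k != "colliders" && k != "interaction" &&
        k != "fixture") {
      def[[k]] <- merge_config(def[[k]], user[[k]], paste0(path, k, "."))
    } else {
      def[[k]] <- user[[k]]
    }
  }
  def
}

#' Validate a configuration (or config file)
#'
#' Runs every invariant check — time-step/damping bound, stiffness ranges,
#' fixture validity and mesh manifoldness — and reports pass/fail per
#' check.
#'
#' @param config a `sim_config`, a raw list, or a YAML file path.
#' @return data frame with columns `check` and `pass`.
#' @export
validate_sim_config <- function(config) {
  if (is.character(config)) {
    y <- yaml::read_yaml(config)
    config <- tryCatch(merge_config(sim_config_defaults(), y, ""),
                       error = function(e) {
                         return(NULL)
                       })
    if (is.null(config))
      return(data.frame(check = "known keys only", pass = FALSE))
  }
  check_config(config)
}

check_config <- function(cfg) {
  checks <- list()
  add <- function(name, ok) checks[[length(checks) + 1L]] <<- list(name, isTRUE(ok))
  fr <- cfg$forces
  add("dt > 0", fr$dt > 0)
  add("damping*dt in [0,1]", fr$damping >= 0 && fr$damping * fr$dt <= 1)
  add("k_spring >= 0", fr$k_spring >= 0)
  add("spring stability heuristic k*dt^2 <= 1", fr$k_spring * fr$dt^2 <= 1)
  so <- cfg$solver
  add("solver iterations >= 1", so$iterations >= 1)
  add("k_str in [0,1]", so$k_str >= 0 && so$k_str <= 1)
  add("k_bend in [0,1]", so$k_bend >= 0 && so$k_bend <= 1)
  add("break threshold > 0", is.null(so$break_threshold) || so$break_threshold > 0)
  add("steps >= 0", cfg$steps >= 0)
  add("frame_stride >= 0", cfg$frame_stride >= 0)
  mesh_ok <- TRUE; manifold_ok <- TRUE
  m <- tryCatch(config_mesh(cfg), error = function(e) e)
  if (inherits(m, "error")) {
    mesh_ok <- FALSE; manifold_ok <- FALSE
  } else {
    manifold_ok <- !inherits(tryCatch(build_edge_topology(m),
                                      error = function(e) e), "error")
  }
  add("fixture/mesh loadable", mesh_ok)
  add("mesh manifold", manifold_ok)
  data.frame(check = vapply(checks, `[[`, "", 1L),
             pass = vapply(checks, `[[`, TRUE, 2L))
}

# materialize the configured geometry
config_mesh <- function(cfg) {
  if (!is.null(cfg$mesh)) return(load_mesh(cfg$mesh))
  fx <- cfg$fixture
  switch(fx$type %||% "phantom",
         phantom = make_kidney_phantom(phantom_spec(
           subdivision = fx$subdivision %||% 3L,
           kidney_scale = unlist(fx$kidney_scale %||% c(0.055, 0.035, 0.030)),
           tumor_fraction = fx$tumor_fraction %||% 0.35,
           tumor_direction = unlist(fx$tumor_direction %||% c(1, 0.35, 0.25)),
           seed = fx$seed %||% 1L)),
         icosphere = make_icosphere(fx$subdivision %||% 2L,
                                    fx$radius %||% 1),
         grid = make_grid_sheet(fx$nx %||% 5L, fx$ny %||% 5L,
                                fx$spacing %||% 1),
         stop(sprintf("unknown fixture type '%s'", fx$type)))
}
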