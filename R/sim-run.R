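# Batch simulation driver: executes the hybrid loop (force integration ->
# PBD solve -> tear -> interaction events), logs per-step metrics, exports
# OBJ frames at a stride, and writes a versioned JSON run report.
# (config, seed) fully determines every metric and frame byte; the report
# is deterministic except its wall_time_s field.

METRICS_SCHEMA <- "kidneysim-metrics-1"
REPORT_SCHEMA <- "kidneysim-report-1"

#' Run a configured simulation
#'
#' Per step: scripted interaction forces are accumulated, the force model
#' integrates velocities, the PBD solver projects constraints and moves
#' positions, and over-stretched breakable constraints tear. A scripted cut
#' is applied at its step; a scripted resection runs after the loop.
#'
#' @param config a [sim_config()] (or YAML path).
#' @param out_dir output directory (created); `NULL` disables file output.
#' @return list with `state`, `constraints`, `mesh`, `metrics` (data
#'   frame), `report` (list), `resection` (when scripted). Files written:
#'   `metrics.csv`, `report.json`, `frames/frame_%06d.obj`.
#' @export
run_simulation <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_sim_config(config)
  t0 <- proc.time()[["elapsed"]]
  set.seed(config$seed)

  mesh <- config_mesh(config)
  topo <- build_edge_topology(mesh)
  fr <- config$forces
  params <- force_params(k_spring = fr$k_spring, damping = fr$damping,
                         pressure = fr$pressure,
                         offset_magnitude = fr$offset_magnitude,
                         offset_mode = fr$offset_mode, dt = fr$dt)
  so <- config$solver
  scfg <- solver_config(iterations = so$iterations, dt = fr$dt,
                        k_str = so$k_str, k_bend = so$k_bend,
                        break_mode = so$break_mode)
  constraints <- make_constraints(topo, scfg,
                                  breakable = isTRUE(so$breakable),
                                  break_threshold = so$break_threshold %||% 0.4)
  colliders <- config_colliders(config)
  script <- config_script(config)
  state <- soft_body_state(mesh)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (config$frame_stride > 0L)
      dir.create(file.path(out_dir, "frames"), showWarnings = FALSE)
  }
  write_frame <- function(step) {
    if (!is.null(out_dir) && config$frame_stride > 0L &&
        step %% config$frame_stride == 0L) {
      fm <- mesh; fm$vertices <- state$positions
      save_mesh(fm, file.path(out_dir, "frames",
                              sprintf("frame_%06d.obj", step)))
    }
  }

  rest_volume <- mesh_volume(mesh, warn_open = FALSE)
  metrics <- vector("list", config$steps)
  tear_log <- list()
  failure <- NULL
  cut_done <- FALSE
  last_cut <- NULL
  write_frame(0L)

  steps_run <- 0L
  for (step in seq_len(config$steps)) {
    res <- tryCatch({
      contact <- 0
      for (ev in script$pokes) {
        if (ev$step == step) {
          cp <- poke_contact_point(mesh, state, ev)
          if (!is.null(cp)) {
            state <- add_force_to_vertex(state, mesh, cp,
                                         as.numeric(ev$force),
                                         ev$radius %||% 0.02, params)
            contact <- contact + attr(state, "contact_force")
          }
        }
      }
      if (!cut_done && !is.null(script$cut) && script$cut$step == step) {
        cut <- resolve_cut_path(mesh, topo, script$cut, state)
        constraints <- apply_cut(constraints, cut,
                                 mode = script$cut$mode %||% "sever",
                                 break_threshold = so$break_threshold %||% 0.4)
        last_cut <- cut
        cut_done <- TRUE
      }
      state <- integrate_velocities(state, mesh, topo, params)
      state <- solve_step(state, constraints, scfg, colliders = colliders,
                          external_accel = script$gravity)
      torn <- tear_step(constraints, state$positions, mode = scfg$break_mode)
      constraints <- torn$constraints
      if (nrow(torn$removed) > 0L)
        tear_log[[length(tear_log) + 1L]] <-
          cbind(step = step, torn$removed)
      list(contact = contact, tears = nrow(torn$removed))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failure <- list(step = step, message = conditionMessage(res))
      break
    }
    steps_run <- step
    if (step %% config$metrics_stride == 0L) {
      s <- constraints$stretch
      cs <- if (nrow(s) > 0L)
        max(abs(eval_stretch(state$positions[s$i, , drop = FALSE],
                             state$positions[s$j, , drop = FALSE], s$d12)))
      else 0
      b <- constraints$bend
      cb <- if (nrow(b) > 0L) max(abs(bend_values(state$positions, b)), na.rm = TRUE)
      else 0
      metrics[[step]] <- data.frame(
        step = step,
        e_tot = total_energy(state$positions, constraints),
        volume = mesh_volume(mesh, state$positions, warn_open = FALSE),
        kinetic = kinetic_energy(state),
        max_cstr = cs, max_cbend = cb,
        n_constraints = nrow(s) + nrow(b),
        tears = res$tears,
        contact_force = res$contact)
    }
    write_frame(step)
  }
  metrics <- do.call(rbind, metrics[!vapply(metrics, is.null, TRUE)]) %||%
    empty_metrics()

  resection <- NULL
  if (!is.null(script$resect)) {
    cut <- if (cut_done) last_cut
    else resolve_cut_path(mesh, topo, script$resect, state)
    resection <- resect(mesh, cut, script$resect$region %||% "cancerous")
  }

  comps <- length(connected_components_from_constraints(mesh, constraints,
                                                        resection))
  report <- list(
    schema = REPORT_SCHEMA,
    config = unclass(config),
    steps_requested = config$steps,
    steps_run = steps_run,
    rest_volume = rest_volume,
    final_volume = mesh_volume(mesh, state$positions, warn_open = FALSE),
    tear_events = sum(vapply(tear_log, nrow, 1L)),
    final_components = comps,
    resection = if (!is.null(resection)) resection$report,
    failure = failure,
    wall_time_s = proc.time()[["elapsed"]] - t0)

  if (!is.null(out_dir)) {
    write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    if (length(tear_log) > 0L)
      write.csv(do.call(rbind, tear_log), file.path(out_dir, "tears.csv"),
                row.names = FALSE)
  }
  if (!is.null(failure))
    warning(sprintf("simulation aborted at step %d: %s (partial metrics kept)",
                    failure$step, failure$message))
  list(state = state, constraints = constraints, mesh = mesh,
       metrics = metrics, report = report, resection = resection)
}

empty_metrics <- function() {
  data.frame(step = integer(0), e_tot = numeric(0), volume = numeric(0),
             kinetic = numeric(0), max_cstr = numeric(0),
             max_cbend = numeric(0), n_constraints = integer(0),
             tears = integer(0), contact_force = numeric(0))
}

bend_values <- function(positions, b) {
  vapply(seq_len(nrow(b)), function(r)
    eval_bend(positions[b$x1[r], ], positions[b$x2[r], ],
              positions[b$x3[r], ], positions[b$x4[r], ], b$phi12[r]),
    numeric(1))
}

connected_components_from_constraints <- function(mesh, constraints, resection) {
  if (!is.null(resection)) {
    # after resection the split is explicit
    seq_len(2L)
  } else {
    memb <- constraint_graph_components(constraints, n_vertices(mesh))
    unique(memb)
  }
}

config_colliders <- function(cfg) {
  pl <- cfg$colliders$planes %||% list()
  if (length(pl) == 0L) return(NULL)
  collider_set(planes = lapply(pl, function(p)
    list(point = unlist(p$point), normal = unlist(p$normal))))
}

config_script <- function(cfg) {
  it <- cfg$interaction
  if (is.character(it)) it <- jsonlite::read_json(it, simplifyVector = FALSE)
  list(pokes = it$pokes %||% list(),
       cut = it$cut,
       resect = it$resect,
       gravity = if (!is.null(it$gravity)) unlist(it$gravity))
}

poke_contact_point <- function(mesh, state, ev) {
  if (!is.null(ev$point)) return(unlist(ev$point))
  r <- ray(unlist(ev$ray$origin), unlist(ev$ray$direction), normalize = TRUE)
  dm <- mesh; dm$vertices <- state$positions
  hit <- cast_ray(dm, r)
  if (is.null(hit)) NULL else hit$point
}

resolve_cut_path <- function(mesh, topo, spec, state) {
  if (!is.null(spec$samples)) {
    samples <- if (is.data.frame(spec$samples)) spec$samples
    else do.call(rbind, lapply(spec$samples, function(s)
      data.frame(x = s$point[[1L]], y = s$point[[2L]], z = s$point[[3L]],
                 face = s$face)))
    mark_cut_path(mesh, samples, topology = topo)
  } else {
    samples <- plan_boundary_cut(mesh, spec$region %||% "cancerous",
                                 topology = topo)
    mark_cut_path(mesh, samples, topology = topo)
  }
}
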