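# Force-based deformation core: per-vertex composite force assembled from
# spring, damping, pressure and offset components, interaction falloff, and
# semi-implicit Euler time integration.
#
# The damping component is written in the model as a velocity rescaling
# v <- v * (1 - d*dt); it is applied after force integration and plays the
# damping-force slot of the composite force. Integration order is fixed:
# accumulate forces -> dv = F/m * dt -> damping -> dp = v * dt.

#' Construct the per-vertex dynamic state of a soft body
#'
#' Positions, velocities, per-vertex masses and a force accumulator bound to
#' a triangle mesh. Pinned vertices are treated as infinite mass: they never
#' move and their velocity is zeroed after every step.
#'
#' @param mesh a [trimesh()].
#' @param masses scalar or per-vertex masses in kg (default 1, the model's
#'   unit-mass convention).
#' @param pinned integer vector of vertex indices to pin (optional).
#' @return object of class `soft_body_state` with matrices `positions`,
#'   `velocities`, `force_accum` (n x 3) and vectors `masses`, `pinned`.
#' @export
soft_body_state <- function(mesh, masses = 1, pinned = integer(0)) {
  n <- n_vertices(mesh)
  masses <- rep_len(as.numeric(masses), n)
  if (any(masses <= 0)) stop("masses must be > 0")
  pin <- rep(FALSE, n)
  pin[pinned] <- TRUE
  structure(list(positions = mesh$vertices,
                 velocities = matrix(0, n, 3L),
                 masses = masses,
                 force_accum = matrix(0, n, 3L),
                 pinned = pin,
                 step_count = 0L),
            class = "soft_body_state")
}

#' @export
print.soft_body_state <- function(x, ...) {
  cat(sprintf("soft_body_state: %d vertices (%d pinned), step %d\n",
              nrow(x$positions), sum(x$pinned), x$step_count))
  invisible(x)
}

#' Force model parameters
#'
#' @param k_spring spring stiffness (N/m) for edge springs.
#' @param damping velocity damping rate d (1/s); the per-step rescaling is
#'   `v * (1 - damping*dt)`, so `damping*dt` must lie in `[0, 1]`.
#' @param pressure P (N/m^2) applied along outward face normals; negative
#'   values deflate.
#' @param offset_magnitude magnitude (N) of the interaction offset force that
#'   drives contacted vertices along their inward normals.
#' @param offset_mode `"inward-normal"` (default) or `"fixed-direction"`.
#' @param offset_direction unit 3-vector, used when
#'   `offset_mode = "fixed-direction"`.
#' @param dt integration time step (s).
#' @return object of class `force_params`.
#' @export
force_params <- function(k_spring = 50, damping = 0.5, pressure = 0,
                         offset_magnitude = 0, offset_mode = "inward-normal",
                         offset_direction = c(0, 0, -1), dt = 0.01) {
  offset_mode <- match.arg(offset_mode, c("inward-normal", "fixed-direction"))
  p <- structure(list(k_spring = k_spring, damping = damping,
                      pressure = pressure,
                      offset_magnitude = offset_magnitude,
                      offset_mode = offset_mode,
                      offset_direction = offset_direction, dt = dt),
                 class = "force_params")
  validate_force_params(p)
  p
}

#' Validate force-parameter stability bounds
#'
#' Rejects `dt <= 0` and `damping*dt` outside `[0, 1]` (beyond 1 the
#' rescaling flips velocity sign); warns when `k_spring * dt^2` exceeds 1
#' per unit mass (explicit-integrator stiffness heuristic).
#'
#' @param p a `force_params`.
#' @param mass reference mass for the stiffness heuristic (default 1).
#' @return `p` invisibly.
#' @export
validate_force_params <- function(p, mass = 1) {
  if (p$dt <= 0) stop("dt must be > 0")
  if (p$damping < 0 || p$damping * p$dt > 1)
    stop("damping*dt must lie in [0, 1]")
  if (p$k_spring < 0) stop("k_spring must be >= 0")
  if (p$k_spring * p$dt^2 / mass > 1)
    warning("k_spring*dt^2/m > 1: explicit integration may be unstable")
  invisible(p)
}

#' Edge-spring forces (Hooke's law along each edge)
#'
#' For each edge `(i, j)` with rest length `d12`, a force of magnitude
#' `k_spring * (|x_i - x_j| - d12)` pulls the endpoints together (or pushes
#' apart when compressed), applied equal-and-opposite. Coincident endpoints
#' contribute nothing (direction undefined).
#'
#' @param topology an [build_edge_topology()] result from the rest mesh.
#' @param positions current n x 3 vertex positions.
#' @param k_spring stiffness (N/m).
#' @return n x 3 matrix of accumulated per-vertex forces (N).
#' @export
spring_forces <- function(topology, positions, k_spring) {
  e <- topology$edges
  d <- positions[e[, 2L], , drop = FALSE] - positions[e[, 1L], , drop = FALSE]
  len <- row_norms(d)
  ok <- len > 0
  mag <- numeric(length(len))
  mag[ok] <- k_spring * (len[ok] - topology$rest_lengths[ok]) / len[ok]
  fe <- d * mag  # force on endpoint 1 (toward 2 when stretched)
  acc <- rowsum(rbind(fe, -fe), group = c(e[, 1L], e[, 2L]))
  out <- matrix(0, nrow(positions), 3L)
  out[as.integer(rownames(acc)), ] <- acc
  out
}

#' Pressure forces on a closed surface
#'
#' Per face, the force `P * area * n_hat` (current area, current outward
#' normal) is distributed in equal thirds to the face's vertices. Degenerate
#' faces contribute nothing.
#'
#' @param mesh a `trimesh` (connectivity).
#' @param positions current n x 3 vertex positions.
#' @param P pressure (N/m^2); negative deflates.
#' @return n x 3 matrix of per-vertex forces (N).
#' @export
pressure_forces <- function(mesh, positions, P) {
  if (P == 0) return(matrix(0, nrow(positions), 3L))
  cr <- face_cross(mesh, positions)      # = 2 * area * n_hat
  ff <- cr * (P / 2)                      # per-face force P * A * n
  f <- mesh$faces
  acc <- rowsum(rbind(ff, ff, ff) / 3, group = c(f[, 1L], f[, 2L], f[, 3L]))
  out <- matrix(0, nrow(positions), 3L)
  out[as.integer(rownames(acc)), ] <- acc
  out
}

#' Velocity damping
#'
#' Componentwise rescaling `v * (1 - d*dt)`; at `d*dt = 1` motion stops
#' entirely.
#'
#' @param velocity numeric vector or matrix of velocities.
#' @param d damping rate (1/s).
#' @param dt time step (s); `d*dt` must be in `[0, 1]`.
#' @return damped velocities, same shape.
#' @export
apply_damping <- function(velocity, d, dt) {
  if (d * dt > 1 || d * dt < 0) stop("damping*dt must lie in [0, 1]")
  velocity * (1 - d * dt)
}

#' Interaction force falloff with distance
#'
#' Attenuates a force magnitude as `F / (1 + distance^2)`; the `1 +` keeps
#' full strength at zero distance.
#'
#' @param F force magnitude (N), finite.
#' @param distance distance from the contact point (m), `>= 0`.
#' @return attenuated magnitude.
#' @export
falloff_force <- function(F, distance) {
  if (any(!is.finite(F))) stop("F must be finite")
  if (any(distance < 0)) stop("distance must be >= 0")
  F / (1 + distance^2)
}

#' Apply an interaction force around a contact point
#'
#' Every vertex within `radius` of `contact_point` receives `force_vector`
#' attenuated by the squared-distance falloff, plus an optional offset
#' component along the inward vertex normal (or a fixed direction) that
#' drives contacted vertices into the surface.
#'
#' @param state a `soft_body_state`.
#' @param mesh the bound `trimesh` (for vertex normals).
#' @param contact_point 3-vector on or near the surface.
#' @param force_vector 3-vector (N); zero length is a no-op.
#' @param radius interaction radius (m).
#' @param params a [force_params()] (supplies the offset settings).
#' @return `state` with `force_accum` updated; attribute
#'   `"contact_force"` holds the total applied force magnitude (the
#'   haptic-event scalar).
#' @export
add_force_to_vertex <- function(state, mesh, contact_point, force_vector,
                                radius, params = force_params()) {
  fmag <- sqrt(sum(force_vector^2))
  if (fmag == 0) {
    attr(state, "contact_force") <- 0
    return(state)
  }
  d <- row_norms(state$positions - matrix(contact_point, nrow(state$positions),
                                          3L, byrow = TRUE))
  sel <- which(d <= radius)
  if (length(sel) > 0L) {
    scale <- falloff_force(fmag, d[sel]) / fmag
    add <- matrix(force_vector, length(sel), 3L, byrow = TRUE) * scale
    if (params$offset_magnitude != 0) {
      off <- if (params$offset_mode == "inward-normal") {
        -vertex_normals(mesh, state$positions)[sel, , drop = FALSE]
      } else {
        matrix(params$offset_direction, length(sel), 3L, byrow = TRUE)
      }
      add <- add + off * (params$offset_magnitude * scale)
    }
    state$force_accum[sel, ] <- state$force_accum[sel, , drop = FALSE] + add
    attr(state, "contact_force") <- sum(row_norms(add))
  } else {
    attr(state, "contact_force") <- 0
  }
  state
}

#' Composite per-vertex force
#'
#' Assembles the spring and pressure components (the damping component is a
#' velocity rescaling applied during integration, and interaction/offset
#' forces arrive through [add_force_to_vertex()]'s accumulator) and adds any
#' previously accumulated interaction forces.
#'
#' @param state a `soft_body_state`.
#' @param mesh the bound `trimesh`.
#' @param topology rest-mesh [build_edge_topology()].
#' @param params a [force_params()].
#' @return n x 3 matrix of total per-vertex force (N); aborts naming the
#'   offending component if any entry is non-finite.
#' @export
composite_force <- function(state, mesh, topology, params) {
  fs <- spring_forces(topology, state$positions, params$k_spring)
  if (any(!is.finite(fs))) stop("non-finite spring force component")
  fp <- pressure_forces(mesh, state$positions, params$pressure)
  if (any(!is.finite(fp))) stop("non-finite pressure force component")
  fo <- state$force_accum
  if (any(!is.finite(fo))) stop("non-finite accumulated interaction force")
  fs + fp + fo
}

#' Integrate accumulated forces into velocities
#'
#' The velocity half of the semi-implicit Euler step:
#' `v <- (v + F/m * dt) * (1 - damping*dt)`, pinned vertices zeroed, force
#' accumulator cleared. Used on its own by the hybrid loop (where the PBD
#' solver moves positions) and by [step_soft_body()] for pure force-based
#' integration.
#'
#' @inheritParams composite_force
#' @return updated `soft_body_state`.
#' @export
integrate_velocities <- function(state, mesh, topology, params) {
  F <- composite_force(state, mesh, topology, params)
  v <- state$velocities + F / state$masses * params$dt
  v <- apply_damping(v, params$damping, params$dt)
  v[state$pinned, ] <- 0
  state$velocities <- v
  state$force_accum[] <- 0
  state
}

#' One explicit soft-body time step
#'
#' Semi-implicit Euler: accumulate forces, `v <- (v + F/m*dt)*(1-d*dt)`,
#' `p <- p + v*dt`; pinned vertices unchanged; the force accumulator is
#' cleared and vertex normals are recomputed for the moved surface.
#'
#' @inheritParams composite_force
#' @return updated `soft_body_state` (with fresh `normals` element); aborts
#'   with the vertex index and step number if a position becomes non-finite.
#' @export
step_soft_body <- function(state, mesh, topology, params) {
  state <- integrate_velocities(state, mesh, topology, params)
  p <- state$positions + state$velocities * params$dt
  p[state$pinned, ] <- state$positions[state$pinned, , drop = FALSE]
  if (any(!is.finite(p))) {
    bad <- which(!is.finite(p), arr.ind = TRUE)[1L, 1L]
    stop(sprintf("non-finite position at vertex %d after step %d",
                 bad, state$step_count + 1L))
  }
  state$positions <- p
  state$step_count <- state$step_count + 1L
  state$normals <- vertex_normals(mesh, p)
  state
}

#' Total kinetic energy of a state
#'
#' @param state a `soft_body_state`.
#' @return `sum(0.5 * m * |v|^2)` in joules.
#' @export
kinetic_energy <- function(state) {
  0.5 * sum(state$masses * rowSums(state$velocities^2))
}
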