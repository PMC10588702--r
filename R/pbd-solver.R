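# Position-based dynamics: constraint generation, single-constraint
# evaluation and projection (reference R implementations), the Gauss-Seidel
# solve step (compiled kernel), total-energy monitoring, and breakable
# constraints (tearing).

#' Solver configuration
#'
#' @param iterations Gauss-Seidel solver loop count per time step (>= 1).
#' @param dt time step (s).
#' @param k_str default stretch stiffness in `[0, 1]`.
#' @param k_bend default bend stiffness in `[0, 1]`.
#' @param break_mode `"relative"` (extension ratio over rest length, default)
#'   or `"absolute"` (extension in meters) for the tearing criterion.
#' @return object of class `solver_config`.
#' @export
solver_config <- function(iterations = 4L, dt = 0.01, k_str = 0.9,
                          k_bend = 0.5, break_mode = "relative") {
  if (iterations < 1L) stop("iterations must be >= 1")
  if (dt <= 0) stop("dt must be > 0")
  if (k_str < 0 || k_str > 1 || k_bend < 0 || k_bend > 1)
    stop("stiffness parameters must lie in [0, 1]")
  break_mode <- match.arg(break_mode, c("relative", "absolute"))
  structure(list(iterations = as.integer(iterations), dt = dt,
                 k_str = k_str, k_bend = k_bend, break_mode = break_mode),
            class = "solver_config")
}

#' Build the constraint set of a mesh
#'
#' One stretch constraint per edge (rest length from the rest mesh) and one
#' bend constraint per interior edge (rest dihedral deviation `phi12`,
#' 0 for a coplanar pair).
#'
#' @param topology an [build_edge_topology()] result.
#' @param config a [solver_config()] supplying default stiffnesses.
#' @param breakable logical: mark all stretch constraints breakable.
#' @param break_threshold threshold used for breakable constraints
#'   (relative extension by default; see [tear_step()]).
#' @return object of class `constraint_set`: data frames `stretch`
#'   (`i, j, d12, k, breakable, threshold`) and `bend`
#'   (`x1..x4, phi12, k`).
#' @export
make_constraints <- function(topology, config = solver_config(),
                             breakable = FALSE, break_threshold = 0.4) {
  e <- topology$edges
  stretch <- data.frame(i = e[, 1L], j = e[, 2L],
                        d12 = topology$rest_lengths,
                        k = config$k_str,
                        breakable = breakable,
                        threshold = ifelse(breakable, break_threshold, NA_real_))
  d <- topology$dihedrals
  bend <- data.frame(x1 = d[, 1L], x2 = d[, 2L], x3 = d[, 3L], x4 = d[, 4L],
                     phi12 = topology$phi12, k = config$k_bend)
  structure(list(stretch = stretch, bend = bend), class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  cat(sprintf("constraint_set: %d stretch (%d breakable), %d bend\n",
              nrow(x$stretch), sum(x$stretch$breakable), nrow(x$bend)))
  invisible(x)
}

#' Evaluate a stretch constraint
#'
#' `C_str = |p_i - p_j| - d12`: positive when stretched beyond the rest
#' length, negative when compressed.
#'
#' @param p_i,p_j 3-vectors (or matching matrices of rows).
#' @param d12 rest length(s).
#' @return scalar (or vector) constraint value.
#' @export
eval_stretch <- function(p_i, p_j, d12) {
  if (is.matrix(p_i)) row_norms(p_i - p_j) - d12
  else sqrt(sum((p_i - p_j)^2)) - d12
}

#' Project a single stretch constraint (reference implementation)
#'
#' Mass-weighted PBD projection: `dp_i = -(w_i/(w_i+w_j)) C n_ij`,
#' `dp_j = +(w_j/(w_i+w_j)) C n_ij` with `w = 1/m` (0 for pinned), scaled by
#' the per-iteration stiffness `k' = 1 - (1-k)^(1/n_s)`. With `k = 1` and
#' `n_s = 1` the constraint is satisfied exactly after one projection.
#'
#' @param positions n x 3 matrix.
#' @param constraint list with `i`, `j`, `d12`, `k`.
#' @param invmass numeric vector of inverse masses (0 = pinned).
#' @param iterations solver iteration count used for stiffness conversion.
#' @return corrected positions matrix; coincident endpoints are skipped.
#' @export
project_stretch <- function(positions, constraint, invmass, iterations = 1L) {
  i <- constraint$i; j <- constraint$j
  wi <- invmass[i]; wj <- invmass[j]
  if (wi + wj <= 0) return(positions)
  d <- positions[i, ] - positions[j, ]
  len <- sqrt(sum(d^2))
  if (len <= 1e-300) return(positions)
  kp <- per_iteration_stiffness(constraint$k, iterations)
  corr <- kp * (len - constraint$d12) / (len * (wi + wj))
  positions[i, ] <- positions[i, ] - wi * corr * d
  positions[j, ] <- positions[j, ] + wj * corr * d
  positions
}

per_iteration_stiffness <- function(k, iterations) 1 - (1 - k)^(1 / iterations)

#' Evaluate a bend constraint
#'
#' `C_bend = acos(n1 . n2) - phi12` where `n1` is the unit normal of the
#' triangle `(p1, p3, p2)` and `n2` of `(p1, p2, p4)` (both outward for a
#' consistently wound mesh, so a coplanar pair with `phi12 = 0` evaluates
#' to 0). The dot product is clamped to `[-1, 1]`.
#'
#' @param p1,p2,p3,p4 3-vectors; `(p1, p2)` is the shared edge.
#' @param phi12 rest dihedral deviation (radians, in `[0, pi]`).
#' @return scalar constraint value, or `NA` when a triangle is degenerate
#'   (the solver skips the constraint that sweep).
#' @export
eval_bend <- function(p1, p2, p3, p4, phi12) {
  n1 <- vcross(p3 - p1, p2 - p1)
  n2 <- vcross(p2 - p1, p4 - p1)
  l1 <- sqrt(sum(n1^2)); l2 <- sqrt(sum(n2^2))
  if (l1 < 1e-300 || l2 < 1e-300) return(NA_real_)
  d <- sum(n1 * n2) / (l1 * l2)
  acos(min(1, max(-1, d))) - phi12
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Project a single bend constraint (reference implementation)
#'
#' Moves the four vertices along the analytic gradient of the dihedral
#' constraint, mass-weighted and stiffness-scaled as in
#' [project_stretch()]. Skips the constraint when a triangle is degenerate
#' or the gradient norm falls below 1e-12.
#'
#' @param positions n x 3 matrix.
#' @param constraint list with `x1..x4`, `phi12`, `k`.
#' @param invmass inverse-mass vector (0 = pinned).
#' @param iterations iteration count for stiffness conversion.
#' @return corrected positions matrix.
#' @export
project_bend <- function(positions, constraint, invmass, iterations = 1L) {
  idx <- c(constraint$x1, constraint$x2, constraint$x3, constraint$x4)
  kp <- per_iteration_stiffness(constraint$k, iterations)
  .pbd_gauss_seidel(positions, invmass,
                    matrix(integer(0), 0L, 2L), numeric(0), numeric(0),
                    matrix(idx - 1L, 1L, 4L), pi - constraint$phi12, kp,
                    integer(0), matrix(numeric(0), 0L, 3L),
                    matrix(numeric(0), 0L, 3L), 1L)
}

#' Static collider definitions
#'
#' Colliders are unaffected by the simulation (the organ bed convention):
#' half-space planes and static triangle meshes.
#'
#' @param planes list of `list(point = c(x,y,z), normal = c(x,y,z))`
#'   half-spaces; the soft body is kept on the positive-normal side.
#' @param meshes list of static `trimesh` obstacles.
#' @return object of class `collider_set`.
#' @export
collider_set <- function(planes = list(), meshes = list()) {
  planes <- lapply(planes, function(p) {
    n <- p$normal / sqrt(sum(p$normal^2))
    list(point = as.numeric(p$point), normal = as.numeric(n))
  })
  structure(list(planes = planes, meshes = meshes), class = "collider_set")
}

#' Generate collision constraints for predicted positions
#'
#' One inequality constraint (point + outward unit witness normal, sense
#' `>= 0`) per vertex whose motion segment `x -> p` ends below a collider
#' plane or crosses a static collider triangle; none otherwise.
#'
#' @param positions current n x 3 positions (segment start `x`).
#' @param predicted predicted n x 3 positions (`p`).
#' @param colliders a [collider_set()].
#' @return list with `vertex` (integer), `point` (k x 3), `normal` (k x 3).
#' @export
generate_collision_constraints <- function(positions, predicted, colliders) {
  vert <- integer(0); pt <- NULL; nrm <- NULL
  for (pl in colliders$planes) {
    s <- (predicted - matrix(pl$point, nrow(predicted), 3L, byrow = TRUE)) %*%
      pl$normal
    hit <- which(s < 0)
    if (length(hit) > 0L) {
      vert <- c(vert, hit)
      pt <- rbind(pt, matrix(pl$point, length(hit), 3L, byrow = TRUE))
      nrm <- rbind(nrm, matrix(pl$normal, length(hit), 3L, byrow = TRUE))
    }
  }
  for (cm in colliders$meshes) {
    fn <- face_normals(cm)
    for (v in seq_len(nrow(predicted))) {
      seg <- predicted[v, ] - positions[v, ]
      lin <- sqrt(sum(seg^2))
      if (lin <= 0) next
      hit <- cast_ray(cm, ray(positions[v, ], seg / lin))
      if (!is.null(hit) && hit$t <= lin) {
        vert <- c(vert, v)
        pt <- rbind(pt, hit$point)
        nrm <- rbind(nrm, fn[hit$face, ])
      }
    }
  }
  list(vertex = vert,
       point = pt %||% matrix(numeric(0), 0L, 3L),
       normal = nrm %||% matrix(numeric(0), 0L, 3L))
}

#' One position-based-dynamics solve step
#'
#' Predicts `p = x + v dt` (plus optional external acceleration
#' `a dt^2`), generates collision constraints against the static colliders,
#' runs `config$iterations` Gauss-Seidel sweeps projecting all constraints
#' in the fixed order stretch -> bend -> collision, then sets
#' `v = (p - x)/dt` and `x = p`. Pinned vertices never move.
#'
#' @param state a [soft_body_state()].
#' @param constraints a [make_constraints()] result.
#' @param config a [solver_config()].
#' @param colliders optional [collider_set()].
#' @param external_accel optional 3-vector or n x 3 matrix of accelerations
#'   (e.g. gravity) applied during prediction.
#' @return updated `soft_body_state`.
#' @export
solve_step <- function(state, constraints, config, colliders = NULL,
                       external_accel = NULL) {
  x <- state$positions
  v <- state$velocities
  if (!is.null(external_accel)) {
    a <- if (is.matrix(external_accel)) external_accel
         else matrix(external_accel, nrow(x), 3L, byrow = TRUE)
    v <- v + a * config$dt
    v[state$pinned, ] <- 0
  }
  p <- x + v * config$dt
  p[state$pinned, ] <- x[state$pinned, , drop = FALSE]

  cc <- if (!is.null(colliders))
    generate_collision_constraints(x, p, colliders)
  else list(vertex = integer(0), point = matrix(numeric(0), 0L, 3L),
            normal = matrix(numeric(0), 0L, 3L))

  invmass <- 1 / state$masses
  invmass[state$pinned] <- 0
  s <- constraints$stretch; b <- constraints$bend
  p <- .pbd_gauss_seidel(
    p, invmass,
    cbind(s$i, s$j) - 1L, s$d12,
    per_iteration_stiffness(s$k, config$iterations),
    cbind(b$x1, b$x2, b$x3, b$x4) - 1L, pi - b$phi12,
    per_iteration_stiffness(b$k, config$iterations),
    cc$vertex - 1L, cc$point, cc$normal,
    config$iterations)

  state$velocities <- (p - x) / config$dt
  state$velocities[state$pinned, ] <- 0
  state$positions <- p
  state$step_count <- state$step_count + 1L
  state
}

#' Total constraint energy
#'
#' `E_tot = sum(k_str C_str^2 + k_bend C_bend^2)` over the constraint set:
#' non-negative, zero exactly when every weighted constraint is satisfied.
#' Degenerate bend configurations contribute 0 that sweep.
#'
#' @param positions n x 3 matrix.
#' @param constraints a `constraint_set`.
#' @return scalar energy.
#' @export
total_energy <- function(positions, constraints) {
  s <- constraints$stretch
  e <- 0
  if (nrow(s) > 0L) {
    C <- eval_stretch(positions[s$i, , drop = FALSE],
                      positions[s$j, , drop = FALSE], s$d12)
    e <- e + sum(s$k * C^2)
  }
  b <- constraints$bend
  if (nrow(b) > 0L) {
    Cb <- vapply(seq_len(nrow(b)), function(r)
      eval_bend(positions[b$x1[r], ], positions[b$x2[r], ],
                positions[b$x3[r], ], positions[b$x4[r], ], b$phi12[r]),
      numeric(1))
    e <- e + sum(b$k * Cb^2, na.rm = TRUE)
  }
  e
}

#' Remove over-stretched breakable constraints (tearing)
#'
#' Every breakable stretch constraint whose extension exceeds its break
#' threshold is removed permanently; bend constraints hinged on a removed
#' edge are removed with it. The criterion is the relative extension
#' `|p_i - p_j| / d12 - 1` (or the absolute extension in meters when
#' `mode = "absolute"`).
#'
#' @param constraints a `constraint_set`.
#' @param positions current n x 3 positions.
#' @param mode `"relative"` (default) or `"absolute"`.
#' @return list: `constraints` (surviving set), `removed` (data frame of
#'   removed stretch constraints with their extension at removal).
#' @export
tear_step <- function(constraints, positions, mode = "relative") {
  mode <- match.arg(mode, c("relative", "absolute"))
  s <- constraints$stretch
  if (nrow(s) == 0L || !any(s$breakable))
    return(list(constraints = constraints,
                removed = cbind(s[0, ], extension = numeric(0))))
  len <- row_norms(positions[s$i, , drop = FALSE] -
                   positions[s$j, , drop = FALSE])
  ext <- if (mode == "relative") len / s$d12 - 1 else len - s$d12
  gone <- which(s$breakable & !is.na(s$threshold) & ext > s$threshold)
  removed <- cbind(s[gone, ], extension = ext[gone])
  if (length(gone) > 0L) {
    constraints$stretch <- s[-gone, , drop = FALSE]
    gk <- paste(pmin(s$i[gone], s$j[gone]), pmax(s$i[gone], s$j[gone]))
    b <- constraints$bend
    bk <- paste(pmin(b$x1, b$x2), pmax(b$x1, b$x2))
    constraints$bend <- b[!(bk %in% gk), , drop = FALSE]
  }
  list(constraints = constraints, removed = removed)
}

#' Connected components of the stretch-constraint graph
#'
#' Vertices joined by surviving stretch constraints; used to observe
#' separation after tearing or cutting.
#'
#' @param constraints a `constraint_set`.
#' @param n_vertices total vertex count.
#' @return integer membership vector (component id per vertex).
#' @export
constraint_graph_components <- function(constraints, n_vertices) {
  s <- constraints$stretch
  g <- igraph::make_empty_graph(n = n_vertices, directed = FALSE)
  if (nrow(s) > 0L)
    g <- igraph::add_edges(g, rbind(s$i, s$j))
  igraph::components(g)$membership
}

#' Serialize / restore a constraint set as JSON
#'
#' The schema stores vertex indices, rest values, stiffnesses and break
#' thresholds so runs can be replayed and diffed.
#'
#' @param constraints a `constraint_set`.
#' @param path output file.
#' @return `path` invisibly for [constraints_to_json()]; a
#'   `constraint_set` for [constraints_from_json()].
#' @export
constraints_to_json <- function(constraints, path) {
  jsonlite::write_json(list(schema = "kidneysim-constraints-1",
                            stretch = constraints$stretch,
                            bend = constraints$bend),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname constraints_to_json
#' @export
constraints_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$schema, "kidneysim-constraints-1"))
    stop("unrecognized constraint schema")
  s <- as.data.frame(x$stretch)
  if (nrow(s) > 0L && is.null(s$threshold)) s$threshold <- NA_real_
  structure(list(stretch = s, bend = as.data.frame(x$bend)),
            class = "constraint_set")
}
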