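# Agent-based model of early microcolony growth.
#
# Cells are rod-shaped (spherocylinders: the ellipsoidal cell body is reduced
# to its axis segment dilated by the cell width for contact purposes), grow
# exponentially, divide at a noisy length threshold, and move with overdamped
# positional and orientational dynamics under Hertzian steric repulsion, a
# short-range adhesive shell (the matrix-protein-mediated cell-cell
# attraction), cell-surface anchoring, and anisotropic friction suppressing
# transverse motion. Forces are exact negative gradients of the pair and
# surface potentials. Integration is explicit Euler with an internal
# substepping guard (max displacement per substep < width/10).

#' Simulation parameter set
#'
#' Defaults are desk-scale calibrations chosen so that contact relaxation is
#' fast relative to growth; the four scanned parameters of the model are
#' `L_div` (cell length at division, micrometres), `r_rep` (range of cell-cell
#' repulsion, micrometres), `r_att` (range of cell-cell attraction,
#' micrometres) and `f_att` (strength of cell-cell attraction, force units).
#'
#' @param L_div division length, micrometres (> width).
#' @param r_rep repulsion range beyond contact, micrometres.
#' @param r_att attraction shell width beyond the repulsion range,
#'   micrometres.
#' @param f_att attraction strength (force units).
#' @param k_rep Hertzian repulsion stiffness (force / micrometre^(3/2)).
#' @param width cell width, micrometres.
#' @param gamma elongation rate, 1/h (default ln 2 / 0.5: 30-min doubling).
#' @param f_surf cell-surface attraction strength.
#' @param r_surf cell-surface attraction range, micrometres.
#' @param zeta_par drag coefficient per unit length along the cell axis.
#' @param zeta_ratio transverse-to-axial friction ratio (>= 1; matrix
#'   polymers suppress transverse motion).
#' @param zeta_rot_factor rotational drag prefactor (rotational drag =
#'   `zeta_rot_factor * zeta_par * zeta_ratio * L^3`).
#' @param dt timestep, hours.
#' @param sigma_div lognormal sd of the division-length noise.
#' @param sigma_ori sd (radians) of the daughter orientation tilt at
#'   division.
#' @param n_target stop once the colony reaches this cell count.
#' @param seed RNG seed used by [run_simulation()].
#' @param max_hours wall-clock safeguard in simulated hours (default scales
#'   with the number of doublings needed).
#' @return list of class `sim_params`.
#' @export
sim_params <- function(L_div = 3.5, r_rep = 0.15, r_att = 0.5, f_att = 5,
                       k_rep = 5e3, width = 0.8, gamma = log(2) / 0.5,
                       f_surf = 20, r_surf = 0.2,
                       zeta_par = 2, zeta_ratio = 5, zeta_rot_factor = 1 / 12,
                       dt = 2e-4, sigma_div = 0.1, sigma_ori = 0.05,
                       n_target = 500, seed = 1L, max_hours = NULL) {
  stopifnot(L_div > width, width > 0, r_rep >= 0, r_att >= 0, f_att >= 0,
            k_rep > 0, gamma > 0, zeta_ratio >= 1, dt > 0, n_target >= 1)
  if (is.null(max_hours)) {
    max_hours <- (log2(max(n_target, 2)) + 10) * log(2) / gamma
  }
  structure(list(L_div = L_div, r_rep = r_rep, r_att = r_att, f_att = f_att,
                 k_rep = k_rep, width = width, gamma = gamma,
                 f_surf = f_surf, r_surf = r_surf,
                 zeta_par = zeta_par, zeta_ratio = zeta_ratio,
                 zeta_rot_factor = zeta_rot_factor,
                 dt = dt, sigma_div = sigma_div, sigma_ori = sigma_ori,
                 n_target = as.integer(n_target), seed = as.integer(seed),
                 max_hours = max_hours),
            class = "sim_params")
}

as_cell <- function(pos, dir, length, width) {
  dir <- dir / sqrt(sum(dir^2))
  list(pos = as.numeric(pos), dir = as.numeric(dir),
       length = length, width = width)
}

#' Contact geometry between two cells
#'
#' Reduces both cells to their axis segments (length `length - width`) and
#' returns the minimal segment-segment separation minus the mean width
#' (`delta < 0` means steric overlap), the contact normal (from B towards A;
#' a deterministic perpendicular fallback is used for coincident axes) and
#' the two contact points.
#'
#' @param cellA,cellB cell descriptions: lists with `pos` (3-vector), `dir`
#'   (unit 3-vector), `length`, `width`.
#' @return list with `delta`, `normal`, `contact_A`, `contact_B`.
#' @export
contact_geometry <- function(cellA, cellB) {
  g <- seg_closest_cpp(cellA$pos, cellA$dir, cellA$length, cellA$width,
                       cellB$pos, cellB$dir, cellB$length, cellB$width)
  dv <- g$cA - g$cB
  dist <- g$dist
  if (dist > 1e-12) {
    normal <- dv / dist
  } else {
    ref <- if (abs(cellA$dir[3]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
    normal <- c(cellA$dir[2] * ref[3] - cellA$dir[3] * ref[2],
                cellA$dir[3] * ref[1] - cellA$dir[1] * ref[3],
                cellA$dir[1] * ref[2] - cellA$dir[2] * ref[1])
    normal <- normal / sqrt(sum(normal^2))
  }
  list(delta = dist - 0.5 * (cellA$width + cellB$width),
       normal = normal, contact_A = g$cA, contact_B = g$cB)
}

#' Pair interaction forces and torques
#'
#' Hertzian repulsion of magnitude `k_rep * (r_rep - delta)^(3/2)` inside the
#' repulsion range and an adhesive shell of magnitude
#' `f_att * min(1, 1 - (delta - r_rep)/r_att)` out to
#' `r_rep + r_att`, applied along the contact normal at the contact points
#' (hence generating torques about the two centroids). The forces on the pair
#' sum to zero, and equal the exact negative gradient of
#' [pair_potential()].
#'
#' @inheritParams contact_geometry
#' @param params a `sim_params`.
#' @return list with `force_A`, `torque_A`, `force_B`, `torque_B`, `delta`,
#'   `normal`.
#' @export
pair_interaction <- function(cellA, cellB, params) {
  pair_force_cpp(cellA$pos, cellA$dir, cellA$length, cellA$width,
                 cellB$pos, cellB$dir, cellB$length, cellB$width,
                 unclass(params))
}

#' @rdname pair_interaction
#' @return `pair_potential()`: the scalar interaction energy.
#' @export
pair_potential <- function(cellA, cellB, params) {
  pair_potential_cpp(cellA$pos, cellA$dir, cellA$length, cellA$width,
                     cellB$pos, cellB$dir, cellB$length, cellB$width,
                     unclass(params))
}

#' Cell-surface interaction
#'
#' Each cap-sphere centre (axis endpoint) at height h above the substrate
#' feels Hertzian repulsion `k_rep * (width/2 - h)^(3/2)` when pressed below
#' contact and a clamped adhesive ramp `f_surf * min(1, 1 - (h -
#' width/2)/r_surf)` out to `width/2 + r_surf`. An isolated horizontal cell
#' rests where repulsion balances adhesion, at
#' `h* = width/2 - (f_surf/k_rep)^(2/3)`.
#'
#' @param cell cell description (see [contact_geometry()]).
#' @param params a `sim_params`.
#' @return list with `force` and `torque` (about the centroid).
#' @export
surface_interaction <- function(cell, params) {
  surface_force_cpp(cell$pos, cell$dir, cell$length, cell$width,
                    unclass(params))
}

#' @rdname surface_interaction
#' @return `surface_potential()`: the scalar cell-surface energy.
#' @export
surface_potential <- function(cell, params) {
  surface_potential_cpp(cell$pos, cell$dir, cell$length, cell$width,
                        unclass(params))
}

#' Simulation state
#'
#' Explicit container for the mechanical state of a colony, used by the
#' stepping primitives [sim_step()] and [grow_and_divide()]; [run_simulation()]
#' advances the same state internally.
#'
#' @param pos n x 3 centroid matrix (micrometres).
#' @param dir n x 3 orientation matrix (rows normalised).
#' @param length,width per-cell lengths and widths (micrometres).
#' @param threshold per-cell division thresholds; defaults drawn around
#'   `L_div` need a prior `set.seed()` call for reproducibility.
#' @param params a `sim_params` (used for the default thresholds).
#' @param time simulation time, hours.
#' @return list of class `sim_state`.
#' @export
sim_state <- function(pos, dir, length, width, threshold = NULL,
                      params = sim_params(), time = 0) {
  pos <- matrix(as.numeric(pos), ncol = 3)
  dir <- matrix(as.numeric(dir), ncol = 3)
  dir <- dir / sqrt(rowSums(dir^2))
  n <- nrow(pos)
  length <- rep_len(length, n)
  width <- rep_len(width, n)
  if (is.null(threshold)) {
    threshold <- params$L_div * exp(stats::rnorm(n, 0, params$sigma_div))
    threshold <- pmax(threshold, 1.2 * length)
  }
  structure(list(pos = pos, dir = dir, length = length, width = width,
                 threshold = rep_len(threshold, n), time = time),
            class = "sim_state")
}

state_from_cpp <- function(lst) {
  structure(list(pos = lst$pos, dir = lst$dir, length = lst$length,
                 width = lst$width, threshold = lst$threshold,
                 time = lst$time),
            class = "sim_state")
}

#' Advance the mechanical state by one timestep
#'
#' One explicit Euler step of the overdamped dynamics (no growth): forces are
#' decomposed along and perpendicular to each cell axis with drags
#' `zeta_par * L` and `zeta_par * zeta_ratio * L`, torques drive rotation
#' against a drag proportional to `L^3`, and the step is internally
#' subdivided whenever any displacement would exceed width/10.
#'
#' @param state a `sim_state`.
#' @param params a `sim_params`.
#' @param nsteps number of timesteps of size `params$dt`.
#' @return the advanced `sim_state`.
#' @export
sim_step <- function(state, params, nsteps = 1L) {
  stopifnot(inherits(state, "sim_state"))
  state_from_cpp(advance_cpp(unclass(state), unclass(params),
                             as.integer(nsteps)))
}

#' Grow and divide cells over one timestep
#'
#' Every cell length is multiplied by `exp(gamma * dt)`; cells at or above
#' their division threshold split into two daughters of half the mother
#' length placed end-to-end along the mother axis (their spherocylinders
#' exactly tile the mother, so siblings are born at contact and the
#' population doubling time equals ln(2)/gamma), with a small random
#' orientation tilt and freshly drawn division thresholds. Uses the R RNG:
#' call `set.seed()` beforehand for reproducibility.
#'
#' @inheritParams sim_step
#' @return the updated `sim_state`.
#' @export
grow_and_divide <- function(state, params) {
  stopifnot(inherits(state, "sim_state"))
  state_from_cpp(grow_divide_cpp(unclass(state), unclass(params)))
}

#' Run a colony growth simulation
#'
#' Initialises a single founder cell lying on the substrate with a random
#' in-plane orientation and alternates mechanical relaxation with growth and
#' division until the colony reaches `n_target` cells. Deterministic given
#' `params$seed`. The division history (time, cell count) is recorded in the
#' sample metadata, together with the full parameter set.
#'
#' @param params a `sim_params`.
#' @param group,condition,replicate metadata labels for the returned sample.
#' @return a `biofilm_sample` with provenance `"simulation"`.
#' @export
run_simulation <- function(params, group = "simulation", condition = "none",
                           replicate = 1L) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  out <- simulate_colony_cpp(unclass(params))
  n <- nrow(out$pos)
  cells <- data.frame(id = seq_len(n),
                      x = out$pos[, 1], y = out$pos[, 2],
                      z = pmax(out$pos[, 3], 0),
                      nx = out$dir[, 1], ny = out$dir[, 2],
                      nz = out$dir[, 3],
                      length = out$length, width = out$width)
  p <- unclass(params)
  p$history <- list(time = out$history_time, n = out$history_n)
  biofilm_sample(cells, group = group, condition = condition,
                 replicate = replicate, provenance = "simulation",
                 params = p)
}

#' Population doubling time of a simulated colony
#'
#' Least-squares slope of log cell count against time over the recorded
#' division history (counts from `from_n` upward), returned as ln(2)/slope.
#'
#' @param sample a simulated `biofilm_sample` (from [run_simulation()]).
#' @param from_n ignore the early founder phase below this count.
#' @return doubling time in hours.
#' @export
doubling_time <- function(sample, from_n = 8) {
  h <- sample$metadata$params$history
  if (is.null(h)) stop("sample has no recorded division history")
  keep <- h$n >= from_n
  if (sum(keep) < 3) stop("history too short to fit a growth rate")
  fit <- stats::lm(log(h$n[keep]) ~ h$time[keep])
  log(2) / unname(stats::coef(fit)[2])
}
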