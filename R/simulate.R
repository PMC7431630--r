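#' External loading cases
#'
#' The five simulated gravitational load distributions: vertical loads
#' `P1..P5` (N, acting -X) at levels L1..L5 together with the lateral offset
#' `D` (mm) of the muscle origins on the base.
#'
#' | case | P1  | P2  | P3  | P4  | P5  | D  |
#' |------|-----|-----|-----|-----|-----|----|
#' | 1    | 635 | 0   | 0   | 0   | 0   | 50 |
#' | 2    | 350 | 50  | 50  | 50  | 50  | 50 |
#' | 3    | 110 | 110 | 110 | 110 | 110 | 50 |
#' | 4    | 110 | 110 | 110 | 110 | 110 | 25 |
#' | 5    | 110 | 110 | 110 | 110 | 110 | 75 |
#'
#' @param case Integer 1..5 selecting a built-in case, or `NULL` when `P`
#'   and `D_mm` are given directly.
#' @param P Custom load vector (N at L1..L5).
#' @param D_mm Custom muscle-origin offset (mm).
#' @param ramp_time Load ramp duration in s; loads rise linearly from zero
#'   and are then held.
#' @return A list of class `loading_case`.
#' @export
#' @examples
#' loading_case(2)
loading_case <- function(case = NULL, P = NULL, D_mm = NULL,
                         ramp_time = 0.2) {
  builtin <- list(
    `1` = list(P = c(635, 0, 0, 0, 0), D = 50),
    `2` = list(P = c(350, 50, 50, 50, 50), D = 50),
    `3` = list(P = c(110, 110, 110, 110, 110), D = 50),
    `4` = list(P = c(110, 110, 110, 110, 110), D = 25),
    `5` = list(P = c(110, 110, 110, 110, 110), D = 75)
  )
  if (!is.null(case)) {
    stopifnot(length(case) == 1, as.character(case) %in% names(builtin))
    b <- builtin[[as.character(case)]]
    P <- b$P
    D_mm <- b$D
  } else {
    if (is.null(P) || is.null(D_mm)) stop("give either `case` or both `P` and `D_mm`")
  }
  stopifnot(all(P >= 0), D_mm > 0, ramp_time >= 0)
  structure(
    list(case = case, P = P, D_mm = D_mm, ramp_time = ramp_time),
    class = "loading_case"
  )
}

#' @export
print.loading_case <- function(x, ...) {
  cat("<loading_case", if (!is.null(x$case)) paste0(" ", x$case) else "",
      ">  P(L1..L5) = ", paste(x$P, collapse = ", "), " N,  D = ", x$D_mm,
      " mm,  ramp = ", x$ramp_time, " s\n", sep = "")
  invisible(x)
}

#' Simulation settings
#'
#' Transient-regularisation and integration settings of the quasi-static
#' simulation.  The nodal masses and stiffness-proportional damping are a
#' numerical surrogate for the neglected upper-body inertia: they shape the
#' transient but the steady state is verified insensitive to them.
#'
#' @param dt Integration step (s).
#' @param control_dt Controller sampling/update period (s); kept on its own
#'   clock so that refining `dt` does not alter the learning trajectory.
#'   Must be an integer multiple of `dt`.
#' @param t_end Simulated horizon (s).
#' @param node_mass Lumped translational mass per node (kg).
#' @param rot_inertia Lumped rotary inertia per node (kg m^2).
#' @param rayleigh_beta Stiffness-proportional damping coefficient (s).
#' @param steady_tol_pos_mm,steady_tol_vel_mm_s,steady_window_s Steady-state
#'   detection tolerances and window.
#' @param record_every Record one sample every this many steps.
#' @param diverge_z_mm Lateral excursion treated as structural divergence.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(dt = 1e-3, control_dt = 1e-3, t_end = 25,
                              node_mass = 0.5,
                              rot_inertia = 1e-5, rayleigh_beta = 1e-3,
                              steady_tol_pos_mm = 0.2,
                              steady_tol_vel_mm_s = 1,
                              steady_window_s = 1,
                              record_every = 1L, diverge_z_mm = 50) {
  stopifnot(dt > 0, t_end > dt, node_mass > 0, rot_inertia > 0,
            rayleigh_beta >= 0, record_every >= 1, control_dt >= dt)
  if (abs(control_dt / dt - round(control_dt / dt)) > 1e-9) {
    stop("control_dt must be an integer multiple of dt")
  }
  structure(
    list(dt = dt, control_dt = control_dt, t_end = t_end,
         node_mass = node_mass,
         rot_inertia = rot_inertia, rayleigh_beta = rayleigh_beta,
         steady_tol_pos_mm = steady_tol_pos_mm,
         steady_tol_vel_mm_s = steady_tol_vel_mm_s,
         steady_window_s = steady_window_s,
         record_every = as.integer(record_every),
         diverge_z_mm = diverge_z_mm),
    class = "simulation_config"
  )
}

#' Run one loading case of the controlled spine
#'
#' Ramps the external loads, advances the coupled plant-muscle-controller
#' system by implicit Newmark integration (average acceleration, Newton
#' iteration each step, step halving on non-convergence) and reports the
#' full histories plus a steady-state snapshot.  With `control = FALSE` the
#' passive column is simulated alone; under the study loads it buckles and
#' the run is flagged unstable.
#'
#' @param case A [loading_case()] (or an integer passed to it).
#' @param geometry A [spine_geometry()].
#' @param gains A [controller_gains()].
#' @param net A [fuzzy_network()].
#' @param config A [simulation_config()].
#' @param control Run with active controllers?
#' @param muscles Optional pre-built [muscle_set()]; defaults to the
#'   ten-muscle set for the case's `D`.
#' @param pulses Optional perturbation table with columns `t0`, `t1`,
#'   `level` (e.g. `"L1"`) and `dP` (N, added in -X during `[t0, t1)`).
#' @return An object of class `spine_sim`; see [tidy.spine_sim()].
#' @export
simulate_case <- function(case, geometry = spine_geometry(),
                          gains = controller_gains(),
                          net = fuzzy_network(),
                          config = simulation_config(),
                          control = TRUE, muscles = NULL, pulses = NULL) {
  if (!inherits(case, "loading_case")) case <- loading_case(case)
  if (is.null(muscles)) muscles <- muscle_set(geometry, D_mm = case$D_mm)
  anat <- geometry$anatomical
  n_lev <- length(anat) - 1L

  nn <- nrow(geometry$coords)
  P_node <- numeric(nn)
  lev_nodes <- rev(anat[-1])                       # L1 first
  P_node[lev_nodes] <- case$P[seq_len(n_lev)]

  pul <- matrix(numeric(0), 0, 4)
  if (!is.null(pulses) && nrow(pulses) > 0) {
    if (any(pulses$t1 > config$t_end) || any(pulses$t0 < 0)) {
      stop("perturbation pulses must lie within the simulation horizon")
    }
    lv <- match(pulses$level, paste0("L", seq_len(n_lev)))
    if (any(is.na(lv))) stop("unknown level in pulses")
    pul <- cbind(pulses$t0, pulses$t1, lev_nodes[lv] - 1L, pulses$dP)
  }

  nsteps <- round(config$t_end / config$dt)
  ke_m <- muscles$ke
  if (length(gains$ke) == n_lev) {
    ke_m <- gains$ke[match(muscles$level, paste0("L", seq_len(n_lev)))]
  }
  target_z <- geometry$coords[muscles$insertion_node, 2]

  res <- cpp_simulate(
    geometry$coords, geometry$EA, geometry$EI,
    as.matrix(cbind(muscles$origin_x_mm, muscles$origin_z_mm)) / 1000,
    muscles$insertion_node - 1L,
    muscles$f_max_N, muscles$l0_mm / 1000, muscles$ldot_max_mm_s / 1000,
    muscles$jsign, ke_m, as.integer(muscles$passive),
    target_z,
    gains$h1, gains$h2, gains$h3, gains$kalpha, gains$eta,
    net$centers, net$sigma, net$norm_e_mm, net$norm_edot_mm_s,
    gains$windup_mm_s,
    P_node, case$ramp_time, pul,
    config$dt, nsteps, config$node_mass, config$rot_inertia,
    config$rayleigh_beta, control, TRUE,
    config$diverge_z_mm / 1000, config$record_every,
    as.integer(round(config$control_dt / config$dt))
  )

  out <- structure(
    list(case = case, geometry = geometry, muscles = muscles, gains = gains,
         net = net, config = config, control = control, raw = res,
         unstable = res$unstable),
    class = "spine_sim"
  )
  out$steady <- summarize_steady(out)
  out
}

# steady-state detection + snapshot helpers -------------------------------

#' Earliest steady-state time of a history
#'
#' Scans the recorded history for the earliest time after the load ramp at
#' which the maximum target deviation and the maximum lateral nodal speed
#' stay within tolerance continuously for a full window.
#'
#' @param time Time grid (s).
#' @param dev_mm Matrix (or vector) of |Z - Z_target| per target node, mm.
#' @param vel_mm_s Matrix of lateral nodal speeds, mm/s.
#' @param tol_pos_mm,tol_vel_mm_s Tolerances.
#' @param window_s Required hold duration (s).
#' @param t_min Do not look before this time (s).
#' @return List with `converged` and `t_converged` (NA when never).
#' @export
detect_steady_state <- function(time, dev_mm, vel_mm_s, tol_pos_mm = 0.2,
                                tol_vel_mm_s = 1, window_s = 1, t_min = 0) {
  dev_mm <- as.matrix(dev_mm)
  vel_mm_s <- as.matrix(vel_mm_s)
  ok <- apply(dev_mm, 1, max) <= tol_pos_mm &
    apply(abs(vel_mm_s), 1, max) <= tol_vel_mm_s & time >= t_min
  if (!any(ok)) return(list(converged = FALSE, t_converged = NA_real_))
  # earliest index from which ok holds for >= window_s
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    if (time[ends[i]] - time[starts[i]] >= window_s) {
      return(list(converged = TRUE,
                  t_converged = time[starts[i]] + window_s))
    }
  }
  list(converged = FALSE, t_converged = NA_real_)
}

summarize_steady <- function(sim) {
  res <- sim$raw
  cfg <- sim$config
  if (isTRUE(res$unstable) || length(res$time) < 3) {
    return(list(converged = FALSE, t_converged = NA_real_))
  }
  anat <- sim$geometry$anatomical
  lumbar <- anat[-1]
  zcols <- 3 * (lumbar - 1) + 2
  z_mm <- sweep(res$U[, zcols, drop = FALSE], 2, 0) * 1000
  dev <- abs(z_mm)                      # target uZ = 0 (reference posture)
  vel <- res$V[, zcols, drop = FALSE] * 1000
  det <- detect_steady_state(res$time, dev, vel,
                             tol_pos_mm = cfg$steady_tol_pos_mm,
                             tol_vel_mm_s = cfg$steady_tol_vel_mm_s,
                             window_s = cfg$steady_window_s,
                             t_min = sim$case$ramp_time)
  n <- length(res$time)
  win <- res$time >= res$time[n] - cfg$steady_window_s
  list(
    converged = det$converged, t_converged = det$t_converged,
    max_err_mm = max(dev[win, ]), max_err_all_mm = max(dev),
    alpha = colMeans(res$alpha[win, , drop = FALSE]),
    force_N = colMeans(res$force[win, , drop = FALSE]),
    axial_N = colMeans(res$axial[win, , drop = FALSE]),
    shear_N = colMeans(res$shear_local[win, , drop = FALSE])
  )
}

#' Section loads of a converged run
#'
#' Mean compression and shear per level over the final steady window, in the
#' local deformed element frame.
#'
#' @param sim A `spine_sim`.
#' @return Tibble `level`, `compression_N`, `shear_N`.
#' @export
section_loads <- function(sim) {
  stopifnot(inherits(sim, "spine_sim"))
  ends <- cbind(sim$steady$axial_N, sim$steady$shear_N)
  recover_section_loads(sim$geometry, ends)
}

#' @export
print.spine_sim <- function(x, ...) {
  cat("<spine_sim> case ",
      if (!is.null(x$case$case)) x$case$case else "custom",
      if (x$control) " (controlled)" else " (no controller)", "\n", sep = "")
  if (isTRUE(x$unstable)) {
    cat("  UNSTABLE: lateral divergence at t = ",
        signif(x$raw$t_unstable, 3), " s\n", sep = "")
  } else {
    cat("  converged: ", x$steady$converged,
        if (isTRUE(x$steady$converged)) {
          paste0(" (t = ", signif(x$steady$t_converged, 4), " s)")
        } else "",
        ";  steady max |e| = ", signif(x$steady$max_err_mm, 3), " mm\n",
        sep = "")
  }
  invisible(x)
}

#' Steady-state muscle forces across a sweep of L1 loads
#'
#' Re-runs a base loading case for a series of vertical loads at L1 and fits
#' a per-muscle linear model of steady-state force versus load.
#'
#' @param L1_loads Vector of L1 loads (N), e.g. `seq(150, 750, by = 200)`.
#' @param base_case The case supplying the L2..L5 loads and `D` (default 2).
#' @param ... Passed on to [simulate_case()].
#' @return Object of class `spine_sweep`: list with `forces` (tibble: load,
#'   level, side, force_N, converged) and `fits` (tibble: level, side, slope,
#'   intercept, r_squared).
#' @export
run_load_sweep <- function(L1_loads, base_case = 2, ...) {
  if (any(L1_loads < 0 | L1_loads > 1000)) {
    stop("L1 loads outside the supported 0..1000 N range")
  }
  base <- loading_case(base_case)
  runs <- lapply(L1_loads, function(p1) {
    cs <- loading_case(P = c(p1, base$P[-1]), D_mm = base$D_mm,
                       ramp_time = base$ramp_time)
    simulate_case(cs, ...)
  })
  forces <- purrr::map2_dfr(runs, L1_loads, function(r, p1) {
    tibble::tibble(
      L1_load_N = p1,
      level = r$muscles$level, side = r$muscles$side,
      force_N = r$steady$force_N,
      alpha = r$steady$alpha,
      converged = isTRUE(r$steady$converged)
    )
  })
  fits <- forces |>
    dplyr::group_by(.data$level, .data$side) |>
    dplyr::group_modify(function(d, key) {
      if (length(unique(d$L1_load_N)) < 2) {
        return(tibble::tibble(slope = NA_real_, intercept = NA_real_,
                              r_squared = NA_real_, degenerate = TRUE))
      }
      fit <- lm(force_N ~ L1_load_N, data = d)
      tibble::tibble(
        slope = coef(fit)[2], intercept = coef(fit)[1],
        r_squared = summary(fit)$r.squared, degenerate = FALSE
      )
    }) |>
    dplyr::ungroup()
  structure(list(forces = forces, fits = fits, runs = runs),
            class = "spine_sweep")
}

#' Perturbation protocol
#'
#' Holds a loading case and superimposes rectangular vertical load pulses at
#' a level while the controllers stay active; the system must re-converge
#' after each pulse.
#'
#' @param case Base loading case (default 1).
#' @param pulses Tibble with `t0`, `t1`, `level`, `dP`; defaults to the
#'   -100 N / +100 N pulse pair at L1 over `[0.5, 1]` and `[1.5, 2]` s,
#'   applied after an initial convergence phase given by `t_offset`.
#' @param t_offset Time added to the default pulse windows so perturbations
#'   hit a converged state (s).
#' @param ... Passed to [simulate_case()].
#' @return A `spine_sim` with the pulse table attached.
#' @export
run_perturbation <- function(case = 1, pulses = NULL, t_offset = 20, ...) {
  if (is.null(pulses)) {
    pulses <- tibble::tibble(
      t0 = c(0.5, 1.5) + t_offset, t1 = c(1.0, 2.0) + t_offset,
      level = "L1", dP = c(-100, 100)
    )
  }
  sim <- simulate_case(case, pulses = pulses, ...)
  sim$pulses <- pulses
  sim
}
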