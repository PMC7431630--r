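#' Follower-load-constrained equilibrium baseline
#'
#' The matched inverse model: on the fixed reference geometry, one muscle
#' force per level (side selected by sign) is solved from the linear system
#' requiring zero shear of the transmitted internal force at each of the five
#' inter-vertebral sections, so that the resultant on the spine is a pure
#' follower load.  With purely nodal loading, zero shear at every section
#' also makes the internal bending moment vanish identically, so this is the
#' complete follower-load condition.
#'
#' The follower direction at each section is, by default, the tangent of a
#' natural cubic spline through the vertebral centres evaluated at the upper
#' node of the section (`tangent = "node"`), reflecting a continuous spinal
#' curve; `tangent = "chord"` uses the piecewise-linear chord of the adjacent
#' nodes instead.
#'
#' @param case A [loading_case()] or an integer 1..5.
#' @param geometry A [spine_geometry()] (the fixed target posture).
#' @param tangent `"node"` or `"chord"` follower-direction convention.
#' @return Object of class `fl_equilibrium`: tibbles `muscle_forces` (level,
#'   side, force_N) and `section_loads` (level, compression_N, shear_N), plus
#'   `residual_shear_N` (the verification maximum |shear|).
#' @export
#' @examples
#' solve_follower_load(2)
solve_follower_load <- function(case, geometry = spine_geometry(),
                                tangent = c("node", "chord")) {
  tangent <- match.arg(tangent)
  if (!inherits(case, "loading_case")) case <- loading_case(case)
  anat <- geometry$anatomical
  n_lev <- length(anat) - 1L
  P <- case$P[seq_len(n_lev)]
  D <- case$D_mm
  nodes <- geometry$coords[anat, , drop = FALSE] * 1000   # mm, base..top
  lev_node <- rev(seq_len(n_lev + 1L)[-1])                # row of L1 first

  slope_at <- local({
    x <- nodes[, 1]
    z <- nodes[, 2]
    if (tangent == "chord") {
      function(k) (z[k + 1] - z[k]) / (x[k + 1] - x[k])
    } else {
      sp <- splinefun(x, z, method = "natural")
      function(k) sp(x[k + 1], deriv = 1)
    }
  })

  udir <- function(i, side) {
    ins <- nodes[lev_node[i], ]
    org <- c(0, side * D)
    d <- org - ins
    d / sqrt(sum(d^2))
  }

  sides <- rep(-1, n_lev)
  for (iter in 1:20) {
    U <- vapply(seq_len(n_lev), function(i) udir(i, sides[i]), numeric(2))
    A <- matrix(0, n_lev, n_lev)
    b <- numeric(n_lev)
    for (k in seq_len(n_lev)) {
      s <- slope_at(k)
      n <- c(-s, 1) / sqrt(1 + s^2)
      above <- which(lev_node > k)
      b[k] <- sum(P[above]) * n[1]       # -(sum of (-P,0) . n)
      for (i in above) A[k, i] <- sum(U[, i] * n)
    }
    Fm <- tryCatch(solve(A, b), error = function(e) {
      stop("follower-load system singular: degenerate muscle geometry")
    })
    new_sides <- ifelse(Fm < 0, -sides, sides)
    Fm <- abs(Fm)
    if (all(new_sides == sides)) break
    sides <- new_sides
  }

  U <- vapply(seq_len(n_lev), function(i) udir(i, sides[i]), numeric(2))
  comp <- numeric(n_lev)
  shear <- numeric(n_lev)
  for (k in seq_len(n_lev)) {
    s <- slope_at(k)
    t <- c(1, s) / sqrt(1 + s^2)
    n <- c(-s, 1) / sqrt(1 + s^2)
    R <- c(0, 0)
    for (i in which(lev_node > k)) {
      R <- R + c(-P[i], 0) + Fm[i] * U[, i]
    }
    comp[k] <- -sum(R * t)
    shear[k] <- sum(R * n)
  }

  lev_lab <- paste0("L", seq_len(n_lev))
  structure(
    list(
      case = case, tangent = tangent,
      muscle_forces = tibble::tibble(
        level = factor(lev_lab, levels = lev_lab),
        side = ifelse(sides > 0, "right", "left"),
        force_N = Fm
      ),
      section_loads = tibble::tibble(
        level = level_names(n_lev),
        compression_N = comp, shear_N = shear
      ),
      residual_shear_N = max(abs(shear))
    ),
    class = "fl_equilibrium"
  )
}

#' @export
print.fl_equilibrium <- function(x, ...) {
  cat("<fl_equilibrium> case ",
      if (!is.null(x$case$case)) x$case$case else "custom",
      " (", x$tangent, " tangents); residual |shear| <= ",
      signif(x$residual_shear_N, 2), " N\n", sep = "")
  mf <- x$muscle_forces[rev(seq_len(nrow(x$muscle_forces))), ]
  names(mf) <- c("muscle", "side", "muscle_force_N")
  print(dplyr::bind_cols(x$section_loads, mf), ...)
  invisible(x)
}

#' Compare control-based and equilibrium-based predictions
#'
#' Side-by-side muscle forces and section loads for the same loading case,
#' with the per-level force differences and their RMSE.
#'
#' @param control A converged `spine_sim`.
#' @param equilibrium A [solve_follower_load()] result for the same case.
#' @return Object of class `model_comparison`: tibbles `muscle_forces`
#'   (per-level resultant force of the active side in each model) and
#'   `section_loads`, plus `rmse_N` and `sum_diff_N` (control minus
#'   equilibrium total).
#' @export
compare_models <- function(control, equilibrium) {
  stopifnot(inherits(control, "spine_sim"),
            inherits(equilibrium, "fl_equilibrium"))
  same <- identical(control$case$P, equilibrium$case$P) &&
    identical(control$case$D_mm, equilibrium$case$D_mm)
  if (!same) stop("control run and equilibrium solution are for different cases")

  # control: per-level force of the dominant (active) muscle
  ctl <- tibble::tibble(
    level = control$muscles$level, side = control$muscles$side,
    force_N = control$steady$force_N
  ) |>
    dplyr::group_by(.data$level) |>
    dplyr::slice_max(.data$force_N, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()

  eq <- equilibrium$muscle_forces
  mf <- dplyr::left_join(
    dplyr::rename(ctl, control_side = "side", control_N = "force_N"),
    dplyr::rename(eq, equilibrium_side = "side", equilibrium_N = "force_N"),
    by = "level"
  )
  mf$diff_N <- mf$control_N - mf$equilibrium_N

  sl <- dplyr::left_join(
    dplyr::rename(section_loads(control),
                  control_compression_N = "compression_N",
                  control_shear_N = "shear_N"),
    dplyr::rename(equilibrium$section_loads,
                  equilibrium_compression_N = "compression_N",
                  equilibrium_shear_N = "shear_N"),
    by = "level"
  )

  structure(
    list(
      muscle_forces = mf, section_loads = sl,
      rmse_N = sqrt(mean(mf$diff_N^2)),
      sum_diff_N = sum(mf$control_N) - sum(mf$equilibrium_N)
    ),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>  RMSE = ", signif(x$rmse_N, 3),
      " N;  sum(control) - sum(equilibrium) = ", signif(x$sum_diff_N, 3),
      " N\n", sep = "")
  print(x$muscle_forces, ...)
  invisible(x)
}
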