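#' Tidy a simulation result
#'
#' @param x A `spine_sim`.
#' @param what One of `"nodes"` (time series of lateral position and target
#'   deviation per lumbar node), `"muscles"` (activation and force per
#'   muscle), or `"sections"` (compression/shear per level).
#' @param ... Unused.
#' @return A long tibble.
#' @export
tidy.spine_sim <- function(x, what = c("nodes", "muscles", "sections"), ...) {
  what <- match.arg(what)
  res <- x$raw
  anat <- x$geometry$anatomical
  n_lev <- length(anat) - 1L
  if (what == "nodes") {
    lumbar <- rev(anat[-1])                      # L1 first
    labs <- paste0("L", seq_len(n_lev))
    cols <- 3 * (lumbar - 1) + 2
    z <- res$U[, cols, drop = FALSE] * 1000
    zt <- x$geometry$coords[lumbar, 2] * 1000
    purrr::map_dfr(seq_len(n_lev), function(i) {
      tibble::tibble(
        time_s = res$time, node = labs[i],
        z_mm = z[, i] + zt[i], target_z_mm = zt[i],
        error_mm = -z[, i],
        zdot_mm_s = res$V[, cols[i]] * 1000
      )
    })
  } else if (what == "muscles") {
    purrr::map_dfr(seq_len(nrow(x$muscles)), function(m) {
      tibble::tibble(
        time_s = res$time,
        level = as.character(x$muscles$level[m]), side = x$muscles$side[m],
        alpha = res$alpha[, m], force_N = res$force[, m]
      )
    })
  } else {
    seg <- element_segment(x$geometry)
    rep_el <- vapply(seq_len(n_lev), function(s) max(which(seg == s)), 1L)
    labs <- level_names(n_lev)
    purrr::map_dfr(seq_len(n_lev), function(k) {
      tibble::tibble(
        time_s = res$time, level = labs[k],
        compression_N = -res$axial[, rep_el[k]],
        shear_N = res$shear_local[, rep_el[k]]
      )
    })
  }
}

#' One-row summary of a simulation
#'
#' @param x A `spine_sim`.
#' @param ... Unused.
#' @return Tibble with convergence flag and time, steady and whole-run
#'   maximum tracking errors, maximum follower-load angle, L5-S1 compression
#'   and the number of active muscles (steady alpha > 0.01).
#' @export
glance.spine_sim <- function(x, ...) {
  sl <- if (!isTRUE(x$unstable)) section_loads(x) else NULL
  tibble::tibble(
    case = if (!is.null(x$case$case)) as.character(x$case$case) else "custom",
    control = x$control,
    unstable = isTRUE(x$unstable),
    converged = isTRUE(x$steady$converged),
    t_converged_s = x$steady$t_converged %||% NA_real_,
    steady_max_err_mm = x$steady$max_err_mm %||% NA_real_,
    learning_max_err_mm = x$steady$max_err_all_mm %||% NA_real_,
    max_fl_angle_deg = if (!is.null(sl)) {
      follower_load_angle(sl)$max_angle_deg
    } else NA_real_,
    compression_L5S1_N = if (!is.null(sl)) {
      sl$compression_N[sl$level == "L5-S1"]
    } else NA_real_,
    n_active_muscles = if (!is.null(x$steady$alpha)) {
      sum(x$steady$alpha > 0.01)
    } else NA_integer_
  )
}

#' @export
tidy.fl_equilibrium <- function(x, ...) {
  dplyr::left_join(
    x$section_loads,
    tibble::tibble(
      level = level_names(nrow(x$muscle_forces)),
      muscle_level = rev(as.character(x$muscle_forces$level)),
      muscle_side = rev(x$muscle_forces$side),
      muscle_force_N = rev(x$muscle_forces$force_N)
    ),
    by = "level"
  )
}

#' @export
glance.fl_equilibrium <- function(x, ...) {
  tibble::tibble(
    case = if (!is.null(x$case$case)) as.character(x$case$case) else "custom",
    tangent = x$tangent,
    residual_shear_N = x$residual_shear_N,
    compression_L5S1_N =
      x$section_loads$compression_N[x$section_loads$level == "L5-S1"],
    sum_muscle_N = sum(x$muscle_forces$force_N)
  )
}

#' @export
tidy.spine_sweep <- function(x, ...) x$forces

#' @export
glance.spine_sweep <- function(x, ...) {
  tibble::tibble(
    n_loads = length(unique(x$forces$L1_load_N)),
    all_converged = all(x$forces$converged),
    min_r_squared_active = {
      # linearity is claimed for the recruited muscles: those above the
      # activation threshold (alpha > 0.01) at every sweep point
      act <- x$forces |>
        dplyr::group_by(.data$level, .data$side) |>
        dplyr::summarise(mn = min(.data$alpha), .groups = "drop") |>
        dplyr::filter(.data$mn > 0.01)
      f <- dplyr::semi_join(x$fits, act, by = c("level", "side"))
      if (nrow(f)) min(f$r_squared, na.rm = TRUE) else NA_real_
    }
  )
}

#' Plot the tracking transient of a run
#'
#' @param object A `spine_sim`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spine_sim <- function(object, ...) {
  d <- tidy(object, "nodes")
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$error_mm,
                                  colour = .data$node)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "lateral tracking error (mm)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot muscle forces versus external L1 load
#'
#' @param object A `spine_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spine_sweep <- function(object, ...) {
  d <- dplyr::filter(object$forces, .data$force_N > 0.5)
  ggplot2::ggplot(d, ggplot2::aes(.data$L1_load_N, .data$force_N,
                                  colour = .data$level,
                                  linetype = .data$side)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "L1 load (N)", y = "steady-state muscle force (N)") +
    ggplot2::theme_minimal()
}

#' Plot per-level compression for both models
#'
#' @param object A `model_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.model_comparison <- function(object, ...) {
  d <- object$section_loads |>
    tidyr::pivot_longer(
      cols = c("control_compression_N", "equilibrium_compression_N"),
      names_to = "model", values_to = "compression_N"
    ) |>
    dplyr::mutate(model = sub("_compression_N", "", .data$model))
  ggplot2::ggplot(d, ggplot2::aes(.data$level, .data$compression_N,
                                  fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "compression (N)") +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
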