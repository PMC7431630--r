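#' Follower-load angle per level
#'
#' The absolute angle between the resultant internal force transmitted
#' across each section and the local deformed tangent -- the direction a
#' hypothetical follower load would take.  `angle = atan2(|shear|,
#' compression)` in degrees; small angles mean the spine carries a near-pure
#' follower load.
#'
#' @param section_loads Tibble with `level`, `compression_N`, `shear_N`
#'   (from [section_loads()] or [solve_follower_load()]).
#' @return Object of class `fl_angle`: tibble `per_level` (level,
#'   angle_deg) plus `max_angle_deg`.
#' @export
#' @examples
#' follower_load_angle(tibble::tibble(
#'   level = "L5-S1", compression_N = 100, shear_N = 5
#' ))
follower_load_angle <- function(section_loads) {
  stopifnot(all(c("level", "compression_N", "shear_N") %in%
                  names(section_loads)))
  if (any(section_loads$compression_N <= 0)) {
    stop("compression must be positive for a meaningful resultant direction")
  }
  ang <- atan2(abs(section_loads$shear_N), section_loads$compression_N) *
    180 / pi
  structure(
    list(
      per_level = tibble::tibble(level = section_loads$level,
                                 angle_deg = ang),
      max_angle_deg = max(ang)
    ),
    class = "fl_angle"
  )
}

#' @export
print.fl_angle <- function(x, ...) {
  cat("<fl_angle> max ", signif(x$max_angle_deg, 3), " deg\n", sep = "")
  print(x$per_level, ...)
  invisible(x)
}

#' Write summary tables for a set of converged runs
#'
#' Emits plain CSV tables: per-case section loads (levels x
#' compression/shear), per-case muscle forces, follower-load angles, and --
#' when a sweep is supplied -- the force-versus-load table with its linear
#' fits.  All numbers are N, mm and degrees.
#'
#' @param results Named list of converged `spine_sim` objects (names used as
#'   case labels).
#' @param dir Output directory (created if missing).
#' @param sweep Optional `spine_sweep`.
#' @param equilibria Optional named list of matching [solve_follower_load()]
#'   solutions merged into the section-load table.
#' @return Invisibly, the paths written.
#' @export
write_summary <- function(results, dir, sweep = NULL, equilibria = NULL) {
  if (length(results) == 0) stop("no results to summarize")
  if (is.null(names(results))) names(results) <- seq_along(results)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  loads <- purrr::imap_dfr(results, function(r, nm) {
    sl <- section_loads(r)
    sl$case <- nm
    sl$model <- "control"
    sl
  })
  if (!is.null(equilibria)) {
    loads <- dplyr::bind_rows(
      loads,
      purrr::imap_dfr(equilibria, function(e, nm) {
        sl <- e$section_loads
        sl$case <- nm
        sl$model <- "equilibrium"
        sl
      })
    )
  }
  forces <- purrr::imap_dfr(results, function(r, nm) {
    tibble::tibble(case = nm, level = r$muscles$level, side = r$muscles$side,
                   force_N = r$steady$force_N, alpha = r$steady$alpha)
  })
  angles <- purrr::imap_dfr(results, function(r, nm) {
    a <- follower_load_angle(section_loads(r))
    d <- a$per_level
    d$case <- nm
    d
  })

  paths <- c(
    section_loads = file.path(dir, "section_loads.csv"),
    muscle_forces = file.path(dir, "muscle_forces.csv"),
    fl_angles = file.path(dir, "fl_angles.csv")
  )
  utils::write.csv(loads, paths["section_loads"], row.names = FALSE)
  utils::write.csv(forces, paths["muscle_forces"], row.names = FALSE)
  utils::write.csv(angles, paths["fl_angles"], row.names = FALSE)
  if (!is.null(sweep)) {
    paths <- c(paths, sweep = file.path(dir, "sweep_forces.csv"),
               sweep_fits = file.path(dir, "sweep_fits.csv"))
    utils::write.csv(sweep$forces, paths["sweep"], row.names = FALSE)
    utils::write.csv(sweep$fits, paths["sweep_fits"], row.names = FALSE)
  }

  report <- file.path(dir, "report.txt")
  lines <- c(
    "spinectrl run summary",
    purrr::imap_chr(results, function(r, nm) {
      sprintf(
        "case %s: converged=%s t=%.2fs steady max|e|=%.3f mm, max FL angle %.2f deg",
        nm, r$steady$converged,
        ifelse(is.na(r$steady$t_converged), -1, r$steady$t_converged),
        r$steady$max_err_mm,
        follower_load_angle(section_loads(r))$max_angle_deg
      )
    })
  )
  writeLines(lines, report)
  invisible(c(paths, report = report))
}
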