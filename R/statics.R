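#' Static fixed point of the controlled spine
#'
#' Independent oracle for the dynamic simulation: at the controllers' fixed
#' point the tracking errors vanish, so the plant rests in static
#' equilibrium with the lumbar lateral coordinates pinned at their targets
#' and one net unilateral muscle force per level supplying exactly the
#' lateral force the posture requires.  This routine solves that constrained
#' static problem directly (signed muscle intensities via Newton on the
#' lateral reaction residuals, with the nonlinear frame re-solved inside),
#' without any controller dynamics.
#'
#' @param case A [loading_case()] or integer.
#' @param geometry A [spine_geometry()].
#' @param muscles Optional [muscle_set()].
#' @return List with `muscle_forces` (tibble: level, side, force_N),
#'   `section_loads`, the displacement vector `u` and the residual.
#' @export
solve_control_static <- function(case, geometry = spine_geometry(),
                                 muscles = NULL) {
  if (!inherits(case, "loading_case")) case <- loading_case(case)
  if (is.null(muscles)) muscles <- muscle_set(geometry, D_mm = case$D_mm)
  anat <- geometry$anatomical
  n_lev <- length(anat) - 1L
  lev_nodes <- rev(anat[-1])                  # L1 first
  nn <- nrow(geometry$coords)
  nd <- 3L * nn

  fext <- numeric(nd)
  fext[3 * (lev_nodes - 1) + 1] <- -case$P[seq_len(n_lev)]
  zdofs <- 3 * (lev_nodes - 1) + 2
  fix <- c(1:3, zdofs)

  Dm <- case$D_mm / 1000
  musc_force <- function(Fs, u) {
    f <- numeric(nd)
    for (i in seq_len(n_lev)) {
      side <- if (Fs[i] >= 0) 1 else -1
      ndx <- lev_nodes[i]
      ins <- geometry$coords[ndx, ] + u[c(3 * ndx - 2, 3 * ndx - 1)]
      d <- c(0, side * Dm) - ins
      uv <- d / sqrt(sum(d^2))
      f[c(3 * ndx - 2, 3 * ndx - 1)] <-
        f[c(3 * ndx - 2, 3 * ndx - 1)] + abs(Fs[i]) * uv
    }
    f
  }

  lat_residual <- function(Fs) {
    u <- numeric(nd)
    free <- setdiff(seq_len(nd), fix)
    for (it in 1:80) {
      a <- assemble_tangent(geometry, u)
      r <- a$f - fext - musc_force(Fs, u)
      if (sqrt(sum(r[free]^2)) < 1e-10) break
      du <- solve(a$K[free, free], -r[free])
      mx <- max(abs(du))
      if (mx > 0.02) du <- du * 0.02 / mx
      u[free] <- u[free] + du
    }
    a <- assemble_tangent(geometry, u)
    r <- a$f - fext - musc_force(Fs, u)
    list(rz = r[zdofs], u = u, ends = a$ends)
  }

  Fs <- rep(1, n_lev)
  for (outer in 1:60) {
    r0 <- lat_residual(Fs)
    if (max(abs(r0$rz)) < 1e-8) break
    J <- matrix(0, n_lev, n_lev)
    h <- 1e-3
    for (k in seq_len(n_lev)) {
      Fp <- Fs
      Fp[k] <- Fp[k] + h
      J[, k] <- (lat_residual(Fp)$rz - r0$rz) / h
    }
    dF <- solve(J, -r0$rz)
    mx <- max(abs(dF))
    if (mx > 200) dF <- dF * 200 / mx
    Fs <- Fs + dF
  }
  r0 <- lat_residual(Fs)

  lev_lab <- paste0("L", seq_len(n_lev))
  list(
    muscle_forces = tibble::tibble(
      level = factor(lev_lab, levels = lev_lab),
      side = ifelse(Fs >= 0, "right", "left"),
      force_N = abs(Fs)
    ),
    section_loads = recover_section_loads(geometry, r0$ends),
    u = r0$u,
    residual_N = max(abs(r0$rz))
  )
}
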