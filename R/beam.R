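#' Assemble the tangent stiffness and internal forces of the spine frame
#'
#' Geometrically nonlinear (corotational) assembly of the 2D beam-column
#' chain: material bending/axial terms plus the geometric (stress-stiffening)
#' terms from the current element axial forces.  The tangent is the exact
#' derivative of the internal force vector.
#'
#' @param geometry A [spine_geometry()].
#' @param u Displacement vector, length `3 * n_nodes`, ordered
#'   `(uX, uZ, theta)` per node, SI units (m, rad).  Defaults to zero.
#' @return List with `f` (internal force vector, N / N m), `K` (tangent
#'   stiffness), and `ends` (matrix, one row per element: axial force `N`
#'   with tension positive, local shear `V` positive toward the local
#'   +normal).
#' @export
assemble_tangent <- function(geometry, u = NULL) {
  nd <- 3L * nrow(geometry$coords)
  if (is.null(u)) u <- numeric(nd)
  stopifnot(length(u) == nd)
  cpp_assemble(geometry$coords, u, geometry$EA, geometry$EI)
}

#' Static solution of the spine frame under nodal loads
#'
#' Full Newton iteration on the corotational frame with the base clamped.
#' Singularity of the tangent operator (structural instability, e.g. axial
#' load beyond the buckling threshold) is reported, never regularised.
#'
#' @param geometry A [spine_geometry()].
#' @param fext External nodal force vector (length `3 * n_nodes`, N).
#' @param u0 Optional starting displacement vector.
#' @param fixed_dofs Indices of constrained dofs; defaults to the three base
#'   dofs (clamped sacrum).
#' @param extra_force Optional function `u -> list(f = ..., K = ...)` adding
#'   configuration-dependent forces (e.g. muscles) and their stiffness.
#' @param tol Relative residual tolerance.
#' @param maxit Maximum Newton iterations.
#' @return List with `u`, `converged`, `singular`, `iterations`, and the
#'   final assembly (`f`, `K`, `ends`).
#' @export
static_solve <- function(geometry, fext, u0 = NULL, fixed_dofs = 1:3,
                         extra_force = NULL, tol = 1e-9, maxit = 100L) {
  nd <- 3L * nrow(geometry$coords)
  stopifnot(length(fext) == nd)
  free <- setdiff(seq_len(nd), fixed_dofs)
  u <- if (is.null(u0)) numeric(nd) else u0
  fscale <- max(1, sqrt(sum(fext^2)))
  singular <- FALSE
  a <- NULL
  converged <- FALSE
  for (it in seq_len(maxit)) {
    a <- assemble_tangent(geometry, u)
    r <- a$f - fext
    K <- a$K
    if (!is.null(extra_force)) {
      xf <- extra_force(u)
      r <- r - xf$f
      if (!is.null(xf$K)) K <- K - xf$K
    }
    if (sqrt(sum(r[free]^2)) < tol * fscale) {
      converged <- TRUE
      break
    }
    du <- tryCatch(solve(K[free, free], -r[free]), error = function(e) NULL)
    if (is.null(du) || any(!is.finite(du))) {
      singular <- TRUE
      break
    }
    # trust-region style cap on the increment (large-rotation robustness)
    mx <- max(abs(du))
    if (mx > 0.02) du <- du * 0.02 / mx
    u[free] <- u[free] + du
  }
  list(
    u = u, converged = converged, singular = singular, iterations = it,
    f = a$f, K = a$K, ends = a$ends
  )
}

#' Recover compression and shear per lumbar level
#'
#' Projects the internal force transmitted across each inter-vertebral
#' section onto the local deformed element tangent (compression, positive
#' compressive) and normal (shear, positive toward +Z).  Loads are constant
#' per element for nodal loading and reported at the element adjacent to each
#' level label; under mesh refinement the sub-element just below the upper
#' vertebra of the level is used.
#'
#' @param geometry A [spine_geometry()].
#' @param ends Element end-force matrix as returned by [assemble_tangent()]
#'   or [static_solve()] (`N` tension-positive, local shear `V`).
#' @return Tibble with `level`, `compression_N`, `shear_N` ordered from
#'   L5-S1 upward.
#' @export
recover_section_loads <- function(geometry, ends) {
  seg <- element_segment(geometry)
  n_seg <- length(geometry$anatomical) - 1L
  # representative element of each anatomical segment: the top sub-element
  rep_el <- vapply(seq_len(n_seg), function(s) max(which(seg == s)), 1L)
  tibble::tibble(
    level = level_names(n_seg),
    compression_N = -ends[rep_el, 1],
    shear_N = ends[rep_el, 2]
  )
}

#' Smallest axial tip load that makes the tangent operator singular
#'
#' Bisection on the tip load of the (straight or curved) column for loss of
#' positive definiteness of the tangent stiffness at the pre-buckling
#' equilibrium; for a straight fixed-free column this converges to the Euler
#' load `pi^2 EI / (4 L^2)`.
#'
#' @param geometry A [spine_geometry()].
#' @param p_range Bracketing interval for the load (N).
#' @param tol Bisection tolerance (N).
#' @return The critical load in N.
#' @export
critical_buckling_load <- function(geometry, p_range = c(1, 1000),
                                   tol = 0.01) {
  nd <- 3L * nrow(geometry$coords)
  tip <- nrow(geometry$coords)
  stable_at <- function(P) {
    fext <- numeric(nd)
    fext[3 * (tip - 1) + 1] <- -P
    s <- static_solve(geometry, fext)
    if (!s$converged || s$singular) return(FALSE)
    free <- 4:nd
    ev <- eigen(s$K[free, free], symmetric = TRUE, only.values = TRUE)$values
    min(ev) > 0
  }
  lo <- p_range[1]
  hi <- p_range[2]
  if (!stable_at(lo)) stop("lower bracket already unstable")
  if (stable_at(hi)) stop("upper bracket still stable; widen p_range")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (stable_at(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Small analytic test models with closed-form expectations
#'
#' Fixture generator for oracle checks: a tip-loaded cantilever (deflection
#' `F L^3 / 3 EI`), a fixed-free column at its Euler buckling load
#' (`pi^2 EI / 4 L^2`), and a single muscle holding one lateral load in pure
#' statics.
#'
#' @param kind One of `"cantilever"`, `"column_buckling"`, `"single_muscle"`.
#' @param n_elements Mesh resolution for the beam fixtures.
#' @param L Column length (m); `EI` flexural rigidity (N m^2); `F` applied
#'   load (N) for the cantilever.
#' @param EI Flexural rigidity in N m^2.
#' @param F Applied load in N.
#' @return List with a `geometry`, a load description, and `expected` (the
#'   closed-form value: tip deflection in mm, critical load in N, or required
#'   muscle tension in N).
#' @export
make_toy_fixture <- function(kind = c("cantilever", "column_buckling",
                                      "single_muscle"),
                             n_elements = 16L, L = 0.19, EI = 1.9, F = 1) {
  kind <- match.arg(kind)
  straight <- function(n) {
    tibble::tibble(
      node = paste0("n", 0:n),
      x_mm = seq(0, L * 1000, length.out = n + 1),
      z_mm = 0
    )
  }
  if (kind == "cantilever") {
    geo <- spine_geometry(straight(n_elements), EI = EI)
    list(
      geometry = geo, tip_load_N = F,
      expected = list(tip_deflection_mm = F * L^3 / (3 * EI) * 1000)
    )
  } else if (kind == "column_buckling") {
    geo <- spine_geometry(straight(n_elements), EI = EI)
    list(
      geometry = geo,
      expected = list(critical_load_N = pi^2 * EI / (4 * L^2))
    )
  } else {
    # one node held by one muscle at angle phi against lateral load W
    phi <- atan2(50, 190)                     # muscle line angle from vertical
    W <- F
    list(
      node_mm = c(190, 0), origin_mm = c(0, -50), lateral_load_N = W,
      expected = list(required_tension_N = W / sin(phi))
    )
  }
}
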