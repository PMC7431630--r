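#' Hill-type muscle force components
#'
#' The phenomenological muscle law
#' `F = f_max * (alpha * fl(l) * fv(ldot) + fp(l))` combines an
#' activation-scaled active force-length and force-velocity term with a
#' passive elastic term.  The three dimensionless factors are:
#'
#' * `force_length()`: the quartic
#'   `fl = 5.1 - 29 r + 56 r^2 - 41 r^3 + 10 r^4` in `r = l / l0`,
#'   clamped at 0 where the polynomial is negative (a muscle cannot push);
#' * `force_velocity()`:
#'   `fv = 0.1433 / (0.1074 + exp(-1.409 sinh(3.2 x + 1.6)))` in
#'   `x = ldot / ldot_max`, strictly increasing (lengthening raises force);
#' * `passive_force()`: `fp = exp(-10.671 + 7.675 r)`.
#'
#' @param l Muscle length (same units as `l0`).
#' @param l0 Resting length.
#' @param ldot Lengthening velocity (positive = lengthening).
#' @param ldot_max Maximum contraction velocity; the model convention is
#'   `ldot_max = l0 / 0.1 s`.
#' @return Dimensionless factor(s); vectorised.
#' @name hill_components
#' @examples
#' force_length(1, 1)              # 1.1 at resting length
#' force_velocity(0, 1)            # ~1.005 isometric
#' passive_force(1, 1)             # ~0.05
NULL

#' @rdname hill_components
#' @export
force_length <- function(l, l0) {
  if (any(l <= 0) || any(l0 <= 0)) stop("lengths must be positive")
  r <- l / l0
  pmax(5.1 - 29 * r + 56 * r^2 - 41 * r^3 + 10 * r^4, 0)
}

#' @rdname hill_components
#' @export
force_velocity <- function(ldot, ldot_max) {
  if (any(ldot_max <= 0)) stop("ldot_max must be positive")
  x <- ldot / ldot_max
  0.1433 / (0.1074 + exp(-1.409 * sinh(3.2 * x + 1.6)))
}

#' @rdname hill_components
#' @export
passive_force <- function(l, l0) {
  if (any(l <= 0) || any(l0 <= 0)) stop("lengths must be positive")
  exp(-10.671 + 7.675 * l / l0)
}

#' Total Hill muscle force
#'
#' `F = f_max * (alpha * fl * fv + fp)`; the activation is clipped to
#' `[0, 1]` and the result is never negative (tensile-only line actuator).
#'
#' @inheritParams hill_components
#' @param alpha Activation level, clipped to `[0, 1]`.
#' @param f_max Maximum isometric force (N).
#' @param passive Include the passive term?  The plant model excludes it by
#'   default (see the package vignette); at the function level it defaults to
#'   the full composition.
#' @return Force in N; vectorised.
#' @export
#' @examples
#' muscle_force(0, 1, 0, 1, 10, f_max = 800)    # pure passive tone, ~40 N
#' muscle_force(1, 1, 0, 1, 10, f_max = 800)    # ~924 N
muscle_force <- function(alpha, l, ldot, l0, ldot_max, f_max = 800,
                         passive = TRUE) {
  alpha <- pmin(pmax(alpha, 0), 1)
  act <- alpha * force_length(l, l0) * force_velocity(ldot, ldot_max)
  f_max * (act + if (passive) passive_force(l, l0) else 0)
}

#' Build the ten-muscle set for a loading case
#'
#' Five bilateral pairs of straight-line actuators run from origins on the
#' fixed base at `(X = 0, Z = +/- D)` to the lumbar vertebral centres L1..L5.
#' Resting lengths default to each muscle's length in the target posture, so
#' the defended posture is also the muscles' reference state.
#'
#' @param geometry A [spine_geometry()].
#' @param D_mm Lateral offset of the muscle origins on the base (mm).
#' @param f_max Maximum isometric force per muscle (N).
#' @param l0_mm Optional resting-length override (vector of 10, mm).
#' @param passive Logical; carry the passive term into the plant coupling.
#'   Defaults to `FALSE`: with `l0` anchored at the target posture the
#'   passive term would add about 40 N of resting tension per muscle, a
#'   compressive preload the modelled spinal loads do not contain.
#' @return Tibble of class `muscle_set`: one row per muscle with level, side,
#'   origin/insertion coordinates (mm), `l0_mm`, `ldot_max_mm_s`, `f_max_N`,
#'   insertion node index, error weight `ke` and Jacobian sign `jsign`.
#' @export
#' @examples
#' muscle_set(spine_geometry(), D_mm = 50)
muscle_set <- function(geometry, D_mm = 50, f_max = 800, l0_mm = NULL,
                       passive = FALSE) {
  if (D_mm <= 0) stop("muscle origin offset D must be positive")
  anat <- geometry$anatomical
  n_lev <- length(anat) - 1L
  lev_labels <- paste0("L", seq_len(n_lev))            # L1 is the top
  ins_nodes <- rev(anat[-1])                           # node of L1 first
  ke_default <- c(15, 7, 2.5, 1, 0.1)[seq_len(n_lev)]

  grid <- tidyr::expand_grid(
    level = factor(lev_labels, levels = lev_labels),
    side = c("left", "right")
  )
  grid$insertion_node <- rep(ins_nodes, each = 2)
  grid$origin_x_mm <- 0
  grid$origin_z_mm <- ifelse(grid$side == "left", -D_mm, D_mm)
  grid$insertion_x_mm <- geometry$coords[grid$insertion_node, 1] * 1000
  grid$insertion_z_mm <- geometry$coords[grid$insertion_node, 2] * 1000
  len <- sqrt((grid$insertion_x_mm - grid$origin_x_mm)^2 +
                (grid$insertion_z_mm - grid$origin_z_mm)^2)
  grid$l0_mm <- if (is.null(l0_mm)) len else l0_mm
  grid$ldot_max_mm_s <- grid$l0_mm / 0.1
  grid$f_max_N <- f_max
  grid$ke <- rep(ke_default, each = 2)
  grid$passive <- passive
  out <- assign_jacobian_signs(grid)
  class(out) <- c("muscle_set", class(out))
  out
}

#' Muscle length, velocity and line of action from a plant state
#'
#' Straight-line kinematics in the deformed configuration: the length is the
#' Euclidean distance origin to insertion, the lengthening velocity is the
#' analytic projection of the insertion nodal velocity on the line of action
#' (not a finite difference), and the unit vector points origin to insertion.
#'
#' @param muscles A [muscle_set()].
#' @param geometry The [spine_geometry()] the set was built on.
#' @param u,v Displacement and velocity vectors (SI), as in [static_solve()].
#' @return Tibble with `l_mm`, `ldot_mm_s`, `ux`, `uz` per muscle.
#' @export
muscle_kinematics <- function(muscles, geometry, u = NULL, v = NULL) {
  nd <- 3L * nrow(geometry$coords)
  if (is.null(u)) u <- numeric(nd)
  if (is.null(v)) v <- numeric(nd)
  idx <- muscles$insertion_node
  ins_x <- geometry$coords[idx, 1] * 1000 + u[3 * (idx - 1) + 1] * 1000
  ins_z <- geometry$coords[idx, 2] * 1000 + u[3 * (idx - 1) + 2] * 1000
  dx <- ins_x - muscles$origin_x_mm
  dz <- ins_z - muscles$origin_z_mm
  l <- sqrt(dx^2 + dz^2)
  if (any(l < 1e-9)) stop("muscle origin and insertion coincide")
  ux <- dx / l
  uz <- dz / l
  vx <- v[3 * (idx - 1) + 1] * 1000
  vz <- v[3 * (idx - 1) + 2] * 1000
  tibble::tibble(
    level = muscles$level, side = muscles$side,
    l_mm = l, ldot_mm_s = ux * vx + uz * vz,
    ux = ux, uz = uz
  )
}

#' Assign the control Jacobian sign of each muscle
#'
#' For a single-input single-output loop only the sign of
#' `j = dZ / dalpha` is needed: a muscle whose origin sits at `-D` pulls its
#' insertion toward `-Z`, so `j = -1`; the mirrored muscle has `j = +1`.
#' The sign is fixed for the whole simulation.
#'
#' @param muscles A muscle table with `origin_z_mm` and `insertion_z_mm`.
#' @return The table with a `jsign` column added.
#' @export
assign_jacobian_signs <- function(muscles) {
  dz <- muscles$origin_z_mm - muscles$insertion_z_mm
  if (any(abs(dz) < 1e-12)) {
    stop("muscle line of action has no lateral component; Jacobian sign undefined")
  }
  muscles$jsign <- ifelse(dz > 0, 1L, -1L)
  muscles
}
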