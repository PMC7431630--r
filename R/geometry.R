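#' Reference nodal coordinates of the laterally flexed lumbar spine
#'
#' The frontal-plane posture the controllers defend: the sacrum base at the
#' origin plus the five lumbar vertebral centres L5 up to L1.  X is vertical
#' (gravity acts in -X), Z is lateral.
#'
#' @return A tibble with columns `node` (`"S1"`, `"L5"` ... `"L1"`),
#'   `x_mm` and `z_mm`.
#' @export
#' @examples
#' lumbar_nodes()
lumbar_nodes <- function() {
  tibble::tibble(
    node = c("S1", "L5", "L4", "L3", "L2", "L1"),
    x_mm = c(0, 38, 80, 105, 150, 190),
    z_mm = c(0, 0.4, 1.7, 3.0, 6.2, 10.0)
  )
}

#' Build the beam-column geometry of the lumbar spine
#'
#' Constructs a validated chain of two-node beam elements from the sacrum base
#' to L1.  The default geometry is the reference laterally bent posture with a
#' flexural rigidity of 1.9 N m^2 and a constant cross-section of 1225 mm^2
#' (a 35 mm square section, from which the axial rigidity `EA` is derived as
#' `E = EI / I`; axial strain is negligible either way).
#'
#' @param nodes Data frame with columns `node`, `x_mm`, `z_mm`, ordered from
#'   the fixed base upward.  Defaults to [lumbar_nodes()].
#' @param EI Flexural rigidity in N m^2.
#' @param area_mm2 Cross-section area in mm^2 (used only to derive `EA`).
#' @param refine Integer; number of sub-elements each anatomical segment is
#'   split into (mesh refinement).  Refinement inserts nodes on the straight
#'   chords; the anatomical nodes are tracked so that muscles and controllers
#'   always act on the vertebral centres.
#' @return An object of class `spine_geometry`: a list with the node table
#'   (tibble, mm), `coords` (matrix in metres, one row per mesh node), the
#'   indices of the anatomical nodes, `EI`, `EA` and element count.
#' @export
#' @examples
#' geo <- spine_geometry()
#' geo
spine_geometry <- function(nodes = lumbar_nodes(), EI = 1.9, area_mm2 = 1225,
                           refine = 1L) {
  stopifnot(is.data.frame(nodes), all(c("x_mm", "z_mm") %in% names(nodes)))
  if (!"node" %in% names(nodes)) nodes$node <- paste0("n", seq_len(nrow(nodes)))
  nodes <- tibble::as_tibble(nodes)
  if (nrow(nodes) < 2) stop("need at least two nodes (base + one vertebra)")
  if (is.null(EI) || !is.finite(EI) || EI <= 0) {
    stop("flexural rigidity EI must be a positive number")
  }
  if (area_mm2 <= 0) stop("cross-section area must be positive")
  if (any(diff(nodes$x_mm) <= 0)) {
    stop("node X coordinates must increase strictly from base to top")
  }
  refine <- as.integer(refine)
  stopifnot(refine >= 1L)

  side_mm <- sqrt(area_mm2)            # square section
  I_m4 <- (side_mm / 1000)^4 / 12
  E <- EI / I_m4
  EA <- E * (area_mm2 * 1e-6)

  base <- cbind(nodes$x_mm, nodes$z_mm) / 1000
  if (refine == 1L) {
    coords <- base
    anat <- seq_len(nrow(base))
  } else {
    coords <- base[1, , drop = FALSE]
    anat <- 1L
    for (e in seq_len(nrow(base) - 1)) {
      for (s in seq_len(refine)) {
        p <- base[e, ] + (s / refine) * (base[e + 1, ] - base[e, ])
        coords <- rbind(coords, p)
      }
      anat <- c(anat, nrow(coords))
    }
  }

  structure(
    list(
      nodes = nodes, coords = coords, anatomical = anat,
      EI = EI, EA = EA, area_mm2 = area_mm2,
      n_elements = nrow(coords) - 1L, refine = refine
    ),
    class = "spine_geometry"
  )
}

#' @export
print.spine_geometry <- function(x, ...) {
  cat("<spine_geometry> ", nrow(x$coords), " nodes / ", x$n_elements,
      " elements (refine = ", x$refine, ")\n", sep = "")
  cat("  EI = ", x$EI, " N m^2, EA = ", signif(x$EA, 4), " N\n", sep = "")
  print(x$nodes, ...)
  invisible(x)
}

#' @export
tidy.spine_geometry <- function(x, ...) x$nodes

# names of the inter-vertebral levels, element k joins mesh segment k:
# element between anatomical nodes i and i+1
level_names <- function(n_lumbar = 5L) {
  labs <- c("L5-S1", "L4-L5", "L3-L4", "L2-L3", "L1-L2")
  rev(rev(labs)[seq_len(n_lumbar)])
}

# map each mesh element to the anatomical segment it belongs to
element_segment <- function(geometry) {
  anat <- geometry$anatomical
  seg <- integer(geometry$n_elements)
  for (k in seq_along(anat)[-1]) {
    seg[(anat[k - 1]):(anat[k] - 1)] <- k - 1L
  }
  seg
}
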