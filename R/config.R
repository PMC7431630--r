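#' Read a run configuration file
#'
#' A structured YAML description of a run.  Recognised blocks (all optional;
#' defaults are the study conditions):
#'
#' ```yaml
#' geometry:
#'   EI: 1.9            # N m^2
#'   area_mm2: 1225
#'   refine: 1
#'   nodes:             # omit to use the built-in posture
#'     - {node: S1, x_mm: 0, z_mm: 0}
#' loading:
#'   case: 2            # or P: [350, 50, 50, 50, 50] with D_mm: 50
#'   ramp_time: 0.2
#' muscles: {f_max: 800, passive: false}
#' controller:
#'   h1: 2, h2: 2, h3: 2, kalpha: 0.2
#'   ke: [15, 7, 2.5, 1, 0.1]
#'   eta: 0.002
#'   grid: 7
#' simulation: {dt: 0.001, t_end: 25}
#' ```
#'
#' @param path Path to the YAML file.
#' @return List with `geometry`, `case`, `muscles`, `gains`, `net`,
#'   `config`, ready to pass to [simulate_case()].
#' @export
read_spine_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read configuration files")
  }
  cf <- yaml::read_yaml(path)
  gb <- cf$geometry %||% list()
  nodes <- if (!is.null(gb$nodes)) {
    dplyr::bind_rows(lapply(gb$nodes, tibble::as_tibble))
  } else {
    lumbar_nodes()
  }
  geometry <- spine_geometry(
    nodes,
    EI = gb$EI %||% 1.9,
    area_mm2 = gb$area_mm2 %||% 1225,
    refine = gb$refine %||% 1L
  )
  lb <- cf$loading %||% list(case = 1)
  case <- if (!is.null(lb$case)) {
    loading_case(lb$case, ramp_time = lb$ramp_time %||% 0.2)
  } else {
    loading_case(P = unlist(lb$P), D_mm = lb$D_mm,
                 ramp_time = lb$ramp_time %||% 0.2)
  }
  mb <- cf$muscles %||% list()
  muscles <- muscle_set(geometry, D_mm = case$D_mm,
                        f_max = mb$f_max %||% 800,
                        passive = isTRUE(mb$passive))
  cb <- cf$controller %||% list()
  gains <- controller_gains(
    h1 = cb$h1 %||% 2, h2 = cb$h2 %||% 2, h3 = cb$h3 %||% 2,
    kalpha = cb$kalpha %||% 0.2,
    ke = unlist(cb$ke %||% c(15, 7, 2.5, 1, 0.1)),
    eta = cb$eta %||% controller_gains()$eta,
    windup_mm_s = cb$windup_mm_s %||% 50
  )
  net <- fuzzy_network(n = cb$grid %||% 7L)
  sb <- cf$simulation %||% list()
  config <- simulation_config(
    dt = sb$dt %||% 1e-3, t_end = sb$t_end %||% 25,
    node_mass = sb$node_mass %||% 0.5,
    rayleigh_beta = sb$rayleigh_beta %||% 1e-3
  )
  list(geometry = geometry, case = case, muscles = muscles, gains = gains,
       net = net, config = config)
}
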