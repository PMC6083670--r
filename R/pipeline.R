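#' Run configuration for the head-imaging experiments
#'
#' Assembles all tunable settings with defaults mirroring the reference
#' operating point: 1 GHz, 6.6 mW per element, an 8-element array at 35 mm
#' standoff, a 10 mm stroke sphere at three canonical locations in the
#' z = 26.6 mm plane, solver tolerance 1e-3 with ILU(0)-preconditioned GMRES,
#' and a six-model mesh ladder.
#'
#' @param frequency Operating frequency (Hz).
#' @param spacing Cell size of the 2D scene (mm).
#' @param shells Head shell geometry, see [default_head_shells()].
#' @param stroke_radius Stroke sphere radius (mm).
#' @param stroke_locations Named list of stroke centres (mm).
#' @param plane_z Analysis plane (mm).
#' @param n_elements,standoff Array size and radial standoff (mm).
#' @param power Transmit power per element (W).
#' @param method,tolerance,preconditioner,max_iterations Solver settings.
#' @param mesh_ladder Element sizes (mm) for the convergence protocol,
#'   finest last.
#' @param convergence_tolerance Absolute probe-|E| tolerance (V/m).
#' @param pml_depth_mm Physical PML depth (mm), held fixed across mesh sizes.
#' @param pml_order,pml_reflection PML grading order and design reflection.
#' @param margin_mm Air margin between array and PML (mm).
#' @param rho Tissue density for SAR (kg/m^3).
#' @param sar_limit SAR safety limit (W/kg).
#' @param seed Seed applied before each experiment.
#' @param out_dir Optional output directory for CSV summaries.
#' @return An object of class `run_config`.
#' @export
run_config <- function(frequency = 1e9,
                       spacing = 2,
                       shells = default_head_shells(),
                       stroke_radius = 10,
                       stroke_locations = list(
                         front = c(0, -70, 26.6),
                         centre = c(0, 0, 26.6),
                         side = c(22, 0, 26.6)
                       ),
                       plane_z = 26.6,
                       n_elements = 8, standoff = 35,
                       power = 6.6e-3,
                       method = "gmres", tolerance = 1e-3,
                       preconditioner = "ilu0", max_iterations = 4000L,
                       mesh_ladder = c(6, 4.5, 3.5, 2.8, 2.3, 2),
                       convergence_tolerance = 1e-3,
                       pml_depth_mm = 24, pml_order = 3,
                       pml_reflection = 1e-6,
                       margin_mm = 20,
                       rho = 1050, sar_limit = 2,
                       seed = 1L, out_dir = NULL) {
  if (tolerance <= 0 || tolerance >= 1) stop("`tolerance` must be in (0, 1)")
  if (frequency < 1e8 || frequency > 3e9) {
    warning("frequency outside the 0.1-3 GHz dispersion validity band")
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  structure(
    list(frequency = frequency, spacing = spacing, shells = shells,
         stroke_radius = stroke_radius, stroke_locations = stroke_locations,
         plane_z = plane_z, n_elements = n_elements, standoff = standoff,
         power = power, method = method, tolerance = tolerance,
         preconditioner = preconditioner, max_iterations = max_iterations,
         mesh_ladder = mesh_ladder,
         convergence_tolerance = convergence_tolerance,
         pml_depth_mm = pml_depth_mm, pml_order = pml_order,
         pml_reflection = pml_reflection, margin_mm = margin_mm,
         rho = rho, sar_limit = sar_limit, seed = seed, out_dir = out_dir),
    class = "run_config"
  )
}

#' Load a run configuration from a YAML file
#'
#' Reads a YAML file whose keys mirror the arguments of [run_config()];
#' unspecified keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(vals$stroke_locations)) {
    vals$stroke_locations <- lapply(vals$stroke_locations, as.numeric)
  }
  # YAML scalars like "1.0e9" arrive as strings; coerce numeric-typed keys
  defaults <- formals(run_config)
  for (nm in setdiff(names(vals), "stroke_locations")) {
    if (is.character(vals[[nm]]) && is.numeric(eval(defaults[[nm]]))) {
      vals[[nm]] <- as.numeric(vals[[nm]])
    }
  }
  do.call(run_config, vals)
}

provenance <- function(config) {
  list(config_hash = rlang::hash(unclass(config)),
       package_version = as.character(utils::packageVersion("mwihead")),
       timestamp = format(Sys.time(), tz = "UTC"))
}

#' Build the 2D simulation scene for a configuration
#'
#' Generates the synthetic layered head at the configured cell size, extracts
#' the analysis plane, pads it with air so the elliptical array and the PML
#' fit, and places the array on the head's in-plane outline at the configured
#' standoff with power-calibrated feed amplitudes.
#'
#' @param config A [run_config()].
#' @param spacing Override of the cell size (mm), used by the mesh ladder.
#' @return List with `slice` (embedded healthy `phantom_slice`), `array`
#'   layout, `amplitude` (A), `semi_axes` (in-plane head outline, mm),
#'   `plane_z` (actual grid plane, mm), `pml` spec and `config`.
#' @export
setup_scene <- function(config, spacing = config$spacing) {
  phantom <- generate_layered_head(config$shells, spacing = spacing)
  zi <- slice_index_at(phantom, "z", config$plane_z)
  slice <- extract_slice(phantom, "z", zi)
  outer_ax <- config$shells[[1]]
  scale <- sqrt(max(0, 1 - (slice$fixed_coord / outer_ax[3])^2))
  semi2 <- outer_ax[1:2] * scale
  arr <- place_array(semi2, n = config$n_elements, standoff = config$standoff,
                     z = slice$fixed_coord)
  half_extent <- semi2 + config$standoff + config$margin_mm +
    config$pml_depth_mm
  slice <- embed_slice(slice, half_extent)
  pml_cells <- max(4L, as.integer(round(config$pml_depth_mm / spacing)))
  list(
    slice = slice, array = arr,
    amplitude = source_amplitude_for_power(config$power, config$frequency),
    semi_axes = semi2, plane_z = slice$fixed_coord,
    pml = pml_spec(pml_cells, config$pml_order, config$pml_reflection),
    phantom = phantom, config = config
  )
}

scene_sources <- function(scene, element) {
  arr <- scene$array[scene$array$element %in% element, ]
  tibble::tibble(x = arr$x, y = arr$y,
                 amplitude = complex(real = scene$amplitude, imaginary = 0))
}

scene_problem <- function(scene, dielectric, element) {
  helmholtz_problem(dielectric, scene_sources(scene, element),
                    frequency = scene$config$frequency, pml = scene$pml)
}

scene_solve <- function(scene, dielectric, element) {
  cfg <- scene$config
  sys <- assemble_2d(scene_problem(scene, dielectric, element))
  solve_field(sys, method = cfg$method, tolerance = cfg$tolerance,
              max_iterations = cfg$max_iterations,
              preconditioner = cfg$preconditioner)
}

# transmitter pairing: lateral location <-> element 1 (facing +x), frontal
# <-> element 7 (facing the nose at -y), central examined from both
location_transmitters <- function(location) {
  switch(location,
    front = 7L, side = 1L, centre = c(7L, 1L),
    stop("unknown stroke location: ", location)
  )
}

#' Run the differential stroke-detection experiment
#'
#' For each configured stroke location and each stroke type, solves the
#' normal and the stroke-affected head with the paired transmitter(s)
#' (frontal location with element 7 facing the nose, lateral with element 1,
#' central with both) and derives the differential report. Deterministic for
#' a fixed configuration.
#'
#' @param config A [run_config()].
#' @return List with `reports` (named `diff_report`s), `summary` (one tibble
#'   row per case), and `contrast` (haemorrhagic vs ischaemic ordering per
#'   location/transmitter with the host-tissue label). If `config$out_dir` is
#'   set the summary is also written as `stroke_summary.csv`.
#' @export
run_stroke_experiment <- function(config = run_config()) {
  set.seed(config$seed)
  scene <- setup_scene(config)
  healthy <- build_dielectric_map(scene$slice, frequency = config$frequency)

  txs <- sort(unique(unlist(lapply(names(config$stroke_locations),
                                   location_transmitters))))
  normals <- lapply(txs, function(tx) scene_solve(scene, healthy, tx))
  names(normals) <- as.character(txs)

  reports <- list()
  rows <- list()
  for (loc in names(config$stroke_locations)) {
    ctr <- config$stroke_locations[[loc]]
    for (tx in location_transmitters(loc)) {
      for (kind in c("haemorrhagic", "ischaemic")) {
        spec <- stroke_spec(kind, centre = ctr, radius = config$stroke_radius)
        dmap <- build_dielectric_map(scene$slice, frequency = config$frequency,
                                     stroke = spec)
        sol <- scene_solve(scene, dmap, tx)
        rep <- diff_analysis(normals[[as.character(tx)]], sol, spec)
        key <- paste(loc, kind, paste0("tx", tx), sep = "_")
        reports[[key]] <- rep
        rows[[key]] <- dplyr::bind_cols(
          tibble::tibble(location = loc, transmitter = tx),
          glance.diff_report(rep)
        )
      }
    }
  }
  summary <- dplyr::bind_rows(rows)

  host <- host_tissue_labels(scene, config)
  contrast <- dplyr::bind_rows(lapply(names(config$stroke_locations), function(loc) {
    dplyr::bind_rows(lapply(location_transmitters(loc), function(tx) {
      h <- reports[[paste(loc, "haemorrhagic", paste0("tx", tx), sep = "_")]]
      i <- reports[[paste(loc, "ischaemic", paste0("tx", tx), sep = "_")]]
      out <- contrast_compare(h, i, region_label = host[[loc]])
      dplyr::bind_cols(tibble::tibble(location = loc, transmitter = tx), out)
    }))
  }))

  if (!is.null(config$out_dir)) {
    utils::write.csv(summary, file.path(config$out_dir, "stroke_summary.csv"),
                     row.names = FALSE)
  }
  structure(list(reports = reports, summary = summary, contrast = contrast),
            provenance = provenance(config))
}

# dominant healthy tissue inside each stroke sphere (the label the stroke
# contrast is judged against)
host_tissue_labels <- function(scene, config) {
  ct <- canonical_tissues()
  out <- list()
  for (loc in names(config$stroke_locations)) {
    ctr <- config$stroke_locations[[loc]]
    co <- slice_coords(scene$slice)
    dfix <- ctr[3] - scene$plane_z
    r2 <- config$stroke_radius^2 - dfix^2
    d2 <- outer((co[[1]] - ctr[1])^2, (co[[2]] - ctr[2])^2, "+")
    lab <- scene$slice$labels[d2 <= r2]
    lab <- lab[lab != TISSUE_ID[["air"]]]
    dom <- as.integer(names(which.max(table(lab))))
    out[[loc]] <- ct$tissue[match(dom, ct$canonical_id)]
  }
  out
}

#' Run the mesh-convergence protocol
#'
#' Rebuilds the healthy scene at each element size of the configured ladder
#' (finest last; the physical domain and PML depth are held fixed), solves
#' with element 7 transmitting, probes |E| at the frontal stroke-sphere centre
#' (the paper-style protocol of a stroke sphere filled with healthy tissue)
#' and applies the coarsest-model-within-tolerance selection rule.
#'
#' @param config A [run_config()].
#' @return A `convergence_report` (see [mesh_convergence_study()]).
#' @export
run_convergence_experiment <- function(config = run_config()) {
  set.seed(config$seed)
  probe <- config$stroke_locations$front[1:2]
  problems <- lapply(config$mesh_ladder, function(h) {
    scene <- setup_scene(config, spacing = h)
    healthy <- build_dielectric_map(scene$slice, frequency = config$frequency)
    scene_problem(scene, healthy, 7L)
  })
  rep <- mesh_convergence_study(problems, probe_point = probe,
                                tolerance = config$convergence_tolerance)
  if (!is.null(config$out_dir)) {
    utils::write.csv(tibble::as_tibble(rep),
                     file.path(config$out_dir, "convergence.csv"),
                     row.names = FALSE)
  }
  rep
}

#' Run the iterative-solver benchmark
#'
#' Benchmarks GMRES, FGMRES and BiCGStab on the healthy scene with element 7
#' transmitting; all methods must reproduce the same probe |E| (wall time is
#' reported, never asserted).
#'
#' @param config A [run_config()].
#' @param methods Methods to compare.
#' @return Benchmark tibble, see [solver_benchmark()].
#' @export
run_solver_benchmark <- function(config = run_config(),
                                 methods = c("gmres", "fgmres", "bicgstab")) {
  set.seed(config$seed)
  scene <- setup_scene(config)
  healthy <- build_dielectric_map(scene$slice, frequency = config$frequency)
  tb <- solver_benchmark(scene_problem(scene, healthy, 7L),
                         methods = methods,
                         tolerance = config$tolerance,
                         max_iterations = config$max_iterations,
                         preconditioner = config$preconditioner,
                         probe_point = config$stroke_locations$front[1:2])
  if (!is.null(config$out_dir)) {
    utils::write.csv(tb, file.path(config$out_dir, "benchmark.csv"),
                     row.names = FALSE)
  }
  tb
}

#' Run the SAR safety survey
#'
#' Solves the healthy head once per listed array element, computes the SAR map
#' and reports the peak local SAR, its tissue and the safety verdict per
#' transmitter.
#'
#' @param config A [run_config()].
#' @param elements Transmitting elements to survey.
#' @return Tibble with one safety row per transmitter.
#' @export
run_sar_survey <- function(config = run_config(), elements = c(1, 3, 5, 7)) {
  set.seed(config$seed)
  scene <- setup_scene(config)
  healthy <- build_dielectric_map(scene$slice, frequency = config$frequency)
  rows <- lapply(elements, function(el) {
    sol <- scene_solve(scene, healthy, el)
    chk <- peak_and_check(sar_map(sol, rho = config$rho),
                          limit = config$sar_limit)
    dplyr::bind_cols(tibble::tibble(transmitter = el), chk)
  })
  tb <- dplyr::bind_rows(rows)
  if (!is.null(config$out_dir)) {
    utils::write.csv(tb, file.path(config$out_dir, "sar_survey.csv"),
                     row.names = FALSE)
  }
  tb
}
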