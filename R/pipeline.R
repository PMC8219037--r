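# Pipeline orchestration: YAML configuration, seeded stage execution
# (synth -> measure -> raman -> stats), manifest writing. One global seed
# deterministically derives every stage seed, so a rerun of the same
# config is byte-identical.

stage_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + 104729 * index) %% 2147483647)
}

#' Default developmental stage series
#'
#' A four-stage synthetic emulation of shell-tissue development: cell
#' volume grows 13-fold from first to last stage (isometric radius factor
#' 13^(1/3)), lobe count rises from 0 (isodiametric) to 12 and bump
#' amplitude from 0 to 0.35, while the tissue phantom's intercellular
#' fraction rises from 0 to 0.45. These are the package's reference study
#' conditions for trend tests.
#'
#' @param base_radius first-stage cell radius in µm
#' @param n_stages number of stages (default 4)
#' @return list of per-stage parameter lists (`name`, `radius`, `n_lobes`,
#'   `bump_amplitude`, `ics_fraction`, `domain_factor`)
#' @export
developmental_series <- function(base_radius = 5, n_stages = 4L) {
  fac <- 13^((seq_len(n_stages) - 1) / (3 * (n_stages - 1)))
  lobes <- round(seq(0, 12, length.out = n_stages))
  amp <- seq(0, 0.35, length.out = n_stages)
  ics <- seq(0, 0.45, length.out = n_stages)
  lapply(seq_len(n_stages), function(s) {
    # lobes add volume on top of the ellipsoid; shrink the base radius so
    # the stage-to-stage *volume* factor stays on the 13-fold trajectory
    infl <- lobe_volume_inflation(lobes[s], amp[s])
    list(name = sprintf("stage%d", s),
         radius = base_radius * fac[s] / infl^(1 / 3),
         n_lobes = lobes[s], bump_amplitude = amp[s],
         ics_fraction = ics[s], domain_factor = fac[s])
  })
}

# quadrature estimate of the volume factor a K-lobe bump field adds to a
# unit ball (unjittered directions; seed jitter averages out)
lobe_volume_inflation <- function(n_lobes, amplitude, sharpness = 12) {
  if (n_lobes == 0 || amplitude == 0) return(1)
  u <- fibonacci_sphere(2000)
  d <- fibonacci_sphere(n_lobes)
  r <- 1 + amplitude * rowSums(exp(sharpness * (u %*% t(d) - 1)))
  mean(r^3)
}

#' Default pipeline configuration
#'
#' A small, fully synthetic configuration exercising every stage; all
#' fields can be overridden from a YAML file with the same structure.
#'
#' @param seed global seed
#' @param outdir output directory
#' @return nested configuration list
#' @export
default_pipeline_config <- function(seed = 1L, outdir = "scleromorph-out") {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    synth = list(
      n_per_stage = 2L,
      base_radius = 5,
      n_stages = 3L,
      spacing = c(0.6, 0.6, 0.6),
      tissue = list(n_cells = 8L, domain_size = c(30, 30, 30),
                    wall_thickness = 0, ics_fraction = 0.3,
                    spacing = c(0.75, 0.75, 0.75)),
      cube = list(shape = c(24L, 24L),
                  endmembers = c("cellulose", "pectin_de_high"),
                  noise_sd = 0.02, n_spikes = 3L)),
    measure = list(smoothing_radius = 2L),
    raman = list(k = 2L, max_iter = 300L, tol = 1e-7,
                 band_window = c(2831, 3009), despike_z = 8,
                 omp_max_atoms = 3L),
    stats = list(alpha = 0.05))
}

#' Load a pipeline configuration from YAML
#'
#' Fields present in the file override the defaults; unknown keys raise an
#' error naming the offender.
#'
#' @param path YAML file
#' @return configuration list
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- default_pipeline_config()
  merge_cfg <- function(base, over, prefix = "") {
    for (k in names(over)) {
      if (!k %in% names(base))
        stop("unknown configuration key: ", prefix, k)
      if (is.list(base[[k]]) && is.list(over[[k]]) &&
          !is.null(names(base[[k]])))
        base[[k]] <- merge_cfg(base[[k]], over[[k]], paste0(prefix, k, "."))
      else base[[k]] <- over[[k]]
    }
    base
  }
  merge_cfg(base, raw)
}

cfg_path <- function(cfg, ...) file.path(cfg$outdir, ...)

#' Synthesize pipeline inputs (label stacks, cube, truth)
#'
#' Writes per-stage lobed-cell stacks, a tissue stack, a hyperspectral
#' cube with sidecar, and a ground-truth JSON into the output directory.
#'
#' @param cfg configuration list (see [default_pipeline_config()])
#' @return (invisibly) list of written files
#' @export
cmd_synth <- function(cfg) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- developmental_series(cfg$synth$base_radius, cfg$synth$n_stages)
  files <- character(0)
  truth <- list()
  for (s in seq_along(stages)) {
    st <- stages[[s]]
    for (i in seq_len(cfg$synth$n_per_stage)) {
      sd_ <- stage_seed(cfg$seed, 100 * s + i)
      spec <- lobed_cell_spec(base_radii = rep(st$radius, 3),
                              n_lobes = st$n_lobes,
                              bump_amplitude = st$bump_amplitude,
                              spacing = cfg$synth$spacing, seed = sd_)
      cell <- make_lobed_cell(spec)
      f <- cfg_path(cfg, sprintf("cells_%s_%02d.tif", st$name, i))
      write_label_stack(cell$volume, f)
      files <- c(files, f)
      truth[[sprintf("%s_%02d", st$name, i)]] <-
        list(n_lobes = cell$truth$n_lobes, volume_um3 = cell$truth$volume_um3,
             seed = sd_)
    }
  }
  tcfg <- cfg$synth$tissue
  tspec <- tissue_spec(n_cells = tcfg$n_cells, domain_size = tcfg$domain_size,
                       wall_thickness = tcfg$wall_thickness,
                       ics_fraction = tcfg$ics_fraction,
                       spacing = tcfg$spacing,
                       seed = stage_seed(cfg$seed, 9001))
  tis <- make_tissue(tspec)
  ft <- cfg_path(cfg, "tissue.tif")
  write_label_stack(tis$volume, ft)
  truth$tissue <- list(adjacency = tis$truth$adjacency, seed = tspec$seed)

  lib <- default_reference_library()
  cspec <- cube_spec(shape = cfg$synth$cube$shape,
                     endmember_names = cfg$synth$cube$endmembers,
                     noise_sd = cfg$synth$cube$noise_sd,
                     n_spikes = cfg$synth$cube$n_spikes,
                     seed = stage_seed(cfg$seed, 9002))
  cub <- make_hyperspectral_cube(cspec, lib)
  fc <- cfg_path(cfg, "cube.tif")
  fw <- cfg_path(cfg, "cube_wavenumbers.csv")
  write_cube(cub$cube, fc, fw)
  truth$cube <- list(spikes = cub$truth$spikes, seed = cspec$seed)

  jsonlite::write_json(truth, cfg_path(cfg, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, ft, fc, fw, cfg_path(cfg, "truth.json"))
  write_manifest(cfg, "synth", files)
  invisible(list(files = files, truth = truth))
}

#' Measure synthesized (or provided) label stacks
#'
#' One descriptor record per whole cell (cells cut off by the volume
#' border are excluded); records carry their stage name. The tissue stack
#' is measured without lobe counts and its contact table is written too.
#'
#' @param cfg configuration list
#' @return (invisibly) the records data.frame
#' @export
cmd_measure <- function(cfg) {
  stages <- developmental_series(cfg$synth$base_radius, cfg$synth$n_stages)
  recs <- list()
  for (s in seq_along(stages)) {
    st <- stages[[s]]
    pat <- sprintf("^cells_%s_\\d+\\.tif$", st$name)
    for (f in sort(list.files(cfg$outdir, pattern = pat, full.names = TRUE))) {
      vol <- read_label_stack(f, cfg$synth$spacing)
      r <- measure_cells(vol, lobes = TRUE,
                         smoothing_radius = cfg$measure$smoothing_radius)
      if (nrow(r)) {
        r$stage <- st$name
        r$source <- basename(f)
        recs[[length(recs) + 1]] <- r
      }
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    cbind(measure_cells(labeled_volume(array(0L, c(2, 2, 2)), c(1, 1, 1))),
          data.frame(stage = character(0), source = character(0)))
  write_records_csv(records, cfg_path(cfg, "records.csv"))

  ft <- cfg_path(cfg, "tissue.tif")
  if (file.exists(ft)) {
    vol <- read_label_stack(ft, cfg$synth$tissue$spacing)
    tr <- measure_cells(vol, lobes = FALSE)
    write_records_csv(tr, cfg_path(cfg, "tissue_records.csv"))
    write_records_csv(as.data.frame(contact_areas(vol)),
                      cfg_path(cfg, "tissue_contacts.csv"))
  }
  write_manifest(cfg, "measure", cfg_path(cfg, "records.csv"))
  invisible(records)
}

#' Run the Raman stage on the synthesized cube
#'
#' Despikes, writes the CH band-integral image, runs NMF unmixing (seeded
#' from the global seed), writes endmember spectra and abundance maps, and
#' an OMP report of each endmember against the default reference library.
#'
#' @param cfg configuration list
#' @return (invisibly) list with the NMF result and OMP report
#' @export
cmd_raman <- function(cfg) {
  cube <- read_cube(cfg_path(cfg, "cube.tif"),
                    cfg_path(cfg, "cube_wavenumbers.csv"))
  if (cfg$raman$k > dim(cube$cube)[3])
    stop("raman.k (", cfg$raman$k, ") exceeds the number of bands")
  ds <- despike(cube, z_threshold = cfg$raman$despike_z)
  img <- integrate_band(ds$cube, cfg$raman$band_window)
  write.csv(img, cfg_path(cfg, "band_integral.csv"), row.names = FALSE)
  nm <- nmf_unmix(ds$cube, k = cfg$raman$k, seed = stage_seed(cfg$seed, 9003),
                  max_iter = cfg$raman$max_iter, tol = cfg$raman$tol)
  lib <- default_reference_library()
  for (i in seq_len(nm$k))
    write_spectrum_csv(spectrum(nm$wavenumbers, nm$endmembers[i, ]),
                       cfg_path(cfg, sprintf("endmember_%d.csv", i)))
  # abundance maps as one multipage TIFF (scaled) + scale sidecar
  amax <- max(nm$abundances, 1e-300)
  tiff::writeTIFF(lapply(seq_len(nm$k), function(i) nm$abundances[, , i] / amax),
                  cfg_path(cfg, "abundances.tif"), bits.per.sample = 32L)
  write.csv(data.frame(scale = amax), cfg_path(cfg, "abundances_scale.csv"),
            row.names = FALSE)
  assign_tab <- match_endmembers(nm, lib)
  write.csv(assign_tab, cfg_path(cfg, "endmember_assignments.csv"),
            row.names = FALSE)
  omp_rows <- lapply(seq_len(nm$k), function(i) {
    fit <- omp_fit(spectrum(nm$wavenumbers, nm$endmembers[i, ]), lib,
                   max_atoms = cfg$raman$omp_max_atoms)
    if (!length(fit$selected))
      return(data.frame(endmember = i, component = NA_character_,
                        coefficient = NA_real_,
                        residual_norm = fit$residual_norm))
    data.frame(endmember = i, component = fit$selected,
               coefficient = as.numeric(fit$coefficients),
               residual_norm = fit$residual_norm)
  })
  omp_report <- do.call(rbind, omp_rows)
  write.csv(omp_report, cfg_path(cfg, "omp_report.csv"), row.names = FALSE)
  write_manifest(cfg, "raman", cfg_path(cfg, c("band_integral.csv",
                                               "omp_report.csv")))
  invisible(list(nmf = nm, omp = omp_report, spikes = ds$spikes))
}

#' Stage-comparison statistics on measured records
#'
#' @param cfg configuration list
#' @return (invisibly) the [summarize_stages()] result
#' @export
cmd_stats <- function(cfg) {
  records <- read_records_csv(cfg_path(cfg, "records.csv"))
  if (!nrow(records)) stop("no records to compare; run cmd_measure first")
  res <- summarize_stages(records, stage = "stage", alpha = cfg$stats$alpha)
  write.csv(res$summary, cfg_path(cfg, "stage_summary.csv"), row.names = FALSE)
  write.csv(res$pairwise, cfg_path(cfg, "stage_pairwise.csv"), row.names = FALSE)
  write_manifest(cfg, "stats", cfg_path(cfg, c("stage_summary.csv",
                                               "stage_pairwise.csv")))
  invisible(res)
}

write_manifest <- function(cfg, stage, files) {
  mf <- cfg_path(cfg, "manifest.json")
  cfg_echo <- cfg
  cfg_echo$outdir <- NULL  # path-independent manifest: reruns compare equal
  manifest <- if (file.exists(mf))
    jsonlite::read_json(mf, simplifyVector = FALSE) else
      list(config = cfg_echo, stages = list())
  manifest$stages[[stage]] <- list(
    seed = cfg$seed,
    files = as.list(basename(unlist(files))))
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mf)
}

#' Run the full pipeline
#'
#' `synth`, `measure`, `raman`, `stats`, in order, under one global seed;
#' rerunning the same configuration reproduces every output byte for
#' byte.
#'
#' @param cfg configuration list or path to a YAML file
#' @param stages subset of stages to run (default all, in order)
#' @return (invisibly) the configuration used
#' @export
run_pipeline <- function(cfg, stages = c("synth", "measure", "raman", "stats")) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  for (s in stages) {
    switch(s,
           synth = cmd_synth(cfg),
           measure = cmd_measure(cfg),
           raman = cmd_raman(cfg),
           stats = cmd_stats(cfg),
           stop("unknown pipeline stage: ", s))
  }
  invisible(cfg)
}
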