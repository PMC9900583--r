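# Run configuration and the end-to-end pipeline driver. Every reference
# constant lives in exactly one place: pipeline_config().

#' Default run configuration
#'
#' All tunable constants of the pipeline with their reference defaults:
#' harmonic frequency scaling 0.98, instrument width fraction 0.01
#' (sigma = 0.01 nu), NCI density thresholds 18 and 15 nm^-3 with
#' reduced-gradient cutoff 0.5, conformer-graph edge threshold 10
#' Angstrom, Boltzmann temperature 400 K, the "admp-b3lyp-n07d" shift-law
#' profile, and the base RNG seed.
#'
#' @param ... named overrides of any default
#' @return list of class `run_config`
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    scale_factor = 0.98,
    width_fraction = 0.01,
    nci_rho_hbond = 18,
    nci_rho_weak = 15,
    nci_s_max = 0.5,
    graph_threshold = 10,
    temperature = 400,
    shift_profile = "admp-b3lyp-n07d",
    psd_window = "hann",
    psd_pad = 4L,
    psd_runs = 30L,
    makeup_kappa = 0.5,
    seed = 0L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  if (cfg$scale_factor <= 0 || cfg$width_fraction <= 0 ||
      cfg$graph_threshold <= 0 || cfg$temperature <= 0) {
    stop("scale factor, width fraction, graph threshold and temperature ",
         "must be positive")
  }
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:\n")
  for (k in names(unclass(x))) cat(sprintf("  %-16s %s\n", k,
                                           format(x[[k]])))
  invisible(x)
}

#' Run the analysis pipeline over a set of input files
#'
#' Pre-flight checks that every referenced input exists, then runs the
#' stages the inputs support: ion counts -> action spectrum; stick
#' spectra + Gibbs table -> scaled, broadened, Boltzmann-weighted
#' composite; dipole trajectories -> averaged dynamic spectrum. Outputs
#' are written as two-column text next to a machine-readable JSON-like
#' manifest of the parameters and seeds used.
#'
#' @param config a `run_config`
#' @param inputs named list; any of `ion_counts` (file), `sticks`
#'   (character vector of stick-spectrum files), `gibbs` (file, same
#'   order/count as `sticks`), `dipoles` (character vector of dipole
#'   trajectory files, equal sampling)
#' @param out_dir output directory (created if needed)
#' @return invisibly, a list with the computed objects and the manifest
#' @export
run_pipeline <- function(config = pipeline_config(), inputs = list(),
                         out_dir = ".") {
  files <- as.character(unlist(inputs, use.names = FALSE))
  missing <- files[!file.exists(files)]
  if (length(missing) > 0L) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  results <- list()
  outputs <- character(0)
  if (!is.null(inputs$ion_counts)) {
    rec <- read_ion_counts(inputs$ion_counts)
    act <- build_action_spectrum(rec)
    p <- file.path(out_dir, "action_spectrum.dat")
    writeLines(c("# nu sigma", sprintf("%.10g %.10g", act$nu, act$sigma)), p)
    results$action_spectrum <- act
    outputs <- c(outputs, p)
  }
  if (!is.null(inputs$sticks)) {
    specs <- lapply(inputs$sticks, function(f) {
      broaden(scale_frequencies(read_stick_spectrum(f),
                                config$scale_factor),
              width_fraction = config$width_fraction)
    })
    if (!is.null(inputs$gibbs)) {
      gt <- read_gibbs_table(inputs$gibbs)
      if (nrow(gt) != length(specs)) {
        stop("Gibbs table rows must match the number of stick spectra")
      }
      cs <- rank_and_weight(conformer_set(gibbs = gt$gibbs,
                                          names = gt$name),
                            temperature = config$temperature)
      comp <- composite(specs, cs$abundance)
      p <- file.path(out_dir, "composite_spectrum.dat")
      write_spectrum(comp, p)
      results$conformers <- cs
      results$composite <- comp
      outputs <- c(outputs, p)
    }
    results$harmonic_spectra <- specs
  }
  if (!is.null(inputs$dipoles)) {
    trajs <- lapply(inputs$dipoles, read_dipole_trajectory)
    dyn <- dynamic_spectrum(
      trajs,
      psd_options(window = config$psd_window, pad = config$psd_pad,
                  runs = config$psd_runs),
      scale_factor = config$scale_factor,
      width_fraction = config$width_fraction,
      kappa = config$makeup_kappa)
    p <- file.path(out_dir, "dynamic_spectrum.dat")
    write_spectrum(dyn, p)
    results$dynamic_spectrum <- dyn
    outputs <- c(outputs, p)
  }
  manifest <- list(
    package = "conformIR",
    version = as.character(utils::packageVersion("conformIR")),
    parameters = unclass(config),
    inputs = inputs,
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  mp <- file.path(out_dir, "run_manifest.txt")
  writeLines(deparse_manifest(manifest), mp)
  results$manifest <- manifest
  invisible(results)
}

# flat key: value rendering of the nested manifest list
deparse_manifest <- function(x, prefix = "") {
  out <- character(0)
  for (k in names(x)) {
    v <- x[[k]]
    key <- if (nzchar(prefix)) paste0(prefix, ".", k) else k
    if (is.list(v)) {
      out <- c(out, deparse_manifest(v, key))
    } else {
      out <- c(out, paste0(key, ": ", paste(format(v), collapse = " ")))
    }
  }
  out
}
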