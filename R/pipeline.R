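#' Run the full predictor-benchmarking pipeline
#'
#' Orchestrates the analysis end-to-end: electrical-variable conversion,
#' per-frequency screening of every variable in every terminal
#' configuration, sensitivity-score ranking, the fixed-frequency
#' (LCR-meter) subset in 2T, the clamp-vs-needle electrode comparison
#' (when both electrode types are present), and the literature score
#' recomputation. When \code{outDir} is given, each table is written as a
#' CSV alongside a JSON run manifest recording inputs, parameters and
#' outputs.
#'
#' @param spectra an \linkS4class{ImpedanceExperiment}, or the path of a
#'   spectra CSV (see \code{\link{readSpectra}}).
#' @param plants a plant-record \code{data.frame}, or the path of a plants
#'   CSV; may be \code{NULL} if \code{spectra} already carries
#'   \code{rdm_g}.
#' @param m0 characteristic root mass (g) for the sensitivity scores.
#' @param mode screening mode, see \code{\link{screenVariable}}.
#' @param lcrFrequencies test frequencies (Hz) for the LCR-meter table.
#' @param alpha significance level of the electrode comparison.
#' @param outDir optional output directory.
#' @param seed optional seed recorded in the manifest (the pipeline itself
#'   is deterministic; randomness only enters upstream simulation).
#' @return (invisibly) a list with \code{screens}, \code{table1}
#'   (variable ranking), \code{table2} (LCR subset), \code{electrodes},
#'   \code{literature} and \code{manifest}.
#' @examples
#' study <- simulateStudy(SimulationConfig(nPlants = 12, seed = 3),
#'                        configs = "3T", electrodes = "clamp")
#' bench <- runBenchmark(study$spectra)
#' head(bench$table1)
#' @export
runBenchmark <- function(spectra, plants = NULL, m0 = 1,
                         mode = c("soil_averaged", "pooled"),
                         lcrFrequencies = c(116.0933, 1250, 13459.00),
                         alpha = 0.01, outDir = NULL, seed = NULL) {
  mode <- match.arg(mode)
  inputs <- list()
  if (is.character(spectra)) {
    inputs$spectra <- spectra
    spectra <- readSpectra(spectra)
  }
  if (is.character(plants)) {
    inputs$plants <- plants
    plants <- readPlants(plants)
  }
  if (!is.null(plants))
    spectra <- attachPlants(spectra, plants)
  if (!"rdm_g" %in% colnames(colData(spectra)))
    stop("stage variables: no root dry mass available; supply 'plants'")
  ve <- electricalVariables(spectra, screeningVariables())
  cd <- colData(spectra)
  configs <- sort(unique(cd$config[cd$electrode == "clamp"]))
  if (!length(configs))
    stop("stage screen: no clamp spectra to screen")
  screens <- list()
  for (v in screeningVariables()) for (cfg in configs)
    screens[[paste(v, cfg, sep = ".")]] <-
      screenVariable(ve, v, cfg, electrode = "clamp", mode = mode)
  table1 <- rankVariables(screens, m0 = m0)
  table2 <- NULL
  if ("2T" %in% configs) {
    s2t <- screens[paste(screeningVariables(), "2T", sep = ".")]
    table2 <- lcrSubset(s2t, lcrFrequencies, m0 = m0)
  }
  electrodes <- NULL
  if (all(.ELECTRODES %in% unique(cd$electrode)))
    electrodes <- compareElectrodes(ve, "Cp", alpha = alpha)
  literature <- recomputeScores(bundledLiterature())
  manifest <- list(
    tool = "rootcap", version = as.character(packageVersion("rootcap")),
    command = "runBenchmark",
    parameters = list(m0 = m0, mode = mode,
                      lcr_frequencies = lcrFrequencies, alpha = alpha),
    seed = seed,
    inputs = if (length(inputs))
      lapply(inputs, function(p)
        list(path = p, md5 = unname(tools::md5sum(p)))) else NULL,
    n_spectra = ncol(spectra),
    n_plants = length(unique(cd$plant_id)))
  out <- list(screens = screens, table1 = table1, table2 = table2,
              electrodes = electrodes, literature = literature,
              manifest = manifest)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    .writeTable <- function(d, name) {
      if (is.null(d)) return(NULL)
      p <- file.path(outDir, name)
      write.csv(d, p, row.names = FALSE)
      p
    }
    paths <- c(.writeTable(table1, "table1.csv"),
               .writeTable(table2, "table2.csv"),
               .writeTable(electrodes, "electrodes.csv"),
               .writeTable(literature, "literature.csv"))
    manifest$outputs <- basename(paths)
    out$manifest <- manifest
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(out)
}

#' One-command synthetic demonstration run
#'
#' Simulates a default study (30 plants, three soils, all terminal
#' configurations and both electrode types) and runs
#' \code{\link{runBenchmark}} on it.
#'
#' @param seed RNG seed driving the whole run.
#' @param outDir optional output directory for the benchmark tables.
#' @param nPlants cohort size, default 30.
#' @return (invisibly) the \code{\link{runBenchmark}} result, with the
#'   \linkS4class{SimulationConfig} attached as \code{$sim}.
#' @export
demoBenchmark <- function(seed = 1, outDir = NULL, nPlants = 30) {
  sim <- SimulationConfig(nPlants = nPlants, seed = seed)
  study <- simulateStudy(sim)
  out <- runBenchmark(study$spectra, outDir = outDir, seed = seed)
  out$sim <- sim
  invisible(out)
}
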