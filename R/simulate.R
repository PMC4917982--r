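#' SimulationConfig: parameterization of the synthetic plant-soil circuit
#'
#' The simulator represents a measured plant-soil system as three
#' dispersions in series: \code{Z*(f) = Z_plant + Z_soil + Z_contact},
#' each a parallel RC element, plus a noise model. The plant element
#' carries the root-mass signal: its capacitance is
#' \code{C_plant = (aTrue * RDM + bTrue) nF} (times a per-plant biological
#' scatter factor) and its resistance \code{R_plant = plantRScale /
#' (RDM + 0.05)} ohm, so larger root systems conduct better. The soil
#' element is soil-type specific (with per-pot lognormal variability) and
#' the contact element models the electrode-tissue/soil interface: it is
#' counted twice in 2T, once in 3T and not at all in 4T sensing, which
#' instead receives extra multiplicative noise emulating the stem-base
#' position sensitivity of its voltage electrode. Needle (vs clamp) stem
#' electrodes apply a magnitude distortion growing with log-frequency.
#'
#' Noise has three scales, reflecting how such measurements actually vary:
#' per-point instrument repeatability (small), per-hookup (spectrum-level)
#' gain/phase variability plus a cable-coupling gain error growing linearly
#' with frequency, and per-plant biological scatter shared by all hookups
#' of the same plant.
#'
#' @slot nPlants number of plants (default 30).
#' @slot seed RNG seed for \code{\link{simulateStudy}}.
#' @slot rdmMean,rdmSd,rdmMin,rdmMax truncated-normal root dry mass
#'   distribution, grams (defaults 0.2, 0.19, 0.02, 0.72).
#' @slot aTrue,bTrue the generating linear relation between plant
#'   capacitance (nF) and root dry mass (g): slope nF/g and intercept nF
#'   (defaults 4.2 and 0.37).
#' @slot biolSdLog sdlog of the per-plant lognormal biological scatter,
#'   applied (as independent draws) to the plant capacitance about its
#'   linear relation and to the plant resistance about its mass law
#'   (default 0.15).
#' @slot plantRScale plant resistance scale, ohm gram (default 2e5).
#' @slot soilPresets data.frame (soil, r_ohm, c_f): soil parallel-RC
#'   elements per soil type.
#' @slot soilProportions share of plants grown in each soil type
#'   (default 14/8/8 out of 30 for silt_loam/loam/sandy_loam).
#' @slot soilSdLog sdlog of per-pot lognormal variability of the soil
#'   resistance (default 0.5).
#' @slot contactR,contactC,contactSdLog contact element: median resistance
#'   (ohm), capacitance (F) and per-hookup lognormal scatter of the
#'   resistance.
#' @slot electrodeDistortion slope (per decade of frequency) of the needle
#'   vs clamp magnitude distortion; \code{fRef} is the frequency at which
#'   the distortion vanishes.
#' @slot fRef reference frequency for the needle distortion, Hz.
#' @slot couplingZ relative spectrum-level gain error at the top grid
#'   frequency, growing linearly with f (default 0.15).
#' @slot noiseZ,noiseTheta per-point magnitude (relative, lognormal) and
#'   phase (degrees, additive) repeatability noise.
#' @slot noiseZSpectrum,noiseThetaSpectrum per-hookup magnitude gain
#'   (relative) and phase offset (degrees) noise.
#' @slot noise4T extra per-hookup multiplicative magnitude noise applied in
#'   4T sensing (stem-base electrode position sensitivity).
#' @slot grid frequency grid, Hz.
#' @seealso \code{\link{simulateStudy}}, \code{\link{plantSoilSpectrum}}
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(nPlants = "numeric", seed = "numeric",
                 rdmMean = "numeric", rdmSd = "numeric",
                 rdmMin = "numeric", rdmMax = "numeric",
                 aTrue = "numeric", bTrue = "numeric",
                 biolSdLog = "numeric", plantRScale = "numeric",
                 soilPresets = "data.frame", soilProportions = "numeric",
                 soilSdLog = "numeric",
                 contactR = "numeric", contactC = "numeric",
                 contactSdLog = "numeric",
                 electrodeDistortion = "numeric", fRef = "numeric",
                 couplingZ = "numeric",
                 noiseZ = "numeric", noiseTheta = "numeric",
                 noiseZSpectrum = "numeric", noiseThetaSpectrum = "numeric",
                 noise4T = "numeric", grid = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nPlants < 0) msg <- c(msg, "nPlants must be >= 0")
  if (object@rdmMin >= object@rdmMax)
    msg <- c(msg, "rdmMin must be < rdmMax")
  if (object@rdmMin <= 0) msg <- c(msg, "rdmMin must be > 0")
  if (object@rdmSd <= 0) msg <- c(msg, "rdmSd must be > 0")
  if (any(c(object@plantRScale, object@contactR, object@contactC,
            object@soilPresets$r_ohm, object@soilPresets$c_f) <= 0))
    msg <- c(msg, "all resistances and capacitances must be > 0")
  if (any(c(object@biolSdLog, object@soilSdLog, object@contactSdLog,
            object@couplingZ, object@noiseZ, object@noiseTheta,
            object@noiseZSpectrum, object@noiseThetaSpectrum,
            object@noise4T) < 0))
    msg <- c(msg, "noise terms must be >= 0")
  if (!setequal(object@soilPresets$soil, .SOILS))
    msg <- c(msg, "soilPresets must cover silt_loam, loam, sandy_loam")
  if (length(object@soilProportions) != 3L ||
      any(object@soilProportions < 0) || sum(object@soilProportions) == 0)
    msg <- c(msg, "soilProportions must be 3 nonnegative shares")
  if (any(object@grid <= 0) ||
      (length(object@grid) > 1L && any(diff(object@grid) <= 0)))
    msg <- c(msg, "grid must be strictly increasing and positive")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' All arguments default to the emulated study conditions: ~30 wheat plants
#' across three soils (14 silt loam, 8 loam, 8 sandy loam), root dry mass
#' truncated-normal with mean 0.2 g, sd 0.19 g on [0.02, 0.72] g, a linear
#' plant-capacitance relation \code{C = 4.2 RDM + 0.37} nF, and spectra on
#' the canonical 26-point grid. See \linkS4class{SimulationConfig} for the
#' meaning and units of each parameter.
#'
#' @param nPlants,seed,rdmMean,rdmSd,rdmMin,rdmMax,aTrue,bTrue see class doc.
#' @param biolSdLog,plantRScale,soilPresets,soilProportions,soilSdLog idem.
#' @param contactR,contactC,contactSdLog,electrodeDistortion,fRef idem.
#' @param couplingZ,noiseZ,noiseTheta,noiseZSpectrum,noiseThetaSpectrum idem.
#' @param noise4T,grid idem.
#' @return a validated \linkS4class{SimulationConfig}.
#' @export
SimulationConfig <- function(nPlants = 30, seed = 1,
                             rdmMean = 0.2, rdmSd = 0.19,
                             rdmMin = 0.02, rdmMax = 0.72,
                             aTrue = 4.2, bTrue = 0.37,
                             biolSdLog = 0.15, plantRScale = 2e5,
                             soilPresets = data.frame(
                               soil = c("silt_loam", "loam", "sandy_loam"),
                               r_ohm = c(25000, 12000, 40000),
                               c_f = c(1.5e-6, 8e-7, 2.5e-6)),
                             soilProportions = c(silt_loam = 14, loam = 8,
                                                 sandy_loam = 8) / 30,
                             soilSdLog = 0.5,
                             contactR = 1000, contactC = 1e-9,
                             contactSdLog = 0.15,
                             electrodeDistortion = 0.04, fRef = 0.5,
                             couplingZ = 0.15,
                             noiseZ = 0.003, noiseTheta = 0.005,
                             noiseZSpectrum = 0.05,
                             noiseThetaSpectrum = 0.01,
                             noise4T = 0.2,
                             grid = defaultGrid()) {
  new("SimulationConfig", nPlants = nPlants, seed = seed,
      rdmMean = rdmMean, rdmSd = rdmSd, rdmMin = rdmMin, rdmMax = rdmMax,
      aTrue = aTrue, bTrue = bTrue, biolSdLog = biolSdLog,
      plantRScale = plantRScale, soilPresets = soilPresets,
      soilProportions = soilProportions, soilSdLog = soilSdLog,
      contactR = contactR, contactC = contactC, contactSdLog = contactSdLog,
      electrodeDistortion = electrodeDistortion, fRef = fRef,
      couplingZ = couplingZ, noiseZ = noiseZ, noiseTheta = noiseTheta,
      noiseZSpectrum = noiseZSpectrum,
      noiseThetaSpectrum = noiseThetaSpectrum, noise4T = noise4T,
      grid = grid)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nPlants, "plants, seed", object@seed, "\n")
  cat("  RDM ~ truncN(", object@rdmMean, ",", object@rdmSd, ") on [",
      object@rdmMin, ",", object@rdmMax, "] g\n")
  cat("  C_plant =", object@aTrue, "x RDM +", object@bTrue,
      "nF (biol sdlog", object@biolSdLog, ")\n")
  cat("  grid:", length(object@grid), "frequencies,",
      format(min(object@grid)), "-", format(max(object@grid)), "Hz\n")
  invisible(NULL)
})

#' Sample root dry masses
#'
#' Draws from the configured truncated normal distribution (inverse-CDF
#' sampling: exactly one uniform draw per plant, so results are
#' reproducible under a fixed RNG state).
#'
#' @param sim a \linkS4class{SimulationConfig}.
#' @param n number of plants; defaults to \code{sim@nPlants}.
#' @return numeric vector of root dry masses in grams, all inside
#'   \code{[rdmMin, rdmMax]}.
#' @export
sampleRdm <- function(sim = SimulationConfig(), n = sim@nPlants) {
  if (n == 0) return(numeric(0))
  lo <- pnorm((sim@rdmMin - sim@rdmMean) / sim@rdmSd)
  hi <- pnorm((sim@rdmMax - sim@rdmMean) / sim@rdmSd)
  sim@rdmMean + sim@rdmSd * qnorm(runif(n, lo, hi))
}

#' Impedance of a parallel RC element
#' @param R resistance, ohm.
#' @param C capacitance, farad.
#' @param f frequency, Hz (vectorized).
#' @return complex impedance, ohm.
#' @export
parallelImpedance <- function(R, C, f) {
  R / (1 + 1i * 2 * pi * f * R * C)
}

# one fixed-size block of standard-normal draws per spectrum, consumed
# whether or not a term applies, so RNG streams align across configurations
.spectrumDraws <- function(nf) {
  list(contact = rnorm(2), pos4T = rnorm(1),
       pointZ = rnorm(nf), pointTheta = rnorm(nf))
}

.zeroDraws <- function(nf) {
  list(contact = c(0, 0), pos4T = 0,
       pointZ = numeric(nf), pointTheta = numeric(nf))
}

#' Simulate one impedance spectrum of a plant-soil system
#'
#' Computes, by complex arithmetic over the series network described in
#' \linkS4class{SimulationConfig}, the (Z, theta) spectrum of one hookup of
#' one plant. With \code{noise = FALSE} every random term is frozen (the
#' contact element sits at its median, no measurement or position noise),
#' making the output an exact deterministic function of the circuit.
#'
#' @param rdm root dry mass, grams.
#' @param soil soil type (\code{"silt_loam"}, \code{"loam"},
#'   \code{"sandy_loam"}).
#' @param config terminal configuration: the contact element is counted
#'   twice for \code{"2T"}, once for \code{"3T"}, zero times for
#'   \code{"4T"}.
#' @param electrode \code{"clamp"} or \code{"needle"} (needle applies the
#'   configured magnitude distortion).
#' @param sim a \linkS4class{SimulationConfig}.
#' @param noise draw and apply the noise model (consumes RNG)?
#' @param biolFactor,resistFactor,soilFactor per-plant multiplicative
#'   factors for the plant capacitance, the plant resistance and the soil
#'   resistance, shared across the hookups of one plant;
#'   \code{\link{simulateStudy}} supplies them.
#' @param couplingDraw standard-normal draw behind the cable-coupling gain
#'   error. The stray coupling belongs to the cable/soil-electrode layout
#'   of a potted plant, so it is one draw per plant, shared across hookups;
#'   \code{\link{simulateStudy}} supplies it (\code{NULL} draws internally
#'   when \code{noise = TRUE}).
#' @param gainDraw,thetaOffDraw standard-normal draws behind the hookup
#'   gain and phase-offset noise. A stem electrode is attached once per
#'   plant and electrode type while the terminal configurations are cycled
#'   by moving the soil electrodes, so these are drawn once per
#'   (plant, electrode) and shared across configurations;
#'   \code{\link{simulateStudy}} supplies them.
#' @return a \code{data.frame} with columns \code{frequency_hz, z_ohm,
#'   theta_deg}.
#' @export
plantSoilSpectrum <- function(rdm, soil, config = "3T", electrode = "clamp",
                              sim = SimulationConfig(), noise = TRUE,
                              biolFactor = 1, resistFactor = 1,
                              soilFactor = 1,
                              couplingDraw = NULL, gainDraw = NULL,
                              thetaOffDraw = NULL) {
  config <- match.arg(config, .TERMINAL_CONFIGS)
  electrode <- match.arg(electrode, .ELECTRODES)
  soil <- match.arg(soil, .SOILS)
  f <- sim@grid
  nf <- length(f)
  dr <- if (noise) .spectrumDraws(nf) else .zeroDraws(nf)
  if (is.null(couplingDraw)) couplingDraw <- if (noise) rnorm(1) else 0
  if (is.null(gainDraw)) gainDraw <- if (noise) rnorm(1) else 0
  if (is.null(thetaOffDraw)) thetaOffDraw <- if (noise) rnorm(1) else 0
  cPlant <- (sim@aTrue * rdm + sim@bTrue) * 1e-9 * biolFactor
  rPlant <- sim@plantRScale / (rdm + 0.05) * resistFactor
  preset <- sim@soilPresets[sim@soilPresets$soil == soil, ]
  z <- parallelImpedance(rPlant, cPlant, f) +
    parallelImpedance(preset$r_ohm * soilFactor, preset$c_f, f)
  nContact <- c("2T" = 2L, "3T" = 1L, "4T" = 0L)[[config]]
  if (nContact > 0L)
    for (k in seq_len(nContact))
      z <- z + parallelImpedance(
        sim@contactR * exp(sim@contactSdLog * dr$contact[k]),
        sim@contactC, f)
  zmag <- Mod(z)
  theta <- Arg(z) * 180 / pi
  if (electrode == "needle")
    zmag <- zmag * (1 + sim@electrodeDistortion * log10(f / sim@fRef))
  gain <- exp(sim@noiseZSpectrum * gainDraw +
              sim@couplingZ * (f / max(f)) * couplingDraw +
              sim@noiseZ * dr$pointZ)
  if (config == "4T") gain <- gain * exp(sim@noise4T * dr$pos4T)
  zmag <- zmag * gain
  theta <- theta + sim@noiseThetaSpectrum * thetaOffDraw +
    sim@noiseTheta * dr$pointTheta
  theta <- pmax(pmin(theta, 180), -180)
  data.frame(frequency_hz = f, z_ohm = zmag, theta_deg = theta)
}

.assignSoils <- function(n, proportions) {
  # largest-remainder apportionment, deterministic
  target <- n * proportions / sum(proportions)
  counts <- floor(target)
  left <- n - sum(counts)
  if (left > 0) {
    extra <- order(target - counts, decreasing = TRUE)[seq_len(left)]
    counts[extra] <- counts[extra] + 1
  }
  rep(names(proportions), times = counts)
}

#' Simulate a full root-mass benchmarking study
#'
#' Draws a cohort of plants (root dry mass and soil assignment), then
#' simulates one impedance spectrum per requested (terminal configuration,
#' electrode) combination per plant. Fully reproducible: all randomness
#' flows from \code{sim@seed}, and per-plant biological and soil factors
#' are shared across that plant's hookups.
#'
#' @param sim a \linkS4class{SimulationConfig}.
#' @param configs terminal configurations to measure.
#' @param electrodes stem electrode types to measure.
#' @param noise apply the noise model (default TRUE)?
#' @return a list with \code{spectra} (an
#'   \linkS4class{ImpedanceExperiment} with root dry mass attached) and
#'   \code{plants} (a \code{data.frame} of plant records).
#' @examples
#' study <- simulateStudy(SimulationConfig(nPlants = 6, seed = 7),
#'                        configs = "3T", electrodes = "clamp")
#' study$spectra
#' @export
simulateStudy <- function(sim = SimulationConfig(),
                          configs = c("2T", "3T", "4T"),
                          electrodes = c("clamp", "needle"),
                          noise = TRUE) {
  configs <- match.arg(configs, .TERMINAL_CONFIGS, several.ok = TRUE)
  electrodes <- match.arg(electrodes, .ELECTRODES, several.ok = TRUE)
  set.seed(sim@seed)
  n <- sim@nPlants
  ids <- sprintf("plant%02d", seq_len(n))
  rdm <- sampleRdm(sim, n)
  soil <- .assignSoils(n, sim@soilProportions)
  plants <- data.frame(plant_id = ids, rdm_g = rdm, soil = soil)
  nf <- length(sim@grid)
  cols <- expand.grid(electrode = electrodes, config = configs,
                      plant = seq_len(n), stringsAsFactors = FALSE)
  cols <- cols[order(cols$plant), ]  # all hookups of a plant consecutive
  Z <- matrix(NA_real_, nf, nrow(cols))
  th <- matrix(NA_real_, nf, nrow(cols))
  j <- 0L
  for (i in seq_len(n)) {
    biolFactor <- if (noise) exp(sim@biolSdLog * rnorm(1)) else 1
    resistFactor <- if (noise) exp(sim@biolSdLog * rnorm(1)) else 1
    soilFactor <- if (noise) exp(sim@soilSdLog * rnorm(1)) else 1
    couplingDraw <- if (noise) rnorm(1) else 0
    # one stem-electrode hookup per (plant, electrode); both blocks are
    # always drawn so RNG streams align across requested designs
    hookup <- list(clamp = if (noise) rnorm(2) else c(0, 0),
                   needle = if (noise) rnorm(2) else c(0, 0))
    for (cfg in configs) for (el in electrodes) {
      j <- j + 1L
      sp <- plantSoilSpectrum(rdm[i], soil[i], cfg, el, sim, noise = noise,
                              biolFactor = biolFactor,
                              resistFactor = resistFactor,
                              soilFactor = soilFactor,
                              couplingDraw = couplingDraw,
                              gainDraw = hookup[[el]][1L],
                              thetaOffDraw = hookup[[el]][2L])
      Z[, j] <- sp$z_ohm
      th[, j] <- sp$theta_deg
    }
  }
  cd <- DataFrame(plant_id = rep(ids, each = length(configs) *
                                   length(electrodes)),
                  config = rep(rep(configs, each = length(electrodes)),
                               times = n),
                  electrode = rep(electrodes,
                                  times = n * length(configs)),
                  soil = rep(soil, each = length(configs) *
                               length(electrodes)))
  ie <- ImpedanceExperiment(Z, th, sim@grid, cd)
  ie <- attachPlants(ie, plants)
  list(spectra = ie, plants = plants)
}

#' Write a simulated study to CSV files
#'
#' @param study result of \code{\link{simulateStudy}}.
#' @param dir output directory (created if needed).
#' @return character vector of the two file paths, invisibly.
#' @export
writeSimulation <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- file.path(dir, "spectra.csv")
  pl <- file.path(dir, "plants.csv")
  writeSpectra(study$spectra, sp)
  writePlants(study$plants, pl)
  invisible(c(sp, pl))
}

#' The generator's optimum frequency
#'
#' The grid frequency at which noiseless simulated parallel capacitance is
#' most linearly determined by root dry mass (pooled across soils), i.e.
#' where the soil and contact dispersions distort the plant capacitance
#' least. Computed from a deterministic noise-free cohort whose root masses
#' are the truncated-normal quantiles, so the result is a property of the
#' circuit alone. Ties go to the lowest frequency.
#'
#' @param sim a \linkS4class{SimulationConfig}.
#' @param config terminal configuration, default \code{"3T"}.
#' @param nRef size of the reference cohort, default 30.
#' @return a frequency in Hz (member of the grid).
#' @export
optimumFrequency <- function(sim = SimulationConfig(), config = "3T",
                             nRef = 30) {
  lo <- pnorm((sim@rdmMin - sim@rdmMean) / sim@rdmSd)
  hi <- pnorm((sim@rdmMax - sim@rdmMean) / sim@rdmSd)
  p <- lo + (hi - lo) * (seq_len(nRef) - 0.5) / nRef
  rdm <- sim@rdmMean + sim@rdmSd * qnorm(p)
  soil <- .assignSoils(nRef, sim@soilProportions)
  cp <- vapply(seq_len(nRef), function(i) {
    sp <- plantSoilSpectrum(rdm[i], soil[i], config, "clamp", sim,
                            noise = FALSE)
    computeVariable(sp$z_ohm, sp$theta_deg, sp$frequency_hz, "Cp")
  }, numeric(length(sim@grid)))
  r2 <- apply(cp, 1L, function(y) cor(rdm, y)^2)
  sim@grid[which.max(r2)]
}
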