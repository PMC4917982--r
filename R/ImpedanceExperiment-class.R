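#' ImpedanceExperiment: a container for impedance spectra
#'
#' An \code{ImpedanceExperiment} extends
#' \link[SummarizedExperiment]{SummarizedExperiment} to hold a set of
#' electrical impedance spectra measured on plant-soil systems. Rows are
#' injected-current frequencies (Hz, strictly increasing), columns are
#' individual spectra (one hookup of one plant in one terminal configuration
#' with one stem electrode). Two assays are mandatory:
#' \describe{
#'   \item{\code{Z}}{impedance magnitude, in ohm (all values > 0);}
#'   \item{\code{theta}}{phase angle, in degrees, in [-180, 180]
#'     (negative for capacitive systems).}
#' }
#' \code{colData} carries \code{plant_id}, \code{config} (\code{"2T"},
#' \code{"3T"} or \code{"4T"}), \code{electrode} (\code{"clamp"} or
#' \code{"needle"}), \code{soil} (\code{"silt_loam"}, \code{"loam"} or
#' \code{"sandy_loam"}) and, once plant records are attached, \code{rdm_g},
#' the root dry mass in grams.
#'
#' @slot .. see \link[SummarizedExperiment]{SummarizedExperiment}; no extra
#'   slots are added, only validity constraints and accessors.
#'
#' @seealso \code{\link{readSpectra}}, \code{\link{simulateStudy}},
#'   \code{\link{electricalVariables}}
#' @exportClass ImpedanceExperiment
setClass("ImpedanceExperiment", contains = "SummarizedExperiment")

.TERMINAL_CONFIGS <- c("2T", "3T", "4T")
.ELECTRODES <- c("clamp", "needle")
.SOILS <- c("silt_loam", "loam", "sandy_loam")

.validImpedanceExperiment <- function(object) {
  msg <- character()
  an <- assayNames(object)
  if (!all(c("Z", "theta") %in% an))
    return("assays 'Z' and 'theta' are required")
  f <- rowData(object)$frequency_hz
  if (is.null(f))
    msg <- c(msg, "rowData must contain 'frequency_hz'")
  else {
    if (any(!is.finite(f)) || any(f <= 0))
      msg <- c(msg, "frequencies must be finite and > 0")
    if (nrow(object) > 1L && any(diff(f) <= 0))
      msg <- c(msg, "frequencies must be strictly increasing (no duplicates)")
  }
  Z <- assay(object, "Z")
  th <- assay(object, "theta")
  if (any(!is.na(Z) & Z <= 0))
    msg <- c(msg, "impedance magnitudes Z must be > 0")
  if (any(!is.na(th) & abs(th) > 180))
    msg <- c(msg, "phase angles must lie in [-180, 180] degrees")
  cd <- colData(object)
  need <- c("plant_id", "config", "electrode", "soil")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ",
                         paste(miss, collapse = ", ")))
  else {
    if (!all(cd$config %in% .TERMINAL_CONFIGS))
      msg <- c(msg, "config must be one of 2T, 3T, 4T")
    if (!all(cd$electrode %in% .ELECTRODES))
      msg <- c(msg, "electrode must be 'clamp' or 'needle'")
    if (!all(cd$soil %in% .SOILS))
      msg <- c(msg, "soil must be one of silt_loam, loam, sandy_loam")
    key <- paste(cd$plant_id, cd$config, cd$electrode)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (plant_id, config, electrode) spectra")
  }
  if ("rdm_g" %in% colnames(cd) &&
      any(!is.na(cd$rdm_g) & cd$rdm_g <= 0))
    msg <- c(msg, "root dry mass rdm_g must be > 0")
  if (length(msg)) msg else TRUE
}

setValidity("ImpedanceExperiment", .validImpedanceExperiment)

#' Construct an ImpedanceExperiment
#'
#' @param Z numeric matrix of impedance magnitudes (ohm), frequencies in rows,
#'   spectra in columns. Rows need not be pre-sorted: rows are ordered by
#'   \code{frequency}.
#' @param theta numeric matrix of phase angles (degrees), same dimensions.
#' @param frequency numeric vector of frequencies in Hz, one per row.
#' @param colData a \code{data.frame} or \code{DataFrame} with one row per
#'   column of \code{Z}, carrying at least \code{plant_id}, \code{config},
#'   \code{electrode} and \code{soil}.
#' @return an \linkS4class{ImpedanceExperiment}.
#' @examples
#' f <- c(10, 100, 1000)
#' Z <- matrix(1000, 3, 1)
#' th <- matrix(-45, 3, 1)
#' cd <- data.frame(plant_id = "p1", config = "3T",
#'                  electrode = "clamp", soil = "loam")
#' ImpedanceExperiment(Z, th, f, cd)
#' @export
ImpedanceExperiment <- function(Z, theta, frequency, colData) {
  Z <- as.matrix(Z)
  theta <- as.matrix(theta)
  stopifnot(identical(dim(Z), dim(theta)),
            length(frequency) == nrow(Z))
  o <- order(frequency)
  se <- SummarizedExperiment(
    assays = list(Z = Z[o, , drop = FALSE], theta = theta[o, , drop = FALSE]),
    rowData = DataFrame(frequency_hz = frequency[o]),
    colData = as(colData, "DataFrame"))
  rownames(se) <- format(frequency[o], trim = TRUE)
  if (is.null(colnames(se)))
    colnames(se) <- paste(colData$plant_id, colData$config,
                          colData$electrode, sep = ".")
  new("ImpedanceExperiment", se)
}

#' @describeIn ImpedanceExperiment the frequency support, in Hz.
#' @param x an \code{ImpedanceExperiment}.
#' @export
frequencies <- function(x) rowData(x)$frequency_hz

#' Attach plant records (root dry mass) to an ImpedanceExperiment
#'
#' Joins per-plant root dry mass onto the spectra by \code{plant_id},
#' storing it as \code{colData(x)$rdm_g}. Soil labels, when present in both,
#' are cross-checked.
#'
#' @param x an \linkS4class{ImpedanceExperiment}.
#' @param plants a \code{data.frame} with columns \code{plant_id},
#'   \code{rdm_g} and optionally \code{soil}, as returned by
#'   \code{\link{readPlants}}.
#' @return \code{x} with \code{rdm_g} filled in.
#' @export
attachPlants <- function(x, plants) {
  stopifnot(is(x, "ImpedanceExperiment"),
            all(c("plant_id", "rdm_g") %in% colnames(plants)))
  idx <- match(colData(x)$plant_id, plants$plant_id)
  if (anyNA(idx)) {
    bad <- unique(colData(x)$plant_id[is.na(idx)])
    stop("no plant record for plant_id: ", paste(bad, collapse = ", "))
  }
  if ("soil" %in% colnames(plants)) {
    mism <- colData(x)$soil != plants$soil[idx]
    if (any(mism))
      stop("soil mismatch between spectra and plant records for plant_id: ",
           paste(unique(colData(x)$plant_id[mism]), collapse = ", "))
  }
  colData(x)$rdm_g <- plants$rdm_g[idx]
  validObject(x)
  x
}

setMethod("show", "ImpedanceExperiment", function(object) {
  cd <- colData(object)
  cat("ImpedanceExperiment:", nrow(object), "frequencies x",
      ncol(object), "spectra\n")
  f <- frequencies(object)
  if (length(f))
    cat("  frequency range:", format(min(f)), "-", format(max(f)), "Hz\n")
  cat("  plants:", length(unique(cd$plant_id)),
      "| configs:", paste(sort(unique(cd$config)), collapse = "/"),
      "| electrodes:", paste(sort(unique(cd$electrode)), collapse = "/"),
      "\n")
  cat("  root dry mass attached:",
      if ("rdm_g" %in% colnames(cd)) "yes" else "no", "\n")
  invisible(NULL)
})
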