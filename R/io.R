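#' The canonical 26-point frequency grid
#'
#' Reconstructs the instrument's 26 logarithmically distributed injected
#' current frequencies between 0.5 and 20,000 Hz. The upper 25 points form a
#' geometric ladder descending from 20,000 Hz with ratio \code{2^(4/7)}
#' (four points per octave-and-a-bit; 20000/2^4 = 1250 Hz falls on the
#' ladder exactly). The ladder's 26th value would be ~1.0 Hz; the lowest
#' point is instead fixed at the instrument's stated 0.5 Hz minimum. The
#' ladder reproduces the frequencies quoted with measurement results
#' (78, 116, 1250, 13458 Hz, ...) to better than 0.5% relative.
#'
#' @return a strictly increasing numeric vector of 26 frequencies in Hz.
#' @examples
#' g <- defaultGrid()
#' range(g)   # 0.5 .. 20000
#' @export
defaultGrid <- function() {
  ladder <- 20000 * 2^(-(24:0) * 4 / 7)
  c(0.5, ladder)
}

#' Snap frequencies onto a reference grid
#'
#' Frequencies within 1% relative distance of a grid point are replaced by
#' that grid point; others are kept as-is (the pipeline does not require the
#' canonical grid).
#'
#' @param f numeric vector of frequencies in Hz.
#' @param grid reference grid, default \code{\link{defaultGrid}()}.
#' @param tol relative tolerance, default 0.01.
#' @return numeric vector, same length as \code{f}.
#' @export
matchToGrid <- function(f, grid = defaultGrid(), tol = 0.01) {
  vapply(f, function(fi) {
    i <- which.min(abs(grid - fi))
    if (abs(grid[i] - fi) <= tol * fi) grid[i] else fi
  }, numeric(1))
}

.requireColumns <- function(d, cols, what) {
  miss <- setdiff(cols, colnames(d))
  if (length(miss))
    stop(what, " file is missing column(s): ", paste(miss, collapse = ", "))
}

#' Read impedance spectra from a long-format CSV
#'
#' The file must have header columns \code{plant_id, config, electrode,
#' soil, frequency_hz, z_ohm, theta_deg}, one row per measured frequency.
#' Rows are grouped into one spectrum per (plant_id, config, electrode) and
#' sorted by increasing frequency; frequencies are snapped onto the
#' canonical grid within 1% relative tolerance.
#'
#' @param path path to the CSV file.
#' @param grid reference frequency grid for snapping; \code{NULL} disables
#'   snapping.
#' @return an \linkS4class{ImpedanceExperiment}.
#' @export
readSpectra <- function(path, grid = defaultGrid()) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  .requireColumns(d, c("plant_id", "config", "electrode", "soil",
                       "frequency_hz", "z_ohm", "theta_deg"), "spectra")
  row0 <- seq_len(nrow(d)) + 1L  # +1: header line
  bad <- which(!is.finite(d$frequency_hz) | d$frequency_hz <= 0)
  if (length(bad))
    stop("non-positive or missing frequency_hz at file row(s) ",
         paste(row0[bad], collapse = ", "))
  bad <- which(!is.finite(d$z_ohm) | d$z_ohm <= 0)
  if (length(bad))
    stop("non-positive or missing z_ohm at file row(s) ",
         paste(row0[bad], collapse = ", "))
  bad <- which(!is.finite(d$theta_deg) | abs(d$theta_deg) > 180)
  if (length(bad))
    stop("theta_deg outside [-180, 180] at file row(s) ",
         paste(row0[bad], collapse = ", "))
  if (!is.null(grid))
    d$frequency_hz <- matchToGrid(d$frequency_hz, grid)
  key <- paste(d$plant_id, d$config, d$electrode, sep = "\r")
  dupkey <- paste(key, d$frequency_hz, sep = "\r")
  if (anyDuplicated(dupkey)) {
    bad <- row0[duplicated(dupkey)]
    stop("duplicate frequency within a spectrum at file row(s) ",
         paste(bad, collapse = ", "))
  }
  freqs <- sort(unique(d$frequency_hz))
  cols <- unique(key)
  Z <- matrix(NA_real_, length(freqs), length(cols))
  th <- matrix(NA_real_, length(freqs), length(cols))
  ri <- match(d$frequency_hz, freqs)
  ci <- match(key, cols)
  Z[cbind(ri, ci)] <- d$z_ohm
  th[cbind(ri, ci)] <- d$theta_deg
  first <- match(cols, key)
  cd <- DataFrame(plant_id = d$plant_id[first],
                  config = d$config[first],
                  electrode = d$electrode[first],
                  soil = d$soil[first])
  ImpedanceExperiment(Z, th, freqs, cd)
}

#' Write impedance spectra to a long-format CSV
#'
#' Inverse of \code{\link{readSpectra}}: every (spectrum, frequency) pair
#' with a non-missing measurement becomes one row, at full precision.
#'
#' @param x an \linkS4class{ImpedanceExperiment}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSpectra <- function(x, path) {
  stopifnot(is(x, "ImpedanceExperiment"))
  cd <- as.data.frame(colData(x))
  f <- frequencies(x)
  Z <- assay(x, "Z")
  th <- assay(x, "theta")
  n <- ncol(x)
  d <- data.frame(
    plant_id = rep(cd$plant_id, each = length(f)),
    config = rep(cd$config, each = length(f)),
    electrode = rep(cd$electrode, each = length(f)),
    soil = rep(cd$soil, each = length(f)),
    frequency_hz = rep(f, times = n),
    z_ohm = as.vector(Z),
    theta_deg = as.vector(th))
  d <- d[complete.cases(d[, c("z_ohm", "theta_deg")]), ]
  write.csv(format(d, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read plant records (root dry mass)
#'
#' The file must have columns \code{plant_id, rdm_g, soil}; root dry mass is
#' in grams and must be positive, plant ids unique.
#'
#' @param path path to the CSV file.
#' @return a \code{data.frame} with columns \code{plant_id}, \code{rdm_g},
#'   \code{soil}.
#' @export
readPlants <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  .requireColumns(d, c("plant_id", "rdm_g", "soil"), "plants")
  if (anyDuplicated(d$plant_id))
    stop("duplicate plant_id: ",
         paste(unique(d$plant_id[duplicated(d$plant_id)]), collapse = ", "))
  bad <- which(!is.finite(d$rdm_g) | d$rdm_g <= 0)
  if (length(bad))
    stop("non-positive root dry mass rdm_g at file row(s) ",
         paste(bad + 1L, collapse = ", "))
  d[, c("plant_id", "rdm_g", "soil")]
}

#' Write plant records
#' @param plants data.frame with \code{plant_id, rdm_g, soil}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePlants <- function(plants, path) {
  write.csv(format(plants[, c("plant_id", "rdm_g", "soil")],
                   digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
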