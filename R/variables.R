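#' Candidate electrical variables
#'
#' \code{screeningVariables()} returns the eight linearly independent
#' variables screened as root-mass predictors: parallel/serial capacitance
#' (Cp, Cs, farad), parallel/serial resistance (Rp, Rs, ohm), conductance
#' (G, siemens), impedance magnitude (Zmag, ohm), reactance (X, ohm) and
#' phase angle (theta, degrees). \code{allVariables()} adds the two
#' redundant ones: resistance R (equal to Rs) and susceptance B
#' (proportional to Cp, \code{B = -omega * Cp}), which are computable but
#' excluded from ranking.
#'
#' @return character vector of variable names.
#' @export
screeningVariables <- function()
  c("Cp", "Cs", "Rp", "Rs", "G", "Zmag", "X", "theta")

#' @rdname screeningVariables
#' @export
allVariables <- function() c(screeningVariables(), "R", "B")

#' SI unit of an electrical variable
#' @param variable character vector of variable names.
#' @return character vector of units ("F", "Ohm", "S" or "deg").
#' @export
variableUnit <- function(variable) {
  u <- c(Cp = "F", Cs = "F", Rp = "Ohm", Rs = "Ohm", G = "S",
         Zmag = "Ohm", X = "Ohm", theta = "deg", R = "Ohm", B = "S")
  out <- u[variable]
  if (anyNA(out)) stop("unknown variable: ",
                       paste(variable[is.na(out)], collapse = ", "))
  unname(out)
}

#' Complex impedance from magnitude and phase
#'
#' \code{Z* = Z e^(j theta) = Z cos(theta) + j Z sin(theta)}, with the phase
#' supplied in degrees (negative for capacitive systems).
#'
#' @param z impedance magnitude, ohm.
#' @param theta_deg phase angle, degrees.
#' @return complex vector, in ohm.
#' @examples
#' toComplex(100, -90)   # a pure capacitor: 0 - 100i
#' @export
toComplex <- function(z, theta_deg) {
  th <- theta_deg * pi / 180
  complex(real = z * cos(th), imaginary = z * sin(th))
}

#' Compute one electrical variable from (Z, theta, f)
#'
#' Closed forms of the serial and parallel equivalent RC circuits, with
#' \code{omega = 2 pi f}:
#' \describe{
#'   \item{R, Rs}{\code{Z cos(theta)} (ohm)}
#'   \item{X}{\code{Z sin(theta)} (ohm)}
#'   \item{Cs}{\code{-1 / (omega Z sin(theta))} (F)}
#'   \item{G}{\code{cos(theta) / Z} (S)}
#'   \item{B}{\code{sin(theta) / Z} (S)}
#'   \item{Rp}{\code{Z / cos(theta)} (ohm)}
#'   \item{Cp}{\code{-sin(theta) / (omega Z)} (F)}
#'   \item{Zmag, theta}{Z (ohm) and the phase itself (degrees), unchanged}
#' }
#' The minus signs make capacitances positive for capacitive (theta < 0)
#' systems; positive (inductive) phases are accepted and yield negative
#' capacitances so that noisy measurements near theta = 0 do not fail.
#' \code{theta = 0} exactly is a domain error for Cs (singular) and
#' \code{theta = +/-90} degrees for Rp.
#'
#' @param z impedance magnitude (ohm), vectorized.
#' @param theta_deg phase angle (degrees).
#' @param frequency_hz injected-current frequency (Hz); needed for Cp, Cs, B.
#' @param variable one variable name, see \code{\link{allVariables}}.
#' @return numeric vector of values in the variable's SI unit.
#' @examples
#' computeVariable(1000, -90, 1000, "Cp")  # 1/(2*pi*1000*1000) F
#' computeVariable(1000, 0, 1000, "G")     # 1e-3 S
#' @export
computeVariable <- function(z, theta_deg, frequency_hz, variable) {
  variable <- match.arg(variable, allVariables())
  n <- max(length(z), length(theta_deg), length(frequency_hz))
  z <- rep_len(z, n); theta_deg <- rep_len(theta_deg, n)
  frequency_hz <- rep_len(frequency_hz, n)
  ok <- is.finite(z) & is.finite(theta_deg)
  if (any(z[ok] <= 0))
    stop("impedance magnitude must be > 0 (variable ", variable, ")")
  th <- theta_deg * pi / 180
  w <- 2 * pi * frequency_hz
  if (variable %in% c("Cp", "Cs", "B") && any(frequency_hz[ok] <= 0))
    stop("frequency must be > 0 for variable ", variable)
  .sing <- function(bad, what) {
    bad <- which(ok & bad)
    if (length(bad))
      stop("singular conversion for variable ", variable, " (", what,
           ") at sample(s) ", paste(bad, collapse = ", "))
  }
  switch(variable,
    Zmag = z,
    theta = theta_deg,
    R = ,
    Rs = z * cos(th),
    X = z * sin(th),
    G = cos(th) / z,
    B = sin(th) / z,
    Cp = -sin(th) / (w * z),
    Cs = { .sing(theta_deg == 0, "theta = 0"); -1 / (w * z * sin(th)) },
    Rp = { .sing(abs(theta_deg) == 90, "theta = +/-90 deg")
           z / cos(th) })
}

#' Convert an ImpedanceExperiment into electrical-variable assays
#'
#' Applies \code{\link{computeVariable}} to every sample of every spectrum,
#' returning a \link[SummarizedExperiment]{SummarizedExperiment} with the
#' same dimensions, row (frequency) data and column metadata as the input
#' and one assay per requested variable.
#'
#' @param x an \linkS4class{ImpedanceExperiment}.
#' @param variables character vector of variable names; default the eight
#'   screening variables.
#' @return a \code{SummarizedExperiment} of variable values (SI units).
#' @export
electricalVariables <- function(x, variables = screeningVariables()) {
  stopifnot(is(x, "ImpedanceExperiment"))
  variables <- match.arg(variables, allVariables(), several.ok = TRUE)
  Z <- assay(x, "Z")
  th <- assay(x, "theta")
  f <- frequencies(x)
  fmat <- matrix(f, nrow(x), ncol(x))
  out <- lapply(variables, function(v) {
    m <- matrix(computeVariable(as.vector(Z), as.vector(th),
                                as.vector(fmat), v),
                nrow(x), ncol(x), dimnames = dimnames(Z))
    m
  })
  names(out) <- variables
  se <- SummarizedExperiment(assays = out, rowData = rowData(x),
                             colData = colData(x))
  metadata(se)$units <- variableUnit(variables)
  se
}

#' Long-format table of electrical variable values
#'
#' @param ve a \code{SummarizedExperiment} from
#'   \code{\link{electricalVariables}}.
#' @param capacitanceUnit report capacitances in farad (\code{"F"}) or
#'   nanofarad (\code{"nF"}, the unit used for reporting regressions).
#' @return a \code{data.frame} with columns \code{plant_id, config,
#'   electrode, soil, variable, frequency_hz, value, unit}.
#' @export
variablesTable <- function(ve, capacitanceUnit = c("F", "nF")) {
  capacitanceUnit <- match.arg(capacitanceUnit)
  cd <- as.data.frame(colData(ve))
  f <- rowData(ve)$frequency_hz
  pieces <- lapply(assayNames(ve), function(v) {
    m <- assay(ve, v)
    unit <- variableUnit(v)
    if (unit == "F" && capacitanceUnit == "nF") {
      m <- m * 1e9
      unit <- "nF"
    }
    data.frame(plant_id = rep(cd$plant_id, each = length(f)),
               config = rep(cd$config, each = length(f)),
               electrode = rep(cd$electrode, each = length(f)),
               soil = rep(cd$soil, each = length(f)),
               variable = v,
               frequency_hz = rep(f, times = ncol(m)),
               value = as.vector(m),
               unit = unit)
  })
  do.call(rbind, pieces)
}
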