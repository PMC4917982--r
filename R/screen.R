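#' Ordinary least-squares fit of an electrical variable on root dry mass
#'
#' Fits \code{y = a * RDM + b} and reports the slope, intercept, coefficient
#' of determination (the squared Pearson correlation) and the two-sided
#' p-value for the null hypothesis of zero slope.
#'
#' @param x root dry masses, grams (length >= 3, not constant).
#' @param y electrical variable values, same length.
#' @return a one-row \code{data.frame} with columns \code{slope_a,
#'   intercept_b, r2, p_value, n}.
#' @examples
#' fitLinear(c(1, 2, 3), c(2, 4, 6))  # a = 2, b = 0, r2 = 1
#' @export
fitLinear <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L)
    stop("insufficient data: need at least 3 complete (RDM, value) pairs, got ",
         n)
  if (diff(range(x)) == 0)
    stop("degenerate design: root dry mass is constant")
  if (diff(range(y)) == 0)  # flat response carries no information about RDM
    return(data.frame(slope_a = 0, intercept_b = y[1], r2 = 0, p_value = 1,
                      n = n))
  fit <- lm(y ~ x)
  a <- unname(coef(fit)[2L])
  # slope t-test from the fit residuals (avoids summary.lm's perfect-fit
  # warning on noiseless data; p = 0 there)
  seA <- sqrt(sum(fit$residuals^2) / (n - 2) / sum((x - mean(x))^2))
  p <- if (seA == 0) 0 else 2 * pt(-abs(a / seA), df = n - 2)
  data.frame(slope_a = a,
             intercept_b = unname(coef(fit)[1L]),
             r2 = cor(x, y)^2,
             p_value = p,
             n = n)
}

#' Significance stars for a regression p-value
#'
#' \code{"***"} for p < 0.01, \code{"**"} for 0.01 <= p < 0.05, otherwise
#' \code{""}.
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
significanceStars <- function(p) {
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ""))
}

#' ScreenResult: per-frequency regression screen of one variable
#'
#' Holds, for one electrical variable in one terminal configuration, the
#' linear regression on root dry mass at every frequency, plus the maximum
#' determination frequency \code{fMax} and its determination coefficient
#' \code{r2Max}.
#'
#' @slot variable the screened electrical variable.
#' @slot config terminal configuration ("2T", "3T" or "4T").
#' @slot electrode stem electrode type used.
#' @slot mode \code{"pooled"} (one regression per frequency over all plants)
#'   or \code{"soil_averaged"} (the r2 curve is the arithmetic mean of
#'   per-soil r2 values, while slope and intercept come from the pooled
#'   fit).
#' @slot results \code{data.frame} with one row per frequency:
#'   \code{frequency_hz, slope_a, intercept_b, r2, p_value, n, stars} (and
#'   \code{r2_pooled} in soil-averaged mode). p-values are per-frequency,
#'   with no multiple-testing correction.
#' @slot fMax frequency (Hz) maximising the screened r2 curve; ties are
#'   broken toward the lowest frequency.
#' @slot r2Max the screened r2 curve's value at \code{fMax}.
#' @seealso \code{\link{screenVariable}}, \code{\link{rankVariables}}
#' @exportClass ScreenResult
setClass("ScreenResult",
  representation(variable = "character", config = "character",
                 electrode = "character", mode = "character",
                 results = "data.frame", fMax = "numeric",
                 r2Max = "numeric"))

setValidity("ScreenResult", function(object) {
  r <- object@results
  msg <- character()
  need <- c("frequency_hz", "slope_a", "intercept_b", "r2", "p_value", "n")
  if (!all(need %in% colnames(r)))
    return("results must contain frequency_hz, slope_a, intercept_b, r2, p_value, n")
  if (any(r$r2 < 0 | r$r2 > 1, na.rm = TRUE))
    msg <- c(msg, "r2 must lie in [0, 1]")
  if (any(r$p_value < 0 | r$p_value > 1, na.rm = TRUE))
    msg <- c(msg, "p_value must lie in [0, 1]")
  if (!object@fMax %in% r$frequency_hz)
    msg <- c(msg, "fMax must be one of the screened frequencies")
  if (length(msg)) msg else TRUE
})

#' @describeIn ScreenResult maximum determination frequency, Hz.
#' @param object a \code{ScreenResult}.
#' @export
fMax <- function(object) object@fMax

#' @describeIn ScreenResult maximum of the screened r2 curve.
#' @export
r2Max <- function(object) object@r2Max

#' @describeIn ScreenResult the per-frequency regression table.
#' @export
screenTable <- function(object) object@results

setMethod("show", "ScreenResult", function(object) {
  cat("ScreenResult:", object@variable, "~ RDM |", object@config, "/",
      object@electrode, "(", object@mode, ")\n")
  cat("  ", nrow(object@results), "frequencies; f_max =",
      format(object@fMax), "Hz, r2_max =", format(object@r2Max, digits = 3),
      "\n")
  i <- which(object@results$frequency_hz == object@fMax)
  cat("  at f_max: a =", format(object@results$slope_a[i], digits = 4),
      ", b =", format(object@results$intercept_b[i], digits = 4),
      ", n =", object@results$n[i], "\n")
  invisible(NULL)
})

#' Screen one electrical variable against root dry mass across frequency
#'
#' For one variable and one terminal configuration, regresses the variable
#' on root dry mass at every frequency of the support and locates the
#' maximum determination frequency \code{f_max} (the frequency with the
#' largest screened r2; ties go to the lowest frequency).
#'
#' In \code{"pooled"} mode the screened r2 curve is that of the single
#' regression over all plants. In \code{"soil_averaged"} mode (the default)
#' the r2 curve is the arithmetic mean of per-soil r2 values at each
#' frequency -- mirroring how frequency screens are summarised across growth
#' substrates -- while the reported slope and intercept still come from the
#' pooled fit (a single calibration line across soils).
#'
#' @param ve a \code{SummarizedExperiment} from
#'   \code{\link{electricalVariables}} whose \code{colData} carries
#'   \code{rdm_g} (attach it with \code{\link{attachPlants}} before
#'   converting).
#' @param variable the variable (assay) to screen.
#' @param config terminal configuration to select.
#' @param electrode stem electrode to select, default \code{"clamp"}.
#' @param mode \code{"soil_averaged"} or \code{"pooled"}.
#' @return a \linkS4class{ScreenResult}.
#' @export
screenVariable <- function(ve, variable, config,
                           electrode = "clamp",
                           mode = c("soil_averaged", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(variable %in% assayNames(ve))
  cd <- colData(ve)
  if (!"rdm_g" %in% colnames(cd))
    stop("no root dry mass in colData; use attachPlants() before ",
         "electricalVariables()")
  sel <- cd$config == config & cd$electrode == electrode
  if (!any(sel))
    stop("no spectra for config ", config, " with electrode ", electrode)
  if (anyNA(cd$rdm_g[sel])) {
    bad <- unique(cd$plant_id[sel][is.na(cd$rdm_g[sel])])
    stop("missing plant record (rdm_g) for plant_id: ",
         paste(bad, collapse = ", "))
  }
  m <- assay(ve, variable)[, sel, drop = FALSE]
  rdm <- cd$rdm_g[sel]
  soil <- cd$soil[sel]
  f <- rowData(ve)$frequency_hz
  rows <- lapply(seq_along(f), function(i) {
    pooled <- fitLinear(rdm, m[i, ])
    if (mode == "soil_averaged") {
      r2s <- vapply(unique(soil), function(s) {
        j <- soil == s
        ok <- is.finite(rdm[j]) & is.finite(m[i, j])
        if (sum(ok) < 3L || diff(range(rdm[j][ok])) == 0) return(NA_real_)
        fitLinear(rdm[j], m[i, j])$r2
      }, numeric(1))
      if (all(is.na(r2s)))
        stop("soil_averaged screen: no soil group with >= 3 plants and ",
             "varying RDM at ", f[i], " Hz")
      pooled$r2_pooled <- pooled$r2
      pooled$r2 <- mean(r2s, na.rm = TRUE)
    }
    cbind(data.frame(frequency_hz = f[i]), pooled)
  })
  res <- do.call(rbind, rows)
  res$stars <- significanceStars(res$p_value)
  imax <- which.max(res$r2)  # first maximum = lowest frequency on ties
  new("ScreenResult", variable = variable, config = config,
      electrode = electrode, mode = mode, results = res,
      fMax = res$frequency_hz[imax], r2Max = res$r2[imax])
}
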