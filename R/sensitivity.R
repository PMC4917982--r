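#' Sensitivity score of a linear root-mass predictor
#'
#' A determination coefficient alone does not make an electrical variable a
#' useful root-mass estimator: if the regression intercept \code{b} is large
#' relative to the signal \code{a * m0} at the characteristic root mass
#' \code{m0}, the ratio of two measurements no longer approximates the ratio
#' of two root masses. The sensitivity score combines both requirements:
#'
#' \deqn{s = \max\left(r^2_{max} \times \left(1 - \left|\frac{b}{a\,m_0}\right|\right),\ 0\right)}
#'
#' \code{s = 1} means measurement ratios equal root-mass ratios with perfect
#' determination; \code{s = 0} means only very large root-mass differences
#' would register.
#'
#' @param r2max maximum determination coefficient, in [0, 1].
#' @param a regression slope (variable unit per gram), nonzero.
#' @param b regression intercept (variable unit).
#' @param m0 characteristic root mass, grams (default 1 g, the order of
#'   magnitude of an adult cereal root system in pots).
#' @return the score \code{s}, in [0, 1]. Vectorized over all arguments.
#' @examples
#' sensitivityScore(0.787, 4.2, 0.37)        # ~0.718
#' sensitivityScore(0.73, 1, 1.33)           # 0: intercept-dominated
#' @export
sensitivityScore <- function(r2max, a, b, m0 = 1) {
  n <- max(length(r2max), length(a), length(b), length(m0))
  r2max <- rep_len(r2max, n); a <- rep_len(a, n)
  b <- rep_len(b, n); m0 <- rep_len(m0, n)
  if (any(!is.finite(a) | a == 0))
    stop("slope a must be nonzero: intercept:slope ratio undefined")
  if (any(m0 <= 0)) stop("characteristic mass m0 must be > 0")
  if (any(r2max < 0 | r2max > 1)) stop("r2max must lie in [0, 1]")
  pmax(r2max * (1 - abs(b / (a * m0))), 0)
}

.scoreFromScreenRow <- function(variable, config, frequency_hz, r2, slope_a,
                                intercept_b, p_value, m0) {
  data.frame(variable = variable, config = config,
             frequency_hz = frequency_hz,
             m0_g = m0,
             ratio = abs(intercept_b / (slope_a * m0)),
             s = sensitivityScore(r2, slope_a, intercept_b, m0),
             r2 = r2,
             slope_a = slope_a, intercept_b = intercept_b,
             p_value = p_value, stars = significanceStars(p_value))
}

#' Rank electrical variables by sensitivity score
#'
#' Builds the predictor-ranking table: for every screen, the sensitivity
#' score is computed from the pooled regression (slope, intercept) at that
#' screen's maximum determination frequency together with \code{r2Max}.
#' Rows are sorted by score (descending), ties broken by \code{r2Max}
#' descending then variable name.
#'
#' @param screens a list of \linkS4class{ScreenResult} objects, one per
#'   (variable, configuration).
#' @param m0 characteristic root mass in grams, default 1.
#' @return a \code{data.frame} with columns \code{variable, config,
#'   frequency_hz (f_max), m0_g, ratio, s, r2 (r2_max), slope_a,
#'   intercept_b, p_value, stars}.
#' @export
rankVariables <- function(screens, m0 = 1) {
  if (is(screens, "ScreenResult")) screens <- list(screens)
  rows <- lapply(screens, function(sc) {
    stopifnot(is(sc, "ScreenResult"))
    r <- sc@results
    i <- which(r$frequency_hz == sc@fMax)[1L]
    .scoreFromScreenRow(sc@variable, sc@config, sc@fMax, sc@r2Max,
                        r$slope_a[i], r$intercept_b[i], r$p_value[i], m0)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$s, -out$r2, out$variable), ]
  rownames(out) <- NULL
  out
}

#' Sensitivity scores at fixed test frequencies (LCR-meter conditions)
#'
#' Handheld LCR meters measure at a few fixed frequencies in two-terminal
#' mode. This evaluates every screened variable at the requested
#' frequencies, computing each score from that frequency's own regression
#' (its r2, slope and intercept) rather than from the spectrum-wide maximum.
#'
#' @param screens a list of \linkS4class{ScreenResult} objects.
#' @param frequencies test frequencies in Hz; defaults to the grid points
#'   closest to the 100/1000/10000 Hz settings of handheld meters. Matched
#'   to the screened support within 1% relative tolerance.
#' @param m0 characteristic root mass in grams, default 1.
#' @return a \code{data.frame} in the same format as
#'   \code{\link{rankVariables}}, one row per (screen, frequency).
#' @export
lcrSubset <- function(screens, frequencies = c(116.0933, 1250, 13459.00),
                      m0 = 1) {
  if (is(screens, "ScreenResult")) screens <- list(screens)
  rows <- lapply(screens, function(sc) {
    stopifnot(is(sc, "ScreenResult"))
    r <- sc@results
    do.call(rbind, lapply(frequencies, function(f) {
      i <- which(abs(r$frequency_hz - f) <= 0.01 * f)
      if (!length(i))
        stop("frequency ", f, " Hz absent from the screened support of ",
             sc@variable, "/", sc@config)
      i <- i[1L]
      .scoreFromScreenRow(sc@variable, sc@config, r$frequency_hz[i],
                          r$r2[i], r$slope_a[i], r$intercept_b[i],
                          r$p_value[i], m0)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
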