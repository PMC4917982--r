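# Independent forward models used as oracles: all complex arithmetic here is
# written against R's complex class directly, never through package helpers.

# impedance of an ideal parallel RC via admittance, Y = 1/R + j w C
oracleParallelRC <- function(R, C, f) {
  1 / (1 / R + 1i * 2 * pi * f * C)
}

# impedance of an ideal serial RC, Z = R + 1/(j w C)
oracleSerialRC <- function(R, C, f) {
  R + 1 / (1i * 2 * pi * f * C)
}

# (Z, theta) samples from a complex impedance
asPolar <- function(z) {
  list(z_ohm = Mod(z), theta_deg = Arg(z) * 180 / pi)
}

# all eight screening variables from (Z, theta_deg, f) via complex
# admittance arithmetic -- the reference the package implementation is
# checked against
oracleVariables <- function(z, theta_deg, f) {
  zs <- complex(modulus = z, argument = theta_deg * pi / 180)
  y <- 1 / zs
  w <- 2 * pi * f
  list(Cp = Im(y) / w,
       Cs = -1 / (w * Im(zs)),
       Rp = 1 / Re(y),
       Rs = Re(zs),
       G = Re(y),
       Zmag = Mod(zs),
       X = Im(zs),
       theta = Arg(zs) * 180 / pi)
}

# build an ImpedanceExperiment holding given complex spectra (cols) on grid f
makeExperiment <- function(zstar, f, plant_id, config = "3T",
                           electrode = "clamp", soil = "loam",
                           rdm_g = NULL) {
  zstar <- as.matrix(zstar)
  cd <- data.frame(plant_id = plant_id,
                   config = rep_len(config, ncol(zstar)),
                   electrode = rep_len(electrode, ncol(zstar)),
                   soil = rep_len(soil, ncol(zstar)))
  ie <- ImpedanceExperiment(Mod(zstar), Arg(zstar) * 180 / pi, f, cd)
  if (!is.null(rdm_g))
    ie <- attachPlants(ie, data.frame(plant_id = unique(plant_id),
                                      rdm_g = rdm_g,
                                      soil = cd$soil[!duplicated(plant_id)]))
  ie
}

# a small spectra data.frame in the on-disk long format
makeSpectraCsv <- function(path, d) {
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  path
}

# closed-form OLS by the normal equations, with the t-test p-value --
# independent of fitLinear's lm route
oracleOls <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  a <- sxy / sxx
  b <- mean(y) - a * mean(x)
  r2 <- sxy^2 / (sxx * sum((y - mean(y))^2))
  se <- sqrt(sum((y - a * x - b)^2) / (n - 2) / sxx)
  list(a = a, b = b, r2 = r2, p = 2 * pt(-abs(a / se), df = n - 2))
}

# exact signed-rank two-sided p by brute-force enumeration of all 2^n sign
# vectors (the acceptance oracle); same doubling convention as the test
oracleSignedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wnull <- as.vector(signs %*% r)
  pLe <- mean(Wnull <= W + 1e-9)
  pGe <- mean(Wnull >= W - 1e-9)
  min(1, 2 * min(pLe, pGe))
}
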