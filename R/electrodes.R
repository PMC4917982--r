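#' Relative clamp-needle capacitance difference
#'
#' For a plant measured with both stem electrode types, the relative
#' difference between the clamp capacitance \code{C_c} and the needle
#' capacitance \code{C_n} is \code{|C_c - C_n| / C_c} (a dimensionless
#' fraction; multiply by 100 for percent).
#'
#' @param c_clamp capacitance measured with the alligator clamp, farad
#'   (nonzero).
#' @param c_needle capacitance measured with the needle, farad.
#' @return numeric vector of relative differences.
#' @examples
#' deltaCp(1.0e-9, 0.94e-9)  # 0.06
#' @export
deltaCp <- function(c_clamp, c_needle) {
  if (any(c_clamp == 0, na.rm = TRUE))
    stop("clamp capacitance is zero: relative difference undefined")
  abs(c_clamp - c_needle) / c_clamp
}

#' Wilcoxon signed-rank test for paired measurements
#'
#' Two-sided paired signed-rank test. Zero differences are dropped before
#' ranking (Wilcoxon's original treatment); tied absolute differences share
#' average ranks. For up to 20 nonzero differences the p-value comes from
#' the exact null distribution of the positive-rank sum, computed by
#' dynamic programming over all \code{2^n} sign assignments (equivalent to
#' full enumeration, including under ties); above 20 a normal approximation
#' with tie-corrected variance and continuity correction is used.
#'
#' @param x first member of each pair (e.g. clamp capacitances), or the
#'   paired differences if \code{y} is \code{NULL}.
#' @param y second member of each pair, or \code{NULL}.
#' @param alpha significance level, default 0.01.
#' @param exactMax largest number of nonzero differences for which the
#'   exact distribution is used (default 20).
#' @return a list with \code{statistic} (positive-rank sum W),
#'   \code{p_value} (two-sided), \code{n_nonzero}, \code{method}
#'   (\code{"exact"}, \code{"normal_approximation"} or
#'   \code{"degenerate"}), \code{degenerate} (TRUE when all differences are
#'   zero, in which case p = 1) and \code{significant} (p < alpha).
#' @examples
#' wilcoxonSignedRank(c(1, 2, 3, 4, 5), c(0, 1, 2, 3, 4))$p_value  # 0.0625
#' @export
wilcoxonSignedRank <- function(x, y = NULL, alpha = 0.01, exactMax = 20L) {
  d <- if (is.null(y)) x else {
    stopifnot(length(x) == length(y))
    x - y
  }
  d <- d[is.finite(d)]
  if (!length(d)) stop("no complete pairs")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, p_value = 1, n_nonzero = 0L,
                method = "degenerate", degenerate = TRUE,
                significant = FALSE))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exactMax) {
    # null distribution of 2W by subset-sum DP over the doubled ranks
    # (doubling makes average ties integral); counts fit exactly in doubles
    r2 <- as.integer(round(2 * r))
    counts <- numeric(sum(r2) + 1L)
    counts[1L] <- 1
    for (s in r2) {
      shifted <- c(numeric(s), counts[seq_len(length(counts) - s)])
      counts <- counts + shifted
    }
    tot <- 2^n
    w2 <- as.integer(round(2 * W))
    pLe <- sum(counts[seq_len(w2 + 1L)]) / tot
    pGe <- sum(counts[(w2 + 1L):length(counts)]) / tot
    p <- min(1, 2 * min(pLe, pGe))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - 0.5 * sign(W - mu)) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approximation"
  }
  list(statistic = W, p_value = p, n_nonzero = n, method = method,
       degenerate = FALSE, significant = p < alpha)
}

#' Compare clamp and needle stem electrodes per frequency
#'
#' Pairs, per plant and terminal configuration, the capacitance (or any
#' other variable) measured with the clamp against that measured with the
#' needle, then reports at every frequency the mean relative difference
#' \code{|C_c - C_n| / C_c} and a two-sided Wilcoxon signed-rank test of
#' the paired values at level \code{alpha}. Per-frequency tests carry no
#' multiple-testing correction.
#'
#' @param ve a \code{SummarizedExperiment} from
#'   \code{\link{electricalVariables}} containing spectra for both
#'   electrode types.
#' @param variable the assay to compare, default \code{"Cp"}.
#' @param alpha significance level, default 0.01.
#' @return a \code{data.frame} with one row per (config, frequency):
#'   \code{config, frequency_hz, mean_delta, p_value, n_pairs,
#'   significant}. \code{mean_delta} is a fraction; the attribute
#'   \code{"zero_handling"} records that zero differences are dropped.
#' @export
compareElectrodes <- function(ve, variable = "Cp", alpha = 0.01) {
  stopifnot(variable %in% assayNames(ve))
  cd <- colData(ve)
  m <- assay(ve, variable)
  f <- rowData(ve)$frequency_hz
  out <- list()
  for (cfg in sort(unique(cd$config))) {
    ic <- which(cd$config == cfg & cd$electrode == "clamp")
    im <- which(cd$config == cfg & cd$electrode == "needle")
    if (!length(ic) && !length(im)) next
    idx <- match(cd$plant_id[ic], cd$plant_id[im])
    if (anyNA(idx) || length(im) > length(ic)) {
      missing_needle <- cd$plant_id[ic][is.na(idx)]
      missing_clamp <- setdiff(cd$plant_id[im], cd$plant_id[ic])
      stop("unpaired electrode measurements in ", cfg,
           if (length(missing_needle))
             paste0("; no needle spectrum for plant_id: ",
                    paste(missing_needle, collapse = ", ")),
           if (length(missing_clamp))
             paste0("; no clamp spectrum for plant_id: ",
                    paste(missing_clamp, collapse = ", ")))
    }
    cc <- m[, ic, drop = FALSE]
    cn <- m[, im[idx], drop = FALSE]
    rows <- lapply(seq_along(f), function(i) {
      ok <- is.finite(cc[i, ]) & is.finite(cn[i, ])
      wt <- wilcoxonSignedRank(cc[i, ok], cn[i, ok], alpha = alpha)
      data.frame(config = cfg, frequency_hz = f[i],
                 mean_delta = mean(deltaCp(cc[i, ok], cn[i, ok])),
                 p_value = wt$p_value, n_pairs = sum(ok),
                 significant = wt$significant)
    })
    out[[cfg]] <- do.call(rbind, rows)
  }
  if (!length(out))
    stop("no clamp/needle spectra to compare")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "alpha") <- alpha
  attr(res, "zero_handling") <- "zero differences dropped before ranking"
  res
}
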