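#' Published capacitance-root mass regressions
#'
#' A compilation of linear regressions between parallel capacitance and
#' root mass from prior greenhouse and field experiments, summarised by
#' each study's characteristic root mass \code{m0_g} (grams, fresh or dry
#' per \code{root_state}), its printed intercept:slope ratio
#' \code{b/(a m0)}, its determination coefficient \code{r2} and the
#' sensitivity score \code{s_printed} as published. Rows lacking the ratio
#' carry flag \code{"incomplete"}; one row is \code{"ambiguous_source"}
#' (columns not legible in the source) and one
#' \code{"inconsistent_printed"} (its printed score does not follow from
#' its printed inputs); flagged rows are passed through but excluded from
#' score-reproduction checks.
#'
#' @return a \code{data.frame} with columns \code{study, species, m0_g,
#'   ratio, r2, s_printed, media, root_state, flags}.
#' @export
bundledLiterature <- function() {
  path <- system.file("extdata", "literature_table3.csv",
                      package = "rootcap", mustWork = TRUE)
  d <- read.csv(path, stringsAsFactors = FALSE)
  d$flags[is.na(d$flags)] <- ""
  d
}

#' Recompute sensitivity scores for literature regressions
#'
#' Applies \code{s = max(r2 * (1 - |ratio|), 0)} to every entry that has
#' both an intercept:slope ratio and a determination coefficient. Entries
#' missing either are passed through with \code{s = NA} and the
#' \code{"incomplete"} flag (missing fields are flags, not errors).
#'
#' @param entries a \code{data.frame} with at least columns \code{ratio}
#'   and \code{r2}, e.g. from \code{\link{bundledLiterature}}.
#' @return \code{entries} with a numeric column \code{s} appended (and
#'   \code{flags} updated for incomplete rows).
#' @examples
#' lit <- recomputeScores(bundledLiterature())
#' lit[lit$study == "Wheat multi-soil benchmark", c("ratio", "r2", "s")]
#' @export
recomputeScores <- function(entries) {
  stopifnot(all(c("ratio", "r2") %in% colnames(entries)))
  if (!"flags" %in% colnames(entries)) entries$flags <- ""
  complete <- is.finite(entries$ratio) & is.finite(entries$r2)
  entries$s <- NA_real_
  entries$s[complete] <- pmax(
    entries$r2[complete] * (1 - abs(entries$ratio[complete])), 0)
  mark <- !complete & !grepl("incomplete", entries$flags)
  entries$flags[mark] <- sub("^;", "", paste(entries$flags[mark],
                                             "incomplete", sep = ";"))
  entries
}
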