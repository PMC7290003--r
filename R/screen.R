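# Fluorescence screening arithmetic: fold change of line fluorescence over
# wild-type autofluorescence, the five-bin classification, and library
# dispersion summaries.

SCREEN_BINS <- c(0, 10, 250, 800, 1500, Inf)
SCREEN_BIN_LABELS <- c("<10", "10–250", "250–800",
                       "800–1,500", ">1,500")

#' Fluorescence fold change over wild type
#'
#' @param lineMean mean fluorescence of a transformant line (arbitrary
#'   units).
#' @param wtMean mean wild-type autofluorescence in the same units (> 0).
#' @return `lineMean / wtMean`.
#' @export
foldChange <- function(lineMean, wtMean) {
  if (any(wtMean <= 0)) stop("wild-type mean must be > 0")
  lineMean / wtMean
}

#' Bin a fold change into the five screening groups
#'
#' Bins are half-open, lower-inclusive: `[0,10)`, `[10,250)`, `[250,800)`,
#' `[800,1500)`, `[1500,Inf)`. Every non-negative fold change maps to
#' exactly one bin; note the boundary convention puts e.g. a fold change of
#' exactly 1500 into the top bin.
#'
#' @param fc numeric vector of fold changes (>= 0).
#' @return character vector of bin labels.
#' @export
binFoldChange <- function(fc) {
  if (any(fc < 0)) stop("fold changes must be >= 0")
  SCREEN_BIN_LABELS[findInterval(fc, SCREEN_BINS, rightmost.closed = FALSE)]
}

#' Summarise a screening library
#'
#' @param foldChanges numeric vector of per-line fold changes (>= 2 values).
#' @return list with `mean` (arithmetic mean fold change), `sem` (sample
#'   standard deviation / sqrt(n)), `n`, and `bin_fractions` (named, sums
#'   to 1).
#' @export
librarySummary <- function(foldChanges) {
  n <- length(foldChanges)
  if (n < 2L) stop("at least two lines are required")
  bins <- factor(binFoldChange(foldChanges), levels = SCREEN_BIN_LABELS)
  fractions <- setNames(as.numeric(table(bins)) / n, SCREEN_BIN_LABELS)
  list(mean = mean(foldChanges), sem = sd(foldChanges) / sqrt(n), n = n,
       bin_fractions = fractions)
}

#' Screen a plate table of line fluorescence against wild-type controls
#'
#' @param plate data.frame with columns `line_id`, `fluorescence` and a
#'   logical `wildtype` column flagging control rows.
#' @return data.frame with `line_id`, `line_mean`, `fold_change`,
#'   `bin_label`; wild-type rows are aggregated into the reference mean.
#' @export
screenPlate <- function(plate) {
  stopifnot(all(c("line_id", "fluorescence", "wildtype") %in% names(plate)))
  wt <- plate$fluorescence[plate$wildtype]
  if (length(wt) == 0L) stop("no wild-type control rows")
  wtMean <- mean(wt)
  lines <- plate[!plate$wildtype, , drop = FALSE]
  agg <- tapply(lines$fluorescence, lines$line_id, mean)
  fc <- foldChange(as.numeric(agg), wtMean)
  data.frame(line_id = names(agg), line_mean = as.numeric(agg),
             wt_mean = wtMean, fold_change = fc,
             bin_label = binFoldChange(fc), stringsAsFactors = FALSE)
}
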