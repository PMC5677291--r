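#' Skin-temperature features for one epoch
#'
#' The three SKT features of the panel: `SKTavg` the mean temperature,
#' `SKTslope` the excursion `max - min` (a range, per the panel
#' definition), and `SKTstd` the sample standard deviation.
#'
#' @param x An `"skt"` [time_series()] with at least 2 samples.
#' @return Named list `SKTavg`, `SKTslope`, `SKTstd`; all `NA`
#'   (missing-feature marker) for a single-sample input.
#' @export
skt_features <- function(x) {
  stopifnot(inherits(x, "time_series"))
  if (x$channel != "skt") stop("`x` must be an skt channel", call. = FALSE)
  v <- x$samples
  if (length(v) < 2L)
    return(list(SKTavg = NA_real_, SKTslope = NA_real_, SKTstd = NA_real_))
  list(SKTavg = mean(v), SKTslope = max(v) - min(v), SKTstd = stats::sd(v))
}
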