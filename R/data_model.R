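#' @useDynLib pinnitrack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate coef dgamma dnorm lm mad median optim optimize
#'   prcomp quantile rbeta rexp rgamma rnorm rpois runif sd setNames var
#'   pchisq qnorm rbinom
#' @importFrom utils head read.csv tail write.csv
NULL

.POSIX_ORIGIN <- "1970-01-01"

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (is.character(x) || is.factor(x))
    return(as.POSIXct(as.character(x), tz = "UTC",
                      tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                     "%Y-%m-%d")))
  as.POSIXct(x, tz = "UTC", origin = .POSIX_ORIGIN)
}

#' Seal metadata table
#'
#' One row per instrumented animal: identity, sex, morphometrics, tagging
#' window and tagging location. Body mass, if missing, is filled from the
#' allometric equation.
#'
#' @param id character ids, unique.
#' @param sex "M" or "F".
#' @param standard_length,girth cm, positive.
#' @param body_mass kg; `NA` entries are computed with
#'   [estimate_body_mass()].
#' @param tag_start,tag_end POSIXct (UTC); `tag_end >= tag_start`.
#' @param start_lat,start_lon tagging site, degrees.
#' @return a `data.frame` of class `seal_metadata`.
#' @export
seal_metadata <- function(id, sex, standard_length, girth, body_mass = NA,
                          tag_start, tag_end, start_lat, start_lon) {
  df <- data.frame(id = as.character(id), sex = as.character(sex),
                   standard_length = standard_length, girth = girth,
                   body_mass = body_mass,
                   tag_start = as_utc(tag_start), tag_end = as_utc(tag_end),
                   start_lat = start_lat, start_lon = start_lon,
                   stringsAsFactors = FALSE)
  miss <- is.na(df$body_mass)
  if (any(miss))
    df$body_mass[miss] <- estimate_body_mass(df$standard_length[miss], df$girth[miss])
  validate_seal_metadata(df)
  class(df) <- c("seal_metadata", "data.frame")
  df
}

validate_seal_metadata <- function(df) {
  if (anyDuplicated(df$id)) stop("duplicate seal ids")
  if (!all(df$sex %in% c("M", "F"))) stop("sex must be M or F")
  if (any(df$standard_length <= 0) || any(df$girth <= 0) || any(df$body_mass <= 0))
    stop("length, girth and mass must be positive")
  if (any(df$tag_end < df$tag_start)) stop("tag_end before tag_start")
  invisible(df)
}

# Validate and canonicalise one per-seal observation stream: sort by time,
# drop duplicate timestamps (keep first).
canonicalise_stream <- function(df, time_col, label) {
  if (nrow(df) == 0) return(df)
  df <- df[order(df$seal_id, df[[time_col]]), , drop = FALSE]
  key <- paste(df$seal_id, as.numeric(df[[time_col]]))
  dup <- duplicated(key)
  if (any(dup))
    message(sum(dup), " duplicate-timestamp ", label, " record(s) dropped (kept first)")
  rownames(df) <- NULL
  df[!dup, , drop = FALSE]
}

#' Validate a full telemetry dataset
#'
#' Checks every type invariant of the observation streams: coordinate
#' ranges, positive depths/durations, strictly increasing per-seal times,
#' profile consistency, non-overlapping haul-outs, 6-h activity percentages
#' summing to 100, CTD depth monotonicity.
#'
#' @param dataset a list as returned by [read_dataset()] or
#'   [simulate_population()].
#' @return invisibly, the dataset; stops with a descriptive error on the
#'   first violated invariant.
#' @export
validate_dataset <- function(dataset) {
  fx <- dataset$fixes
  if (nrow(fx) > 0) {
    if (any(abs(fx$lat) > 90)) stop("fix latitude outside [-90, 90] at record ",
                                    which(abs(fx$lat) > 90)[1])
    if (any(fx$lon <= -180 | fx$lon > 180))
      stop("fix longitude outside (-180, 180] at record ",
           which(fx$lon <= -180 | fx$lon > 180)[1])
    for (id in unique(fx$seal_id)) {
      tt <- fx$time[fx$seal_id == id]
      if (any(diff(as.numeric(tt)) <= 0)) stop("non-increasing fix times for seal ", id)
    }
  }
  dv <- dataset$dives
  if (nrow(dv) > 0) {
    if (any(dv$max_depth <= 0)) stop("non-positive dive depth at record ",
                                     which(dv$max_depth <= 0)[1])
    if (any(dv$duration_min <= 0)) stop("non-positive dive duration at record ",
                                        which(dv$duration_min <= 0)[1])
    if (!is.null(dv$profile)) {
      for (i in seq_len(nrow(dv))) {
        pr <- dv$profile[[i]]
        if (is.null(pr)) next
        if (any(pr$depth > dv$max_depth[i] + 1e-6) ||
            abs(max(pr$depth) - dv$max_depth[i]) > 1e-6)
          stop("dive profile inconsistent with max_depth at record ", i)
      }
    }
  }
  sm <- dataset$summaries
  if (!is.null(sm) && nrow(sm) > 0) {
    tot <- sm$pct_diving + sm$pct_surface + sm$pct_hauled
    bad <- abs(tot - 100) > 0.5 |
      sm$pct_diving < 0 | sm$pct_surface < 0 | sm$pct_hauled < 0 |
      sm$pct_diving > 100 | sm$pct_surface > 100 | sm$pct_hauled > 100
    if (any(bad)) stop("activity percentages invalid at summary record ", which(bad)[1])
  }
  ho <- dataset$haulouts
  if (!is.null(ho) && nrow(ho) > 0) {
    if (any(ho$end_time <= ho$start_time)) stop("haul-out with end <= start")
    for (id in unique(ho$seal_id)) {
      h <- ho[ho$seal_id == id, ]
      h <- h[order(h$start_time), ]
      if (nrow(h) > 1 &&
          any(as.numeric(h$start_time[-1]) < as.numeric(h$end_time[-nrow(h)])))
        stop("overlapping haul-out events for seal ", id)
    }
  }
  ct <- dataset$ctd
  if (!is.null(ct) && nrow(ct) > 0 && !is.null(ct$samples)) {
    for (i in seq_len(nrow(ct))) {
      s <- ct$samples[[i]]
      if (any(diff(s$depth) <= 0)) stop("CTD depths not strictly increasing, cast ", i)
      if (any(s$salinity < 0)) stop("negative salinity, cast ", i)
    }
  }
  invisible(dataset)
}
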