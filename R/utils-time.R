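#' @import data.table
#' @importFrom stats median quantile rbinom rlnorm rnorm rpois runif sd var
#'   predict setNames aggregate chisq.test complete.cases
#' @importFrom utils head tail write.csv read.csv
NULL

# Timestamps are numeric epoch seconds on the participant's *local* clock
# (the generator emits local time directly; a tz_offset column in
# participants.csv is honoured by shifting on read).  All time-of-day and
# day-of-week logic below therefore needs no timezone handling.

SECONDS_PER_DAY <- 86400L
EPOCH_SECONDS <- 900L # 15-minute grid

#' Hour of day (0-23) of a local-clock timestamp
#' @param t numeric epoch seconds (local clock)
#' @return integer hour in 0..23
#' @keywords internal
hour_of_day <- function(t) as.integer(floor((t %% SECONDS_PER_DAY) / 3600))

#' Day of week with Monday = 0 .. Sunday = 6
#' @param t numeric epoch seconds (local clock)
#' @return integer in 0..6
#' @keywords internal
day_of_week <- function(t) {
  # 1970-01-01 was a Thursday -> index 3 under Monday = 0
  as.integer((floor(t / SECONDS_PER_DAY) + 3) %% 7)
}

#' Calendar day index (days since 1970-01-01, local clock)
#' @keywords internal
day_index <- function(t) as.integer(floor(t / SECONDS_PER_DAY))

#' Snap a timestamp down to the containing 15-minute epoch boundary
#' @keywords internal
snap_epoch <- function(t) floor(t / EPOCH_SECONDS) * EPOCH_SECONDS

DAY_NAMES <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")

`%||%` <- function(a, b) if (is.null(a)) b else a
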