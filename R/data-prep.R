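#' Default season map
#'
#' Months are grouped into a winter season (November-January), a summer
#' season (August-September) and an off-peak season (the remaining months).
#' The grouping is configurable because month groupings are center-specific;
#' see [compare_month_groupings()] for choosing one from data.
#'
#' @param winter,summer integer month numbers (1-12) for the two peak
#'   seasons; all other months are off-peak.
#' @return Character vector of length 12 mapping month number to season
#'   label (`"winter"`, `"summer"`, `"off_peak"`).
#' @export
default_season_map <- function(winter = c(11, 12, 1), summer = c(8, 9)) {
  if (length(intersect(winter, summer)))
    stop("winter and summer months overlap")
  map <- rep("off_peak", 12)
  map[winter] <- "winter"
  map[summer] <- "summer"
  map
}

season_levels <- c("winter", "summer", "off_peak")

#' Example national-holiday calendar
#'
#' A small synthetic list of national-holiday dates for 2019, spanning all
#' three seasons, used as the default calendar by the synthetic generator
#' and by [derive_features()]. Real analyses should supply the actual
#' calendar of their center's country.
#'
#' @return Vector of `Date`s.
#' @export
example_holidays <- function() {
  as.Date(c(
    "2019-01-01", "2019-02-05", "2019-02-06", "2019-02-28", "2019-04-04",
    "2019-04-05", "2019-05-01", "2019-06-07", "2019-08-30", "2019-09-13",
    "2019-10-10", "2019-11-12", "2019-12-25", "2019-12-31"
  ))
}

#' Split rescheduled bookings into separate booking records
#'
#' A rescheduling request is treated as a cancellation plus a new booking:
#' a booking with N reschedule events becomes N + 1 records, where record
#' k's cancellation date and record k + 1's booking date are both the k-th
#' reschedule request date. The final record keeps the original cancellation
#' status (if any).
#'
#' @param bookings data frame with at least `id`, `booking_date`,
#'   `examination_date`, `cancellation_date` (Date, NA if none); other
#'   columns are carried along.
#' @param reschedules data frame with `id`, `request_date`,
#'   `new_examination_date` (Dates); events for one booking must be in time
#'   order. May be empty or `NULL`.
#' @return Data frame of split records with the same columns as `bookings`.
#' @export
#' @examples
#' b <- data.frame(id = 1, booking_date = as.Date("2019-02-03"),
#'                 examination_date = as.Date("2019-08-05"),
#'                 cancellation_date = as.Date(NA))
#' r <- data.frame(id = 1,
#'                 request_date = as.Date(c("2019-04-07", "2019-06-02")),
#'                 new_examination_date = as.Date(c("2019-09-03",
#'                                                  "2019-10-15")))
#' split_reschedules(b, r)
split_reschedules <- function(bookings, reschedules = NULL) {
  stopifnot(is.data.frame(bookings),
            all(c("id", "booking_date", "examination_date",
                  "cancellation_date") %in% names(bookings)))
  if (is.null(reschedules) || nrow(reschedules) == 0) return(bookings)
  stopifnot(all(c("id", "request_date", "new_examination_date") %in%
                  names(reschedules)))
  out <- vector("list", nrow(bookings))
  for (i in seq_len(nrow(bookings))) {
    rec <- bookings[i, , drop = FALSE]
    ev <- reschedules[reschedules$id == rec$id, , drop = FALSE]
    if (nrow(ev) == 0) {
      out[[i]] <- rec
      next
    }
    ev <- ev[order(ev$request_date), , drop = FALSE]
    pieces <- rec[rep(1L, nrow(ev) + 1L), , drop = FALSE]
    cur_exam <- rec$examination_date
    for (k in seq_len(nrow(ev))) {
      if (ev$request_date[k] > cur_exam)
        stop("booking ", rec$id, ": reschedule requested after the ",
             "then-current examination date")
      pieces$examination_date[k] <- cur_exam
      pieces$cancellation_date[k] <- ev$request_date[k]
      pieces$booking_date[k + 1L] <- ev$request_date[k]
      cur_exam <- ev$new_examination_date[k]
    }
    last <- nrow(ev) + 1L
    pieces$examination_date[last] <- cur_exam
    pieces$cancellation_date[last] <- rec$cancellation_date
    out[[i]] <- pieces
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Impute a missing booking date as the calendar midpoint
#'
#' When the request date of a reschedule is missing, the new record's
#' booking date is imputed as the midpoint between the original booking
#' date and the new examination date, rounded down to a whole day.
#'
#' @param original_booking_date,new_examination_date `Date`s (vectorized);
#'   the former must not be after the latter.
#' @return `Date` midpoint(s).
#' @export
#' @examples
#' impute_missing_booking_date(as.Date("2019-02-03"), as.Date("2019-09-03"))
impute_missing_booking_date <- function(original_booking_date,
                                        new_examination_date) {
  a <- as.Date(original_booking_date)
  b <- as.Date(new_examination_date)
  if (any(a > b)) stop("original booking date after new examination date")
  a + floor(as.numeric(b - a) / 2)
}

#' Derive the analysis variables of a booking record
#'
#' Computes, per record: appointment lead time (whole days between booking
#' and examination), the last-minute flag (lead time <= 7), the
#' group-booking flag (group size >= 2), the holiday-examination flag, the
#' examination season, the age-interval flag (age in \[45, 70\]) and the
#' late-cancellation label (a cancellation recorded within 7 days of the
#' examination date; no-shows, pre-flagged as `no_show = 1`, count as late
#' cancellations too). Re-deriving is idempotent.
#'
#' @param records data frame with columns `age`, `gender`, `booking_date`,
#'   `examination_date`, `set_id`, `price`, `group_size`,
#'   `cancellation_date` (NA when absent); optional `no_show` flag.
#' @param holidays vector of `Date`s ([example_holidays()] by default).
#' @param season_map month-to-season map from [default_season_map()].
#' @return The input with derived columns `lead_time`, `last_minute`,
#'   `group_booking`, `holiday_examination`, `season` (factor), and
#'   `late_cancellation` appended/overwritten, plus `age_interval`.
#' @export
derive_features <- function(records, holidays = example_holidays(),
                            season_map = default_season_map()) {
  mandatory <- c("age", "booking_date", "examination_date", "set_id",
                 "group_size", "cancellation_date")
  missing_cols <- setdiff(mandatory, names(records))
  if (length(missing_cols))
    stop("missing mandatory field(s): ", paste(missing_cols, collapse = ", "))
  bd <- as.Date(records$booking_date)
  ed <- as.Date(records$examination_date)
  cd <- as.Date(records$cancellation_date)
  if (any(bd > ed, na.rm = TRUE))
    stop("booking date after examination date")
  if (any(cd < bd, na.rm = TRUE))
    stop("cancellation date before booking date")

  records$lead_time <- as.integer(ed - bd)
  records$last_minute <- as.integer(records$lead_time <= 7)
  records$group_booking <- as.integer(records$group_size >= 2)
  records$holiday_examination <- as.integer(ed %in% holidays)
  month <- as.integer(format(ed, "%m"))
  records$season <- factor(season_map[month], levels = season_levels)
  records$age_interval <- as.integer(records$age >= 45 & records$age <= 70)
  late <- !is.na(cd) & as.numeric(ed - cd) <= 7
  if (!is.null(records$no_show)) late <- late | records$no_show == 1
  records$late_cancellation <- as.integer(late)
  records
}
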