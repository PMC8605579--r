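# Per-cluster booking counts and late-cancellation counts of the motivating
# case study (season x group booking x age interval), used as the default
# synthetic population and as the frozen cluster estimate of the default
# case-study configuration.
case_study_clusters <- function() {
  data.frame(
    season = factor(rep(c("winter", "summer", "off_peak"), each = 4),
                    levels = season_levels),
    group_booking = rep(c(1, 1, 0, 0), 3),
    age_interval = rep(c(1, 0, 1, 0), 3),
    bookings = c(583, 247, 842, 433,
                 236, 111, 578, 311,
                 835, 420, 2319, 1131),
    late_cancellations = c(20, 15, 31, 22,
                           10, 4, 19, 16,
                           32, 19, 42, 39)
  )
}

#' Synthetic booking-population specification
#'
#' Defines the statistical structure the generator emulates: the
#' 12-cluster composition (season x group booking x age interval) with its
#' per-cluster late-cancellation rates, low-frequency holiday and
#' last-minute flags with their logit-scale effects, the aggregate-set
#' booking mix, and set prices. Defaults reproduce the case-study
#' structure; prices are synthetic placeholders inside the reported
#' 20,000-100,000 NTD range (per-set prices were never published).
#'
#' @param cluster_sizes 12 positive counts, ordered as in
#'   `case_study_clusters()` (winter/summer/off-peak x group yes/no x age
#'   in/out).
#' @param cluster_rates 12 baseline late-cancellation probabilities.
#' @param holiday_rate probability an examination falls on a national
#'   holiday.
#' @param holiday_effect logit-scale additive effect of a holiday
#'   examination on late cancellation.
#' @param last_minute_rate probability a booking is made within 7 days of
#'   the examination.
#' @param last_minute_effect logit-scale effect of a last-minute booking.
#' @param gender_split probability of `female` (gender is generated as
#'   pure noise: it carries no effect).
#' @param set_mix per-set booking shares (must sum to 1).
#' @param prices per-set prices, NTD.
#' @param year calendar year for examination dates.
#' @param seed integer RNG seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(cluster_sizes = case_study_clusters()$bookings,
                           cluster_rates =
                             case_study_clusters()$late_cancellations /
                             case_study_clusters()$bookings,
                           holiday_rate = 0.01,
                           holiday_effect = 0.5702,
                           last_minute_rate = 47 / 8046,
                           last_minute_effect = 2.0522,
                           gender_split = 0.5,
                           set_mix = c(3068, 3514, 648, 816) / 8046,
                           prices = c(25000, 28000, 60000, 85000),
                           year = 2019,
                           seed = 1) {
  stopifnot(length(cluster_sizes) == 12, all(cluster_sizes > 0),
            length(cluster_rates) == 12,
            all(cluster_rates >= 0), all(cluster_rates <= 1),
            holiday_rate >= 0, holiday_rate <= 1,
            last_minute_rate >= 0, last_minute_rate <= 1,
            length(set_mix) == length(prices), all(set_mix >= 0))
  if (abs(sum(set_mix) - 1) > 1e-8) stop("set mix must sum to 1")
  structure(as.list(environment()), class = "synthetic_spec")
}

# months per season, aligned with default_season_map()
season_months <- list(winter = c(11, 12, 1), summer = c(8, 9),
                      off_peak = c(2, 3, 4, 5, 6, 7, 10))

#' Generate synthetic booking records
#'
#' Emits raw booking records (the fields a center's booking system would
#' export) whose derived features place each record in its intended
#' cluster: ages sampled inside/outside \[45, 70\], examination months
#' inside the cluster's season, group sizes 1 versus 2-4. Late-cancellation
#' labels are Bernoulli draws at the cluster rate shifted on the logit
#' scale by the holiday and last-minute flags; late-cancelled records get a
#' cancellation date within 7 days of the examination, and a small fraction
#' of the rest get an early (harmless) cancellation. Reproducible per
#' seed.
#'
#' @param spec a [synthetic_spec()].
#' @param holidays holiday calendar used to place holiday examinations.
#' @return Data frame of raw booking records (`id`, `age`, `gender`,
#'   `booking_date`, `booking_type`, `examination_date`, `set_id`, `price`,
#'   `group_size`, `cancellation_date`, `no_show`); pass through
#'   [derive_features()] for analysis variables.
#' @export
generate_bookings <- function(spec = synthetic_spec(),
                              holidays = example_holidays()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  cl <- case_study_clusters()
  cl$bookings <- spec$cluster_sizes
  n <- sum(cl$bookings)
  idx <- rep(seq_len(12), cl$bookings)

  season <- as.character(cl$season)[idx]
  group <- cl$group_booking[idx]
  age_in <- cl$age_interval[idx]

  age <- ifelse(age_in == 1, sample(45:70, n, replace = TRUE),
                sample(c(20:44, 71:85), n, replace = TRUE))
  group_size <- ifelse(group == 1, sample(2:4, n, replace = TRUE), 1L)
  gender <- sample(c("female", "male"), n, replace = TRUE,
                   prob = c(spec$gender_split, 1 - spec$gender_split))
  set_idx <- sample.int(length(spec$set_mix), n, replace = TRUE,
                        prob = spec$set_mix)

  # examination dates: within the cluster's season months; a slice lands on
  # holidays (only holidays inside the season's months are eligible)
  hol_month <- as.integer(format(holidays, "%m"))
  exam <- as.Date(rep(NA, n))
  is_holiday <- stats::runif(n) < spec$holiday_rate
  for (s in names(season_months)) {
    in_s <- season == s
    months <- season_months[[s]]
    hols <- holidays[hol_month %in% months]
    days <- seq(as.Date(paste0(spec$year, "-01-01")),
                as.Date(paste0(spec$year, "-12-31")), by = "day")
    days <- days[as.integer(format(days, "%m")) %in% months]
    non_hol <- days[!days %in% holidays]
    take_hol <- in_s & is_holiday & length(hols) > 0
    if (any(take_hol))
      exam[take_hol] <- sample(hols, sum(take_hol), replace = TRUE)
    rest <- in_s & !take_hol
    exam[rest] <- sample(non_hol, sum(rest), replace = TRUE)
  }

  last_minute <- stats::runif(n) < spec$last_minute_rate
  lead <- ifelse(last_minute, sample(0:7, n, replace = TRUE),
                 sample(8:180, n, replace = TRUE))
  booking_date <- exam - lead

  base_rate <- spec$cluster_rates[idx]
  logit <- stats::qlogis(pmin(pmax(base_rate, 1e-12), 1 - 1e-12)) +
    spec$holiday_effect * (exam %in% holidays) +
    spec$last_minute_effect * last_minute
  p_late <- stats::plogis(logit)
  late <- stats::runif(n) < p_late

  cancellation_date <- as.Date(rep(NA, n))
  gap <- sample(0:7, n, replace = TRUE)
  cancellation_date[late] <- pmax(exam[late] - gap[late], booking_date[late])
  # some non-late bookings cancel early (resolved vacancies, label 0)
  early <- !late & lead > 15 & stats::runif(n) < 0.05
  egap <- sample(8:60, n, replace = TRUE)
  cancellation_date[early] <- pmax(exam[early] - egap[early],
                                   booking_date[early])

  data.frame(
    id = seq_len(n),
    age = age,
    gender = gender,
    booking_date = booking_date,
    booking_type = sample(c("in_person", "online", "other"), n,
                          replace = TRUE, prob = c(0.3, 0.6, 0.1)),
    examination_date = exam,
    set_id = paste0("set", set_idx),
    price = spec$prices[set_idx],
    group_size = group_size,
    cancellation_date = cancellation_date,
    no_show = 0L
  )
}

#' Default case-study center configuration
#'
#' The aggregate four-set, five-resource configuration of the motivating
#' case study: ideal consumer levels K = (36, 36, 24, 4, 2) for basic
#' check, breast check, gastroenteroscope, MRI and DWI, maximum allowable
#' overage U = K/2 (i.e. 18, 18, 12, 2, 1), the set-resource matrix
#' implied by the published capacity constraints, the elicited marginal
#' overage-cost schedule with its fitted quadratic extrapolation, and the
#' published per-cluster late-cancellation counts as a frozen cluster
#' model. Set prices and original limits are synthetic placeholders
#' (unpublished).
#'
#' @return List with `config` ([center_config()]), `schedule`
#'   ([cost_schedule()]), `cluster_model` ([cluster_model()]) and
#'   `uniform_rate` ([uniform_rate()]-like, 269/8046).
#' @export
#' @examples
#' cs <- default_case_study_config()
#' search_space(cs$config)$rhs  # 54 54 36 6 3
default_case_study_config <- function() {
  sets <- data.frame(
    name = c("set1_basic_colono", "set2_basic_breast_colono",
             "set3_exquisite_mri", "set4_elite_mri_dwi"),
    price = c(25000, 28000, 60000, 85000),
    original_limit = c(2, 22, 3, 3)
  )
  resources <- data.frame(
    name = c("basic", "breast", "gastroenteroscope", "mri", "dwi"),
    ideal_level = c(36, 36, 24, 4, 2),
    max_overage = c(18, 18, 12, 2, 1)
  )
  requirements <- list(
    set1_basic_colono = c("basic", "gastroenteroscope"),
    set2_basic_breast_colono = c("basic", "breast", "gastroenteroscope"),
    set3_exquisite_mri = c("basic", "mri"),
    set4_elite_mri_dwi = c("basic", "mri", "dwi")
  )
  config <- center_config(sets, resources, requirements)
  schedule <- cost_schedule()
  counts <- case_study_clusters()
  fallback <- structure(
    list(q1 = sum(counts$late_cancellations),
         q2 = sum(counts$bookings),
         rate = sum(counts$late_cancellations) / sum(counts$bookings)),
    class = "uniform_rate")
  cm <- cluster_model(counts, fallback,
                      levels = list(season = season_levels,
                                    group_booking = c("1", "0"),
                                    age_interval = c("1", "0")))
  list(config = config, schedule = schedule, cluster_model = cm,
       uniform_rate = fallback)
}
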