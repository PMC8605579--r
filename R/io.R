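booking_schema <- c("id", "age", "gender", "booking_date", "booking_type",
                    "examination_date", "set_id", "price", "group_size",
                    "cancellation_date")

#' Read booking records from CSV
#'
#' Dates must be ISO-8601 (`YYYY-MM-DD`); the cancellation date may be
#' empty or `NA`. Rows with unparseable dates are dropped and reported.
#'
#' @param path CSV file with at least the columns `id`, `age`, `gender`,
#'   `booking_date`, `booking_type`, `examination_date`, `set_id`,
#'   `price`, `group_size`, `cancellation_date`.
#' @return Data frame of typed booking records; dropped row numbers are in
#'   `attr(, "dropped_rows")`.
#' @export
read_bookings <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(booking_schema, names(raw))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  parse_date <- function(x) as.Date(x, format = "%Y-%m-%d")
  bd <- parse_date(raw$booking_date)
  ed <- parse_date(raw$examination_date)
  cd_raw <- trimws(raw$cancellation_date)
  has_cd <- !(cd_raw %in% c("", "NA", "N/A", NA))
  cd <- as.Date(rep(NA, nrow(raw)))
  cd[has_cd] <- parse_date(cd_raw[has_cd])
  bad <- is.na(bd) | is.na(ed) | (has_cd & is.na(cd))
  if (any(bad))
    message(sum(bad), " row(s) dropped for unparseable dates: rows ",
            paste(utils::head(which(bad), 10), collapse = ", "))
  out <- data.frame(
    id = raw$id, age = as.numeric(raw$age), gender = raw$gender,
    booking_date = bd, booking_type = raw$booking_type,
    examination_date = ed, set_id = raw$set_id,
    price = as.numeric(raw$price), group_size = as.integer(raw$group_size),
    cancellation_date = cd
  )
  if ("no_show" %in% names(raw)) out$no_show <- as.integer(raw$no_show)
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_rows") <- which(bad)
  out
}

#' Write booking records to CSV
#'
#' @param records booking-record data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bookings <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Load a center configuration file
#'
#' Reads a YAML (or JSON) center configuration: set list (name, price,
#' original_limit), resource list (name, ideal_level, and either
#' max_overage or overage_fraction), per-set resource requirements, and
#' the marginal overage-cost schedule. All structural invariants (binary
#' V with no empty set column, positive prices, nondecreasing marginal
#' costs) are validated at load. An optional
#' `extrapolation_coefficients: [a, b]` key overrides the fitted curve for
#' reproducibility.
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return List with `config` ([center_config()]) and `schedule`
#'   ([cost_schedule()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (k in c("sets", "resources", "requirements", "cost_schedule")) {
    if (is.null(spec[[k]])) stop("config is missing the '", k, "' key")
  }
  sets <- do.call(rbind, lapply(spec$sets, function(s)
    data.frame(name = s$name, price = s$price,
               original_limit = s$original_limit)))
  resources <- do.call(rbind, lapply(spec$resources, function(r) {
    U <- if (!is.null(r$max_overage)) r$max_overage
         else if (!is.null(r$overage_fraction))
           floor(r$overage_fraction * r$ideal_level)
         else stop("resource '", r$name,
                   "' needs max_overage or overage_fraction")
    data.frame(name = r$name, ideal_level = r$ideal_level, max_overage = U)
  }))
  config <- center_config(sets, resources,
                          lapply(spec$requirements, unlist))
  schedule <- cost_schedule(
    marginal = unlist(spec$cost_schedule$marginal),
    coefficients = spec$cost_schedule$extrapolation_coefficients
  )
  list(config = config, schedule = schedule)
}

#' Save a center configuration to YAML
#'
#' @param config a [center_config()].
#' @param schedule a [cost_schedule()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, schedule, path) {
  reqs <- lapply(seq_len(n_sets(config)), function(j)
    rownames(config$V)[config$V[, j] == 1L])
  names(reqs) <- colnames(config$V)
  spec <- list(
    sets = lapply(seq_len(nrow(config$sets)), function(i)
      as.list(config$sets[i, ])),
    resources = lapply(seq_len(nrow(config$resources)), function(i)
      as.list(config$resources[i, ])),
    requirements = reqs,
    cost_schedule = list(marginal = schedule$marginal)
  )
  yaml::write_yaml(spec, path)
  invisible(path)
}

#' Serialize / restore a cluster model
#'
#' Cluster models are written as JSON (factor definitions plus the count
#' table) so an optimization run can reuse a frozen estimate.
#'
#' @param model a [cluster_model()].
#' @param path JSON file.
#' @return `path` / the restored `cluster_model`.
#' @export
write_cluster_model <- function(model, path) {
  stopifnot(inherits(model, "cluster_model"))
  cl <- model$clusters
  if (!is.null(cl)) {
    cl <- cl[, setdiff(names(cl), "rate"), drop = FALSE]
    for (f in model$factors) cl[[f]] <- as.character(cl[[f]])
  }
  jsonlite::write_json(
    list(factors = model$factors, levels = model$levels, clusters = cl,
         fallback = list(q1 = model$fallback$q1, q2 = model$fallback$q2)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_cluster_model
#' @export
read_cluster_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fb <- structure(list(q1 = x$fallback$q1, q2 = x$fallback$q2,
                       rate = x$fallback$q1 / x$fallback$q2),
                  class = "uniform_rate")
  counts <- if (is.null(x$clusters) || !length(x$clusters)) NULL
            else as.data.frame(x$clusters)
  cluster_model(counts, fb, levels = x$levels)
}

#' Run manifest
#'
#' Every CLI results file is accompanied by a manifest recording the
#' command, configuration paths, seed, package version and timestamp —
#' enough to reproduce the output exactly.
#'
#' @param command CLI verb or calling function.
#' @param inputs named list/vector of input paths and parameters.
#' @param seed integer seed used.
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(command, inputs = list(), seed = NA_integer_) {
  structure(
    list(command = command, inputs = inputs, seed = seed,
         package = "overbookr",
         version = as.character(utils::packageVersion("overbookr")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest"
  )
}

write_manifest <- function(manifest, results_path) {
  jsonlite::write_json(unclass(manifest),
                       paste0(results_path, ".manifest.json"),
                       auto_unbox = TRUE, null = "null")
}
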