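#' Build a center configuration
#'
#' A center configuration describes the examination sets a physical
#' examination center sells, the capacity-limited resources those sets
#' consume, and the binary set-resource matrix linking them. Booking limits
#' are chosen per set, but overage (consumers beyond the ideal level) is
#' incurred per resource, so the two sides are tied together only through
#' this matrix.
#'
#' @param sets data frame with columns `name` (unique), `price` (> 0, NTD)
#'   and `original_limit` (nonnegative integer, the center's pre-optimization
#'   booking limit for the set).
#' @param resources data frame with columns `name` (unique),
#'   `ideal_level` (nonnegative integer; the maximum consumers the resource
#'   serves in regular time) and `max_overage` (nonnegative integer; the
#'   largest overage the center will ever tolerate on the resource).
#' @param requirements either a binary matrix with one row per resource and
#'   one column per set, or a named list mapping each set name to the
#'   character vector of resource names it requires.
#'
#' @return An object of class `center_config`.
#' @export
#' @examples
#' cfg <- center_config(
#'   sets = data.frame(name = c("a", "b"), price = c(100, 200),
#'                     original_limit = c(2, 2)),
#'   resources = data.frame(name = "scope", ideal_level = 3, max_overage = 1),
#'   requirements = list(a = "scope", b = "scope")
#' )
#' cfg
center_config <- function(sets, resources, requirements) {
  stopifnot(is.data.frame(sets), is.data.frame(resources))
  need_s <- c("name", "price", "original_limit")
  need_r <- c("name", "ideal_level", "max_overage")
  if (!all(need_s %in% names(sets)))
    stop("`sets` must have columns: ", paste(need_s, collapse = ", "))
  if (!all(need_r %in% names(resources)))
    stop("`resources` must have columns: ", paste(need_r, collapse = ", "))
  if (anyDuplicated(sets$name)) stop("duplicated set names")
  if (anyDuplicated(resources$name)) stop("duplicated resource names")
  if (any(sets$price <= 0)) stop("every set price must be positive")
  if (any(sets$original_limit < 0)) stop("original booking limits must be >= 0")
  if (any(resources$ideal_level < 0) || any(resources$max_overage < 0))
    stop("ideal consumer levels and maximum overages must be >= 0")

  n <- nrow(resources)
  m <- nrow(sets)
  if (is.list(requirements) && !is.matrix(requirements)) {
    V <- matrix(0L, n, m, dimnames = list(resources$name, sets$name))
    if (!setequal(names(requirements), sets$name))
      stop("`requirements` names must match set names")
    for (s in names(requirements)) {
      res <- requirements[[s]]
      bad <- setdiff(res, resources$name)
      if (length(bad))
        stop("unknown resource(s) for set '", s, "': ",
             paste(bad, collapse = ", "))
      V[res, s] <- 1L
    }
  } else {
    V <- requirements
    if (!is.matrix(V) || nrow(V) != n || ncol(V) != m)
      stop("requirement matrix must be ", n, " x ", m)
    if (!all(V %in% c(0, 1))) stop("requirement matrix entries must be 0 or 1")
    storage.mode(V) <- "integer"
    dimnames(V) <- list(resources$name, sets$name)
  }
  if (any(colSums(V) == 0))
    stop("set(s) using no resource: ",
         paste(sets$name[colSums(V) == 0], collapse = ", "),
         " (unbounded booking limit)")

  structure(
    list(sets = sets, resources = resources, V = V),
    class = "center_config"
  )
}

#' @export
print.center_config <- function(x, ...) {
  cat("<center_config> ", ncol(x$V), " sets, ", nrow(x$V), " resources\n",
      sep = "")
  cat("sets:\n")
  print(x$sets, row.names = FALSE)
  cat("resources:\n")
  print(x$resources, row.names = FALSE)
  cat("set-resource matrix:\n")
  print(x$V)
  invisible(x)
}

n_sets <- function(config) ncol(config$V)
n_resources <- function(config) nrow(config$V)

#' Per-resource overage levels for a realized show-up vector
#'
#' Given the number of consumers showing up (without late cancellation) for
#' each set, the load on resource i is the sum of show-ups over the sets that
#' use it; its overage level is the load above the ideal consumer level,
#' clamped at zero.
#'
#' @param shows integer vector of per-set show-up counts, length equal to the
#'   number of sets.
#' @param config a [center_config()].
#' @return Named integer vector of per-resource overage levels.
#' @export
#' @examples
#' cfg <- default_case_study_config()$config
#' overage_level(c(0, 29, 0, 0), cfg)
overage_level <- function(shows, config) {
  if (length(shows) != n_sets(config))
    stop("`shows` must have length ", n_sets(config))
  if (any(shows < 0)) stop("show-up counts must be >= 0")
  load <- as.vector(config$V %*% shows)
  pmax(load - config$resources$ideal_level, 0)
}

#' Feasible region of booking-limit combinations
#'
#' The search space contains every integer booking-limit vector N with
#' `V %*% N <= K + U` for all resources, i.e. combinations under which no
#' realized show-up pattern can push a resource beyond its maximum allowable
#' overage. Under the no-overbooking (NO) policy every `U_i` is forced to 0.
#'
#' @param config a [center_config()].
#' @param overbooking if `FALSE`, use `U_i = 0` for every resource (NO
#'   policy); otherwise use the configured maximum overages.
#' @return An object of class `search_space` with the set-resource matrix and
#'   the per-resource right-hand sides `K + U`.
#' @export
#' @examples
#' sp <- search_space(default_case_study_config()$config)
#' sp$rhs
search_space <- function(config, overbooking = TRUE) {
  U <- if (overbooking) config$resources$max_overage else 0L
  rhs <- config$resources$ideal_level + U
  structure(
    list(V = config$V, rhs = stats::setNames(rhs, config$resources$name),
         overbooking = overbooking),
    class = "search_space"
  )
}

#' @export
print.search_space <- function(x, ...) {
  cat("<search_space> ", ncol(x$V), " sets; per-resource capacity K + U:\n",
      sep = "")
  print(x$rhs)
  invisible(x)
}

#' Is a booking-limit combination feasible?
#'
#' @param N integer vector of per-set booking limits.
#' @param space a [search_space()].
#' @return `TRUE` iff `V %*% N <= K + U` holds for every resource.
#' @export
is_feasible <- function(N, space) {
  if (length(N) != ncol(space$V))
    stop("`N` must have length ", ncol(space$V))
  if (any(N < 0) || any(N != round(N))) return(FALSE)
  all(as.vector(space$V %*% N) <= space$rhs)
}

#' Enumerate all feasible booking-limit combinations
#'
#' Lists the full (finite) feasible region in ascending lexicographic order
#' (the last set's limit varies fastest). Residual capacities prune the
#' recursion, so only feasible prefixes are visited.
#'
#' @param space a [search_space()].
#' @return Integer matrix with one row per feasible combination and one
#'   column per set.
#' @export
#' @examples
#' cfg <- center_config(
#'   sets = data.frame(name = c("a", "b"), price = c(1, 1),
#'                     original_limit = c(0, 0)),
#'   resources = data.frame(name = "r", ideal_level = 2, max_overage = 0),
#'   requirements = list(a = "r", b = "r")
#' )
#' enumerate_search_space(search_space(cfg))
enumerate_search_space <- function(space) {
  V <- space$V
  m <- ncol(V)
  if (any(colSums(V) == 0))
    stop("search space unbounded: a set uses no resource")
  out <- vector("list", 64L)
  n_out <- 0L
  N <- integer(m)
  recurse <- function(j, resid) {
    # max N_j allowed by every resource the set uses
    uses <- V[, j] == 1L
    cap <- min(resid[uses])
    for (v in 0:cap) {
      N[j] <<- v
      r2 <- resid - v * V[, j]
      if (j == m) {
        n_out <<- n_out + 1L
        out[[n_out]] <<- N
      } else {
        recurse(j + 1L, r2)
      }
    }
  }
  recurse(1L, space$rhs)
  mat <- matrix(unlist(out[seq_len(n_out)]), ncol = m, byrow = TRUE)
  colnames(mat) <- colnames(V)
  mat
}
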