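#' Uniform late-cancellation rate
#'
#' The naive estimator: if there are q1 late cancellations among q2
#' bookings, every booking gets rate r = q1 / q2 and the show-up count is
#' binomial with success probability 1 - r.
#'
#' @param records data frame with a `late_cancellation` 0/1 column (see
#'   [derive_features()]).
#' @return Object of class `uniform_rate`: list with `q1`, `q2`, `rate`.
#' @export
uniform_rate <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("cannot estimate a rate from zero bookings")
  if (is.null(records$late_cancellation))
    stop("records lack a `late_cancellation` column; run derive_features()")
  q1 <- sum(records$late_cancellation == 1)
  q2 <- nrow(records)
  structure(list(q1 = q1, q2 = q2, rate = q1 / q2), class = "uniform_rate")
}

#' @export
print.uniform_rate <- function(x, ...) {
  cat(sprintf("<uniform_rate> %d late cancellations / %d bookings = %.2f%%\n",
              x$q1, x$q2, 100 * x$rate))
  invisible(x)
}

wald_p <- function(fit) {
  s <- summary(fit)$coefficients
  stats::setNames(s[, "Pr(>|z|)"], rownames(s))
}

# p-value for a (possibly multi-level) model variable: the smallest Wald p
# among its non-reference levels. Returns NA if the variable is absent.
var_p_value <- function(fit, var, data) {
  p <- wald_p(fit)
  hits <- names(p)[startsWith(names(p), var)]
  hits <- setdiff(hits, "(Intercept)")
  if (!length(hits)) return(NA_real_)
  min(p[hits])
}

#' Staged logistic regression for late cancellation
#'
#' Mirrors a three-stage model-building protocol: stage-1 (literature) and
#' stage-2 (exploratory) variables are entered together and the
#' insignificant ones removed; the untested stage-3 variables are then
#' offered and kept only if significant; the final model is refitted on the
#' retained set. A categorical variable is retained when any of its
#' non-reference levels reaches Wald p < alpha. Variables in
#' `force_include` are kept regardless of significance (and flagged).
#'
#' @param records data frame of derived booking records; the response is
#'   the 0/1 `late_cancellation` column. Variables named in the stages must
#'   be columns.
#' @param stage1,stage2,stage3 character vectors of variable names.
#' @param alpha significance threshold in (0, 1\].
#' @param force_include variables exempt from removal.
#' @return Object of class `lc_model`: list with the final `fit` (a `glm`),
#'   `retained`, `dropped`, `forced`, `alpha`, and a `report` data frame of
#'   coefficients, standard errors, z and p values.
#' @export
fit_late_cancellation_model <- function(records,
                                        stage1 = c("age_interval", "gender",
                                                   "season", "set_id"),
                                        stage2 = c("group_booking",
                                                   "last_minute",
                                                   "holiday_examination"),
                                        stage3 = character(0),
                                        alpha = 0.05,
                                        force_include = character(0)) {
  stopifnot(alpha > 0, alpha <= 1)
  vars <- unique(c(stage1, stage2, stage3))
  missing_cols <- setdiff(c("late_cancellation", vars), names(records))
  if (length(missing_cols))
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "))

  dat <- records
  for (v in vars) {
    if (!is.numeric(dat[[v]])) {
      f <- factor(dat[[v]])
      # most frequent level as reference, so coefficients read as risk
      # shifts of the minority conditions
      dat[[v]] <- stats::relevel(f, ref = names(which.max(table(f))))
    }
  }

  fit_on <- function(vs) {
    if (!length(vs)) vs <- "1"
    f <- stats::as.formula(paste("late_cancellation ~",
                                 paste(vs, collapse = " + ")))
    fit <- withCallingHandlers(
      stats::glm(f, family = stats::binomial(), data = dat),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          stop("possible perfect separation among: ",
               paste(vs, collapse = ", "), call. = FALSE)
        invokeRestart("muffleWarning")
      })
    if (!fit$converged)
      stop("logistic regression failed to converge for: ",
           paste(vs, collapse = ", "))
    fit
  }

  # stages 1 + 2 together, then prune
  fit12 <- fit_on(unique(c(stage1, stage2)))
  p12 <- vapply(unique(c(stage1, stage2)),
                function(v) var_p_value(fit12, v, dat), numeric(1))
  keep <- names(p12)[!is.na(p12) & p12 < alpha]
  keep <- union(keep, intersect(force_include, names(p12)))

  # stage 3 offered on top of the survivors
  kept3 <- character(0)
  if (length(stage3)) {
    fit3 <- fit_on(unique(c(keep, stage3)))
    p3 <- vapply(stage3, function(v) var_p_value(fit3, v, dat), numeric(1))
    kept3 <- names(p3)[!is.na(p3) & p3 < alpha]
    kept3 <- union(kept3, intersect(force_include, stage3))
  }
  retained <- unique(c(keep, kept3))
  final <- fit_on(retained)

  s <- summary(final)$coefficients
  report <- data.frame(
    term = rownames(s), coefficient = s[, "Estimate"],
    std_error = s[, "Std. Error"], z = s[, "z value"],
    p_value = s[, "Pr(>|z|)"], row.names = NULL
  )
  structure(
    list(fit = final, retained = retained,
         dropped = setdiff(vars, retained),
         forced = intersect(force_include, retained),
         alpha = alpha, report = report),
    class = "lc_model"
  )
}

#' @export
print.lc_model <- function(x, ...) {
  cat("<lc_model> retained:", paste(x$retained, collapse = ", "), "\n")
  if (length(x$dropped))
    cat("dropped:", paste(x$dropped, collapse = ", "), "\n")
  if (length(x$forced))
    cat("force-included:", paste(x$forced, collapse = ", "), "\n")
  print(transform(x$report,
                  coefficient = round(coefficient, 4),
                  std_error = round(std_error, 4),
                  z = round(z, 3), p_value = round(p_value, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Build a cluster model of late-cancellation rates
#'
#' Crosses the retained categorical factors into clusters and estimates
#' each cluster's late-cancellation rate as its empirical proportion.
#' Factors whose minority level has fewer than `min_count` records are
#' excluded first (rare flags such as holiday examinations or last-minute
#' bookings make per-cluster rates too noisy). If no factor survives, the
#' model degenerates to the uniform rate with a warning.
#'
#' @param records derived booking records.
#' @param factors character vector of candidate clustering factors.
#' @param min_count minimum minority-level size for a factor to be used.
#' @return Object of class `cluster_model`; see [cluster_model()].
#' @export
build_clusters <- function(records,
                           factors = c("season", "group_booking",
                                       "age_interval"),
                           min_count = 100) {
  stopifnot(min_count >= 1)
  missing_cols <- setdiff(c("late_cancellation", factors), names(records))
  if (length(missing_cols))
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "))
  fallback <- uniform_rate(records)

  used <- character(0)
  for (f in factors) {
    counts <- table(records[[f]])
    if (length(counts) < 2) next
    if (min(counts) >= min_count) used <- c(used, f)
  }
  if (!length(used)) {
    warning("no clustering factor survives the min_count rule; ",
            "degenerating to the uniform rate")
    return(cluster_model(counts = NULL, fallback = fallback))
  }

  fl <- lapply(used, function(f) {
    x <- records[[f]]
    if (is.factor(x)) factor(x) else factor(x)
  })
  names(fl) <- used
  levs <- lapply(fl, levels)
  grid <- expand.grid(rev(levs), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)[, rev(seq_along(levs)),
                                                drop = FALSE]
  names(grid) <- used
  key_rec <- do.call(paste, c(lapply(fl, as.character), sep = "\r"))
  key_grid <- do.call(paste, c(lapply(grid, as.character), sep = "\r"))
  bookings <- as.vector(table(factor(key_rec, levels = key_grid)))
  lates <- vapply(key_grid,
                  function(k) sum(records$late_cancellation[key_rec == k]),
                  numeric(1))
  counts <- cbind(grid,
                  bookings = bookings,
                  late_cancellations = as.numeric(lates))
  cluster_model(counts = counts, fallback = fallback, levels = levs)
}

#' Construct a cluster model from tabulated counts
#'
#' Builds the same object as [build_clusters()] directly from a per-cluster
#' count table, e.g. a frozen published table, so an optimization run can
#' reuse an estimate without the raw records.
#'
#' @param counts data frame with one row per cluster: the factor columns,
#'   plus `bookings` and `late_cancellations`; or `NULL` for a degenerate
#'   (uniform-rate-only) model.
#' @param fallback a [uniform_rate()] used for empty clusters.
#' @param levels optional named list of factor levels (defaults to the
#'   values seen in `counts`, in order of appearance).
#' @return Object of class `cluster_model` with elements `clusters` (the
#'   count table with a `rate` column), `factors`, `levels`, `fallback`.
#' @export
cluster_model <- function(counts, fallback, levels = NULL) {
  stopifnot(inherits(fallback, "uniform_rate"))
  if (is.null(counts)) {
    return(structure(list(clusters = NULL, factors = character(0),
                          levels = list(), fallback = fallback),
                     class = "cluster_model"))
  }
  factors <- setdiff(names(counts), c("bookings", "late_cancellations"))
  stopifnot(length(factors) >= 1,
            all(counts$late_cancellations <= counts$bookings))
  if (is.null(levels))
    levels <- lapply(counts[factors], function(x) unique(as.character(x)))
  counts$rate <- ifelse(counts$bookings > 0,
                        counts$late_cancellations / counts$bookings,
                        NA_real_)
  structure(list(clusters = counts, factors = factors, levels = levels,
                 fallback = fallback),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  if (is.null(x$clusters)) {
    cat("<cluster_model> degenerate (uniform rate only)\n")
  } else {
    cat("<cluster_model> ", nrow(x$clusters), " clusters over ",
        paste(x$factors, collapse = " x "), "\n", sep = "")
    tab <- x$clusters
    tab$rate <- sprintf("%.2f%%", 100 * tab$rate)
    print(tab, row.names = FALSE)
  }
  print(x$fallback)
  invisible(x)
}

#' Estimate a booking's late-cancellation probability
#'
#' Looks up the cluster a booking belongs to and returns that cluster's
#' empirical late-cancellation rate; empty clusters fall back to the
#' uniform rate.
#'
#' @param model a `cluster_model`.
#' @param newdata data frame with one row per booking carrying all
#'   clustering factor columns (e.g. `season`, `group_booking`,
#'   `age_interval`).
#' @return Numeric vector of probabilities, one per row.
#' @export
#' @examples
#' cs <- default_case_study_config()
#' estimate_probability(cs$cluster_model,
#'                      data.frame(season = "summer", group_booking = 0,
#'                                 age_interval = 0))
estimate_probability <- function(model, newdata) {
  stopifnot(inherits(model, "cluster_model"), is.data.frame(newdata))
  if (is.null(model$clusters))
    return(rep(model$fallback$rate, nrow(newdata)))
  missing_cols <- setdiff(model$factors, names(newdata))
  if (length(missing_cols))
    stop("newdata lacks factor(s): ", paste(missing_cols, collapse = ", "))
  for (f in model$factors) {
    vals <- as.character(newdata[[f]])
    bad <- setdiff(unique(vals), model$levels[[f]])
    if (length(bad))
      stop("unknown level(s) for ", f, ": ", paste(bad, collapse = ", "))
  }
  key_model <- do.call(paste,
                       c(lapply(model$clusters[model$factors], as.character),
                         sep = "\r"))
  key_new <- do.call(paste,
                     c(lapply(newdata[model$factors], as.character),
                       sep = "\r"))
  idx <- match(key_new, key_model)
  r <- model$clusters$rate[idx]
  r[is.na(r)] <- model$fallback$rate
  r
}

#' Compare candidate month groupings by model fit
#'
#' Refits the staged logistic model once per candidate season grouping and
#' reports residual deviance and AIC, lower being better. Which grouping
#' "best explains" late cancellation is center-specific; this utility makes
#' the comparison explicit rather than baking a grouping in.
#'
#' @param records raw booking records (features are re-derived per
#'   candidate).
#' @param groupings named list of season maps (each from
#'   [default_season_map()]).
#' @param ... passed to [fit_late_cancellation_model()].
#' @inheritParams derive_features
#' @return Data frame with one row per grouping: `grouping`, `deviance`,
#'   `aic`, ordered by deviance.
#' @export
compare_month_groupings <- function(records, groupings,
                                    holidays = example_holidays(), ...) {
  stopifnot(length(groupings) >= 1, !is.null(names(groupings)))
  rows <- lapply(names(groupings), function(g) {
    feat <- derive_features(records, holidays = holidays,
                            season_map = groupings[[g]])
    # explanatory power is compared on the full offered model (no pruning),
    # so every candidate is judged on the same variable set
    m <- fit_late_cancellation_model(feat, ..., alpha = 1)
    data.frame(grouping = g, deviance = stats::deviance(m$fit),
               aic = stats::AIC(m$fit))
  })
  out <- do.call(rbind, rows)
  out[order(out$deviance), , drop = FALSE]
}
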