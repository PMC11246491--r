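#' Jaccard similarity between two path collections
#'
#' Path identity is the entity-ID sequence only; dates and quantities are
#' excluded, so the same route used on different days is one path. The
#' unique index compares the *sets* of distinct paths,
#' \eqn{J(A,B) = |A \cap B| / |A \cup B|}; the weighted index accounts for
#' how often each path occurs,
#' \eqn{J_w(A,B) = \sum_i \min(a_i, b_i) / \sum_i \max(a_i, b_i)} with
#' \eqn{a_i, b_i} the multiplicities of path \eqn{i}. Two empty collections
#' are identical, so both indices return 1 in that case.
#'
#' @param a,b Path tibbles (see [path_records()]).
#' @param weight For `jaccard_weighted()`: `"count"` (default — multiplicity
#'   is the number of records with that path) or `"quantity"` (records are
#'   weighted by their delivered units).
#' @return A number in \[0, 1\].
#' @examples
#' p1 <- path_records(list(c("M","D","F"), c("M","F")),
#'                    list(as.Date(c("2010-01-01","2010-01-05")), as.Date("2010-01-02")),
#'                    c(1L, 2L))
#' jaccard_unique(p1, p1)
#' @export
jaccard_unique <- function(a, b) {
  ka <- unique(path_keys(a))
  kb <- unique(path_keys(b))
  if (length(ka) == 0L && length(kb) == 0L) return(1)
  length(intersect(ka, kb)) / length(union(ka, kb))
}

#' @rdname jaccard_unique
#' @export
jaccard_weighted <- function(a, b, weight = c("count", "quantity")) {
  weight <- match.arg(weight)
  wa <- if (weight == "count") rep(1L, nrow(a)) else a$quantity
  wb <- if (weight == "count") rep(1L, nrow(b)) else b$quantity
  ta <- tapply(wa, path_keys(a), sum)
  tb <- tapply(wb, path_keys(b), sum)
  keys <- union(names(ta), names(tb))
  if (length(keys) == 0L) return(1)
  ai <- ifelse(keys %in% names(ta), ta[keys], 0)
  bi <- ifelse(keys %in% names(tb), tb[keys], 0)
  denom <- sum(pmax(ai, bi))
  if (denom == 0) return(1)
  sum(pmin(ai, bi)) / denom
}

#' Path-length histogram
#'
#' The length of a distribution path is its number of distribution steps,
#' i.e. the number of entities minus one (a manufacturer shipping straight
#' to a pharmacy is length 1).
#'
#' @param paths A path tibble.
#' @return A tibble with columns `length` and `count` (counts sum to the
#'   number of records), with attribute `"mean_length"` (`NA` for an empty
#'   collection).
#' @export
path_length_histogram <- function(paths) {
  len <- lengths(paths$path) - 1L
  if (length(len) == 0L) {
    out <- tibble::tibble(length = integer(0), count = integer(0))
    attr(out, "mean_length") <- NA_real_
    return(out)
  }
  tab <- table(len)
  out <- tibble::tibble(length = as.integer(names(tab)),
                        count = as.integer(tab))
  attr(out, "mean_length") <- mean(len)
  out
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere with the IUGG mean Earth radius
#' 6371.0088 km, fixed for reproducibility of distance numbers.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorized).
#' @return Distance(s) in km.
#' @examples
#' great_circle_km(0, 0, 0, 180)  # antipodal: half the circumference
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE) ||
      any(abs(c(lon1, lon2)) > 180, na.rm = TRUE)) {
    stop("coordinates out of range")
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371.0088)
}

#' Empirical complementary cumulative distribution function
#'
#' Returns the CCDF of a sample as a step function sampled at the distinct
#' observed values: `ccdf(x)` is the fraction of observations strictly
#' greater than `x`. Nonincreasing, in \[0, 1\].
#'
#' @param x Numeric sample.
#' @return A tibble with columns `value` and `ccdf`.
#' @export
empirical_ccdf <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(tibble::tibble(value = numeric(0), ccdf = numeric(0)))
  v <- sort(unique(x))
  tibble::tibble(value = v,
                 ccdf = vapply(v, function(t) mean(x > t), numeric(1L)))
}

#' Geographic travel statistics of distribution paths
#'
#' Computes, for each path, the total great-circle distance travelled along
#' its consecutive entity pairs; the mean distance at each distribution step
#' (step 1 is manufacturer to first distributor), averaged over the paths
#' that have at least that many steps; and the CCDF of total distance —
#' the probability that a package travels more than a given distance.
#' Paths visiting an entity absent from the coordinate table are skipped
#' and counted.
#'
#' @param paths A path tibble.
#' @param coords Entity coordinate table: columns `dea_number` (or
#'   `entity_id`), `lat`, `lon` in decimal degrees.
#' @return A list with `per_path` (tibble `path_id`, `total_km`),
#'   `step_means` (tibble `step`, `mean_km`, `n_paths`), `ccdf` (tibble
#'   `value`, `ccdf`), and `n_skipped`.
#' @export
path_distances <- function(paths, coords) {
  idcol <- if ("dea_number" %in% names(coords)) "dea_number" else "entity_id"
  lat <- stats::setNames(as.numeric(coords$lat), coords[[idcol]])
  lon <- stats::setNames(as.numeric(coords$lon), coords[[idcol]])
  n <- nrow(paths)
  known <- vapply(paths$path, function(p) all(p %in% names(lat)), logical(1L))
  n_skipped <- sum(!known)
  legs <- lapply(paths$path[known], function(p) {
    k <- length(p)
    if (k < 2L) return(numeric(0))
    great_circle_km(lat[p[-k]], lon[p[-k]], lat[p[-1L]], lon[p[-1L]])
  })
  totals <- vapply(legs, sum, numeric(1L))
  per_path <- tibble::tibble(path_id = which(known), total_km = totals)
  max_steps <- if (length(legs)) max(lengths(legs)) else 0L
  step_means <- tibble::tibble(
    step = seq_len(max_steps),
    mean_km = vapply(seq_len(max_steps), function(k) {
      v <- vapply(legs[lengths(legs) >= k], `[[`, numeric(1L), k)
      mean(v)
    }, numeric(1L)),
    n_paths = vapply(seq_len(max_steps), function(k) sum(lengths(legs) >= k),
                     integer(1L))
  )
  list(per_path = per_path, step_means = step_means,
       ccdf = empirical_ccdf(totals), n_skipped = n_skipped)
}

#' Days-in-transit distribution
#'
#' Days in transit of a path is its last shipping date minus its first —
#' the time a package spends between leaving its origin and reaching the
#' final distributor. Single-hop paths spend 0 days.
#'
#' @param paths A path tibble.
#' @return A list with `per_path` (tibble `path_id`, `days`), `pdf` (tibble
#'   `days`, `prob`), `ccdf` (tibble `value`, `ccdf`), and `summary`
#'   (one-row tibble with median, mean, quartiles).
#' @export
transit_time_distribution <- function(paths) {
  days <- vapply(paths$dates, function(d) {
    as.integer(max(d) - min(d))
  }, integer(1L))
  per_path <- tibble::tibble(path_id = seq_along(days), days = days)
  pdf <- if (length(days)) {
    tab <- table(days)
    tibble::tibble(days = as.integer(names(tab)),
                   prob = as.integer(tab) / sum(tab))
  } else tibble::tibble(days = integer(0), prob = numeric(0))
  smry <- tibble::tibble(
    n = length(days),
    mean = if (length(days)) mean(days) else NA_real_,
    median = if (length(days)) stats::median(days) else NA_real_,
    q1 = if (length(days)) unname(stats::quantile(days, 0.25)) else NA_real_,
    q3 = if (length(days)) unname(stats::quantile(days, 0.75)) else NA_real_,
    max = if (length(days)) max(days) else NA_real_
  )
  list(per_path = per_path, pdf = pdf, ccdf = empirical_ccdf(days),
       summary = smry)
}

#' Distributor entry and exit rates
#'
#' Year-over-year turnover of active entities: the entry rate in year
#' \eqn{t} is the fraction of year-\eqn{t} entrants relative to the
#' previous year's active set, \eqn{|A_t \setminus A_{t-1}| / |A_{t-1}|};
#' the exit rate is \eqn{|A_{t-1} \setminus A_t| / |A_{t-1}|}. The previous
#' year's active set is the denominator for both (the standard turnover
#' convention); alternative conventions can be compared by transforming the
#' input.
#'
#' @param activity Tidy activity table: columns `year` (integer) and
#'   `entity_id`, one row per (year, active entity); or a named list of
#'   entity-ID vectors keyed by year.
#' @return A tibble with columns `year`, `n_active`, `entry_rate`,
#'   `exit_rate` (rates `NA` for the first year). Years must be consecutive.
#' @export
entry_exit_rates <- function(activity) {
  if (is.list(activity) && !is.data.frame(activity)) {
    activity <- tibble::tibble(
      year = rep(as.integer(names(activity)), lengths(activity)),
      entity_id = unlist(activity, use.names = FALSE)
    )
  }
  years <- sort(unique(as.integer(activity$year)))
  if (length(years) < 2L) stop("need at least 2 years of activity")
  if (any(diff(years) != 1L)) stop("years must be consecutive (gap found)")
  sets <- lapply(years, function(y) unique(activity$entity_id[activity$year == y]))
  entry <- c(NA_real_, vapply(seq_along(years)[-1L], function(i) {
    length(setdiff(sets[[i]], sets[[i - 1L]])) / length(sets[[i - 1L]])
  }, numeric(1L)))
  exit <- c(NA_real_, vapply(seq_along(years)[-1L], function(i) {
    length(setdiff(sets[[i - 1L]], sets[[i]])) / length(sets[[i - 1L]])
  }, numeric(1L)))
  tibble::tibble(year = years, n_active = lengths(sets),
                 entry_rate = entry, exit_rate = exit)
}

#' Year-to-year path similarity
#'
#' Unique Jaccard similarity between the path sets of consecutive years —
#' the stability measure for the distribution system: abrupt shifts would
#' show as low similarity.
#'
#' @param paths_by_year Named list of path tibbles keyed by year, or a
#'   single path tibble with an extra `year` column.
#' @return A tibble with columns `year_from`, `year_to`, `jaccard`, with
#'   attribute `"summary"` holding box-plot statistics (min, q1, median,
#'   q3, max).
#' @export
year_to_year_similarity <- function(paths_by_year) {
  if (is.data.frame(paths_by_year)) {
    stopifnot("year" %in% names(paths_by_year))
    paths_by_year <- split(paths_by_year, paths_by_year$year)
  }
  years <- sort(as.integer(names(paths_by_year)))
  if (length(years) < 2L) stop("need at least 2 years of paths")
  sim <- vapply(seq_along(years)[-1L], function(i) {
    jaccard_unique(paths_by_year[[as.character(years[i - 1L])]],
                   paths_by_year[[as.character(years[i])]])
  }, numeric(1L))
  out <- tibble::tibble(year_from = years[-length(years)],
                        year_to = years[-1L],
                        jaccard = sim)
  fv <- stats::fivenum(sim)
  attr(out, "summary") <- tibble::tibble(
    min = fv[1L], q1 = fv[2L], median = fv[3L], q3 = fv[4L], max = fv[5L]
  )
  out
}

#' Per-year active-entity table from transactions
#'
#' Convenience: derives the tidy `(year, entity_id)` activity table used by
#' [entry_exit_rates()] from a transaction stream (an entity is active in a
#' year when it appears as sender or receiver of any transaction that
#' year).
#'
#' @param transactions Transaction tibble.
#' @param ids Optional subset of entity IDs to restrict to (e.g. mid-chain
#'   distributors only).
#' @return Tidy tibble with columns `year`, `entity_id`.
#' @export
yearly_activity <- function(transactions, ids = NULL) {
  yr <- as.integer(format(transactions$date, "%Y"))
  act <- tibble::tibble(
    year = rep(yr, 2L),
    entity_id = c(transactions$sender_id, transactions$receiver_id)
  )
  act <- dplyr::distinct(act)
  if (!is.null(ids)) act <- act[act$entity_id %in% ids, , drop = FALSE]
  act
}
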