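#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a path reconstruction into one row per completed path
#'
#' @param x A `path_reconstruction` object.
#' @param ... Unused.
#' @return A tibble with one row per completed path: `path_id`, `origin`,
#'   `destination`, `length` (distribution steps), `quantity`,
#'   `first_date`, `last_date`, `days_in_transit`, `exogenous_origin`,
#'   `product_code`.
#' @export
tidy.path_reconstruction <- function(x, ...) {
  p <- x$paths
  n <- nrow(p)
  tibble::tibble(
    path_id = seq_len(n),
    origin = vapply(p$path, `[`, character(1L), 1L),
    destination = vapply(p$path, function(v) v[length(v)], character(1L)),
    length = lengths(p$path) - 1L,
    quantity = p$quantity,
    first_date = if (n) as.Date(vapply(p$dates, function(d) as.character(min(d)),
                                       character(1L))) else as.Date(character(0)),
    last_date = if (n) as.Date(vapply(p$dates, function(d) as.character(max(d)),
                                      character(1L))) else as.Date(character(0)),
    days_in_transit = vapply(p$dates, function(d) as.integer(max(d) - min(d)),
                             integer(1L)),
    exogenous_origin = p$exogenous_origin,
    product_code = p$product_code
  )
}

#' One-row summary of a path reconstruction
#'
#' @param x A `path_reconstruction` object.
#' @param ... Unused.
#' @return A one-row tibble: path counts, delivered units, mean path
#'   length, exogenous counts, residual units and processing diagnostics.
#' @export
glance.path_reconstruction <- function(x, ...) {
  d <- x$diagnostics
  lens <- lengths(x$paths$path) - 1L
  tibble::tibble(
    policy = x$policy,
    n_paths = nrow(x$paths),
    units_delivered = sum(x$paths$quantity),
    mean_path_length = if (length(lens)) mean(lens) else NA_real_,
    n_exogenous_paths = sum(x$paths$exogenous_origin),
    units_residual = sum(x$residual_stocks$quantity),
    n_transactions = d$n_transactions,
    n_skipped = d$n_skipped,
    n_self_loops = d$n_self_loops,
    n_exogenous_batches = d$n_exogenous_batches
  )
}

#' @rdname tidy.path_reconstruction
#' @export
tidy.path_simulation <- function(x, ...) {
  tidy.path_reconstruction(list(paths = x$ground_truth), ...)
}

#' @rdname glance.path_reconstruction
#' @export
glance.path_simulation <- function(x, ...) {
  lens <- lengths(x$ground_truth$path) - 1L
  tibble::tibble(
    policy = x$config$policy,
    n_paths = nrow(x$ground_truth),
    units_delivered = sum(x$ground_truth$quantity),
    mean_path_length = if (length(lens)) mean(lens) else NA_real_,
    units_residual = sum(x$residual_stocks$quantity),
    n_transactions = nrow(x$transactions)
  )
}
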