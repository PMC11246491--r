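#' Load a dyadic shipping-transaction table
#'
#' Reads a chronological table of dyadic shipments (one row per shipment
#' between a sender and a receiver, as in a DEA ARCOS sales extract) and
#' returns it as a tibble sorted for chronological processing. Sorting is a
#' *stable* sort on the shipping date only: rows sharing a date keep their
#' input order, recorded in the `seq` column. No finer-than-daily timestamp
#' exists in this kind of administrative data, so `seq` is the within-day
#' tie-breaker used throughout the package.
#'
#' Malformed rows (unparseable date, missing or non-positive quantity) are
#' collected rather than fatal by default, since large administrative
#' extracts contain dirt; the skipped rows are attached as the
#' `"problems"` attribute and counted in `"n_malformed"`. With
#' `strict = TRUE` any malformed row is an error.
#'
#' @param source A file path, connection, or a data frame already in memory.
#' @param schema_map Named character vector mapping the canonical column
#'   names (`date`, `sender_id`, `receiver_id`, `product_code`, `quantity`,
#'   `sender_type`, `receiver_type`) to the column headers present in the
#'   file. Defaults to the identity mapping. `product_code`, `sender_type`
#'   and `receiver_type` are optional columns; the rest are mandatory.
#' @param date_format Date format string passed to [as.Date()]; default
#'   ISO-8601 (`"%Y-%m-%d"`).
#' @param strict If `TRUE`, malformed rows are an error instead of being
#'   skipped.
#'
#' @return A tibble with columns `date` (Date), `sender_id`, `receiver_id`,
#'   `product_code`, `quantity` (integer), `sender_type`, `receiver_type`,
#'   and `seq` (0-based input-order index), sorted by `(date, seq)`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "date,sender_id,receiver_id,product_code,quantity,sender_type,receiver_type",
#'   "2010-06-22,M1,D1,00001000150,200,manufacturer,distributor",
#'   "2010-07-29,D1,D2,00001000150,10,distributor,distributor"
#' ), f)
#' load_transactions(f)
#' @export
load_transactions <- function(source,
                              schema_map = NULL,
                              date_format = "%Y-%m-%d",
                              strict = FALSE) {
  canonical <- c("date", "sender_id", "receiver_id", "product_code",
                 "quantity", "sender_type", "receiver_type")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(schema_map)) {
    bad <- setdiff(names(schema_map), canonical)
    if (length(bad) > 0L) {
      stop("unknown schema_map entries: ", paste(bad, collapse = ", "))
    }
    map[names(schema_map)] <- unname(schema_map)
  }

  raw <- if (is.data.frame(source)) {
    tibble::as_tibble(source)
  } else {
    readr::read_csv(source, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  }

  mandatory <- c("date", "sender_id", "receiver_id", "quantity")
  for (col in canonical) {
    if (!map[[col]] %in% names(raw)) {
      if (col %in% mandatory) {
        stop("missing mandatory column: '", map[[col]], "' (for ", col, ")")
      }
      raw[[map[[col]]]] <- NA_character_
    }
  }

  txns <- tibble::tibble(
    date = parse_flexible_date(as.character(raw[[map[["date"]]]]), date_format),
    sender_id = as.character(raw[[map[["sender_id"]]]]),
    receiver_id = as.character(raw[[map[["receiver_id"]]]]),
    product_code = as.character(raw[[map[["product_code"]]]]),
    quantity = suppressWarnings(as.integer(as.numeric(raw[[map[["quantity"]]]]))),
    sender_type = normalize_entity_type(raw[[map[["sender_type"]]]]),
    receiver_type = normalize_entity_type(raw[[map[["receiver_type"]]]]),
    seq = seq_len(nrow(raw)) - 1L
  )

  bad_date <- is.na(txns$date)
  bad_qty <- is.na(txns$quantity) | txns$quantity < 1L
  malformed <- bad_date | bad_qty
  if (any(malformed)) {
    msg <- paste0(sum(malformed), " malformed row(s): ",
                  sum(bad_date), " unparseable date(s), ",
                  sum(bad_qty), " missing/non-positive quantity(ies)")
    if (strict) stop(msg)
    message("load_transactions: ", msg, " skipped")
  }
  problems <- txns[malformed, , drop = FALSE]
  txns <- txns[!malformed, , drop = FALSE]

  txns <- dplyr::arrange(txns, .data$date)  # dplyr::arrange is stable
  attr(txns, "n_malformed") <- nrow(problems)
  attr(txns, "problems") <- problems
  txns
}

parse_flexible_date <- function(x, date_format) {
  as.Date(x, format = date_format, optional = TRUE)
}

#' Map entity-type labels onto the three-tier typing
#'
#' The path terminology distinguishes manufacturers, distributors and
#' "final distributors" — the umbrella for every entity that is neither a
#' manufacturer nor a distributor (hospitals, pharmacies, practitioners,
#' clinics), which terminates a distribution path.
#'
#' @param x Character vector of free-text business-activity or type labels.
#' @param manufacturer_pattern,distributor_pattern Regular expressions
#'   (case-insensitive) identifying manufacturers and mid-chain
#'   distributors; anything matching neither is a final distributor.
#' @return Character vector over `{"manufacturer", "distributor",
#'   "final_distributor"}` (`NA` stays `NA`).
#' @examples
#' classify_business_activity(c("Manufacturer", "Distributor", "Retail Pharmacy"))
#' @export
classify_business_activity <- function(x,
                                       manufacturer_pattern = "manufact",
                                       distributor_pattern = "^distrib|wholesal|reverse distrib") {
  x <- as.character(x)
  out <- rep(NA_character_, length(x))
  known <- !is.na(x)
  lx <- tolower(trimws(x[known]))
  typ <- ifelse(grepl(manufacturer_pattern, lx, ignore.case = TRUE), "manufacturer",
         ifelse(grepl(distributor_pattern, lx, ignore.case = TRUE), "distributor",
                "final_distributor"))
  out[known] <- typ
  out
}

normalize_entity_type <- function(x) {
  x <- as.character(x)
  out <- rep(NA_character_, length(x))
  known <- !is.na(x)
  out[known] <- classify_business_activity(x[known])
  out
}

#' Load an entity table
#'
#' Reads the entity register (one row per DEA number, with its business
#' activity and location) and derives the three-tier `entity_type` used by
#' the reconstruction engine. Latitude/longitude columns are optional and
#' caller-supplied; range-checked when present.
#'
#' @param source File path, connection, or data frame with columns
#'   `dea_number`, `business_activity`, `city`, `state`, `zip`, and
#'   optionally `lat`, `lon`.
#' @param ... Passed on to [classify_business_activity()].
#' @return A tibble with the input columns plus `entity_type`.
#' @export
load_entities <- function(source, ...) {
  ents <- if (is.data.frame(source)) {
    tibble::as_tibble(source)
  } else {
    readr::read_csv(source, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  }
  if (!"dea_number" %in% names(ents)) {
    stop("missing mandatory column: 'dea_number'")
  }
  if (anyDuplicated(ents$dea_number)) {
    stop("duplicate dea_number values in entity table")
  }
  if (!"business_activity" %in% names(ents)) {
    stop("missing mandatory column: 'business_activity'")
  }
  ents$entity_type <- classify_business_activity(ents$business_activity, ...)
  for (col in c("lat", "lon")) {
    if (col %in% names(ents)) ents[[col]] <- as.numeric(ents[[col]])
  }
  if (all(c("lat", "lon") %in% names(ents))) {
    ok <- is.na(ents$lat) | (abs(ents$lat) <= 90)
    ok <- ok & (is.na(ents$lon) | (abs(ents$lon) <= 180))
    if (!all(ok)) stop("entity coordinates out of range")
  }
  ents
}

#' Split an 11-digit National Drug Code
#'
#' An NDC is an 11-digit product identifier: the first 5 digits identify the
#' labeler (manufacturer), the next 4 the drug formulation (active
#' ingredient, dosage form, strength), and the last 2 the package size.
#' Hyphens and spaces are stripped before splitting.
#'
#' @param code Character vector of NDC codes, with or without separators.
#' @return A tibble with columns `ndc` (the 11 digits), `labeler_code`,
#'   `formulation_code`, `package_size_code`.
#' @examples
#' parse_ndc("00001-0001-50")
#' @export
parse_ndc <- function(code) {
  stripped <- gsub("[-\\s]", "", as.character(code), perl = TRUE)
  bad <- !grepl("^[0-9]{11}$", stripped)
  if (any(bad)) {
    stop("invalid NDC (must be 11 digits after separator removal): ",
         paste(utils::head(code[bad], 3L), collapse = ", "))
  }
  tibble::tibble(
    ndc = stripped,
    labeler_code = substr(stripped, 1L, 5L),
    formulation_code = substr(stripped, 6L, 9L),
    package_size_code = substr(stripped, 10L, 11L)
  )
}

#' Load a product table
#'
#' @param source File path, connection, or data frame with columns `ndc`
#'   and `active_ingredient`.
#' @return A tibble with the NDC split into its labeler / formulation /
#'   package-size parts plus `active_ingredient`.
#' @export
load_products <- function(source) {
  prods <- if (is.data.frame(source)) {
    tibble::as_tibble(source)
  } else {
    readr::read_csv(source, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  }
  if (!"ndc" %in% names(prods)) stop("missing mandatory column: 'ndc'")
  parsed <- parse_ndc(prods$ndc)
  parsed$active_ingredient <-
    if ("active_ingredient" %in% names(prods)) as.character(prods$active_ingredient)
    else NA_character_
  parsed
}
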