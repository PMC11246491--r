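#' Build a tibble of distribution-path records
#'
#' A distribution path is the complete journey of a quantity of one product:
#' the ordered entity sequence from its origin (normally a manufacturer) to
#' a final distributor, the chronology of shipping dates between consecutive
#' entities, and the units delivered. Paths are stored as a tibble with one
#' row per record and list-columns for the sequences, so the usual dplyr
#' verbs apply.
#'
#' @param path List of character vectors (entity IDs, length >= 2 each).
#' @param dates List of Date vectors, each one shorter than its path.
#' @param quantity Integer vector of delivered units (>= 1).
#' @param exogenous_origin Logical: `TRUE` when the record descends from a
#'   synthetic origin batch created because a non-manufacturer shipped more
#'   than its recorded inflow (see [reconstruct()]); such records are less
#'   reliable and can be filtered out.
#' @param product_code Optional NDC per record.
#' @return A `path_tbl` tibble with columns `path`, `dates`, `quantity`,
#'   `exogenous_origin`, `product_code`.
#' @export
path_records <- function(path, dates, quantity,
                         exogenous_origin = FALSE,
                         product_code = NA_character_) {
  n <- length(path)
  out <- tibble::tibble(
    path = as.list(path),
    dates = as.list(dates),
    quantity = as.integer(rep_len(quantity, n)),
    exogenous_origin = rep_len(as.logical(exogenous_origin), n),
    product_code = rep_len(as.character(product_code), n)
  )
  class(out) <- c("path_tbl", class(out))
  out
}

#' Validate distribution-path records
#'
#' Checks the structural invariants every path record must satisfy: at least
#' two entities, exactly one date per distribution step, nondecreasing
#' dates, and a positive quantity. When an entity table is supplied, the
#' terminal entity must be typed `final_distributor`.
#'
#' @param paths A path tibble as returned by [path_records()] or
#'   [reconstruct()].
#' @param entities Optional entity table (with `dea_number`, `entity_type`)
#'   for the terminal-type check.
#' @return Invisibly `paths`; errors name the first offending record index.
#' @export
validate_paths <- function(paths, entities = NULL) {
  if (nrow(paths) == 0L) return(invisible(paths))
  plen <- lengths(paths$path)
  dlen <- lengths(paths$dates)
  bad <- which(plen < 2L)
  if (length(bad)) stop("record ", bad[1L], ": path has fewer than 2 entities")
  bad <- which(dlen != plen - 1L)
  if (length(bad)) stop("record ", bad[1L], ": need exactly length(path) - 1 dates")
  nondec <- vapply(paths$dates, function(d) !is.unsorted(as.integer(d)), logical(1L))
  bad <- which(!nondec)
  if (length(bad)) stop("record ", bad[1L], ": dates must be nondecreasing")
  bad <- which(is.na(paths$quantity) | paths$quantity < 1L)
  if (length(bad)) stop("record ", bad[1L], ": quantity must be a positive integer")
  if (!is.null(entities)) {
    type_of <- stats::setNames(entities$entity_type, entities$dea_number)
    term <- vapply(paths$path, function(p) p[length(p)], character(1L))
    bad <- which(is.na(type_of[term]) | type_of[term] != "final_distributor")
    if (length(bad)) stop("record ", bad[1L], ": terminal entity is not a final distributor")
  }
  invisible(paths)
}

#' Write distribution paths as JSON Lines
#'
#' One JSON object per line with keys `path` (entity-ID array), `dates`
#' (ISO-8601 date array) and `quantity`, in that fixed order so output is
#' diff-stable. `exogenous_origin` is written as a fourth key only when
#' `TRUE`, keeping the plain three-key schema for ordinary records while
#' making the round trip through [read_paths_jsonl()] lossless.
#'
#' @param paths A path tibble; validated with [validate_paths()] first.
#' @param sink Output file path or connection.
#' @return Invisibly, the number of lines written.
#' @export
write_paths_jsonl <- function(paths, sink) {
  validate_paths(paths)
  n <- nrow(paths)
  lines <- character(n)
  if (n > 0L) {
    for (i in seq_len(n)) {
      obj <- paste0(
        '{"path":', jsonlite::toJSON(as.character(paths$path[[i]])),
        ',"dates":', jsonlite::toJSON(format(paths$dates[[i]], "%Y-%m-%d")),
        ',"quantity":', format(paths$quantity[i])
      )
      if (isTRUE(paths$exogenous_origin[i])) {
        obj <- paste0(obj, ',"exogenous_origin":true')
      }
      lines[i] <- paste0(obj, "}")
    }
  }
  writeLines(lines, sink, sep = "\n", useBytes = TRUE)
  invisible(n)
}

#' Read distribution paths from JSON Lines
#'
#' Inverse of [write_paths_jsonl()]. Blank lines are skipped; a malformed
#' line or a line missing a mandatory key (`path`, `dates`, `quantity`) is
#' an error naming the line number. Unknown keys are ignored.
#'
#' @param source Input file path or connection.
#' @param product_code Optional NDC recorded on every record (the published
#'   layout is one file per product, so the code lives in the file name).
#' @return A path tibble as from [path_records()].
#' @export
read_paths_jsonl <- function(source, product_code = NA_character_) {
  lines <- readLines(source, warn = FALSE, encoding = "UTF-8")
  keep <- which(nzchar(trimws(lines)))
  path <- vector("list", length(keep))
  dates <- vector("list", length(keep))
  quantity <- integer(length(keep))
  exo <- logical(length(keep))
  for (j in seq_along(keep)) {
    ln <- keep[j]
    rec <- tryCatch(jsonlite::fromJSON(lines[ln], simplifyVector = TRUE),
                    error = function(e) {
                      stop("malformed JSON at line ", ln, ": ", conditionMessage(e))
                    })
    for (key in c("path", "dates", "quantity")) {
      if (is.null(rec[[key]])) stop("line ", ln, ": missing key '", key, "'")
    }
    path[[j]] <- as.character(rec$path)
    dates[[j]] <- as.Date(as.character(rec$dates))
    quantity[j] <- as.integer(rec$quantity)
    exo[j] <- isTRUE(rec$exogenous_origin)
  }
  path_records(path, dates, quantity, exo, product_code)
}

# Canonical path identity: the entity-ID sequence only. Dates and quantities
# are excluded so that the same route used on different days counts as the
# same path — the identity under which FIFO/LIFO and year-to-year overlaps
# are computed.
path_keys <- function(paths) {
  vapply(paths$path, paste, character(1L), collapse = "\x1f")
}

# Canonical full serialization (path + dates + quantity), for exact
# multiset comparison in round-trip tests.
path_signatures <- function(paths) {
  vapply(seq_len(nrow(paths)), function(i) {
    paste(paste(paths$path[[i]], collapse = "\x1f"),
          paste(as.integer(paths$dates[[i]]), collapse = ","),
          paths$quantity[i], sep = "|")
  }, character(1L))
}
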