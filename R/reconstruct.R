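#' Shared-prefix path storage
#'
#' Batch splitting means thousands of batches can share the same ancestry;
#' copying the full entity sequence into every batch would make memory grow
#' with the sum of materialized path lengths. Instead paths are stored as a
#' reversed tree of immutable nodes: each node records its parent, the
#' entity appended, and the shipping date of that step. A batch holds only a
#' node id; the full sequence is materialized on emission.
#'
#' `path_arena()` creates the store; `path_node()` appends a node (parent
#' `0L` starts a new origin); `materialize_path()` walks the parent chain
#' and returns the entity and date sequences; `arena_size()` returns the
#' number of nodes allocated — memory is proportional to this, not to the
#' sum of materialized lengths.
#'
#' @param parent Parent node id (`0L` for an origin node).
#' @param entity Entity id appended at this node.
#' @param date Integer day of the shipment into `entity` (`NA` for origins).
#' @param arena An arena created by `path_arena()`.
#' @param id A node id.
#' @return `path_node()` the new node id; `materialize_path()` a list with
#'   `path` (character) and `dates` (integer days); `arena_size()` an
#'   integer count.
#' @examples
#' a <- path_arena()
#' n0 <- path_node(a, 0L, "D0", NA_integer_)
#' n1 <- path_node(a, n0, "D1", 0L)
#' materialize_path(a, n1)
#' @export
path_arena <- function() {
  a <- new.env(parent = emptyenv())
  a$parent <- integer(256L)
  a$entity <- character(256L)
  a$date <- integer(256L)
  a$n <- 0L
  a
}

#' @rdname path_arena
#' @export
path_node <- function(arena, parent, entity, date) {
  n <- arena$n + 1L
  if (n > length(arena$parent)) {
    grow <- 2L * length(arena$parent)
    arena$parent <- c(arena$parent, integer(grow))
    arena$entity <- c(arena$entity, character(grow))
    arena$date <- c(arena$date, integer(grow))
  }
  arena$parent[n] <- parent
  arena$entity[n] <- entity
  arena$date[n] <- date
  arena$n <- n
  n
}

#' @rdname path_arena
#' @export
materialize_path <- function(arena, id) {
  ids <- integer(16L)
  k <- 0L
  while (id != 0L) {
    k <- k + 1L
    if (k > length(ids)) ids <- c(ids, integer(length(ids)))
    ids[k] <- id
    id <- arena$parent[id]
  }
  ids <- rev(ids[seq_len(k)])
  list(path = arena$entity[ids],
       dates = arena$date[ids[-1L]])
}

#' @rdname path_arena
#' @export
arena_size <- function(arena) arena$n

#' Draw an allocation from a policy-ordered stock
#'
#' Reference implementation of the dispatch rule on an explicit batch table.
#' The stock is a tibble of batches in arrival order (oldest first) with
#' columns `batch_id` and `quantity`. Under FIFO the oldest batches are
#' consumed first; under LIFO the newest. Batches are consumed greedily in
#' policy order until `amount` is covered; a partially consumed batch keeps
#' its position (age is arrival, not remaining size). If the stock total is
#' short, the shortfall is covered by a single synthetic batch with
#' `batch_id` `NA` and the result is flagged.
#'
#' @param stock Tibble with columns `batch_id`, `quantity`, rows oldest
#'   first.
#' @param amount Positive integer to draw.
#' @param policy `"fifo"` or `"lifo"`.
#' @return A tibble of allocations (`batch_id`, `drawn`) in dispatch order,
#'   with attributes `"remaining"` (the stock after the draw) and
#'   `"shortfall"` (units covered synthetically, 0 when none).
#' @examples
#' stock <- tibble::tibble(batch_id = c("B3", "B6"), quantity = c(4L, 2L))
#' draw_allocations(stock, 5L, "fifo")
#' draw_allocations(stock, 5L, "lifo")
#' @export
draw_allocations <- function(stock, amount, policy = c("fifo", "lifo")) {
  policy <- match.arg(tolower(policy), c("fifo", "lifo"))
  stopifnot(amount >= 1L)
  idx <- if (policy == "fifo") seq_len(nrow(stock)) else rev(seq_len(nrow(stock)))
  need <- as.integer(amount)
  alloc_id <- character(0)
  alloc_q <- integer(0)
  consumed <- integer(0)
  for (i in idx) {
    if (need == 0L) break
    take <- min(need, stock$quantity[i])
    if (take > 0L) {
      alloc_id <- c(alloc_id, as.character(stock$batch_id[i]))
      alloc_q <- c(alloc_q, take)
      stock$quantity[i] <- stock$quantity[i] - take
      need <- need - take
      if (stock$quantity[i] == 0L) consumed <- c(consumed, i)
    }
  }
  shortfall <- need
  if (shortfall > 0L) {
    alloc_id <- c(alloc_id, NA_character_)
    alloc_q <- c(alloc_q, shortfall)
  }
  remaining <- if (length(consumed)) stock[-consumed, , drop = FALSE] else stock
  out <- tibble::tibble(batch_id = alloc_id, drawn = alloc_q)
  attr(out, "remaining") <- remaining
  attr(out, "shortfall") <- shortfall
  out
}

# Fast array-backed stock used inside the engine: a deque of (quantity,
# node-id, exogenous-flag) slots. Arrival keys increase monotonically while
# transactions are processed chronologically, so pushing at the tail keeps
# the policy order without sorting; FIFO pops at the head, LIFO at the tail.
new_stock <- function() {
  s <- new.env(parent = emptyenv())
  s$q <- integer(8L)
  s$node <- integer(8L)
  s$exo <- logical(8L)
  s$lo <- 1L
  s$hi <- 0L
  s
}

stock_push <- function(s, qty, node, exo) {
  hi <- s$hi + 1L
  if (hi > length(s$q)) {
    keep <- if (s$hi >= s$lo) s$lo:s$hi else integer(0)
    n <- length(keep)
    cap <- max(16L, 2L * n)
    q <- integer(cap); q[seq_len(n)] <- s$q[keep]
    nd <- integer(cap); nd[seq_len(n)] <- s$node[keep]
    ex <- logical(cap); ex[seq_len(n)] <- s$exo[keep]
    s$q <- q; s$node <- nd; s$exo <- ex
    s$lo <- 1L
    hi <- n + 1L
  }
  s$q[hi] <- qty
  s$node[hi] <- node
  s$exo[hi] <- exo
  s$hi <- hi
  invisible(s)
}

stock_total <- function(s) {
  if (s$hi < s$lo) 0L else sum(s$q[s$lo:s$hi])
}

#' Reconstruct distribution paths from dyadic shipping transactions
#'
#' Processes shipping transactions chronologically, maintaining a
#' policy-ordered stock of batches per (entity, product). Each transaction
#' draws exactly its quantity from the sender's stock — oldest batches first
#' under FIFO, newest first under LIFO — splitting and combining batches as
#' needed. Every drawn allocation becomes a new batch at the receiver with
#' its path extended by the receiver and its date chronology extended by the
#' shipping date; when the receiver is a final distributor (any entity that
#' is neither manufacturer nor distributor) the allocation is emitted as a
#' completed distribution path instead of entering stock. Batches still in
#' stock when the stream ends are in transit and are *not* emitted.
#'
#' When a sender's stock cannot cover a shipment, an origin batch is created
#' at the sender for the shortfall. For manufacturers this is the normal
#' start of a path: manufacturers produce, so their shipments originate
#' paths. For any other sender it means the data do not record where the
#' goods came from (e.g. stock predating the observation window); such
#' origin batches are *exogenous* and every path descending from one is
#' flagged `exogenous_origin = TRUE` so unreliable paths can be filtered
#' rather than silently mixed in.
#'
#' @param transactions Transaction tibble as from [load_transactions()]
#'   (sorted by date with `seq` as within-date tie-break; if `seq` is
#'   missing, input order is used).
#' @param entities Entity table with `dea_number` and `entity_type`
#'   (see [load_entities()]); used to resolve sender/receiver types. When
#'   `NULL`, the `sender_type` / `receiver_type` columns of the transactions
#'   are used instead.
#' @param policy `"fifo"` (default; recommended practice for perishables)
#'   or `"lifo"`.
#' @param on_unknown_entity `"skip"` (default; skip the transaction and
#'   count it) or `"error"` for transactions whose sender or receiver type
#'   cannot be resolved.
#' @param on_date_regression `"warn"` (default; administrative data contain
#'   corrections) or `"error"` when a transaction date precedes the last
#'   date of the batch it extends.
#' @return A `path_reconstruction` object: a list with
#'   \describe{
#'     \item{paths}{completed-path tibble (`path`, `dates`, `quantity`,
#'       `exogenous_origin`, `product_code`)}
#'     \item{residual_stocks}{tibble of end-of-stream stock per
#'       (entity, product)}
#'     \item{diagnostics}{one-row tibble: transactions processed / skipped /
#'       self-loops, exogenous batches and units, manufacturer-origin units}
#'     \item{policy}{the policy used}
#'   }
#' @examples
#' wx <- worked_example()
#' res <- reconstruct(wx$transactions, wx$entities, policy = "fifo")
#' res$paths
#' @export
reconstruct <- function(transactions,
                        entities = NULL,
                        policy = c("fifo", "lifo"),
                        on_unknown_entity = c("skip", "error"),
                        on_date_regression = c("warn", "error")) {
  policy <- match.arg(tolower(policy), c("fifo", "lifo"))
  on_unknown_entity <- match.arg(on_unknown_entity)
  on_date_regression <- match.arg(on_date_regression)
  fifo <- policy == "fifo"

  tx <- transactions
  if (!"seq" %in% names(tx)) tx$seq <- seq_len(nrow(tx)) - 1L
  if (!"product_code" %in% names(tx)) tx$product_code <- NA_character_
  ord <- order(as.integer(tx$date), tx$seq, method = "radix")
  tx <- tx[ord, , drop = FALSE]

  type_of <- NULL
  if (!is.null(entities)) {
    type_of <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(entities))) {
      assign(entities$dea_number[i], entities$entity_type[i], envir = type_of)
    }
  }
  resolve_type <- function(id, fallback) {
    if (!is.null(type_of)) {
      t <- get0(id, envir = type_of, ifnotfound = NA_character_)
      if (!is.na(t)) return(t)
    }
    fallback
  }

  arena <- path_arena()
  stocks <- new.env(parent = emptyenv())
  last_date <- new.env(parent = emptyenv())  # node id -> last step date

  n <- nrow(tx)
  dates_i <- as.integer(tx$date)
  out_node <- integer(0)
  out_qty <- integer(0)
  out_exo <- logical(0)
  out_prod <- character(0)
  n_out <- 0L

  n_skipped <- 0L
  n_self <- 0L
  n_exo_batches <- 0L
  n_exo_units <- 0L
  n_origin_units <- 0L
  n_regressions <- 0L

  stype <- as.character(tx$sender_type)
  rtype <- as.character(tx$receiver_type)

  for (i in seq_len(n)) {
    sender <- tx$sender_id[i]
    receiver <- tx$receiver_id[i]
    if (identical(sender, receiver)) {
      n_self <- n_self + 1L
      next
    }
    s_type <- resolve_type(sender, stype[i])
    r_type <- resolve_type(receiver, rtype[i])
    if (is.na(s_type) || is.na(r_type)) {
      if (on_unknown_entity == "error") {
        stop("transaction ", tx$seq[i], ": unresolvable sender or receiver type")
      }
      n_skipped <- n_skipped + 1L
      next
    }
    prod <- tx$product_code[i]
    qty <- tx$quantity[i]
    day <- dates_i[i]
    skey <- paste0(sender, "\x1f", prod)

    s <- get0(skey, envir = stocks, ifnotfound = NULL)
    if (is.null(s)) {
      s <- new_stock()
      assign(skey, s, envir = stocks)
    }

    terminal <- r_type == "final_distributor"
    rstock <- NULL
    if (!terminal) {
      rkey <- paste0(receiver, "\x1f", prod)
      rstock <- get0(rkey, envir = stocks, ifnotfound = NULL)
      if (is.null(rstock)) {
        rstock <- new_stock()
        assign(rkey, rstock, envir = stocks)
      }
    }

    need <- qty
    while (need > 0L) {
      if (s$hi < s$lo) {
        # shortfall: create an origin batch at the sender covering the rest
        root <- path_node(arena, 0L, sender, NA_integer_)
        exo <- s_type != "manufacturer"
        if (exo) {
          n_exo_batches <- n_exo_batches + 1L
          n_exo_units <- n_exo_units + need
        } else {
          n_origin_units <- n_origin_units + need
        }
        stock_push(s, need, root, exo)
      }
      slot <- if (fifo) s$lo else s$hi
      take <- min(need, s$q[slot])
      bnode <- s$node[slot]
      bexo <- s$exo[slot]
      ld <- get0(as.character(bnode), envir = last_date, ifnotfound = NA_integer_)
      if (!is.na(ld) && day < ld) {
        n_regressions <- n_regressions + 1L
        if (on_date_regression == "error") {
          stop("transaction ", tx$seq[i], ": shipping date precedes batch chronology")
        }
      }
      node <- path_node(arena, bnode, receiver, day)
      s$q[slot] <- s$q[slot] - take
      if (s$q[slot] == 0L) {
        if (fifo) s$lo <- s$lo + 1L else s$hi <- s$hi - 1L
      }
      if (terminal) {
        n_out <- n_out + 1L
        if (n_out > length(out_node)) {
          grow <- max(256L, length(out_node))
          out_node <- c(out_node, integer(grow))
          out_qty <- c(out_qty, integer(grow))
          out_exo <- c(out_exo, logical(grow))
          out_prod <- c(out_prod, character(grow))
        }
        out_node[n_out] <- node
        out_qty[n_out] <- take
        out_exo[n_out] <- bexo
        out_prod[n_out] <- prod
      } else {
        stock_push(rstock, take, node, bexo)
        assign(as.character(node), day, envir = last_date)
      }
      need <- need - take
    }
  }

  # materialize completed paths
  keep <- seq_len(n_out)
  epoch <- as.Date("1970-01-01")
  mat <- lapply(out_node[keep], function(id) materialize_path(arena, id))
  paths <- path_records(
    path = lapply(mat, `[[`, "path"),
    dates = lapply(mat, function(m) epoch + m$dates),
    quantity = out_qty[keep],
    exogenous_origin = out_exo[keep],
    product_code = out_prod[keep]
  )

  # residual stocks
  keys <- ls(envir = stocks)
  res_entity <- character(0); res_prod <- character(0); res_qty <- integer(0)
  for (k in keys) {
    s <- get(k, envir = stocks)
    tot <- stock_total(s)
    if (tot > 0L) {
      parts <- strsplit(k, "\x1f", fixed = TRUE)[[1L]]
      res_entity <- c(res_entity, parts[1L])
      res_prod <- c(res_prod, if (length(parts) > 1L) parts[2L] else NA_character_)
      res_qty <- c(res_qty, tot)
    }
  }
  residual <- tibble::tibble(entity_id = res_entity, product_code = res_prod,
                             quantity = res_qty)
  residual <- dplyr::arrange(residual, .data$entity_id, .data$product_code)

  diagnostics <- tibble::tibble(
    n_transactions = n,
    n_processed = n - n_skipped - n_self,
    n_skipped = n_skipped,
    n_self_loops = n_self,
    n_exogenous_batches = n_exo_batches,
    n_exogenous_units = n_exo_units,
    n_origin_units = n_origin_units,
    n_date_regressions = n_regressions
  )
  if (n_regressions > 0L && on_date_regression == "warn") {
    warning(n_regressions, " transaction(s) dated before their batch chronology; accepted")
  }

  structure(
    list(paths = paths, residual_stocks = residual,
         diagnostics = diagnostics, policy = policy),
    class = "path_reconstruction"
  )
}

#' @export
print.path_reconstruction <- function(x, ...) {
  d <- x$diagnostics
  cat("<path_reconstruction> policy =", toupper(x$policy), "\n")
  cat("  completed paths:", nrow(x$paths),
      "(", sum(x$paths$quantity), "units delivered )\n")
  cat("  transactions:", d$n_processed, "processed,", d$n_skipped, "skipped,",
      d$n_self_loops, "self-loops\n")
  cat("  exogenous batches:", d$n_exogenous_batches,
      "(", d$n_exogenous_units, "units );",
      "manufacturer-origin units:", d$n_origin_units, "\n")
  cat("  residual stock rows:", nrow(x$residual_stocks),
      "(", sum(x$residual_stocks$quantity), "units in transit )\n")
  invisible(x)
}
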