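#' Configuration for the multi-echelon distribution simulator
#'
#' The simulator forward-simulates the distribution process the
#' reconstruction method assumes: manufacturers dispatch large batches to
#' distributors, who hold them in stock, repack, and forward them — possibly
#' splitting a dispatch across several receivers — until packages reach a
#' final distributor. Because the simulator tracks every allocated unit
#' group explicitly, the true distribution path of every delivered quantity
#' is known, which makes the generator the recovery oracle for
#' [reconstruct()].
#'
#' Defaults emulate a desk-scale regional market: a handful of
#' manufacturers injecting batches of 50–200 packages at a mean rate of 0.6
#' batches per manufacturer-day, an order of magnitude more distributors
#' than manufacturers and an order of magnitude more final distributors
#' than distributors (mirroring the strongly bottom-heavy tiering of real
#' registrant populations), repacking delays of 1–7 days, and dispatches
#' forwarding 90% of each arrival (the residue builds up the aged stock
#' that differentiates FIFO from LIFO).
#'
#' @param n_manufacturers,n_distributors,n_final_distributors Tier sizes.
#' @param n_products Number of distinct NDCs in circulation.
#' @param horizon_days Length of the simulated period in days.
#' @param injection_rate Mean batches injected per manufacturer per day
#'   (Poisson).
#' @param batch_size Integer range `c(min, max)` of units per injected
#'   batch (uniform).
#' @param forward_delay Integer range `c(min, max)` of days (>= 1) between
#'   an arrival at a distributor and the dispatch it triggers (uniform).
#' @param forward_fraction Fraction of each arriving quantity scheduled for
#'   onward dispatch (ceiling); values below 1 leave aging residue in
#'   stock.
#' @param split_max Maximum number of receivers one dispatch is split
#'   across.
#' @param p_terminal Probability that each dispatch portion targets a final
#'   distributor rather than another distributor.
#' @param policy Stock-management policy of the *physical* process:
#'   `"fifo"` or `"lifo"`.
#' @param bbox Coordinate bounding box
#'   `c(lat_min, lat_max, lon_min, lon_max)` from which entity locations
#'   are drawn uniformly (default: roughly the contiguous US).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_manufacturers = 3L,
                              n_distributors = 8L,
                              n_final_distributors = 40L,
                              n_products = 2L,
                              horizon_days = 120L,
                              injection_rate = 0.6,
                              batch_size = c(50L, 200L),
                              forward_delay = c(1L, 7L),
                              forward_fraction = 0.9,
                              split_max = 3L,
                              p_terminal = 0.35,
                              policy = c("fifo", "lifo"),
                              bbox = c(25, 49, -124, -67),
                              seed = 1L) {
  policy <- match.arg(tolower(policy), c("fifo", "lifo"))
  stopifnot(
    n_manufacturers >= 1L, n_distributors >= 1L, n_final_distributors >= 1L,
    n_products >= 1L, horizon_days >= 1L, injection_rate > 0,
    batch_size[1L] >= 1L, batch_size[2L] >= batch_size[1L],
    forward_delay[1L] >= 1L, forward_delay[2L] >= forward_delay[1L],
    forward_fraction > 0, forward_fraction <= 1,
    split_max >= 1L, p_terminal >= 0, p_terminal <= 1
  )
  structure(list(
    n_manufacturers = as.integer(n_manufacturers),
    n_distributors = as.integer(n_distributors),
    n_final_distributors = as.integer(n_final_distributors),
    n_products = as.integer(n_products),
    horizon_days = as.integer(horizon_days),
    injection_rate = injection_rate,
    batch_size = as.integer(batch_size),
    forward_delay = as.integer(forward_delay),
    forward_fraction = forward_fraction,
    split_max = as.integer(split_max),
    p_terminal = p_terminal,
    policy = policy,
    bbox = bbox,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

resample <- function(x, n = 1L) x[sample.int(length(x), n)]

#' Simulate a multi-echelon distribution process
#'
#' Runs the process described in [simulation_config()] day by day and
#' returns the dyadic transaction stream exactly as an administrative
#' register would record it, together with the ground-truth ledger of
#' completed per-unit-group distribution paths and the residual stock at
#' the horizon. Ground truth is tracked with fully materialized per-group
#' journeys, independently of the reconstruction engine's shared-prefix
#' machinery.
#'
#' The policy affects only which physical units fill each shipment, never
#' the sequence of random draws, so two runs with the same seed and
#' different policies produce identical transaction streams — the
#' common-random-numbers pairing used by [perturb_policy()].
#'
#' @param config A [simulation_config()].
#' @param origin_date Calendar date of simulation day 0.
#' @return A `path_simulation` object: list with `transactions`,
#'   `entities`, `ground_truth` (path tibble), `residual_stocks`, and
#'   `config`.
#' @export
simulate_distribution <- function(config, origin_date = as.Date("2006-01-01")) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  fifo <- config$policy == "fifo"

  manufacturers <- sprintf("M%03d", seq_len(config$n_manufacturers))
  distributors <- sprintf("D%03d", seq_len(config$n_distributors))
  finals <- sprintf("F%05d", seq_len(config$n_final_distributors))
  all_ids <- c(manufacturers, distributors, finals)
  types <- c(rep("manufacturer", length(manufacturers)),
             rep("distributor", length(distributors)),
             rep("final_distributor", length(finals)))
  activities <- c(rep("Manufacturer", length(manufacturers)),
                  rep("Distributor", length(distributors)),
                  rep("Pharmacy", length(finals)))
  bb <- config$bbox
  entities <- tibble::tibble(
    dea_number = all_ids,
    business_activity = activities,
    entity_type = types,
    city = NA_character_, state = NA_character_, zip = NA_character_,
    lat = stats::runif(length(all_ids), bb[1L], bb[2L]),
    lon = stats::runif(length(all_ids), bb[3L], bb[4L])
  )
  products <- sprintf("%05d%04d%02d", 10000L + seq_len(config$n_products),
                      sample.int(9999L, config$n_products, replace = TRUE), 10L)

  # mutable state -----------------------------------------------------------
  stocks <- new.env(parent = emptyenv())   # "ent\x1fprod" -> list of groups
  sched <- new.env(parent = emptyenv())    # day -> list of (entity, product, amount)
  tx <- list()                             # accumulated transaction rows
  gt <- list()                             # completed ground-truth records
  n_tx <- 0L
  n_gt <- 0L

  push_txn <- function(day, sender, receiver, prod, qty, st, rt) {
    n_tx <<- n_tx + 1L
    tx[[n_tx]] <<- list(day, sender, receiver, prod, qty, st, rt)
  }
  add_group <- function(ent, prod, group) {
    key <- paste0(ent, "\x1f", prod)
    cur <- get0(key, envir = stocks, ifnotfound = list())
    assign(key, c(cur, list(group)), envir = stocks)
  }
  schedule <- function(day, ent, prod, amount) {
    key <- as.character(day)
    cur <- get0(key, envir = sched, ifnotfound = list())
    assign(key, c(cur, list(list(ent = ent, prod = prod, amount = amount))),
           envir = sched)
  }
  stock_amount <- function(ent, prod) {
    key <- paste0(ent, "\x1f", prod)
    groups <- get0(key, envir = stocks, ifnotfound = list())
    sum(vapply(groups, `[[`, numeric(1L), "qty"))
  }
  # draw `amount` units under the policy; returns list of groups (qty capped)
  draw <- function(ent, prod, amount) {
    key <- paste0(ent, "\x1f", prod)
    groups <- get0(key, envir = stocks, ifnotfound = list())
    idx <- if (fifo) seq_along(groups) else rev(seq_along(groups))
    taken <- list()
    need <- amount
    drop <- integer(0)
    for (i in idx) {
      if (need == 0L) break
      g <- groups[[i]]
      take <- min(need, g$qty)
      piece <- g
      piece$qty <- take
      taken[[length(taken) + 1L]] <- piece
      if (take == g$qty) {
        drop <- c(drop, i)
      } else {
        groups[[i]]$qty <- g$qty - take
      }
      need <- need - take
    }
    if (length(drop)) groups <- groups[-drop]
    assign(key, groups, envir = stocks)
    taken
  }
  deliver <- function(day, sender, receiver, prod, part, terminal) {
    pieces <- draw(sender, prod, part)
    for (p in pieces) {
      p$path <- c(p$path, receiver)
      p$dates <- c(p$dates, day)
      if (terminal) {
        n_gt <<- n_gt + 1L
        gt[[n_gt]] <<- list(path = p$path, dates = p$dates, qty = p$qty,
                            prod = prod)
      } else {
        add_group(receiver, prod, p)
      }
    }
  }

  delay_seq <- config$forward_delay[1L]:config$forward_delay[2L]
  size_seq <- config$batch_size[1L]:config$batch_size[2L]

  for (day in 0:(config$horizon_days - 1L)) {
    # 1. manufacturer injections
    for (m in manufacturers) {
      k <- stats::rpois(1L, config$injection_rate)
      if (k == 0L) next
      for (b in seq_len(k)) {
        prod <- resample(products)
        size <- resample(size_seq)
        recv <- resample(distributors)
        push_txn(day, m, recv, prod, size, "manufacturer", "distributor")
        add_group(recv, prod, list(qty = size, path = c(m, recv), dates = day))
        schedule(day + resample(delay_seq),
                 recv, prod, as.integer(ceiling(config$forward_fraction * size)))
      }
    }
    # 2. scheduled dispatches (insertion order)
    events <- get0(as.character(day), envir = sched, ifnotfound = list())
    for (ev in events) {
      amt <- min(ev$amount, stock_amount(ev$ent, ev$prod))
      if (amt < 1L) next
      kmax <- min(config$split_max, amt)
      k <- if (kmax == 1L) 1L else resample(seq_len(kmax))
      parts <- if (k == 1L) amt else {
        cuts <- sort(resample(seq_len(amt - 1L), k - 1L))
        diff(c(0L, cuts, amt))
      }
      others <- setdiff(distributors, ev$ent)
      for (part in parts) {
        term <- stats::runif(1L) < config$p_terminal || length(others) == 0L
        if (term) {
          recv <- resample(finals)
          push_txn(day, ev$ent, recv, ev$prod, part, "distributor",
                   "final_distributor")
          deliver(day, ev$ent, recv, ev$prod, part, terminal = TRUE)
        } else {
          recv <- resample(others)
          push_txn(day, ev$ent, recv, ev$prod, part, "distributor",
                   "distributor")
          deliver(day, ev$ent, recv, ev$prod, part, terminal = FALSE)
          schedule(day + resample(delay_seq), recv, ev$prod,
                   as.integer(ceiling(config$forward_fraction * part)))
        }
      }
    }
  }

  transactions <- tibble::tibble(
    date = origin_date + vapply(tx, `[[`, numeric(1L), 1L),
    sender_id = vapply(tx, `[[`, character(1L), 2L),
    receiver_id = vapply(tx, `[[`, character(1L), 3L),
    product_code = vapply(tx, `[[`, character(1L), 4L),
    quantity = as.integer(vapply(tx, `[[`, numeric(1L), 5L)),
    sender_type = vapply(tx, `[[`, character(1L), 6L),
    receiver_type = vapply(tx, `[[`, character(1L), 7L),
    seq = seq_len(n_tx) - 1L
  )

  ground_truth <- path_records(
    path = lapply(gt, `[[`, "path"),
    dates = lapply(gt, function(g) origin_date + g$dates),
    quantity = vapply(gt, function(g) as.integer(g$qty), integer(1L)),
    exogenous_origin = FALSE,
    product_code = vapply(gt, `[[`, character(1L), "prod")
  )

  keys <- ls(envir = stocks)
  res <- lapply(keys, function(k) {
    groups <- get(k, envir = stocks)
    tot <- sum(vapply(groups, `[[`, numeric(1L), "qty"))
    parts <- strsplit(k, "\x1f", fixed = TRUE)[[1L]]
    tibble::tibble(entity_id = parts[1L], product_code = parts[2L],
                   quantity = as.integer(tot))
  })
  residual <- dplyr::bind_rows(res)
  residual <- residual[residual$quantity > 0L, , drop = FALSE]
  residual <- dplyr::arrange(residual, .data$entity_id, .data$product_code)

  structure(
    list(transactions = transactions, entities = entities,
         ground_truth = ground_truth, residual_stocks = residual,
         config = config),
    class = "path_simulation"
  )
}

#' @export
print.path_simulation <- function(x, ...) {
  cat("<path_simulation> policy =", toupper(x$config$policy),
      "| seed =", x$config$seed, "\n")
  cat("  transactions:", nrow(x$transactions),
      "| completed ground-truth paths:", nrow(x$ground_truth), "\n")
  cat("  residual stock rows:", nrow(x$residual_stocks),
      "(", sum(x$residual_stocks$quantity), "units in transit )\n")
  invisible(x)
}

#' Paired FIFO/LIFO simulations under common random numbers
#'
#' Runs the simulator twice with the same seed, once under each policy. All
#' random draws (injections, delays, splits, receiver choices) are
#' identical; only the dispatch order of physical units differs, so the two
#' runs share one transaction stream and differ only in their ground-truth
#' paths — the paired design used to contrast the two stock-management
#' assumptions.
#'
#' @param config A [simulation_config()]; its `policy` field is overridden.
#' @return A list with elements `fifo` and `lifo`, both `path_simulation`
#'   objects with identical `transactions`.
#' @export
perturb_policy <- function(config) {
  cf <- config; cf$policy <- "fifo"
  cl <- config; cl$policy <- "lifo"
  sf <- simulate_distribution(cf)
  sl <- simulate_distribution(cl)
  stopifnot(identical(sf$transactions, sl$transactions))
  list(fifo = sf, lifo = sl)
}

#' The worked illustrative scenario
#'
#' A scripted five-transaction scenario (no randomness): on day 0 the
#' manufacturer D0 ships a batch of ten units to distributor D1; on day 1,
#' D1 splits it, shipping two units to D2 and five to D3; on day 3, D2 and
#' D3 each ship one unit to the pharmacy D4. Exactly two distribution paths
#' complete — (D0, D1, D2, D4) and (D0, D1, D3, D4), each of length 3 and
#' quantity 1 — while 3, 1 and 4 units remain in stock at D1, D2 and D3.
#'
#' @param origin_date Calendar date of day 0.
#' @return List with `transactions`, `entities`, and `ground_truth`.
#' @export
worked_example <- function(origin_date = as.Date("2006-01-01")) {
  transactions <- tibble::tibble(
    date = origin_date + c(0L, 1L, 1L, 3L, 3L),
    sender_id = c("D0", "D1", "D1", "D2", "D3"),
    receiver_id = c("D1", "D2", "D3", "D4", "D4"),
    product_code = "00001000150",
    quantity = c(10L, 2L, 5L, 1L, 1L),
    sender_type = c("manufacturer", "distributor", "distributor",
                    "distributor", "distributor"),
    receiver_type = c("distributor", "distributor", "distributor",
                      "final_distributor", "final_distributor"),
    seq = 0:4
  )
  entities <- tibble::tibble(
    dea_number = c("D0", "D1", "D2", "D3", "D4"),
    business_activity = c("Manufacturer", "Distributor", "Distributor",
                          "Distributor", "Pharmacy"),
    entity_type = c("manufacturer", "distributor", "distributor",
                    "distributor", "final_distributor"),
    city = NA_character_, state = NA_character_, zip = NA_character_
  )
  ground_truth <- path_records(
    path = list(c("D0", "D1", "D2", "D4"), c("D0", "D1", "D3", "D4")),
    dates = list(origin_date + c(0L, 1L, 3L), origin_date + c(0L, 1L, 3L)),
    quantity = c(1L, 1L),
    product_code = "00001000150"
  )
  list(transactions = transactions, entities = entities,
       ground_truth = ground_truth)
}

#' The batch-combination shortfall scenario
#'
#' A scripted scenario in which a distributor must combine two batches to
#' fill one order: D3 holds a batch of four units (arrived first, from M0)
#' and a batch of two units (arrived later, from M1) and then ships five
#' units to the pharmacy F0. Under FIFO the four oldest units go first and
#' the remaining one is taken from the newer batch, yielding two completed
#' paths with quantities 4 and 1; under LIFO the newer batch's two units go
#' first and three come from the older batch.
#'
#' @param origin_date Calendar date of day 0.
#' @return List with `transactions` and `entities`.
#' @export
shortfall_example <- function(origin_date = as.Date("2006-01-01")) {
  transactions <- tibble::tibble(
    date = origin_date + c(0L, 1L, 2L),
    sender_id = c("M0", "M1", "D3"),
    receiver_id = c("D3", "D3", "F0"),
    product_code = "00001000150",
    quantity = c(4L, 2L, 5L),
    sender_type = c("manufacturer", "manufacturer", "distributor"),
    receiver_type = c("distributor", "distributor", "final_distributor"),
    seq = 0:2
  )
  entities <- tibble::tibble(
    dea_number = c("M0", "M1", "D3", "F0"),
    business_activity = c("Manufacturer", "Manufacturer", "Distributor",
                          "Pharmacy"),
    entity_type = c("manufacturer", "manufacturer", "distributor",
                    "final_distributor"),
    city = NA_character_, state = NA_character_, zip = NA_character_
  )
  list(transactions = transactions, entities = entities)
}

#' Conservation checks for simulations and reconstructions
#'
#' Verifies the unit-conservation laws both the simulator ledger and the
#' reconstruction result must satisfy: delivered units plus residual stock
#' equal the units injected at path origins (manufacturer injections plus
#' any exogenous batches).
#'
#' @param x A `path_simulation` or `path_reconstruction` object.
#' @return `TRUE` invisibly; error describing the violated law otherwise.
#' @export
check_conservation <- function(x) {
  if (inherits(x, "path_simulation")) {
    injected <- sum(x$transactions$quantity[x$transactions$sender_type == "manufacturer"])
    delivered <- sum(x$ground_truth$quantity)
    residual <- sum(x$residual_stocks$quantity)
    if (injected != delivered + residual) {
      stop("simulation conservation violated: injected ", injected,
           " != delivered ", delivered, " + residual ", residual)
    }
  } else if (inherits(x, "path_reconstruction")) {
    d <- x$diagnostics
    injected <- d$n_origin_units + d$n_exogenous_units
    delivered <- sum(x$paths$quantity)
    residual <- sum(x$residual_stocks$quantity)
    if (injected != delivered + residual) {
      stop("reconstruction conservation violated: origin+exogenous ", injected,
           " != delivered ", delivered, " + residual ", residual)
    }
  } else {
    stop("unsupported object")
  }
  invisible(TRUE)
}
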