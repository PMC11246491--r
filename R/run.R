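#' Run a reconstruction from files to per-product JSONL outputs
#'
#' End-to-end driver: loads the transaction and entity tables (file paths
#' or in-memory data frames), runs [reconstruct()] under the chosen policy,
#' and writes one JSONL file per product code into `out_dir` (named
#' `<ndc>.jsonl`, matching the one-file-per-product layout of published
#' path datasets; `merge_output = TRUE` writes a single `paths.jsonl`
#' instead). A machine-readable run summary is written to
#' `summary.json`.
#'
#' Runs are deterministic: the same inputs and policy produce byte-identical
#' outputs.
#'
#' @param transactions,entities File paths or data frames (see
#'   [load_transactions()], [load_entities()]).
#' @param out_dir Output directory (created if needed).
#' @param policy `"fifo"` or `"lifo"`.
#' @param ndc Optional character vector restricting the run to these
#'   product codes.
#' @param merge_output Write a single `paths.jsonl` instead of one file per
#'   product.
#' @param strict Make malformed input rows fatal.
#' @return Invisibly, the `path_reconstruction` object.
#' @export
run_reconstruct <- function(transactions, entities, out_dir,
                            policy = "fifo", ndc = NULL,
                            merge_output = FALSE, strict = FALSE) {
  tx <- if (is.data.frame(transactions)) transactions
        else load_transactions(transactions, strict = strict)
  ents <- if (is.data.frame(entities)) entities else load_entities(entities)
  if (!is.null(ndc)) {
    ndc <- parse_ndc(ndc)$ndc
    tx <- tx[tx$product_code %in% ndc, , drop = FALSE]
  }
  res <- reconstruct(tx, ents, policy = policy)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- res$paths
  if (merge_output || nrow(paths) == 0L) {
    write_paths_jsonl(paths, file.path(out_dir, "paths.jsonl"))
  } else {
    for (code in sort(unique(paths$product_code))) {
      fname <- if (is.na(code)) "unknown-product.jsonl" else paste0(code, ".jsonl")
      write_paths_jsonl(paths[which(paths$product_code %in% code), , drop = FALSE],
                        file.path(out_dir, fname))
    }
  }
  smry <- c(as.list(glance(res)),
            list(residual_stock_units = sum(res$residual_stocks$quantity)))
  jsonlite::write_json(smry, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Compare FIFO and LIFO reconstructions of the same stream
#'
#' Reconstructs the same transaction stream under both stock-management
#' policies and reports their agreement: unique and weighted Jaccard
#' similarity of the completed-path collections (on the entity-sequence
#' identity) and days-in-transit summaries per policy. This is the
#' validation exercise that quantifies how much the FIFO assumption
#' matters.
#'
#' @param transactions,entities File paths or data frames.
#' @param out Optional path for a JSON report.
#' @return A list with `similarity` (one-row tibble: `jaccard_unique`,
#'   `jaccard_weighted`, `jaccard_weighted_quantity`) and `transit` (tibble
#'   with one row per policy).
#' @export
run_validate <- function(transactions, entities, out = NULL) {
  tx <- if (is.data.frame(transactions)) transactions
        else load_transactions(transactions)
  ents <- if (is.data.frame(entities)) entities else load_entities(entities)
  fifo <- reconstruct(tx, ents, policy = "fifo")
  lifo <- reconstruct(tx, ents, policy = "lifo")
  similarity <- tibble::tibble(
    jaccard_unique = jaccard_unique(fifo$paths, lifo$paths),
    jaccard_weighted = jaccard_weighted(fifo$paths, lifo$paths),
    jaccard_weighted_quantity = jaccard_weighted(fifo$paths, lifo$paths,
                                                 weight = "quantity")
  )
  transit <- dplyr::bind_rows(
    dplyr::mutate(transit_time_distribution(fifo$paths)$summary, policy = "fifo"),
    dplyr::mutate(transit_time_distribution(lifo$paths)$summary, policy = "lifo")
  )
  transit <- dplyr::relocate(transit, "policy")
  report <- list(similarity = similarity, transit = transit)
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
  }
  report
}

#' Simulate a distribution process and write its artifacts
#'
#' Runs [simulate_distribution()] and writes the transaction stream
#' (`transactions.csv`), the entity table (`entities.csv`) and the
#' ground-truth paths (`ground_truth.jsonl`) — the same dialects the loader
#' and reconstruction driver consume.
#'
#' @param out_dir Output directory.
#' @param config A [simulation_config()]; built from `seed` when omitted.
#' @param seed Convenience seed when `config` is omitted.
#' @return Invisibly, the `path_simulation` object.
#' @export
run_simulate <- function(out_dir, config = NULL, seed = 1L) {
  if (is.null(config)) config <- simulation_config(seed = seed)
  sim <- simulate_distribution(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sim$transactions, file.path(out_dir, "transactions.csv"),
                   progress = FALSE)
  readr::write_csv(sim$entities, file.path(out_dir, "entities.csv"),
                   progress = FALSE)
  write_paths_jsonl(sim$ground_truth, file.path(out_dir, "ground_truth.jsonl"))
  invisible(sim)
}
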