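# Shared helpers: canonical serializations for exact multiset comparison and
# independent brute-force oracles used against the package implementations.

path_sig <- function(paths) {
  sort(vapply(seq_len(nrow(paths)), function(i) {
    paste(paste(paths$path[[i]], collapse = ">"),
          paste(as.integer(paths$dates[[i]]), collapse = ","),
          paths$quantity[i], sep = "|")
  }, character(1L)))
}

path_key <- function(paths) {
  vapply(paths$path, paste, character(1L), collapse = ">")
}

expect_same_path_multiset <- function(a, b) {
  expect_identical(path_sig(a), path_sig(b))
}

# brute-force Jaccard oracles working on plain key character vectors
oracle_jaccard_unique <- function(ka, kb) {
  ka <- unique(ka); kb <- unique(kb)
  if (!length(ka) && !length(kb)) return(1)
  sum(ka %in% kb) / length(unique(c(ka, kb)))
}
oracle_jaccard_weighted <- function(ka, kb) {
  keys <- unique(c(ka, kb))
  if (!length(keys)) return(1)
  ai <- vapply(keys, function(k) sum(ka == k), numeric(1L))
  bi <- vapply(keys, function(k) sum(kb == k), numeric(1L))
  sum(pmin(ai, bi)) / sum(pmax(ai, bi))
}

# independent great-circle oracle: spherical law of cosines
oracle_gc_km <- function(lat1, lon1, lat2, lon2, r = 6371.0088) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  c <- sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl)
  r * acos(pmin(1, pmax(-1, c)))
}

# build a path tibble from a list of entity-ID vectors with dummy dates
paths_from_keys <- function(key_list, quantity = 1L) {
  path_records(
    path = key_list,
    dates = lapply(key_list, function(p) as.Date("2010-01-01") + seq_len(length(p) - 1L)),
    quantity = quantity
  )
}

table1_csv <- function(path) {
  writeLines(c(
    "date,sender_id,receiver_id,quantity,sender_type,receiver_type",
    "2010-06-22,RM0231821,RM0270037,200,Manufacturer,Distributor",
    "2010-07-29,RM0270037,PR0205559,10,Distributor,Distributor",
    "2010-07-16,RO0153609,AA1680049,1,Distributor,Hospital",
    "2010-10-11,PR0205559,BP3701047,2,Distributor,Pharmacy"
  ), path)
  path
}
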