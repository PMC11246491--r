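test_that("unique Jaccard matches hand enumeration and its conventions", {
  a <- paths_from_keys(list(c("M", "D1", "F"), c("M", "D2", "F")))
  b <- paths_from_keys(list(c("M", "D2", "F"), c("M", "D3", "F")))
  expect_equal(jaccard_unique(a, b), 1 / 3)  # intersection 1, union 3
  expect_equal(jaccard_unique(a, a), 1)
  disjoint <- paths_from_keys(list(c("X", "Y")))
  expect_equal(jaccard_unique(a, disjoint), 0)
  empty <- paths_from_keys(list())
  expect_equal(jaccard_unique(empty, empty), 1)
  expect_equal(jaccard_unique(empty, a), 0)
})

test_that("weighted Jaccard evaluates the min/max multiplicity ratio", {
  # multiplicities a = (2, 0, 1), b = (1, 1, 1) -> (1+0+1)/(2+1+1) = 0.5
  a <- paths_from_keys(list(c("p1", "x"), c("p1", "x"), c("p3", "x")))
  b <- paths_from_keys(list(c("p1", "x"), c("p2", "x"), c("p3", "x")))
  expect_equal(jaccard_weighted(a, b), 0.5)
  expect_equal(jaccard_weighted(a, a), 1)
  expect_equal(jaccard_weighted(paths_from_keys(list()), a), 0)
  # quantity weighting uses delivered units as multiplicity
  aq <- paths_from_keys(list(c("p1", "x")), quantity = 4L)
  bq <- paths_from_keys(list(c("p1", "x")), quantity = 1L)
  expect_equal(jaccard_weighted(aq, bq, weight = "quantity"), 0.25)
})

test_that("both Jaccard variants match brute-force oracles on random multisets", {
  set.seed(2024)
  pool <- lapply(1:8, function(i) c("M", paste0("D", i), "F"))
  for (rep in 1:30) {
    ka <- sample(1:8, sample(0:10, 1), replace = TRUE)
    kb <- sample(1:8, sample(0:10, 1), replace = TRUE)
    a <- paths_from_keys(pool[ka])
    b <- paths_from_keys(pool[kb])
    sa <- path_key(a); sb <- path_key(b)
    expect_equal(jaccard_unique(a, b), oracle_jaccard_unique(sa, sb))
    expect_equal(jaccard_weighted(a, b), oracle_jaccard_weighted(sa, sb))
    # symmetry and bounds
    expect_equal(jaccard_unique(a, b), jaccard_unique(b, a))
    expect_equal(jaccard_weighted(a, b), jaccard_weighted(b, a))
    expect_true(jaccard_weighted(a, b) >= 0 && jaccard_weighted(a, b) <= 1)
    # with 0/1 multiplicities the two variants coincide
    ua <- paths_from_keys(pool[unique(ka)])
    ub <- paths_from_keys(pool[unique(kb)])
    expect_equal(jaccard_weighted(ua, ub), jaccard_unique(ua, ub))
  }
})

test_that("path-length histograms count distribution steps and conserve records", {
  wx <- worked_example()
  res <- reconstruct(wx$transactions, wx$entities)
  h <- path_length_histogram(res$paths)
  expect_equal(h$length, 3L)
  expect_equal(h$count, 2L)
  expect_equal(attr(h, "mean_length"), 3)

  empty <- path_length_histogram(paths_from_keys(list()))
  expect_equal(nrow(empty), 0L)
  expect_true(is.na(attr(empty, "mean_length")))

  sim <- simulate_distribution(simulation_config(seed = 3, horizon_days = 40))
  hs <- path_length_histogram(sim$ground_truth)
  expect_equal(sum(hs$count), nrow(sim$ground_truth))
  # independent tally
  lens <- lengths(sim$ground_truth$path) - 1L
  for (i in seq_len(nrow(hs))) {
    expect_equal(hs$count[i], sum(lens == hs$length[i]))
  }
})

test_that("great-circle distances match an independent law-of-cosines oracle", {
  expect_equal(great_circle_km(40, -100, 40, -100), 0)
  # antipodal points: half the circumference of the 6371.0088 km sphere
  expect_equal(great_circle_km(0, 0, 0, 180), pi * 6371.0088, tolerance = 1e-9)
  set.seed(77)
  lat1 <- runif(200, -89, 89); lon1 <- runif(200, -179, 179)
  lat2 <- runif(200, -89, 89); lon2 <- runif(200, -179, 179)
  d <- great_circle_km(lat1, lon1, lat2, lon2)
  o <- oracle_gc_km(lat1, lon1, lat2, lon2)
  expect_true(all(abs(d - o) < 1e-6))
  # symmetry and triangle inequality on random triples
  expect_equal(d, great_circle_km(lat2, lon2, lat1, lon1))
  lat3 <- runif(200, -89, 89); lon3 <- runif(200, -179, 179)
  d13 <- great_circle_km(lat1, lon1, lat3, lon3)
  d32 <- great_circle_km(lat3, lon3, lat2, lon2)
  expect_true(all(d <= d13 + d32 + 1e-9))
  expect_error(great_circle_km(95, 0, 0, 0), "out of range")
})

test_that("per-path distances, step means and CCDF follow their definitions", {
  # place D1 100 km east of M along the equator, F 50 km further
  km_per_deg <- pi * 6371.0088 / 180
  coords <- tibble::tibble(
    dea_number = c("M", "D1", "F"),
    lat = 0,
    lon = c(0, 100 / km_per_deg, 150 / km_per_deg)
  )
  p <- paths_from_keys(list(c("M", "D1", "F")))
  pd <- path_distances(p, coords)
  expect_equal(pd$per_path$total_km, 150, tolerance = 1e-9)
  expect_equal(pd$step_means$mean_km, c(100, 50), tolerance = 1e-9)
  expect_equal(pd$n_skipped, 0L)

  # same coordinate four times: zero distance
  same <- paths_from_keys(list(c("M", "M2", "M3", "M4")))
  coords4 <- tibble::tibble(dea_number = c("M", "M2", "M3", "M4"),
                            lat = 10, lon = 20)
  expect_equal(path_distances(same, coords4)$per_path$total_km, 0)

  # unknown entity: path skipped and counted
  missing <- paths_from_keys(list(c("M", "ZZZ")))
  expect_equal(path_distances(missing, coords)$n_skipped, 1L)

  # CCDF at 0 is the fraction of paths with positive distance; nonincreasing
  mixed <- paths_from_keys(list(c("M", "D1"), c("M", "M")))
  cc <- path_distances(mixed, coords)$ccdf
  expect_equal(cc$ccdf[cc$value == 0], 0.5)
  expect_true(all(diff(cc$ccdf) <= 0))
  expect_true(all(cc$ccdf >= 0 & cc$ccdf <= 1))
})

test_that("days in transit span first to last shipping date", {
  single <- paths_from_keys(list(c("M", "F")))
  expect_equal(transit_time_distribution(single)$per_path$days, 0L)

  wx <- worked_example()
  res <- reconstruct(wx$transactions, wx$entities)
  tt <- transit_time_distribution(res$paths)
  expect_equal(tt$per_path$days, c(3L, 3L))
  expect_equal(tt$summary$median, 3)
  expect_equal(sum(tt$pdf$prob), 1)
  expect_true(all(diff(tt$ccdf$ccdf) <= 0))
})

test_that("entry and exit rates follow the previous-year-denominator convention", {
  act <- tibble::tibble(year = c(2006, 2006, 2007, 2007),
                        entity_id = c("a", "b", "b", "c"))
  r <- entry_exit_rates(act)
  expect_equal(r$entry_rate, c(NA, 0.5))
  expect_equal(r$exit_rate, c(NA, 0.5))

  same <- tibble::tibble(year = rep(2006:2007, each = 2),
                         entity_id = rep(c("a", "b"), 2))
  rs <- entry_exit_rates(same)
  expect_equal(rs$entry_rate[2], 0)
  expect_equal(rs$exit_rate[2], 0)

  gap <- tibble::tibble(year = c(2006, 2008), entity_id = "a")
  expect_error(entry_exit_rates(gap), "consecutive")
  expect_error(entry_exit_rates(tibble::tibble(year = 2006, entity_id = "a")),
               "2 years")

  # growth scenario: more entries than exits -> active count increases
  grow <- tibble::tibble(
    year = c(rep(2006, 2), rep(2007, 3), rep(2008, 4)),
    entity_id = c("a", "b", "a", "b", "c", "a", "b", "c", "d")
  )
  rg <- entry_exit_rates(grow)
  expect_true(all(rg$entry_rate[-1] > rg$exit_rate[-1]))
  expect_true(all(diff(rg$n_active) > 0))
})

test_that("year-to-year similarity applies unique Jaccard to consecutive pairs", {
  p <- paths_from_keys(list(c("M", "D1", "F"), c("M", "D2", "F")))
  identical_years <- list(`2006` = p, `2007` = p, `2008` = p)
  s <- year_to_year_similarity(identical_years)
  expect_equal(s$jaccard, c(1, 1))
  smry <- attr(s, "summary")
  expect_equal(smry$median, 1)

  q <- paths_from_keys(list(c("X", "Y")))
  disjoint_years <- list(`2006` = p, `2007` = q)
  expect_equal(year_to_year_similarity(disjoint_years)$jaccard, 0)

  # half-replacement turnover: J = k / 3k = 1/3 exactly by construction
  pool <- lapply(1:60, function(i) c("M", paste0("D", i), "F"))
  y1 <- paths_from_keys(pool[1:40])
  y2 <- paths_from_keys(pool[21:60])  # keeps 20 of 40, adds 20 new
  s2 <- year_to_year_similarity(list(`2006` = y1, `2007` = y2))
  expect_equal(s2$jaccard, 1 / 3)
})

test_that("yearly activity tables are per-year with no cross-year leakage", {
  tx <- tibble::tibble(
    date = as.Date(c("2006-03-01", "2007-03-01")),
    sender_id = c("M1", "M2"), receiver_id = c("D1", "D1"),
    quantity = 1L
  )
  act <- yearly_activity(tx)
  expect_setequal(act$entity_id[act$year == 2006], c("M1", "D1"))
  expect_setequal(act$entity_id[act$year == 2007], c("M2", "D1"))
  restricted <- yearly_activity(tx, ids = c("M1", "M2"))
  expect_setequal(restricted$entity_id, c("M1", "M2"))
})
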