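suit_grid <- function(values, nrows, ncols, yll = 30, cs = 0.5) {
  env_grid(matrix(values, nrows, ncols), 100, yll, cs, name = "p")
}

test_that("classification follows the four half-open bands", {
  g <- suit_grid(c(0.05, 0.2, 0.4, 0.6), 2, 2)
  cl <- classify_suitability(g)
  expect_equal(sort(as.vector(cl$grid$values)), c(0, 1, 2, 3))
  expect_equal(sum(cl$counts), 4)

  # boundaries: 0.1 -> low, 0.3 -> medium, 0.5 -> high, 0.05 -> unsuitable
  b <- suit_grid(c(0.05, 0.1, 0.3, 0.5), 2, 2)
  cb <- classify_suitability(b)
  expect_equal(sort(as.vector(cb$grid$values)), c(0, 1, 2, 3))
  expect_equal(cb$grid$values[matrix(c(2, 2), 1)], 3)  # p = 0.5 is high

  expect_error(classify_suitability(suit_grid(c(0.2, 1.2, 0.3, 0), 2, 2)),
               "outside")
})

test_that("nodata passes through classification", {
  g <- suit_grid(c(0.2, NA, 0.7, 0.0), 2, 2)
  cl <- classify_suitability(g)
  expect_true(is.na(cl$grid$values[2, 1]))
  expect_equal(sum(cl$counts), 3)
})

test_that("class areas conserve the masked grid area and honour geometry", {
  set.seed(8)
  g <- suit_grid(runif(400), 20, 20, yll = 28, cs = 0.25)
  g$values[sample(400, 25)] <- NA
  cl <- classify_suitability(g)
  a <- class_areas(cl)
  total_masked <- sum(cell_area_km2(g$header, seq_len(20)) *
                        rowSums(!is.na(g$values))) / 1e4
  expect_equal(sum(a$areas), total_masked, tolerance = 1e-6 * total_masked)
  expect_equal(a$total_suitable,
               a$areas[["low"]] + a$areas[["medium"]] + a$areas[["high"]],
               tolerance = 1e-12)
  expect_true(all(a$areas >= 0))
})

test_that("an empty class contributes zero area", {
  g <- suit_grid(rep(0.05, 4), 2, 2)
  a <- class_areas(classify_suitability(g))
  expect_equal(a$areas[["high"]], 0)
  expect_equal(a$total_suitable, 0)
})

test_that("area summaries reproduce the reference-table arithmetic", {
  cur <- area_summary(low = 98.51, medium = 57.98, high = 31.62,
                      unsuitable = 771.89)
  expect_equal(round(cur$total_suitable, 2), 188.11)
  fut <- area_summary(low = 167.44, medium = 100.61, high = 36.86,
                      unsuitable = 655.08, baseline = cur)
  expect_equal(round(fut$total_suitable, 2), 304.91)
  expect_equal(round(fut$delta_total, 2), 116.80)
  expect_equal(round(fut$delta[["high"]], 2), 5.24)
})

test_that("binary maps use the strict > 0.5 rule", {
  g <- suit_grid(c(0.5, 0.51, 0.49, NA), 2, 2)
  b <- binary_map(g)
  expect_equal(b$values[1, 1], 0)  # exactly 0.5 is absent
  expect_equal(b$values[2, 1], 1)
  expect_equal(b$values[1, 2], 0)
  expect_true(is.na(b$values[2, 2]))

  empty <- binary_map(suit_grid(rep(0, 4), 2, 2))
  expect_equal(sum(empty$values), 0)
})

test_that("binary-map presence area equals the high-class area off the boundary", {
  set.seed(12)
  v <- runif(100)
  v[abs(v - 0.5) < 0.01] <- 0.6  # keep away from the 0.5 boundary
  g <- suit_grid(v, 10, 10)
  ar_high <- class_areas(classify_suitability(g))$areas[["high"]]
  bin <- binary_map(g)
  h <- g$header
  ar_bin <- sum(cell_area_km2(h, seq_len(10)) *
                  rowSums(bin$values == 1)) / 1e4
  expect_equal(ar_bin, ar_high, tolerance = 1e-9)
})

test_that("change maps satisfy the exact accounting identities", {
  set.seed(19)
  for (rep in 1:5) {
    cur <- binary_map(suit_grid(runif(144), 12, 12))
    fut <- binary_map(suit_grid(runif(144), 12, 12))
    cm <- change_map(cur, fut)
    s <- cm$summary
    h <- cur$header
    area_of <- function(bin) sum(cell_area_km2(h, seq_len(12)) *
                                   rowSums(bin$values == 1)) / 1e4
    expect_equal(s$retention + s$contraction, area_of(cur), tolerance = 1e-9)
    expect_equal(s$retention + s$expansion, area_of(fut), tolerance = 1e-9)
    expect_equal(s$net, s$expansion - s$contraction, tolerance = 1e-12)
    # category exclusivity
    expect_true(all((cm$grid$values %in% 0:3) | is.na(cm$grid$values)))
  }
})

test_that("identical ranges give a zero change map", {
  cur <- binary_map(suit_grid(runif(36), 6, 6))
  cm <- change_map(cur, cur)
  expect_equal(cm$summary$expansion, 0)
  expect_equal(cm$summary$contraction, 0)
  expect_equal(cm$summary$net, 0)
})

test_that("change summaries reproduce the reference net changes", {
  expect_equal(change_summary(25.91, 33.25, 22.33)$net, 3.58, tolerance = 1e-9)
  expect_equal(change_summary(18.48, 30.50, 25.08)$net, -6.60, tolerance = 1e-9)
})

test_that("mismatched headers are an alignment error", {
  a <- binary_map(suit_grid(runif(4), 2, 2))
  b <- binary_map(env_grid(matrix(runif(4), 2, 2), 100, 30, 0.25, name = "p"))
  expect_error(change_map(a, b), "cellsize")
})

test_that("centroids are geometric centres with area weights", {
  # a single presence cell: its centre
  g <- suit_grid(c(1, 0, 0, 0), 2, 2, yll = 30, cs = 0.5)  # presence at NW
  ct <- range_centroid(g)
  expect_equal(ct[["longitude"]], 100.25)
  expect_equal(ct[["latitude"]], 30.75)

  # two equal-latitude cells symmetric about lon 100.5: centroid on 100.5
  g2 <- suit_grid(c(1, 0, 1, 0), 2, 2)
  g2$values[] <- 0; g2$values[1, 1] <- 1; g2$values[1, 2] <- 1
  expect_equal(range_centroid(g2)[["longitude"]], 100.5)

  # two cells at different latitudes: area weighting pulls the centroid
  # below the unweighted midpoint (lower-latitude cell is larger)
  g3 <- suit_grid(rep(0, 4), 2, 2, yll = 40, cs = 1)
  g3$values[1, 1] <- 1; g3$values[2, 1] <- 1
  ctw <- range_centroid(g3)
  ctu <- range_centroid(g3, area_weighted = FALSE)
  a_top <- cell_area_km2(g3$header, 1); a_bot <- cell_area_km2(g3$header, 2)
  want <- (41.5 * a_top + 40.5 * a_bot) / (a_top + a_bot)
  expect_equal(ctw[["latitude"]], want, tolerance = 1e-12)
  expect_equal(ctu[["latitude"]], 41)
  expect_lt(ctw[["latitude"]], ctu[["latitude"]])

  expect_error(range_centroid(binary_map(suit_grid(rep(0, 4), 2, 2))),
               "empty")
})

test_that("migration vectors report oracle distances and bearings", {
  skip_if_not_installed("geosphere")
  mv0 <- migration_vector(c(107, 31), c(107, 31))
  expect_equal(mv0$distance_km, 0)

  mv1 <- migration_vector(c(100, 30), c(100, 31))
  expect_equal(mv1$distance_km, 111.19, tolerance = 1e-3)
  expect_equal(mv1$bearing_deg, 0)

  # reference centroid pair, against the independent great-circle oracle
  mv2 <- migration_vector(c(109.413, 31.876), c(107.194, 31.713))
  expect_equal(mv2$distance_km,
               dist_oracle_km(109.413, 31.876, 107.194, 31.713),
               tolerance = 1e-6)
  expect_true(mv2$bearing_deg >= 0 && mv2$bearing_deg < 360)
})
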