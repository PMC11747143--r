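test_that("bin assignment follows the upper-inclusive convention", {
  expect_equal(assign_bin(0.5), "0-1")
  expect_equal(assign_bin(0), "0-1")
  expect_equal(assign_bin(1.0), "0-1")   # closed upper edge of the lowest bin
  expect_equal(assign_bin(c(1.01, 3, 5, 7, 9)), c("1-3", "1-3", "3-5", "5-7", "7-9"))
  expect_true(is.na(assign_bin(9.5)))
  expect_error(assign_bin(-0.1), "negative")
})

test_that("window lengths: summer is always 123, calendar follows the leap rule", {
  for (y in 2016:2020) expect_equal(window_days(exposure_window("summer", y)), 123)
  expect_equal(window_days(exposure_window("calendar", 2017)), 365)
  expect_equal(window_days(exposure_window("calendar", 2016)), 366)
})

test_that("total and max-consecutive counts match hand counts", {
  w <- exposure_window("summer", 2018)
  s <- make_series(c(4, 4, 6, 4, 4, 4, rep(10, 117)))
  expect_equal(max_consecutive_days_in_bin(s, w, "3-5"), 3)
  expect_equal(total_days_in_bin(s, w, "3-5"), 5)

  const <- make_series(rep(10, 123))
  for (b in salinity_bins()$label) {
    expect_equal(total_days_in_bin(const, w, b), 0)
  }
  for (lv in c(1, 3, 5, 7, 9)) expect_equal(total_days_below(const, w, lv), 0)
})

test_that("missing days are excluded from totals and break runs", {
  vals <- rep(4, 123)
  vals[10] <- NA
  s <- make_series(vals)
  s <- s[!is.na(s$salinity), ]
  w <- exposure_window("summer", 2018)
  expect_equal(total_days_in_bin(s, w, "3-5"), 122)
  expect_equal(max_consecutive_days_in_bin(s, w, "3-5"), 113)
})

test_that("a window with no overlap with the series errors", {
  s <- make_series(rep(5, 30), start = "2018-01-01")
  expect_error(total_days_in_bin(s, exposure_window("summer", 2019), "3-5"),
               "outside the series")
})

test_that("counts satisfy partition, monotonicity and ordering invariants", {
  set.seed(31)
  w <- exposure_window("summer", 2018)
  for (rep in 1:25) {
    vals <- round(runif(200, 0, 12), 3)
    miss <- sample(200, 20)
    s <- make_series(vals, start = "2018-04-01")[-miss, ]
    wl <- window_days(w)
    wv <- s$salinity[match(window_dates(w), s$date)]
    n_miss <- sum(is.na(wv))
    totals <- vapply(salinity_bins()$label, function(b)
      total_days_in_bin(s, w, b), numeric(1))
    above9 <- sum(wv > 9, na.rm = TRUE)
    expect_equal(sum(totals) + above9 + n_miss, wl)
    below <- vapply(c(1, 3, 5, 7, 9), function(lv)
      total_days_below(s, w, lv), numeric(1))
    expect_true(all(diff(below) >= 0))
    for (b in salinity_bins()$label) {
      mx <- max_consecutive_days_in_bin(s, w, b)
      expect_lte(mx, total_days_in_bin(s, w, b))
      expect_lte(total_days_in_bin(s, w, b), wl)
    }
  }
})

test_that("counts agree with the brute-force oracle on random series", {
  set.seed(77)
  bins <- salinity_bins()
  w <- exposure_window("summer", 2018)
  for (rep in 1:40) {
    vals <- round(runif(200, 0, 11), 2)
    if (rep %% 3 == 0) vals[sample(200, 15)] <- NA
    s <- make_series(vals, start = "2018-04-01")
    s <- s[!is.na(s$salinity), ]
    wv <- vals[match(window_dates(w), as.Date("2018-04-01") + 0:199)]
    for (i in seq_len(nrow(bins))) {
      expect_equal(total_days_in_bin(s, w, bins$label[i]),
                   oracle_total_days(wv, bins$lower[i], bins$upper[i], i == 1))
      expect_equal(max_consecutive_days_in_bin(s, w, bins$label[i]),
                   oracle_max_consecutive(wv, bins$lower[i], bins$upper[i], i == 1))
    }
  }
})

test_that("the exposure table has the documented shape and naming", {
  s <- make_series(rep(c(0.5, 2, 4, 6, 8, 10), length.out = 365),
                   start = "2018-01-01")
  et <- build_exposure_table(s)
  expect_equal(ncol(et), 3 + 10)  # 5 bins x {total, consecutive}, summer only
  expect_true(all(c("s_d_su7.9", "c.d_su7.9", "s_d_su0.1") %in% names(et)))
  et2 <- build_exposure_table(s, window_kinds = c("summer", "calendar"))
  expect_equal(ncol(et2), 3 + 20)
  expect_true(all(c("s_d_an7.9", "c.d_an7.9") %in% names(et2)))
  # row-level invariants
  for (nm in grep("^c\\.d_su", names(et), value = TRUE)) {
    tot <- sub("^c\\.d_", "s_d_", nm)
    expect_true(all(et[[nm]] <= et[[tot]]))
    expect_true(all(et[[tot]] <= 123))
  }
  empty <- build_exposure_table(s[0, ])
  expect_equal(nrow(empty), 0)
  expect_equal(ncol(empty), 13)
})

test_that("exposure column names parse back to their parts", {
  p <- oysterthresh:::parse_exposure_column("c.d_su7.9")
  expect_equal(p$kind, "continuous")
  expect_equal(p$window, "summer")
  expect_equal(c(p$lower, p$upper), c(7, 9))
  p2 <- oysterthresh:::parse_exposure_column("s_d_anlt5")
  expect_equal(p2$kind, "total")
  expect_equal(p2$level, 5)
  expect_error(oysterthresh:::parse_exposure_column("abundance"), "not an exposure column")
})

test_that("below-level columns can be added and respect strict inequality", {
  s <- make_series(c(rep(5, 60), rep(4.999, 63)))
  w <- exposure_window("summer", 2018)
  expect_equal(total_days_below(s, w, 5), 63)
  et <- build_exposure_table(s, below = c(5, 9))
  expect_true(all(c("s_d_sult5", "c.d_sult5", "s_d_sult9") %in% names(et)))
  expect_equal(et$s_d_sult5[1], 63)
  expect_equal(et$s_d_sult9[1], 123)
})
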