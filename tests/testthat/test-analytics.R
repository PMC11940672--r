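test_that("normalize_series scales to the initial value", {
  expect_equal(normalize_series(c(2, 4, 6)), c(1, 2, 3))
  expect_equal(normalize_series(c(7, 7, 7)), c(1, 1, 1))
  expect_equal(normalize_series(c(5, 2.5, 0.5)), c(1, 0.5, 0.1))
  expect_warning(out <- normalize_series(c(0, 2, 4)), "max-normalization")
  expect_equal(out, c(0, 0.5, 1))
  fs <- fluor_series(0:2, c(2, 4, 6), c(10, 20, 30))
  nfs <- normalize_series(fs)
  expect_equal(nfs$index_values, c(1, 2, 3))
  expect_equal(nfs$od_values, c(1, 2, 3))
})

test_that("trend sign table: contamination, degradation, growth, flat", {
  t <- c(0, 6, 12, 18)
  contam <- fluor_series(t, c(1, 0.7, 0.4, 0.1), c(1, 1.2, 1.5, 1.9))
  expect_equal(classify_trend(contam)$label, "contamination")
  degr <- fluor_series(t, c(1, 0.8, 0.5, 0.2), c(1, 0.9, 0.7, 0.5))
  expect_equal(classify_trend(degr)$label, "degradation")
  grow <- fluor_series(t, c(1, 1.2, 1.4, 1.7), c(1, 1.3, 1.7, 2.2))
  expect_equal(classify_trend(grow)$label, "healthy_growth")
  flat <- fluor_series(t, rep(3, 4), rep(0.4, 4))
  expect_equal(classify_trend(flat)$label, "indeterminate")
  expect_error(classify_trend(fluor_series(0:2, 1:3, 1:3)), "at least 4")
})

test_that("classification is invariant to positive rescaling of either series", {
  t <- seq(0, 23)
  set.seed(3)
  od <- 1 + 0.05 * t + rnorm(24, 0, 0.01)
  f <- 1 - 0.03 * t + rnorm(24, 0, 0.01)
  v0 <- classify_trend(fluor_series(t, f, od))
  v1 <- classify_trend(fluor_series(t, 37 * f, od))
  v2 <- classify_trend(fluor_series(t, f, 0.2 * od))
  expect_equal(v0$label, "contamination")
  expect_equal(v1$label, v0$label)
  expect_equal(v2$label, v0$label)
  expect_equal(v1$od_slope, v0$od_slope)
})

test_that("verdict reports onset and a confidence in [0, 1]", {
  t <- seq(0, 23)
  f <- c(rep(1, 8), 1 - 0.06 * (1:16))     # decline starts at t = 8
  od <- 1 + 0.04 * t
  v <- classify_trend(fluor_series(t, f, od))
  expect_equal(v$label, "contamination")
  expect_gte(v$confidence, 0)
  expect_lte(v$confidence, 1)
  expect_false(is.na(v$onset_h))
  expect_gte(v$onset_h, 8)
})

test_that("nearest-LED selection reproduces every reference assignment", {
  tbl <- fluorophore_table()
  expected <- c(quinine = 373, rhodamine_6g = 520, rhodamine_b = 520,
                phycocyanin = 615, chlorophyll = 451)
  for (nm in names(expected))
    expect_equal(select_excitation_led(tbl[[nm]])$peak_nm,
                 unname(expected[nm]), info = nm)
})

test_that("LED selection uses the primary maximum and breaks ties short", {
  # chlorophyll's 661 nm secondary maximum is nearer the 657 nm channel,
  # but the primary 429 nm maximum rules
  chl <- fluorophore_table()$chlorophyll
  expect_equal(select_excitation_led(chl)$peak_nm, 451)
  one <- list(led_channel("only", 373, 100))
  expect_equal(select_excitation_led(chl, one)$peak_nm, 373)
  tie_bank <- list(led_channel("a", 500, 100), led_channel("b", 540, 100))
  fl <- fluorophore("f", 520, 600)
  expect_equal(select_excitation_led(fl, tie_bank)$led_id, "a")
  expect_error(select_excitation_led(fl, list()), "empty")
})

test_that("estimate_lod matches the blank-SD convention exactly", {
  cal <- data.frame(concentration = c(0, 10, 20, 30),
                    index = 0.16 * c(0, 10, 20, 30))
  blanks <- c(-2, 0, 2)                     # sd exactly 2
  lod <- estimate_lod(cal, blanks)
  expect_equal(lod$lod_cells_per_ul, 3.3 * 2 / 0.16)   # 41.25
  expect_equal(lod$slope, 0.16)
  expect_equal(lod$r_squared, 1)
  expect_equal(estimate_lod(cal, blanks, k = 3)$lod_cells_per_ul,
               3 * 2 / 0.16)
  expect_equal(estimate_lod(cal, c(1, 1, 1))$lod_cells_per_ul, 0)
})

test_that("estimate_lod is scale-equivariant and rejects flat signals", {
  cal <- data.frame(concentration = c(0, 5, 10, 20),
                    index = c(0.01, 0.05, 0.11, 0.19))
  blanks <- c(0.008, 0.012, 0.011, 0.009)
  base <- estimate_lod(cal, blanks)$lod_cells_per_ul
  scaled_idx <- cal; scaled_idx$index <- scaled_idx$index * 7
  expect_equal(estimate_lod(scaled_idx, blanks * 7)$lod_cells_per_ul, base)
  scaled_conc <- cal; scaled_conc$concentration <- scaled_conc$concentration * 3
  expect_equal(estimate_lod(scaled_conc, blanks)$lod_cells_per_ul, 3 * base)
  flat <- cal; flat$index <- rep(0.01, 4)
  expect_error(estimate_lod(flat, blanks), "not positive")
  expect_error(estimate_lod(cal[cal$concentration < 6, ], blanks),
               "3 distinct")
})
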