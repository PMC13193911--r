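fit_small_model <- function(seed = 101, n = 80) {
  co <- generate_cohort(strong_signal_params(n, seed = seed))$cohort
  list(model = gklc(co, control = forest_control(n_trees = 60, seed = seed + 1)),
       cohort = co)
}

test_that("dose grids enumerate the feasible candidates", {
  expect_length(build_dose_grid(10, 18, 0.5)$candidates, 17)
  expect_equal(build_dose_grid(14, 14, 1)$candidates, 14)
  expect_equal(build_dose_grid(10, 18, 7)$candidates, c(10, 17))
  expect_error(build_dose_grid(18, 10, 1), "inverted")
  expect_error(build_dose_grid(10, 18, 0), "step")
})

test_that("dose injection recomputes interactions and the dosimetric maximum", {
  ms <- fit_small_model()
  rec <- ms$cohort[1, , drop = FALSE]
  rec$volume_cm3 <- 10; rec$kps <- 80; rec$isodose_pct <- 50
  rec$dose_gy <- 14; rec$max_gy <- 28
  ft <- inject_dose(rec, 16, ms$model$encoder)
  expect_equal(unname(ft$x[1, "dose_x_vol"]), 160)
  expect_equal(unname(ft$x[1, "dose_x_kps"]), 1280)
  expect_equal(unname(ft$x[1, "max_gy"]), 32)
  expect_equal(unname(ft$x[1, "dose_gy"]), 16)
})

test_that("injecting the observed dose reproduces the plain transform", {
  ms <- fit_small_model(seed = 102)
  rec <- ms$cohort[3, , drop = FALSE]
  # generated plans satisfy max = dose / (isodose/100) exactly
  plain <- encode_cohort(ms$model$encoder, rec)
  injected <- inject_dose(rec, rec$dose_gy, ms$model$encoder)
  expect_equal(injected$x, plain$x)
})

test_that("doses outside the feasible grid are rejected", {
  ms <- fit_small_model(seed = 103)
  grid <- build_dose_grid(10, 18, 0.5)
  expect_error(inject_dose(ms$cohort[1, , drop = FALSE], 25,
                           ms$model$encoder, grid),
               "outside the feasible range")
})

test_that("a sweep evaluates every candidate and a single-dose grid reduces to one prediction", {
  ms <- fit_small_model(seed = 104)
  rec <- ms$cohort[2, , drop = FALSE]
  grid <- build_dose_grid(10, 18, 0.5)
  sw <- sweep_doses(ms$model, rec, grid)
  expect_equal(nrow(sw$table), 17)
  expect_true(all(is.finite(sw$table$utility)))
  expect_equal(sw$table$utility,
               vapply(sw$curves, function(cu) lc_probability_at(cu, 12), 0))
  one <- sweep_doses(ms$model, rec, build_dose_grid(14, 14, 1))
  expect_equal(nrow(one$table), 1)
  expect_equal(recommend(one)$dose_gy, 14)
})

test_that("the expected-LC utility matches the case summaries", {
  ms <- fit_small_model(seed = 105)
  sw <- sweep_doses(ms$model, ms$cohort[1, , drop = FALSE],
                    build_dose_grid(12, 14, 1), utility = "expected_lc")
  expect_equal(sw$table$utility,
               vapply(sw$summaries, `[[`, 0, "expected_lc_months"))
})

test_that("recommendation tie-breaks toward the lowest dose within tolerance", {
  base <- fit_small_model(seed = 106)
  sw <- sweep_doses(base$model, base$cohort[1, , drop = FALSE],
                    build_dose_grid(10, 12, 1))
  # strictly increasing utilities -> maximum dose
  sw$table$utility <- c(0.2, 0.4, 0.6)
  expect_equal(recommend(sw)$dose_gy, 12)
  # all equal -> minimum dose
  sw$table$utility <- rep(0.5, 3)
  expect_equal(recommend(sw)$dose_gy, 10)
  # within-tolerance preference for the lower dose
  sw$table$utility <- c(0.60, 0.701, 0.703)
  rec <- recommend(sw, tie_tol = 0.005)
  expect_equal(rec$dose_gy, 11)
  expect_match(rec$note, "lowest dose preferred")
  # ranked table is utility-descending, recommendation flagged
  expect_equal(rec$ranked$utility, sort(rec$ranked$utility, decreasing = TRUE))
  expect_equal(rec$ranked$dose_gy[rec$ranked$recommended], 11)
  # pure function of the sweep
  expect_identical(recommend(sw, 0.005), rec)
})

test_that("exports round-trip at full precision and flag the recommended dose", {
  ms <- fit_small_model(seed = 107)
  grid <- build_dose_grid(11, 15, 1)
  sw <- sweep_doses(ms$model, ms$cohort[1, , drop = FALSE], grid)
  rec <- recommend(sw)
  path <- withr::local_tempfile(fileext = ".csv")
  export_candidates(sw, rec, path)
  tab <- read.csv(path)
  expect_equal(nrow(tab), length(grid$candidates))
  expect_equal(tab$utility, sw$table$utility)
  expect_equal(tab$dose_gy[tab$recommended == "TRUE" | tab$recommended == TRUE],
               rec$dose_gy)
  expect_equal(tab$lc_12m, vapply(sw$summaries, function(s) unname(s$lc_at["lc_12m"]), 0))
  curve <- read.csv(sub("\\.csv$", "_curve.csv", path))
  expect_equal(curve$time_months, rec$curve$time)
  expect_equal(curve$lc_probability, rec$curve$surv[1, ])
  meta <- jsonlite::fromJSON(paste0(path, ".meta.json"))
  expect_equal(meta$recommended_dose_gy, rec$dose_gy)
  expect_match(meta$conventions$coverage, "held fixed")
})
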