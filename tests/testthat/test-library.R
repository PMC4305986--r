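test_that("synthetic libraries have the requested sizes and valid entries", {
  lib <- generate_library(C = 6, R = 5, A = 5, seed = 31)
  expect_s3_class(lib, "component_library")
  expect_equal(nrow(lib_class(lib, "constitutive")), 6L)
  expect_equal(nrow(lib_class(lib, "repressor_regulated")), 5L)
  expect_equal(nrow(lib_class(lib, "activator_regulated")), 5L)
  expect_false(anyDuplicated(lib$id) > 0)

  # generator defaults: strengths within the stated decades, Pl a small
  # fraction of Pu, K/n/KI within their configured ranges
  reg <- dplyr::filter(tibble::as_tibble(lib), kind != "constitutive")
  expect_true(all(lib$Pu >= 0.05 & lib$Pu <= 50))
  expect_true(all(reg$Pl / reg$Pu <= 0.1 & reg$Pl / reg$Pu >= 1e-3))
  expect_true(all(reg$K >= 1 & reg$K <= 100))
  expect_true(all(reg$n >= 1 & reg$n <= 4))
  expect_true(all(reg$KI >= 0.1 & reg$KI <= 10))

  expect_identical(generate_library(C = 3, R = 2, A = 2, seed = 9),
                   generate_library(C = 3, R = 2, A = 2, seed = 9))
  expect_error(generate_library(C = 2, strength_decades = c(5, 5)),
               "increasing")
})

test_that("library files round-trip exactly and reject schema violations", {
  withr::local_seed(17)
  for (rep in 1:3) {
    lib <- generate_library(C = sample(1:5, 1), R = sample(0:4, 1),
                            A = sample(1:4, 1), seed = sample.int(1e6, 1))
    path <- withr::local_tempfile(fileext = ".csv")
    write_library(lib, path)
    back <- read_library(path)
    expect_equal(tibble::as_tibble(back), tibble::as_tibble(lib),
                 ignore_attr = TRUE)
  }

  # a repressor-regulated row missing K is rejected with its row named
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,kind,Pu,Pl,K,n,KI",
               "C1,constitutive,2,0,,,",
               "R1,repressor_regulated,5,0.1,,2,1"), path)
  expect_error(read_library(path), "R1.*K > 0")

  writeLines(c("id,kind,Pu,Pl,K,n,KI",
               "C1,constitutive,2,0,,,",
               "C1,constitutive,3,0,,,"), path)
  expect_error(read_library(path), "duplicate")

  writeLines(c("id,kind,Pu,Pl,K,n,KI",
               "Z1,mystery,2,0,,,"), path)
  expect_error(read_library(path), "unknown kind")

  expect_error(read_library(file.path(tempdir(), "no-such-library.csv")),
               class = "glc_config_error")
})

test_that("characterization fitting recovers known parameters", {
  truth <- make_activator_comp(Pu = 8, Pl = 0.4, K = 5, n = 2, KI = 1)
  curve <- tidyr::crossing(x_reg = c(5, 15, 40), inducer = 10^seq(-2, 2, 0.5),
                           replicate = 1L)
  curve$activity <- regulation_activated(truth, curve$x_reg, curve$inducer)
  fit <- fit_component(curve, "activator_regulated")
  est <- fit$component
  for (p in c("Pu", "Pl", "K", "n", "KI"))
    expect_lt(abs(est[[p]] - truth[[p]]) / truth[[p]], 0.01)
  expect_lt(glance(fit)$rss, 1e-8)

  # repressor curve varying the regulator at fixed inducer (KI not identifiable)
  rtruth <- make_repressor_comp(Pu = 12, Pl = 0.6, K = 8, n = 1.5)
  rcurve <- tidyr::crossing(x_reg = 10^seq(-1, 2.5, 0.25), inducer = 0,
                            replicate = 1L)
  rcurve$activity <- regulation_repressed(rtruth, rcurve$x_reg, rcurve$inducer)
  rfit <- fit_component(rcurve, "repressor_regulated")
  for (p in c("Pu", "Pl", "K", "n"))
    expect_lt(abs(rfit$component[[p]] - rtruth[[p]]) / rtruth[[p]], 0.01)
  expect_true(is.na(rfit$component$KI))
})

test_that("fitting tolerates measurement noise and rejects flat curves", {
  truth <- make_activator_comp(Pu = 8, Pl = 0.4, K = 5, n = 2, KI = 1)
  curve <- tidyr::crossing(x_reg = 30, inducer = 10^seq(-1.5, 2, 0.5),
                           replicate = 1:3)
  clean <- regulation_activated(truth, curve$x_reg, curve$inducer)
  curve$activity <- withr::with_seed(5, clean * (1 + 0.05 * rnorm(nrow(curve))))
  fit <- fit_component(curve, "activator_regulated")
  expect_lt(abs(fit$component$Pu - truth$Pu) / truth$Pu, 0.10)

  flat <- tidyr::crossing(x_reg = 1:8, inducer = 1, replicate = 1L)
  flat$activity <- 3
  expect_error(fit_component(flat, "repressor_regulated"),
               class = "glc_numeric_error")
  tiny <- dplyr::slice_head(curve, n = 3)
  expect_error(fit_component(tiny, "activator_regulated"), "5 distinct")

  # constitutive parts: strength is the mean activity
  cc <- tibble::tibble(x_reg = 0, inducer = 0, activity = c(2.1, 1.9, 2.0),
                       replicate = 1:3)
  expect_equal(fit_component(cc, "constitutive")$component$Pu, 2)
  expect_equal(nrow(tidy(fit)), 5L)
})

test_that("calibration plants a dominant, accurately tracking pair", {
  lib <- cached_demo_lib()
  planted <- attr(lib, "planted")
  expect_named(planted, c("constitutive", "activated"))

  # deterministic tracking of the prescribed response within 2% everywhere
  spec <- demo_circuit(lib)
  grid <- exp(seq(log(0.1), log(10), length.out = 81))
  ss <- steady_state(spec, grid)
  ref <- reference_density(reference_response(), grid)
  expect_lt(max(abs(ss$N_ss - ref) / ref), 0.02)

  # with the planted pair removed no remaining pair comes close: every
  # other candidate costs at least 10x more (exhaustive evaluation)
  ranking <- exhaustive_search(lib, demo_template(), reference_response(),
                               frac = 0, draws = 1)
  idx <- attr(lib, "planted_index")
  jstar <- ranking$cost[ranking$i == idx[1] & ranking$j == idx[2]]
  others <- ranking$cost[!(ranking$i == idx[1] & ranking$j == idx[2])]
  expect_gte(min(others), 10 * jstar)

  expect_identical(tibble::as_tibble(cached_demo_lib(3L)),
                   tibble::as_tibble(demo_library(seed = 3)))
  expect_error(
    calibrate_demo_library(reference_response(), circuit_template("repressor")),
    "activator")
})
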