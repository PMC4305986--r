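test_that("fitness is the regularized reciprocal of the cost", {
  expect_equal(design_fitness(1), 1, tolerance = 1e-9)
  expect_equal(design_fitness(0), 1e12)
  expect_gt(design_fitness(0.1), design_fitness(0.2))
  expect_error(design_fitness(-1), "J")
})

test_that("the tracking cost matches an independent trapezoid computation", {
  lib <- cached_demo_lib()
  tmpl <- demo_template()
  ref <- reference_response()
  # hand-rolled oracle: steady-state algebra + trapezoid, no package cost code
  grid <- exp(seq(log(0.1), log(10), length.out = 25))
  tab <- tibble::as_tibble(lib)
  const <- tab[tab$kind == "constitutive", ][2, ]
  act <- tab[tab$kind == "activator_regulated", ][3, ]
  x_reg <- const$Pu / (tmpl$gamma_reg + tmpl$k)
  xs <- x_reg / (1 + act$KI / grid)
  p2 <- act$Pl + (act$Pu - act$Pl) / (1 + (act$K / xs)^act$n)
  x_lys <- p2 / (tmpl$gamma_lys + tmpl$k)
  N <- pmin(pmax(tmpl$Nmax * (1 - tmpl$gamma_N / tmpl$k * x_lys), 0), tmpl$Nmax)
  err2 <- (N - reference_density(ref, grid))^2
  expected <- sum(diff(grid) * (utils::head(err2, -1) + utils::tail(err2, -1)) / 2)

  expect_equal(design_cost(lib, c(2, 3), tmpl, ref, frac = 0, draws = 1),
               expected, tolerance = 1e-12)
})

test_that("cost rewards the planted pair and respects pointwise dominance", {
  lib <- cached_demo_lib()
  tmpl <- demo_template()
  ref <- reference_response()
  idx <- attr(lib, "planted_index")
  j_planted <- design_cost(lib, idx, tmpl, ref, frac = 0, draws = 1)
  # calibration bound: 2% relative everywhere -> J <= (0.02 * max N_ref)^2 * width
  expect_lt(j_planted, (0.02 * 0.7)^2 * 9.9)

  # identical perturbation draws (common random numbers): cost reproducible
  j1 <- design_cost(lib, idx, tmpl, ref, frac = 0.05, draws = 50, seed = 8)
  j2 <- design_cost(lib, idx, tmpl, ref, frac = 0.05, draws = 50, seed = 8)
  expect_identical(j1, j2)

  # parameter fluctuation cannot help a calibrated tracker on average
  expect_gte(design_cost(lib, idx, tmpl, ref, frac = 0.05, draws = 400,
                         seed = 12),
             j_planted)
})

test_that("exhaustive search ranks every pair with stable ties", {
  one <- component_library(dplyr::bind_rows(make_const_comp(Pu = 0.9),
                                            make_activator_comp()))
  r1 <- exhaustive_search(one, demo_template(), reference_response(),
                          frac = 0, draws = 1)
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$constitutive, "C1")

  lib <- cached_demo_lib()
  rk <- exhaustive_search(lib, demo_template(), reference_response(),
                          frac = 0, draws = 1)
  expect_equal(nrow(rk), 36L)
  expect_true(!is.unsorted(rk$cost))
  expect_equal(rk$fitness, design_fitness(rk$cost))
})

test_that("the GA finds the planted pair and is reproducible", {
  lib <- cached_demo_lib()
  des <- ga_search(lib, demo_template(), reference_response(),
                   frac = 0, draws = 1,
                   settings = ga_settings(generations = 40, seed = 5))
  g <- glance(des)
  planted <- attr(lib, "planted")
  expect_equal(g$constitutive, unname(planted["constitutive"]))
  expect_equal(g$regulated, unname(planted["activated"]))

  des2 <- ga_search(lib, demo_template(), reference_response(),
                    frac = 0, draws = 1,
                    settings = ga_settings(generations = 40, seed = 5))
  expect_equal(tidy(des), tidy(des2))

  # a one-pair library degenerates to that pair
  one <- component_library(dplyr::bind_rows(make_const_comp(Pu = 0.9),
                                            make_activator_comp()))
  d1 <- ga_search(one, demo_template(), reference_response(), frac = 0,
                  draws = 1, settings = ga_settings(generations = 2, seed = 1))
  expect_equal(nrow(d1), 1L)
})

test_that("GA attains the exhaustive optimum on random libraries", {
  withr::local_seed(99)
  for (rep in 1:6) {
    lib <- generate_library(C = sample(3:8, 1), R = 0, A = sample(3:8, 1),
                            seed = sample.int(1e6, 1))
    ref <- reference_response()
    ex <- exhaustive_search(lib, demo_template(), ref, frac = 0, draws = 1)
    ga <- ga_search(lib, demo_template(), ref, frac = 0, draws = 1,
                    settings = ga_settings(generations = 60,
                                           seed = sample.int(1e6, 1)))
    expect_equal(ga$cost[1], ex$cost[1], tolerance = 1e-12)
  }
})

test_that("early stopping halts the GA once the goal is reached", {
  lib <- cached_demo_lib()
  idx <- attr(lib, "planted_index")
  jstar <- design_cost(lib, idx, demo_template(), reference_response(),
                       frac = 0, draws = 1)
  des <- ga_search(lib, demo_template(), reference_response(), frac = 0,
                   draws = 1,
                   settings = ga_settings(generations = 100, seed = 5,
                                          stop_J = 2 * jstar))
  expect_lt(glance(des)$generations, 100L)
  # unreachable goal: runs the full budget and still reports the best
  full <- ga_search(lib, demo_template(), reference_response(), frac = 0,
                    draws = 1,
                    settings = ga_settings(generations = 5, seed = 5,
                                           stop_J = 0))
  expect_equal(glance(full)$generations, 5L)
})

test_that("inducer recommendation inverts the prescribed response", {
  ref <- reference_response()
  expect_equal(recommend_inducer(ref, 0.5), 0.5)
  expect_equal(recommend_inducer(ref, 0.3), 1)
  expect_equal(recommend_inducer(ref, 0.4), sqrt(0.5), tolerance = 1e-9)

  # round trip over the attainable interval
  targets <- seq(reference_density(ref, 10) + 1e-6,
                 reference_density(ref, 0.1) - 1e-6, length.out = 40)
  doses <- vapply(targets, function(t) recommend_inducer(ref, t), numeric(1))
  expect_lt(max(abs(reference_density(ref, doses) - targets)), 1e-9)
  expect_true(all(doses >= 0.1 & doses <= 10))

  expect_error(recommend_inducer(ref, 0.9), "attainable")
  expect_error(recommend_inducer(ref, 0.05), "attainable")
})

test_that("design artifacts expose tidy, glance, plots, and a text report", {
  lib <- cached_demo_lib()
  des <- ga_search(lib, demo_template(), reference_response(), frac = 0,
                   draws = 1, settings = ga_settings(generations = 20, seed = 3))
  td <- tidy(des)
  expect_true(all(c("constitutive", "regulated", "cost", "fitness") %in%
                    names(td)))
  tt <- tracking_table(des)
  expect_lt(max(tt$rel_error), 0.02)
  expect_s3_class(autoplot(des), "ggplot")

  path <- withr::local_tempfile(fileext = ".txt")
  write_design_report(des, path)
  report <- readLines(path)
  expect_true(any(grepl(attr(lib, "planted")[["activated"]], report)))
  expect_true(any(grepl("inducer range", report)))
})
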