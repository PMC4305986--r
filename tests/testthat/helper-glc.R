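# shared fixtures, all generated in code

# calibrated demo library is used by several files; build it once
.glc_cache <- new.env(parent = emptyenv())
cached_demo_lib <- function(seed = 1L) {
  key <- paste0("lib", seed)
  if (is.null(.glc_cache[[key]]))
    .glc_cache[[key]] <- demo_library(seed = seed)
  .glc_cache[[key]]
}

make_repressor_comp <- function(Pu = 10, Pl = 1, K = 2, n = 2, KI = 1, id = "R1")
  prbs_component(id, "repressor_regulated", Pu = Pu, Pl = Pl, K = K, n = n, KI = KI)

make_activator_comp <- function(Pu = 10, Pl = 1, K = 3, n = 2, KI = 1, id = "A1")
  prbs_component(id, "activator_regulated", Pu = Pu, Pl = Pl, K = K, n = n, KI = KI)

make_const_comp <- function(Pu = 2, id = "C1")
  prbs_component(id, "constitutive", Pu = Pu)

# random circuit whose density steady state is interior (lysis < growth),
# used for dynamics-vs-closed-form oracle checks
random_interior_spec <- function(topology = c("activator", "repressor"),
                                 u_range = c(0.1, 0.6)) {
  topology <- match.arg(topology)
  kind <- if (topology == "repressor") "repressor_regulated" else "activator_regulated"
  const <- make_const_comp(Pu = exp(runif(1, log(0.05), log(5))), id = "C1")
  reg <- prbs_component("X1", kind,
                        Pu = exp(runif(1, log(0.1), log(20))),
                        Pl = exp(runif(1, log(1e-3), log(0.05))),
                        K = exp(runif(1, log(1), log(100))),
                        n = runif(1, 1, 4),
                        KI = exp(runif(1, log(0.1), log(10))))
  k <- runif(1, 0.02, 0.05)
  spec <- circuit_spec(topology, const, reg,
                       gamma_reg = runif(1, 0.005, 0.05),
                       gamma_lys = runif(1, 0.005, 0.05),
                       k = k, Nmax = runif(1, 0.5, 2), gamma_N = 1)
  # pick an inducer, then set gamma_N so lysis removes a fraction u < 1 of growth
  I <- exp(runif(1, log(0.1), log(10)))
  x_lys <- steady_state(spec, I)$x_lys_ss
  u <- runif(1, u_range[1], u_range[2])
  spec$gamma_N <- u * k / x_lys
  list(spec = spec, I = I, u = u)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)), tol)
}
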