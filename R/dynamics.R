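#' Growth rate of the cell population
#'
#' Right-hand side of the density equation: logistic growth with a first-order
#' kill term proportional to the lysis-protein concentration,
#' `dN/dt = k N (1 - N/Nmax) - gamma_N N x_lys`. With `x_lys = 0` this is
#' plain logistic growth.
#'
#' @param N Cell population density (O.D. 600, >= 0).
#' @param spec A [circuit_spec()] (only `k`, `Nmax`, `gamma_N` are used).
#' @param x_lys Lysis-protein concentration (nM, >= 0).
#' @return dN/dt (O.D./min), vectorized over `N` and `x_lys`.
#' @examples
#' spec <- demo_template()
#' growth_rhs(spec$Nmax, spec, x_lys = 0)  # 0: logistic equilibrium
#' @export
growth_rhs <- function(N, spec, x_lys) {
  check_nonneg_vec(N, "N"); check_nonneg_vec(x_lys, "x_lys")
  spec$k * N * (1 - N / spec$Nmax) - spec$gamma_N * N * x_lys
}

#' Simulate a genetic lysis circuit through time
#'
#' Integrates the three-state model — regulator protein, lysis protein, cell
#' density — on a fixed time grid. With noise disabled the integrator is
#' classical fourth-order Runge-Kutta; with noise enabled it is
#' Euler-Maruyama with additive Gaussian increments of intensity
#' `noise$omega_sd` (per state, per sqrt(min)), and all states are clipped at
#' 0 after each step so concentrations and density stay physical.
#'
#' @param spec A [circuit_spec()].
#' @param I Inducer concentration (nM, >= 0), held constant.
#' @param init Named numeric of initial conditions `x_reg`, `x_lys`, `N`.
#'   Defaults: both proteins at 0, density at 0.05 O.D.
#' @param horizon Simulation length (min). The default 240 min matches the
#'   time at which steady-state densities are read in plate experiments.
#' @param dt Fixed step (min).
#' @param noise A [noise_spec()]; `NULL` means deterministic.
#' @param seed Integer seed for the stochastic increments (required
#'   reproducibility handle when noise is enabled).
#' @param record_every Record one row every this many steps (1 = every step).
#' @return A `glc_trajectory`: a tibble with columns `time`, `x_reg`,
#'   `x_lys`, `N`, one row per recorded time.
#' @examples
#' lib <- demo_library(seed = 1)
#' spec <- demo_circuit(lib)
#' tr <- simulate_circuit(spec, I = 1)
#' tail(tr, 1)
#' @export
simulate_circuit <- function(spec, I, init = c(x_reg = 0, x_lys = 0, N = 0.05),
                             horizon = 240, dt = 0.1, noise = NULL,
                             seed = NULL, record_every = 1L) {
  stopifnot(inherits(spec, "circuit_spec"))
  check_number(I, "I", lower = 0)
  check_number(dt, "dt", lower = 0, strict = TRUE)
  if (horizon < dt) abort("`horizon` must be at least one step `dt`.")
  init <- init[c("x_reg", "x_lys", "N")]
  check_nonneg_vec(init, "init")

  stochastic <- noise_on(noise)
  n_steps <- floor(horizon / dt + 1e-9)
  keep <- seq(0L, n_steps, by = as.integer(record_every))
  if (keep[length(keep)] != n_steps) keep <- c(keep, n_steps)

  pc1 <- regulation_constitutive(spec$constitutive)
  a_reg <- spec$gamma_reg + spec$k
  a_lys <- spec$gamma_lys + spec$k
  comp2 <- spec$regulated

  # full RHS of (x_reg, x_lys, N)
  rhs <- function(s) {
    p2 <- regulation_stage2(comp2, s[1L], I)
    c(pc1 - a_reg * s[1L],
      p2 - a_lys * s[2L],
      spec$k * s[3L] * (1 - s[3L] / spec$Nmax) - spec$gamma_N * s[3L] * s[2L])
  }

  out <- matrix(NA_real_, nrow = length(keep), ncol = 3L)
  state <- as.numeric(init)
  ki <- 1L
  if (0L %in% keep) { out[1L, ] <- state; ki <- 2L }

  do_steps <- function() {
    sq <- if (stochastic) noise$omega_sd * sqrt(dt) else NULL
    for (step in seq_len(n_steps)) {
      if (stochastic) {
        state <<- state + dt * rhs(state) + sq * rnorm(3L)
      } else {
        k1 <- rhs(state)
        k2 <- rhs(state + dt / 2 * k1)
        k3 <- rhs(state + dt / 2 * k2)
        k4 <- rhs(state + dt * k3)
        state <<- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      state[state < 0] <<- 0
      if (any(!is.finite(state)))
        stop_numeric(sprintf(
          "non-finite state at step %d (t = %g min); reduce dt or check rates.",
          step, step * dt))
      if (ki <= length(keep) && keep[ki] == step) {
        out[ki, ] <<- state
        ki <<- ki + 1L
      }
    }
  }
  if (stochastic && is.null(seed))
    abort("stochastic simulation requires a `seed`.")
  with_seed_if(if (stochastic) seed else NULL, do_steps())

  traj <- tibble(time = keep * dt, x_reg = out[, 1L], x_lys = out[, 2L],
                 N = out[, 3L])
  structure(traj, class = c("glc_trajectory", class(traj)),
            inducer = I, topology = spec$topology, stochastic = stochastic,
            seed = seed)
}

#' Simulate across a set of inducer concentrations
#'
#' Runs [simulate_circuit()] once per inducer level with independent noise
#' streams derived from `seed`, and binds the results into one long tibble
#' with an `inducer` column — the shape used for density-versus-time profile
#' plots under different inducer doses.
#'
#' @inheritParams simulate_circuit
#' @param inducers Nonempty numeric vector of inducer concentrations (nM).
#' @return A tibble with columns `inducer`, `time`, `x_reg`, `x_lys`, `N`.
#' @export
inducer_sweep <- function(spec, inducers, init = c(x_reg = 0, x_lys = 0, N = 0.05),
                          horizon = 240, dt = 0.1, noise = NULL, seed = NULL,
                          record_every = 1L) {
  if (length(inducers) == 0L) abort("`inducers` must be nonempty.")
  check_nonneg_vec(inducers, "inducers")
  seeds <- if (noise_on(noise)) {
    if (is.null(seed)) abort("stochastic sweep requires a `seed`.")
    derive_seeds(seed, length(inducers))
  } else rep(list(NULL), length(inducers))
  purrr::map2(as.numeric(inducers), seeds, function(I, s) {
    tr <- simulate_circuit(spec, I, init = init, horizon = horizon, dt = dt,
                           noise = noise, seed = s, record_every = record_every)
    dplyr::mutate(as_tibble(tr), inducer = I, .before = 1L)
  }) |>
    purrr::list_rbind()
}

#' Write a trajectory to a delimited file
#'
#' Plain CSV with a mandatory header row (`time,x_reg,x_lys,N`, plus
#' `inducer` for sweep output).
#'
#' @param traj A trajectory tibble from [simulate_circuit()] or
#'   [inducer_sweep()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  readr::write_csv(as_tibble(traj), path)
  invisible(path)
}

#' @describeIn simulate_circuit Plot the three state variables against time.
#' @param object A `glc_trajectory`.
#' @param ... Unused.
#' @method autoplot glc_trajectory
#' @export
autoplot.glc_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("x_reg", "x_lys", "N"),
                              names_to = "state", values_to = "value")
  long$state <- factor(long$state, levels = c("x_reg", "x_lys", "N"),
                       labels = c("regulator (nM)", "lysis protein (nM)",
                                  "density (O.D. 600)"))
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~state, scales = "free_y", ncol = 1L) +
    ggplot2::labs(x = "time (min)", y = NULL,
                  title = sprintf("Lysis circuit trajectory (I = %g nM)",
                                  attr(object, "inducer")))
}
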