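#' Closed-form steady state of the lysis circuit
#'
#' Setting the time derivatives of the dynamic model to zero gives the
#' steady-state regulator concentration `x_reg_ss = P_c1 / (gamma_reg + k)`,
#' the lysis-protein concentration
#' `x_lys_ss = P_2(x_reg_ss, I) / (gamma_lys + k)` (with `P_2` the regulated
#' stage's Hill activity), and the density
#' `N_ss = Nmax (1 - (gamma_N / k) x_lys_ss)`. A raw density below 0 (lysis
#' outpacing growth) is clamped to 0 and flagged in the `clamped` column.
#' With noise enabled, Gaussian terms `v1`, `v2`, `v3` (SDs from
#' `noise$v_sd`) are added to the three steady-state quantities in order —
#' the noisy regulator feeds the stage-2 activity — and clamping is applied
#' after the noise.
#'
#' @param spec A [circuit_spec()]; `k` must be positive.
#' @param I Inducer concentration(s) (nM, >= 0); vectorized.
#' @param noise A [noise_spec()] or `NULL` (deterministic).
#' @param seed Seed for the noise draws (required when noise is enabled).
#' @return A tibble with one row per inducer level: `inducer`, `x_reg_ss`,
#'   `x_lys_ss`, `N_ss`, `clamped`.
#' @examples
#' lib <- demo_library(seed = 1)
#' steady_state(demo_circuit(lib), I = c(0.1, 0.5, 1, 10))
#' @export
steady_state <- function(spec, I, noise = NULL, seed = NULL) {
  check_nonneg_vec(I, "I")
  if (length(I) == 0L) abort("`I` must be nonempty.")
  if (spec$k <= 0) abort("steady state requires k > 0 (division by k).")
  use_noise <- noise_on(noise)
  if (use_noise && is.null(seed))
    abort("stochastic steady state requires a `seed`.")

  res <- with_seed_if(if (use_noise) seed else NULL, {
    m <- length(I)
    v <- if (use_noise)
      matrix(rnorm(3L * m), ncol = 3L) %*% diag(noise$v_sd)
    else matrix(0, nrow = m, ncol = 3L)
    x_reg <- regulation_constitutive(spec$constitutive) /
      (spec$gamma_reg + spec$k) + v[, 1L]
    x_reg <- pmax(x_reg, 0)
    p2 <- regulation_stage2(spec$regulated, x_reg, I)
    x_lys <- pmax(p2 / (spec$gamma_lys + spec$k) + v[, 2L], 0)
    N_raw <- spec$Nmax * (1 - (spec$gamma_N / spec$k) * x_lys) + v[, 3L]
    tibble(inducer = as.numeric(I), x_reg_ss = x_reg, x_lys_ss = x_lys,
           N_ss = pmin(pmax(N_raw, 0), spec$Nmax),
           clamped = N_raw < 0 | N_raw > spec$Nmax)
  })
  res
}

# the seven perturbed kinetic parameters and their stage-wise noise source
# (stage 1: constitutive strength + regulator degradation; stage 2: regulated
# strengths + lysis-protein degradation; population: k and gamma_N)
pert_param_groups <- list(
  n1 = c("Pu_c", "gamma_reg"),
  n2 = c("Pu_r", "Pl_r", "gamma_lys"),
  n3 = c("k", "gamma_N")
)
pert_param_names <- unlist(pert_param_groups, use.names = FALSE)

#' Monte-Carlo parameter perturbation
#'
#' Kinetic parameters of a living circuit fluctuate in vivo; the design is
#' evaluated over an ensemble of perturbed circuits so a selected component
#' pair is robust rather than just nominally optimal. Each kinetic parameter
#' `p` is replaced by `p (1 + frac z)` with a standard-normal `z`; the
#' default `frac = 0.05` sets each parameter's fluctuation SD to 5% of its
#' nominal value. Parameters of the same expression stage share one noise
#' source per draw (the constitutive strength with the regulator degradation;
#' the regulated strengths with the lysis-protein degradation; the growth
#' rate with the lysis rate), so a draw represents one coherent realization
#' of transcription/translation noise per stage. A draw whose multipliers
#' are not all positive is rejected and redrawn, keeping rates physical.
#'
#' @param spec A [circuit_spec()] (the nominal circuit).
#' @param frac Fractional standard deviation of every kinetic parameter
#'   (dimensionless, >= 0). Values >= 1 trigger a heavy-truncation warning.
#' @param draws Number of Monte-Carlo draws (>= 1).
#' @param seed Integer seed; the same seed reproduces the ensemble.
#' @return A list of `draws` perturbed `circuit_spec` objects.
#' @examples
#' lib <- demo_library(seed = 1)
#' ens <- perturb(demo_circuit(lib), frac = 0.05, draws = 3, seed = 42)
#' sapply(ens, function(s) s$k)
#' @export
perturb <- function(spec, frac = 0.05, draws = 100L, seed = NULL) {
  stopifnot(inherits(spec, "circuit_spec"))
  mult <- perturbation_multipliers(frac, draws, seed)
  lapply(seq_len(draws), function(d) apply_multipliers(spec, mult[d, ]))
}

# draws x 7 matrix of positive multipliers (1 + frac z), one z per stage
perturbation_multipliers <- function(frac = 0.05, draws = 100L, seed = NULL) {
  check_number(frac, "frac", lower = 0)
  if (draws < 1L) abort("`draws` must be >= 1.")
  if (frac >= 1)
    warn("`frac` >= 1: positivity rejection truncates the noise heavily.",
         class = "glc_heavy_truncation")
  with_seed_if(seed, {
    z <- matrix(rnorm(3L * draws), nrow = draws)
    if (frac > 0) {
      bad <- which(1 + frac * z <= 0, arr.ind = TRUE)
      while (nrow(bad) > 0L) {
        z[bad] <- rnorm(nrow(bad))
        bad <- bad[1 + frac * z[bad] <= 0, , drop = FALSE]
      }
    }
    mult <- cbind(z[, 1L], z[, 1L], z[, 2L], z[, 2L], z[, 2L], z[, 3L], z[, 3L])
    colnames(mult) <- pert_param_names[c(1L, 2L, 3L, 4L, 5L, 6L, 7L)]
    1 + frac * mult
  })
}

apply_multipliers <- function(spec, m) {
  spec$constitutive$Pu <- spec$constitutive$Pu * m[["Pu_c"]]
  spec$gamma_reg <- spec$gamma_reg * m[["gamma_reg"]]
  spec$regulated$Pu <- spec$regulated$Pu * m[["Pu_r"]]
  spec$regulated$Pl <- spec$regulated$Pl * m[["Pl_r"]]
  spec$gamma_lys <- spec$gamma_lys * m[["gamma_lys"]]
  spec$k <- spec$k * m[["k"]]
  spec$gamma_N <- spec$gamma_N * m[["gamma_N"]]
  spec
}

#' Predicted steady-state densities over a perturbation ensemble
#'
#' Evaluates the closed-form steady state on an inducer grid for every
#' perturbed circuit in a Monte-Carlo ensemble; this tibble of predicted
#' densities is what the design cost averages over.
#'
#' @inheritParams perturb
#' @param inducers Nonempty inducer grid (nM).
#' @param noise Optional [noise_spec()] adding steady-state v-noise per draw.
#' @param multipliers Optional precomputed matrix from
#'   `perturbation_multipliers()`; when supplied, `frac`/`draws`/`seed` are
#'   ignored (used internally so all design candidates share common random
#'   numbers).
#' @return A tibble with columns `draw`, `inducer`, `N_ss`, `clamped`.
#' @export
predicted_density_ensemble <- function(spec, inducers, frac = 0.05,
                                       draws = 100L, seed = NULL,
                                       noise = NULL, multipliers = NULL) {
  if (length(inducers) == 0L) abort("`inducers` must be nonempty.")
  if (is.null(multipliers))
    multipliers <- perturbation_multipliers(frac, draws, seed)
  n_draws <- nrow(multipliers)
  noise_seeds <- if (noise_on(noise)) derive_seeds((seed %||% 0L) + 1L, n_draws)
                 else rep(list(NULL), n_draws)
  purrr::map(seq_len(n_draws), function(d) {
    sp <- apply_multipliers(spec, multipliers[d, ])
    ss <- steady_state(sp, inducers, noise = noise, seed = noise_seeds[[d]])
    tibble(draw = d, inducer = ss$inducer, N_ss = ss$N_ss,
           clamped = ss$clamped)
  }) |>
    purrr::list_rbind()
}

#' Write a steady-state ensemble to a delimited file
#'
#' @param ensemble Tibble from [predicted_density_ensemble()].
#' @param path Destination CSV file (header `draw,inducer,N_ss,clamped`).
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  readr::write_csv(as_tibble(ensemble), path)
  invisible(path)
}
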