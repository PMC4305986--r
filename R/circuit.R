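#' Circuit specification
#'
#' Bundles the two promoter-RBS components of a genetic lysis circuit with the
#' global kinetic rates. The circuit has two stages: a constitutive component
#' expresses the regulatory protein (repressor or activator), and a regulated
#' component downstream expresses the lysis protein, which kills cells in
#' proportion to its concentration. Cell growth is logistic; the same rate `k`
#' drives both growth and the growth-dilution of intracellular proteins.
#'
#' Default rates describe slow-growing E. coli in the units used throughout
#' the package (minutes, nM, O.D. 600): `k = 0.02` per min (doubling time
#' around 35 min), protein degradation `0.01` per min (half-life around
#' 70 min), carrying capacity `Nmax = 1` O.D., and lysis rate
#' `gamma_N = 5e-4` per nM per min so that densities between 0.1 and 0.7 O.D.
#' correspond to lysis-protein levels of a few tens of nM.
#'
#' @param topology `"repressor"` or `"activator"`: which regulated component
#'   class drives the lysis gene.
#' @param constitutive Constitutive promoter-RBS component (stage 1).
#' @param regulated Regulated promoter-RBS component (stage 2); its kind must
#'   match `topology`.
#' @param gamma_reg Degradation rate of the regulatory protein (1/min).
#' @param gamma_lys Degradation rate of the lysis protein (1/min).
#' @param k Cell growth / protein dilution rate (1/min, > 0).
#' @param Nmax Maximum cell population density (O.D. 600, > 0).
#' @param gamma_N Lysis rate of the lysis protein (1/(nM min)).
#' @return An object of class `circuit_spec`.
#' @examples
#' lib <- generate_library(C = 2, A = 2, seed = 1)
#' circuit_spec("activator",
#'              constitutive = dplyr::filter(lib, id == "C1"),
#'              regulated = dplyr::filter(lib, id == "A1"))
#' @export
circuit_spec <- function(topology = c("activator", "repressor"),
                         constitutive, regulated,
                         gamma_reg = 0.01, gamma_lys = 0.01,
                         k = 0.02, Nmax = 1, gamma_N = 5e-4) {
  topology <- match.arg(topology)
  constitutive <- as_component(constitutive)
  regulated <- as_component(regulated)
  validate_component(constitutive, "constitutive")
  validate_component(regulated, "regulated")
  if (constitutive$kind != "constitutive")
    abort("`constitutive` must be a constitutive component.")
  want <- if (topology == "repressor") "repressor_regulated" else "activator_regulated"
  if (regulated$kind != want)
    abort(sprintf("`regulated` must be %s for the %s topology.", want, topology))
  for (p in c("gamma_reg", "gamma_lys", "gamma_N"))
    check_number(get(p), p, lower = 0)
  check_number(k, "k", lower = 0)
  check_number(Nmax, "Nmax", lower = 0, strict = TRUE)
  structure(
    list(topology = topology, constitutive = constitutive,
         regulated = regulated, gamma_reg = gamma_reg, gamma_lys = gamma_lys,
         k = k, Nmax = Nmax, gamma_N = gamma_N),
    class = "circuit_spec"
  )
}

#' @export
print.circuit_spec <- function(x, ...) {
  cat(sprintf("<circuit_spec> %s topology\n", x$topology))
  cat(sprintf("  stage 1: %s (Pu = %g nM/min)\n", x$constitutive$id, x$constitutive$Pu))
  cat(sprintf("  stage 2: %s (Pu = %g, Pl = %g, K = %g, n = %g, KI = %g)\n",
              x$regulated$id, x$regulated$Pu, x$regulated$Pl,
              x$regulated$K, x$regulated$n, x$regulated$KI))
  cat(sprintf("  rates: gamma_reg %g, gamma_lys %g, k %g /min; Nmax %g OD; gamma_N %g /(nM min)\n",
              x$gamma_reg, x$gamma_lys, x$k, x$Nmax, x$gamma_N))
  invisible(x)
}

# swap the component pair of a template spec (used by the design search)
spec_with_pair <- function(template, constitutive, regulated) {
  template$constitutive <- as_component(constitutive)
  template$regulated <- as_component(regulated)
  template
}

#' Cellular noise specification
#'
#' Additive Gaussian noise settings. `omega_sd` are the intensities of the
#' process noise entering the dynamic model (regulator, lysis protein, and
#' density equations; units per sqrt(min)); `v_sd` are the standard deviations
#' of the steady-state noise terms added to the steady-state regulator and
#' lysis-protein concentrations (nM) and density (O.D.). Defaults are small
#' on the scale of each state variable.
#'
#' @param omega_sd Length-3 nonnegative numeric: process-noise intensities.
#' @param v_sd Length-3 nonnegative numeric: steady-state noise SDs.
#' @param enabled Logical; `FALSE` turns all noise off.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(omega_sd = c(0.1, 0.1, 0.002),
                       v_sd = c(0.5, 0.5, 0.01), enabled = TRUE) {
  omega_sd <- as.numeric(omega_sd); v_sd <- as.numeric(v_sd)
  if (length(omega_sd) != 3L || length(v_sd) != 3L)
    abort("`omega_sd` and `v_sd` must have length 3.")
  check_nonneg_vec(omega_sd, "omega_sd"); check_nonneg_vec(v_sd, "v_sd")
  structure(list(omega_sd = omega_sd, v_sd = v_sd, enabled = isTRUE(enabled)),
            class = "noise_spec")
}

noise_off <- function() noise_spec(enabled = FALSE)

noise_on <- function(noise) !is.null(noise) && isTRUE(noise$enabled)
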