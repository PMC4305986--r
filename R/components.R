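#' Promoter-RBS components
#'
#' A promoter-RBS component is a composite genetic part (promoter plus
#' ribosome binding site) characterized by a lumped kinetic strength for the
#' combined transcription and translation process. Three classes are modelled:
#' `constitutive` parts deliver their maximum strength `Pu` unconditionally;
#' `repressor_regulated` and `activator_regulated` parts interpolate between a
#' minimum strength `Pl` (full repression / no activation) and `Pu` through a
#' Hill function of the effective transcription-factor concentration.
#'
#' @param id Short unique label for the component.
#' @param kind One of `"constitutive"`, `"repressor_regulated"`,
#'   `"activator_regulated"`.
#' @param Pu Maximum promoter-RBS strength (nM/min). Must exceed `Pl`.
#' @param Pl Minimum promoter-RBS strength (nM/min); 0 for constitutive parts.
#' @param K Binding affinity between the regulator and the promoter-RBS (nM);
#'   `NA` for constitutive parts.
#' @param n Binding cooperativity (Hill coefficient, dimensionless, > 0);
#'   `NA` for constitutive parts.
#' @param KI Dissociation constant between the inducer and the regulator (nM);
#'   `NA` for constitutive parts.
#'
#' @return A one-row tibble with columns `id`, `kind`, `Pu`, `Pl`, `K`, `n`,
#'   `KI`. Component libraries are simply row-binds of these.
#' @examples
#' prbs_component("C1", "constitutive", Pu = 2)
#' prbs_component("A1", "activator_regulated", Pu = 10, Pl = 1,
#'                K = 3, n = 2, KI = 1)
#' @export
prbs_component <- function(id, kind, Pu, Pl = 0, K = NA_real_, n = NA_real_,
                           KI = NA_real_) {
  comp <- tibble(
    id = as.character(id), kind = as.character(kind),
    Pu = as.numeric(Pu), Pl = as.numeric(Pl),
    K = as.numeric(K), n = as.numeric(n), KI = as.numeric(KI)
  )
  validate_component(comp)
  comp
}

component_kinds <- c("constitutive", "repressor_regulated", "activator_regulated")

# validate one or more component rows; `where` prefixes error messages
validate_component <- function(comp, where = NULL) {
  pre <- if (is.null(where)) "" else paste0(where, ": ")
  for (r in seq_len(nrow(comp))) {
    row <- comp[r, ]
    tag <- sprintf("%scomponent '%s' (row %d)", pre, row$id, r)
    if (is.na(row$id) || !nzchar(row$id)) abort(sprintf("%s: missing id.", tag))
    if (!row$kind %in% component_kinds)
      abort(sprintf("%s: unknown kind '%s'.", tag, row$kind))
    if (!is.finite(row$Pu) || row$Pu < 0)
      abort(sprintf("%s: Pu must be a nonnegative number.", tag))
    if (row$kind == "constitutive") {
      if (!is.na(row$Pl) && row$Pl != 0)
        abort(sprintf("%s: constitutive components have Pl = 0.", tag))
    } else {
      if (!is.finite(row$Pl) || row$Pl < 0 || row$Pu <= row$Pl)
        abort(sprintf("%s: needs Pu > Pl >= 0.", tag))
      for (p in c("K", "n", "KI")) {
        v <- row[[p]]
        if (!is.finite(v) || v <= 0)
          abort(sprintf("%s: regulated component needs %s > 0.", tag, p))
      }
    }
  }
  invisible(comp)
}

as_component <- function(x) {
  if (is.data.frame(x) && nrow(x) == 1L) return(as_tibble(x))
  abort("expected a single promoter-RBS component (one-row data frame).")
}

#' Effective regulator concentrations
#'
#' Inducers reshape the pool of active transcription factor. For a repressor,
#' the inducer sequesters it, leaving the effective concentration
#' `x_r1* = x_r1 / (1 + I1/KI1)`: all of it at zero inducer, none at saturating
#' inducer. For an activator (e.g. LuxR, active only as the LuxR-AHL complex),
#' the inducer is required to form the active complex,
#' `x_a1* = x_a1 / (1 + KI2/I2)`: none at zero inducer, all of it at
#' saturating inducer. At `I2 = 0` the activator form is defined by its
#' continuous limit, 0.
#'
#' @param x_r1,x_a1 Total repressor / activator concentration (nM, >= 0).
#' @param I1,I2 Inducer concentration (nM, >= 0).
#' @param KI1,KI2 Inducer-regulator dissociation constant (nM, > 0).
#' @return Effective regulator concentration (nM), vectorized over inputs.
#' @examples
#' effective_repressor(4, I1 = 3, KI1 = 1)  # 1
#' effective_activator(6, I2 = 1, KI2 = 1)  # 3
#' @export
effective_repressor <- function(x_r1, I1, KI1) {
  check_nonneg_vec(x_r1, "x_r1"); check_nonneg_vec(I1, "I1")
  if (!is.numeric(KI1) || any(is.na(KI1)) || any(KI1 <= 0))
    abort("`KI1` must be > 0.")
  x_r1 / (1 + I1 / KI1)
}

#' @rdname effective_repressor
#' @export
effective_activator <- function(x_a1, I2, KI2) {
  check_nonneg_vec(x_a1, "x_a1"); check_nonneg_vec(I2, "I2")
  if (!is.numeric(KI2) || any(is.na(KI2)) || any(KI2 <= 0))
    abort("`KI2` must be > 0.")
  out <- x_a1 / (1 + KI2 / I2)
  out[I2 == 0] <- 0
  out
}

#' Promoter-RBS regulation activity
#'
#' The per-cell protein synthesis rate delivered by a promoter-RBS component
#' under its current regulatory input. A constitutive component always runs at
#' its maximum strength `Pu`. A repressor-regulated component runs at
#' `Pl + (Pu - Pl) / (1 + (x_r1*/K)^n)`; a fully de-repressed promoter
#' (`x_r1* = 0`) gives `Pu`. An activator-regulated component runs at
#' `Pl + (Pu - Pl) / (1 + (K/x_a1*)^n)`; with no active complex
#' (`x_a1* = 0`) the limit gives the basal strength `Pl`.
#'
#' @param comp A promoter-RBS component (one-row tibble, see
#'   [prbs_component()]), of the kind matching the function used.
#' @param x_r1,x_a1 Total regulator concentration (nM); the inducer adjustment
#'   of [effective_repressor()] / [effective_activator()] is applied
#'   internally using the component's `KI`.
#' @param I1,I2 Inducer concentration (nM).
#' @return Regulation activity (nM/min), vectorized over regulator/inducer.
#' @examples
#' a2 <- prbs_component("A1", "activator_regulated", Pu = 10, Pl = 1,
#'                      K = 3, n = 2, KI = 1)
#' regulation_activated(a2, x_a1 = 6, I2 = 1)  # half-maximal: 5.5
#' @export
regulation_constitutive <- function(comp) {
  comp <- as_component(comp)
  if (comp$kind != "constitutive")
    abort("`comp` must be a constitutive component.")
  comp$Pu
}

#' @rdname regulation_constitutive
#' @export
regulation_repressed <- function(comp, x_r1, I1) {
  comp <- as_component(comp)
  if (comp$kind != "repressor_regulated")
    abort("`comp` must be a repressor_regulated component.")
  xs <- effective_repressor(x_r1, I1, comp$KI)
  comp$Pl + (comp$Pu - comp$Pl) / (1 + (xs / comp$K)^comp$n)
}

#' @rdname regulation_constitutive
#' @export
regulation_activated <- function(comp, x_a1, I2) {
  comp <- as_component(comp)
  if (comp$kind != "activator_regulated")
    abort("`comp` must be an activator_regulated component.")
  xs <- effective_activator(x_a1, I2, comp$KI)
  hill <- ifelse(xs > 0, 1 / (1 + (comp$K / xs)^comp$n), 0)
  comp$Pl + (comp$Pu - comp$Pl) * hill
}

# regulation activity of the second stage for either topology
regulation_stage2 <- function(comp, x_reg, I) {
  if (comp$kind == "repressor_regulated") regulation_repressed(comp, x_reg, I)
  else regulation_activated(comp, x_reg, I)
}
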