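#' Component library construction and validation
#'
#' A component library is a tibble with one promoter-RBS component per row
#' (columns `id`, `kind`, `Pu`, `Pl`, `K`, `n`, `KI`; see
#' [prbs_component()]) and a `provenance` attribute recording where it came
#' from. `component_library()` validates and classes a data frame of
#' component rows; `lib_class()` extracts one class as a tibble.
#'
#' @param components A data frame of component rows.
#' @param provenance Free-text origin note.
#' @return A `component_library` tibble.
#' @export
component_library <- function(components, provenance = "user") {
  lib <- as_tibble(components)
  need <- c("id", "kind", "Pu", "Pl", "K", "n", "KI")
  missing_cols <- setdiff(need, names(lib))
  if (length(missing_cols) > 0L)
    abort(paste0("library is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  lib <- lib[, need]
  lib$id <- as.character(lib$id)
  lib$kind <- as.character(lib$kind)
  for (cc in need[-(1:2)]) lib[[cc]] <- as.numeric(lib[[cc]])
  validate_component(lib)
  if (anyDuplicated(lib$id))
    abort(paste0("duplicate component id(s): ",
                 paste(unique(lib$id[duplicated(lib$id)]), collapse = ", ")))
  structure(lib, class = c("component_library", class(lib)),
            provenance = provenance)
}

#' @rdname component_library
#' @param lib A `component_library`.
#' @param kind Component class to extract.
#' @export
lib_class <- function(lib, kind = component_kinds) {
  kind <- match.arg(kind)
  as_tibble(lib)[lib$kind == kind, ]
}

#' @export
print.component_library <- function(x, ...) {
  counts <- table(factor(x$kind, levels = component_kinds))
  cat(sprintf(
    "<component_library> %d constitutive, %d repressor-regulated, %d activator-regulated\n",
    counts[["constitutive"]], counts[["repressor_regulated"]],
    counts[["activator_regulated"]]))
  cat("provenance:", attr(x, "provenance"), "\n")
  print(as_tibble(x), ...)
  invisible(x)
}

#' Read / write a component library
#'
#' The on-disk format is a plain CSV with header
#' `id,kind,Pu,Pl,K,n,KI`; `K`, `n`, `KI` are empty for constitutive rows.
#' Writing then reading reproduces every field exactly (full decimal
#' precision is written).
#'
#' @param path File path.
#' @return `read_library()` returns a `component_library`;
#'   `write_library()` returns `path` invisibly.
#' @export
read_library <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("library file not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           id = readr::col_character(),
                           kind = readr::col_character(),
                           .default = readr::col_double()))
  component_library(raw, provenance = sprintf("read from %s", path))
}

#' @rdname read_library
#' @param lib A `component_library`.
#' @export
write_library <- function(lib, path) {
  stopifnot(inherits(lib, "component_library"))
  readr::write_csv(as_tibble(lib), path)
  invisible(path)
}

#' Generate a synthetic promoter-RBS component library
#'
#' Emulates a characterized parts collection: kinetic strengths `Pu` are
#' log-uniform over `strength_decades` decades (so the library spans weak to
#' strong parts the way real promoter/RBS collections do), basal strengths
#' `Pl` are a small log-uniform fraction (0.1-10%) of `Pu`, binding
#' affinities `K` are log-uniform over `K_range`, cooperativities `n`
#' uniform over `n_range`, and inducer dissociation constants `KI`
#' log-uniform over `KI_range`.
#'
#' @param C,R,A Number of constitutive, repressor-regulated, and
#'   activator-regulated components.
#' @param strength_decades Range of `Pu` (nM/min) as `c(min, max)`, spanning
#'   the library's strength decades.
#' @param K_range,KI_range Log-uniform ranges (nM).
#' @param n_range Uniform range for the Hill coefficient.
#' @param seed Integer seed; same seed, same library.
#' @return A `component_library` with `C + R + A` rows and ids `C1..`,
#'   `R1..`, `A1..`.
#' @examples
#' generate_library(C = 3, R = 2, A = 2, seed = 7)
#' @export
generate_library <- function(C = 6L, R = 6L, A = 6L,
                             strength_decades = c(0.05, 50),
                             K_range = c(1, 100), n_range = c(1, 4),
                             KI_range = c(0.1, 10), seed = NULL) {
  if (C < 1L || R < 0L || A < 0L) abort("counts must be >= 1 (C) / >= 0 (R, A).")
  if (any(strength_decades <= 0) || strength_decades[2] <= strength_decades[1])
    abort("`strength_decades` must be an increasing positive range.")
  runif_log <- function(n, rg) exp(runif(n, log(rg[1]), log(rg[2])))
  with_seed_if(seed, {
    mk_reg <- function(nn, prefix, kind) {
      if (nn == 0L) return(NULL)
      Pu <- runif_log(nn, strength_decades)
      tibble(id = paste0(prefix, seq_len(nn)), kind = kind,
             Pu = Pu, Pl = Pu * runif_log(nn, c(1e-3, 1e-1)),
             K = runif_log(nn, K_range), n = runif(nn, n_range[1], n_range[2]),
             KI = runif_log(nn, KI_range))
    }
    const <- tibble(id = paste0("C", seq_len(C)), kind = "constitutive",
                    Pu = runif_log(C, strength_decades), Pl = 0,
                    K = NA_real_, n = NA_real_, KI = NA_real_)
    component_library(
      dplyr::bind_rows(const, mk_reg(R, "R", "repressor_regulated"),
                       mk_reg(A, "A", "activator_regulated")),
      provenance = sprintf("synthetic (seed %s)", seed %||% "NULL"))
  })
}

#' Fit a promoter-RBS component to a characterization curve
#'
#' Recovers kinetic parameters from measured regulation activity (e.g. GFP
#' reporter rates) across regulator and inducer levels, by least squares
#' against the matching Hill regulation function. `Pu`, `K` and `KI` are
#' fitted on the log scale (enforcing positivity), `Pl` as a log fraction of
#' `Pu`, and the cooperativity `n` is bounded to `[0.5, 6]`. `KI` is only
#' fitted when the curve varies the inducer; otherwise the effective
#' regulator equals the total and `KI` is reported as `NA`.
#'
#' @param curve A data frame with columns `x_reg` (regulator concentration,
#'   nM), `inducer` (nM), `activity` (nM/min, >= 0) and `replicate`. A fit
#'   needs at least 5 distinct regulator or inducer levels.
#' @param kind Component class to fit.
#' @param id Id given to the fitted component.
#' @return An object of class `prbs_fit`: a list with the fitted
#'   `component` (one-row tibble), `residuals`, `rss`, and `fitted`.
#'   [tidy()] returns the parameter estimates; [glance()] the fit summary.
#' @examples
#' a2 <- prbs_component("A1", "activator_regulated", Pu = 8, Pl = 0.4,
#'                      K = 5, n = 2, KI = 1)
#' curve <- tidyr::crossing(x_reg = 30, inducer = 10^seq(-2, 2, 0.5),
#'                          replicate = 1L)
#' curve$activity <- regulation_activated(a2, curve$x_reg, curve$inducer)
#' fit <- fit_component(curve, "activator_regulated")
#' tidy(fit)
#' @export
fit_component <- function(curve, kind = component_kinds, id = "fit") {
  kind <- match.arg(kind)
  curve <- as_tibble(curve)
  need <- c("x_reg", "inducer", "activity")
  if (!all(need %in% names(curve)))
    abort("`curve` needs columns x_reg, inducer, activity.")
  check_nonneg_vec(curve$activity, "activity")

  act <- curve$activity
  if (kind == "constitutive") {
    comp <- prbs_component(id, "constitutive", Pu = mean(act))
    return(new_prbs_fit(comp, act - mean(act), act, curve))
  }

  n_levels <- max(length(unique(curve$x_reg)), length(unique(curve$inducer)))
  if (n_levels < 5L)
    abort("characterization needs at least 5 distinct regulator or inducer levels.")
  span <- diff(range(act))
  if (span < 1e-8 * max(mean(act), 1e-12))
    stop_numeric("flat characterization curve: component parameters are not identifiable.")

  vary_I <- length(unique(curve$inducer)) > 1L
  lo <- max(min(act), 1e-9); hi <- max(act)

  predict_fun <- function(p) {
    Pu <- exp(p[["lPu"]])
    Pl <- Pu * stats::plogis(p[["fPl"]])
    K <- exp(p[["lK"]])
    n <- p[["n"]]
    KI <- if (vary_I) exp(p[["lKI"]]) else Inf
    if (kind == "repressor_regulated") {
      xs <- if (vary_I) effective_repressor(curve$x_reg, curve$inducer, KI)
            else curve$x_reg
      Pl + (Pu - Pl) / (1 + (xs / K)^n)
    } else {
      xs <- if (vary_I) effective_activator(curve$x_reg, curve$inducer, KI)
            else curve$x_reg
      hill <- ifelse(xs > 0, 1 / (1 + (K / xs)^n), 0)
      Pl + (Pu - Pl) * hill
    }
  }
  obj <- function(p) sum((predict_fun(p) - act)^2)

  # moderate multi-start over K / KI decades; L-BFGS-B with n in [0.5, 6]
  xs_scale <- if (kind == "activator_regulated" && vary_I)
    stats::median(curve$x_reg) else stats::median(pmax(curve$x_reg, 1e-6))
  k_starts <- exp(log(max(xs_scale, 1e-3)) + c(-2, 0, 2))
  ki_starts <- if (vary_I) exp(log(max(stats::median(curve$inducer[curve$inducer > 0]),
                                       1e-3)) + c(-1, 0, 1)) else NA
  best <- NULL
  for (k0 in k_starts) for (ki0 in ki_starts) for (n0 in c(1, 2, 4)) {
    p0 <- c(lPu = log(hi), fPl = stats::qlogis(min(max(lo / hi, 1e-6), 0.5)),
            lK = log(k0), n = n0)
    lower <- c(-30, -30, -30, 0.5); upper <- c(30, 30, 30, 6)
    if (vary_I) { p0 <- c(p0, lKI = log(ki0)); lower <- c(lower, -30); upper <- c(upper, 30) }
    fit <- tryCatch(
      optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500L)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stop_numeric("characterization fit failed to converge from all starts.")

  p <- best$par
  Pu <- exp(p[["lPu"]]); Pl <- Pu * stats::plogis(p[["fPl"]])
  comp <- prbs_component(id, kind, Pu = Pu, Pl = Pl, K = exp(p[["lK"]]),
                         n = p[["n"]],
                         KI = if (vary_I) exp(p[["lKI"]]) else 1)
  # KI is not identifiable when the curve never varies the inducer
  if (!vary_I) comp$KI <- NA_real_
  fitted <- predict_fun(p)
  new_prbs_fit(comp, act - fitted, fitted, curve)
}

new_prbs_fit <- function(component, residuals, fitted, curve) {
  structure(list(component = component, residuals = residuals,
                 fitted = fitted, rss = sum(residuals^2),
                 n_obs = length(residuals), curve = curve),
            class = "prbs_fit")
}

#' @export
print.prbs_fit <- function(x, ...) {
  cat(sprintf("<prbs_fit> %s component, %d observations, RSS %.4g\n",
              x$component$kind, x$n_obs, x$rss))
  print(x$component)
  invisible(x)
}

#' @rdname fit_component
#' @param x A `prbs_fit`.
#' @param ... Unused.
#' @method tidy prbs_fit
#' @export
tidy.prbs_fit <- function(x, ...) {
  comp <- x$component
  tidyr::pivot_longer(comp[, c("Pu", "Pl", "K", "n", "KI")],
                      dplyr::everything(),
                      names_to = "term", values_to = "estimate") |>
    dplyr::filter(!is.na(.data$estimate))
}

#' @rdname fit_component
#' @method glance prbs_fit
#' @export
glance.prbs_fit <- function(x, ...) {
  tibble(kind = x$component$kind, n_obs = x$n_obs, rss = x$rss,
         sigma = sqrt(x$rss / max(x$n_obs - 4L, 1L)))
}
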