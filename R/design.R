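#' Circuit template: rates without components
#'
#' A template carries the topology and global rates of a circuit while the
#' promoter-RBS component pair is left open — the design search fills the
#' pair in. Defaults are the package's nominal E. coli rates (see
#' [circuit_spec()]).
#'
#' @inheritParams circuit_spec
#' @return An object of class `circuit_template`.
#' @export
circuit_template <- function(topology = c("activator", "repressor"),
                             gamma_reg = 0.01, gamma_lys = 0.01,
                             k = 0.02, Nmax = 1, gamma_N = 5e-4) {
  topology <- match.arg(topology)
  structure(list(topology = topology, gamma_reg = gamma_reg,
                 gamma_lys = gamma_lys, k = k, Nmax = Nmax,
                 gamma_N = gamma_N),
            class = "circuit_template")
}

regulated_kind <- function(topology)
  if (topology == "repressor") "repressor_regulated" else "activator_regulated"

# build a full circuit_spec from a template (or another spec) and a pair
spec_from_pair <- function(template, constitutive, regulated) {
  circuit_spec(template$topology, constitutive = constitutive,
               regulated = regulated, gamma_reg = template$gamma_reg,
               gamma_lys = template$gamma_lys, k = template$k,
               Nmax = template$Nmax, gamma_N = template$gamma_N)
}

pair_components <- function(lib, S, template) {
  const <- lib_class(lib, "constitutive")
  reg <- lib_class(lib, regulated_kind(template$topology))
  if (length(S) != 2L || S[1] < 1L || S[1] > nrow(const) ||
      S[2] < 1L || S[2] > nrow(reg))
    abort(sprintf("invalid candidate indices (%s); library has %d constitutive and %d regulated components.",
                  paste(S, collapse = ", "), nrow(const), nrow(reg)))
  list(constitutive = const[S[1], ], regulated = reg[S[2], ])
}

#' Tracking cost of a candidate component pair
#'
#' The design cost is the expected integrated squared tracking error between
#' the predicted steady-state density and the prescribed response:
#' the squared deviation `(N_ss(S, I) - N_ref(I))^2` is integrated over the
#' feasible inducer range (trapezoidal rule on a log-spaced grid, 25 points
#' by default) and averaged over a Monte-Carlo parameter-perturbation
#' ensemble. A candidate `S` is the pair (constitutive index, regulated
#' index) into the library classes.
#'
#' @param lib A [component_library()].
#' @param S Integer pair: index of the constitutive component and of the
#'   regulated component (within their library classes).
#' @param template A [circuit_template()] (or `circuit_spec`) giving
#'   topology and rates.
#' @param ref A [reference_response()].
#' @param I_range Feasible inducer range `c(I_min, I_max)` (nM).
#' @param n_grid Number of log-spaced integration points.
#' @param frac,draws,seed Perturbation settings (see [perturb()]);
#'   `frac = 0, draws = 1` gives the deterministic cost.
#' @param noise Optional [noise_spec()] for steady-state v-noise.
#' @param multipliers Optional precomputed perturbation multipliers, shared
#'   across candidates so they are compared under common random numbers.
#' @return The scalar cost `J` (O.D.^2 nM).
#' @examples
#' lib <- demo_library(seed = 1)
#' design_cost(lib, S = attr(lib, "planted_index"), demo_template(),
#'             reference_response(), frac = 0, draws = 1)
#' @export
design_cost <- function(lib, S, template, ref, I_range = c(0.1, 10),
                        n_grid = 25L, frac = 0.05, draws = 100L,
                        seed = NULL, noise = NULL, multipliers = NULL) {
  pair <- pair_components(lib, S, template)
  spec <- spec_from_pair(template, pair$constitutive, pair$regulated)
  grid <- trapz_grid(I_range[1], I_range[2], n_grid)
  if (is.null(multipliers))
    multipliers <- perturbation_multipliers(frac, draws, seed)
  ens <- predicted_density_ensemble(spec, grid, noise = noise, seed = seed,
                                    multipliers = multipliers)
  target <- reference_density(ref, grid)
  per_draw <- ens |>
    dplyr::group_by(.data$draw) |>
    dplyr::summarise(j = pracma::trapz(.data$inducer,
                                       (.data$N_ss - target)^2)) |>
    dplyr::pull("j")
  mean(per_draw)
}

#' Fitness of a design cost
#'
#' The genetic algorithm maximizes fitness, the reciprocal of the tracking
#' cost: `F = 1 / (J + 1e-12)`; the small regularizer keeps a perfect fit
#' (`J = 0`) finite. Minimizing `J` and maximizing `F` are equivalent.
#'
#' @param J Nonnegative cost value(s).
#' @return Fitness value(s), strictly decreasing in `J`.
#' @examples
#' design_fitness(1)      # ~1
#' design_fitness(0)      # 1e12
#' @export
design_fitness <- function(J) {
  check_nonneg_vec(J, "J")
  1 / (J + 1e-12)
}

#' Genetic-algorithm settings
#'
#' @param pop_size Population size (>= 2).
#' @param generations Generation cap.
#' @param p_crossover Probability that a parent pair exchanges one index.
#' @param p_mutation Per-gene probability of replacement by a random index.
#' @param elitism Number of best candidates copied unchanged (0 or 1).
#' @param stop_J Early-stop threshold on the best cost (0 = run all
#'   generations).
#' @param seed Integer seed for the whole search.
#' @return An object of class `ga_settings`.
#' @export
ga_settings <- function(pop_size = 20L, generations = 100L,
                        p_crossover = 0.7, p_mutation = 0.1,
                        elitism = 1L, stop_J = 0, seed = NULL) {
  if (pop_size < 2L) abort("`pop_size` must be >= 2.")
  if (generations < 1L) abort("`generations` must be >= 1.")
  for (p in c(p_crossover, p_mutation))
    if (p < 0 || p > 1) abort("GA probabilities must lie in [0, 1].")
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 elitism = as.integer(elitism), stop_J = stop_J,
                 seed = seed),
            class = "ga_settings")
}

new_design_ranking <- function(candidates, method, settings, ref, template,
                               I_range, lib, generations_run = NA_integer_) {
  ranked <- dplyr::arrange(candidates, .data$cost, .data$i, .data$j)
  structure(ranked, class = c("glc_design", class(ranked)),
            method = method, settings = settings, ref = ref,
            template = template, I_range = I_range, lib = lib,
            generations_run = generations_run)
}

evaluate_pairs <- function(pairs, lib, template, ref, I_range, n_grid,
                           multipliers, noise, seed) {
  const <- lib_class(lib, "constitutive")
  reg <- lib_class(lib, regulated_kind(template$topology))
  costs <- purrr::map_dbl(seq_len(nrow(pairs)), function(r) {
    design_cost(lib, c(pairs$i[r], pairs$j[r]), template, ref,
                I_range = I_range, n_grid = n_grid,
                multipliers = multipliers, noise = noise, seed = seed)
  })
  tibble(i = pairs$i, j = pairs$j,
         constitutive = const$id[pairs$i], regulated = reg$id[pairs$j],
         cost = costs, fitness = design_fitness(costs))
}

#' Exhaustive search over all component pairs
#'
#' Evaluates the tracking cost of every (constitutive, regulated) pair in
#' the library under identical cost settings and returns them ranked by
#' ascending cost (ties broken by the constitutive then the regulated
#' index). This is the brute-force oracle the genetic algorithm is checked
#' against; it is guarded above 1e5 pairs.
#'
#' @inheritParams design_cost
#' @return A `glc_design` ranking: a tibble with columns `i`, `j`,
#'   `constitutive`, `regulated`, `cost`, `fitness`.
#' @examples
#' lib <- demo_library(seed = 1)
#' head(exhaustive_search(lib, demo_template(), reference_response(),
#'                        frac = 0, draws = 1), 3)
#' @export
exhaustive_search <- function(lib, template, ref, I_range = c(0.1, 10),
                              n_grid = 25L, frac = 0.05, draws = 100L,
                              seed = NULL, noise = NULL) {
  nC <- nrow(lib_class(lib, "constitutive"))
  nR <- nrow(lib_class(lib, regulated_kind(template$topology)))
  if (nC < 1L || nR < 1L)
    abort(sprintf("library has no components for the %s topology.",
                  template$topology))
  if (nC * nR > 1e5) abort("refusing to enumerate more than 1e5 pairs.")
  multipliers <- perturbation_multipliers(frac, draws, seed)
  pairs <- tidyr::crossing(i = seq_len(nC), j = seq_len(nR))
  cand <- evaluate_pairs(pairs, lib, template, ref, I_range, n_grid,
                         multipliers, noise, seed)
  new_design_ranking(cand, "exhaustive",
                     list(I_range = I_range, n_grid = n_grid, frac = frac,
                          draws = draws, seed = seed),
                     ref, template, I_range, lib)
}

#' Genetic-algorithm search for the best component pair
#'
#' Searches the library for the (constitutive, regulated) pair minimizing
#' the tracking cost, encoding a candidate as its index pair. Each
#' generation applies fitness-proportional reproduction, single-index
#' crossover between parent pairs, per-index uniform random mutation, and
#' elitism on the best pair found; the search stops at the generation cap or
#' as soon as the best cost drops to `stop_J`. All candidates within one
#' search share the same perturbation draws (common random numbers), so
#' costs are comparable and the search is reproducible from its seed.
#'
#' @inheritParams design_cost
#' @param settings A [ga_settings()].
#' @return A `glc_design` ranking of every distinct candidate evaluated,
#'   sorted by ascending cost. `glance()` summarizes the best candidate;
#'   `autoplot()` shows its tracking curve against the reference.
#' @examples
#' lib <- demo_library(seed = 1)
#' des <- ga_search(lib, demo_template(), reference_response(),
#'                  frac = 0, draws = 1,
#'                  settings = ga_settings(generations = 30, seed = 7))
#' glance(des)
#' @export
ga_search <- function(lib, template, ref, I_range = c(0.1, 10), n_grid = 25L,
                      frac = 0.05, draws = 100L, noise = NULL,
                      settings = ga_settings()) {
  nC <- nrow(lib_class(lib, "constitutive"))
  nR <- nrow(lib_class(lib, regulated_kind(template$topology)))
  if (nC < 1L || nR < 1L)
    abort(sprintf("library has no components for the %s topology.",
                  template$topology))
  seed <- settings$seed
  seeds <- if (is.null(seed)) list(NULL, NULL) else as.list(derive_seeds(seed, 2L))
  multipliers <- perturbation_multipliers(frac, draws, seeds[[1]])

  cache <- new.env(parent = emptyenv())
  cost_of <- function(i, j) {
    key <- paste(i, j)
    if (!exists(key, envir = cache, inherits = FALSE))
      assign(key,
             design_cost(lib, c(i, j), template, ref, I_range = I_range,
                         n_grid = n_grid, multipliers = multipliers,
                         noise = noise, seed = seeds[[1]]),
             envir = cache)
    get(key, envir = cache, inherits = FALSE)
  }

  gens_run <- 0L
  with_seed_if(seeds[[2]], {
    pop <- cbind(sample.int(nC, settings$pop_size, replace = TRUE),
                 sample.int(nR, settings$pop_size, replace = TRUE))
    best <- NULL
    for (gen in seq_len(settings$generations)) {
      gens_run <- gen
      costs <- vapply(seq_len(nrow(pop)),
                      function(r) cost_of(pop[r, 1L], pop[r, 2L]), numeric(1))
      gb <- which.min(costs)
      if (is.null(best) || costs[gb] < best$cost)
        best <- list(pair = pop[gb, ], cost = costs[gb])
      if (best$cost <= settings$stop_J) break
      # reproduction: fitness-proportional copying
      fit <- design_fitness(costs)
      parents <- pop[sample.int(nrow(pop), settings$pop_size, replace = TRUE,
                                prob = fit / sum(fit)), , drop = FALSE]
      # crossover: swap one index between consecutive parent pairs
      for (p in seq(1L, settings$pop_size - 1L, by = 2L)) {
        if (runif(1) < settings$p_crossover) {
          g <- sample(1:2, 1L)
          tmp <- parents[p, g]
          parents[p, g] <- parents[p + 1L, g]
          parents[p + 1L, g] <- tmp
        }
      }
      # mutation: replace an index with a uniform random valid index
      mut <- matrix(runif(length(parents)) < settings$p_mutation,
                    nrow = nrow(parents))
      if (any(mut[, 1L]))
        parents[mut[, 1L], 1L] <- sample.int(nC, sum(mut[, 1L]), replace = TRUE)
      if (any(mut[, 2L]))
        parents[mut[, 2L], 2L] <- sample.int(nR, sum(mut[, 2L]), replace = TRUE)
      if (settings$elitism > 0L) parents[1L, ] <- best$pair
      pop <- parents
    }
  })

  keys <- ls(cache)
  idx <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
  cand <- evaluate_pairs(
    tibble(i = as.integer(idx[, 1L]), j = as.integer(idx[, 2L])),
    lib, template, ref, I_range, n_grid, multipliers, noise, seeds[[1]])
  new_design_ranking(cand, "ga", settings, ref, template, I_range, lib,
                     generations_run = gens_run)
}

#' @export
print.glc_design <- function(x, ...) {
  cat(sprintf("<glc_design> %s search, %d candidate(s) evaluated\n",
              attr(x, "method"), nrow(x)))
  best <- x[1L, ]
  cat(sprintf("  best pair: (%s, %s), J = %.4g, F = %.4g\n",
              best$constitutive, best$regulated, best$cost, best$fitness))
  print(as_tibble(x), ...)
  invisible(x)
}

#' Tidiers for design rankings
#'
#' `tidy()` returns the ranked candidate table; `glance()` a one-row
#' summary of the search and its best candidate; `tracking_table()` the
#' best candidate's deterministic steady-state density against the
#' reference over the inducer grid.
#'
#' @param x A `glc_design` from [ga_search()] or [exhaustive_search()].
#' @param ... Unused.
#' @method tidy glc_design
#' @export
tidy.glc_design <- function(x, ...) as_tibble(x)

#' @rdname tidy.glc_design
#' @method glance glc_design
#' @export
glance.glc_design <- function(x, ...) {
  best <- x[1L, ]
  tibble(method = attr(x, "method"), n_evaluated = nrow(x),
         constitutive = best$constitutive, regulated = best$regulated,
         best_cost = best$cost, best_fitness = best$fitness,
         generations = attr(x, "generations_run"))
}

#' @rdname tidy.glc_design
#' @param n_grid Number of log-spaced inducer points in the table.
#' @export
tracking_table <- function(x, n_grid = 25L) {
  stopifnot(inherits(x, "glc_design"))
  template <- attr(x, "template"); lib <- attr(x, "lib")
  ref <- attr(x, "ref"); I_range <- attr(x, "I_range")
  pair <- pair_components(lib, c(x$i[1L], x$j[1L]), template)
  spec <- spec_from_pair(template, pair$constitutive, pair$regulated)
  grid <- trapz_grid(I_range[1], I_range[2], n_grid)
  ss <- steady_state(spec, grid)
  tibble(inducer = grid, N_ss = ss$N_ss,
         N_ref = reference_density(ref, grid),
         rel_error = abs(ss$N_ss - reference_density(ref, grid)) /
           reference_density(ref, grid))
}

#' @rdname tidy.glc_design
#' @param object A `glc_design`.
#' @method autoplot glc_design
#' @export
autoplot.glc_design <- function(object, ...) {
  tt <- tracking_table(object)
  long <- tidyr::pivot_longer(tt, c("N_ss", "N_ref"), names_to = "curve",
                              values_to = "density")
  long$curve <- factor(long$curve, levels = c("N_ref", "N_ss"),
                       labels = c("prescribed response", "best design"))
  ggplot2::ggplot(long, ggplot2::aes(.data$inducer, .data$density,
                                     linetype = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "inducer (nM)", y = "steady-state density (O.D. 600)",
                  title = "Steady-state density vs prescribed response")
}

#' Write a plain-text design report
#'
#' Echoes the search settings, the ranked candidates, and the best
#' candidate's per-inducer tracking table.
#'
#' @param design A `glc_design`.
#' @param path Destination text file.
#' @return `path`, invisibly.
#' @export
write_design_report <- function(design, path) {
  g <- glance(design)
  s <- attr(design, "settings")
  lines <- c(
    "# Genetic lysis circuit design report",
    sprintf("method: %s", g$method),
    sprintf("library provenance: %s", attr(attr(design, "lib"), "provenance")),
    sprintf("inducer range: [%g, %g] nM", attr(design, "I_range")[1],
            attr(design, "I_range")[2]),
    paste0("settings: ", paste(sprintf("%s=%s", names(s),
                                       vapply(s, function(v) paste(format(v), collapse = ","),
                                              character(1))),
                               collapse = " ")),
    sprintf("best pair: (%s, %s)  J = %.6g  F = %.6g", g$constitutive,
            g$regulated, g$best_cost, g$best_fitness),
    "",
    "## Ranked candidates",
    readr::format_csv(tidy(design)),
    "## Best-candidate tracking (deterministic)",
    readr::format_csv(tracking_table(design)))
  writeLines(lines, path)
  invisible(path)
}
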