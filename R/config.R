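#' Declarative run configuration
#'
#' A run configuration is a plain nested list of primitives (so it
#' round-trips through YAML unchanged) describing a complete POPE run:
#' which simulator, which prior, the constraint list, the sampler
#' settings, optional adaptation settings, and output paths.  Re-running
#' an identical configuration reproduces the trace bit for bit.
#'
#' Supported simulator ids: `"gaussian_testbed"` (field `sigma`),
#' `"quadratic_testbed"`, `"niche"` (fields `n_target`, `M`, `D` and the
#' `niche_prior_spec()` thresholds), `"pattern"` (fields of [gm_grid()]).
#'
#' @param simulator list with at least `id`.
#' @param prior `NULL` to use the simulator's canonical prior (`niche`,
#'   `pattern`), or a list of margins `{name, type, ...params}` with
#'   types `normal`, `uniform`, `lognormal`, `beta`.
#' @param constraints list of constraint records `{statistic, direction,
#'   threshold, kernel, epsilon, epsilon_min, objective}` (threshold may
#'   be `.inf` for an unconstrained objective slot).
#' @param sampler list of [pope_config()] fields; `seed` is mandatory.
#' @param adaptation optional list of [adapt_config()] fields.
#' @param output optional list with `trace` and `metadata` paths.
#' @return a `pope_run_config` list.
#' @export
run_config <- function(simulator, constraints, sampler, prior = NULL,
                       adaptation = NULL, output = NULL) {
  cfg <- list(simulator = simulator, prior = prior,
              constraints = constraints, sampler = sampler,
              adaptation = adaptation, output = output)
  validate_run_config(cfg)
  structure(cfg, class = c("pope_run_config", "list"))
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$simulator$id))
    stop("config error: simulator$id is required")
  if (!cfg$simulator$id %in%
      c("gaussian_testbed", "quadratic_testbed", "niche", "pattern"))
    stop("config error: unknown simulator id '", cfg$simulator$id, "'")
  if (is.null(cfg$constraints) || length(cfg$constraints) == 0)
    stop("config error: at least one constraint is required")
  for (k in cfg$constraints) {
    if (is.null(k$statistic) || is.null(k$direction) || is.null(k$threshold))
      stop("config error: constraints need statistic, direction, threshold")
  }
  if (is.null(cfg$sampler$seed))
    stop("config error: sampler$seed is mandatory")
  if (cfg$simulator$id %in% c("gaussian_testbed", "quadratic_testbed") &&
      is.null(cfg$prior))
    stop("config error: testbed simulators need an explicit prior")
  invisible(cfg)
}

#' Read / write run configurations (YAML)
#'
#' @param path file path.
#' @param config a [run_config()].
#' @return `read_run_config` returns the validated `pope_run_config`;
#'   `write_run_config` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
  structure(cfg, class = c("pope_run_config", "list"))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

constraints_from_config <- function(records) {
  lapply(records, function(k)
    constraint_spec(statistic = k$statistic, direction = k$direction,
                    threshold = unlist(k$threshold),
                    kernel = if (is.null(k$kernel)) "gaussian_one_sided" else k$kernel,
                    epsilon = if (is.null(k$epsilon)) 0.01 else k$epsilon,
                    epsilon_min = if (is.null(k$epsilon_min)) 0 else k$epsilon_min,
                    objective = isTRUE(k$objective)))
}

prior_from_config <- function(records) {
  margins <- lapply(records, function(m)
    switch(m$type,
           normal = prior_normal(m$mean %||% 0, m$sd %||% 1),
           uniform = prior_uniform(m$min %||% 0, m$max %||% 1),
           lognormal = prior_lognormal(m$meanlog %||% 0, m$sdlog %||% 1),
           beta = prior_beta(m$shape1 %||% 2, m$shape2 %||% 2),
           stop("config error: unknown prior type '", m$type, "'")))
  names(margins) <- vapply(records, function(m)
    m$name %||% "", character(1))
  pope_prior(margins)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Instantiate a run configuration
#'
#' Turns the declarative configuration into the live objects
#' [run_pope()] needs: the simulator closure, the prior, the constraint
#' specs, the sampler config, and the adaptation config.
#'
#' @param config a [run_config()] (or path to one).
#' @return list with `simulator`, `prior`, `specs`, `sampler`,
#'   `adaptation`.
#' @export
build_run <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  sim <- config$simulator
  simulator <- switch(sim$id,
    gaussian_testbed = gaussian_test_simulator(sim$sigma %||% 0.5),
    quadratic_testbed = quadratic_test_simulator(),
    niche = niche_simulator(n_target = sim$n_target %||% 300,
                            M = sim$M %||% 1),
    pattern = pattern_simulator(gm_grid(
      n_x = sim$n_x %||% 256, length = sim$length %||% 1,
      dt = sim$dt %||% 5e-4, t_final = sim$t_final %||% 8,
      D_WI = sim$D_WI, noise = sim$noise %||% 0.01,
      seed = sim$grid_seed %||% 1)))
  prior <- if (!is.null(config$prior)) {
    prior_from_config(config$prior)
  } else if (sim$id == "niche") {
    ps <- niche_prior_spec(tau_g1 = sim$tau_g1 %||% 399,
                           tau_gd = sim$tau_gd %||% 10,
                           tau_theta = sim$tau_theta %||% 400)
    niche_prior(ps, D = sim$D %||% 8)
  } else if (sim$id == "pattern") {
    gm_prior()
  } else stop("config error: this simulator needs an explicit prior")
  sm <- config$sampler
  sampler <- pope_config(mode = sm$mode %||% "pseudo_marginal",
                         S = sm$S %||% 1,
                         n_iterations = sm$n_iterations %||% 10000,
                         burnin = sm$burnin %||% 0,
                         proposal_scales = unlist(sm$proposal_scales),
                         seed = sm$seed,
                         estimator = sm$estimator %||% "kernel_mc")
  adaptation <- if (!is.null(config$adaptation)) {
    ad <- config$adaptation
    adapt_config(beta = ad$beta %||% 0.2, delta = ad$delta %||% 0.9,
                 gamma = ad$gamma %||% 0.9, window = ad$window %||% 500,
                 adapt_epsilon = ad$adapt_epsilon %||% TRUE,
                 adapt_objective = ad$adapt_objective %||% FALSE,
                 deterministic = ad$deterministic %||% FALSE,
                 ramp = ad$ramp)
  } else NULL
  list(simulator = simulator, prior = prior,
       specs = constraints_from_config(config$constraints),
       sampler = sampler, adaptation = adaptation)
}

#' Execute a run configuration
#'
#' Builds and runs the configured POPE chain; if the configuration names
#' output paths, the trace is written as a tab-separated table and the
#' run metadata (final epsilons and thresholds, acceptance rate,
#' simulation count) as a JSON sidecar.
#'
#' @param config a [run_config()] or a path to a YAML configuration.
#' @param quiet suppress the one-line completion message.
#' @return the `pope_trace`, invisibly when output files are written.
#' @export
execute_run <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  parts <- build_run(config)
  trace <- run_pope(parts$simulator, parts$prior, parts$specs,
                    parts$sampler, adaptation = parts$adaptation)
  if (!is.null(config$output$trace)) {
    write_trace(trace, config$output$trace)
    meta_path <- config$output$metadata %||%
      paste0(config$output$trace, ".meta.json")
    write_trace_metadata(trace, meta_path)
    if (!quiet)
      message("trace written to ", config$output$trace,
              " (acceptance ", round(100 * attr(trace, "acceptance_rate"), 1),
              "%)")
    return(invisible(trace))
  }
  trace
}

#' Trace file IO
#'
#' Traces are written as flat tab-separated tables, one row per iteration
#' (including the initial state), with full double precision so identical
#' runs produce byte-identical files.
#'
#' @param trace a `pope_trace`.
#' @param path output path.
#' @return `path` (write) or the trace data frame (read), invisibly for
#'   the writers.
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  if (nrow(df) == 0) stop("trace file is empty: ", path)
  df$accepted <- as.logical(df$accepted)
  df$burnin <- as.logical(df$burnin)
  class(df) <- c("pope_trace", "data.frame")
  df
}

write_trace_metadata <- function(trace, path) {
  meta <- list(acceptance_rate = attr(trace, "acceptance_rate"),
               n_simulations = attr(trace, "n_simulations"),
               final_eps = attr(trace, "final_eps"),
               final_thresholds = attr(trace, "final_thresholds"),
               n_records = nrow(trace))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Rolling acceptance-rate report
#'
#' Acceptance rates in rolling windows over a trace — the preliminary-run
#' diagnostic used to set epsilon before fixing it (a rate around 20-40%
#' is a common target).
#'
#' @param trace a `pope_trace`.
#' @param window window length in iterations.
#' @return data frame with columns `iteration` and `acceptance_rate`.
#' @export
acceptance_report <- function(trace, window = 100) {
  acc <- trace$accepted[-1]
  n <- length(acc)
  if (n < window) window <- max(1, n)
  at <- seq(window, n, by = window)
  data.frame(iteration = at,
             acceptance_rate = vapply(at, function(i)
               mean(acc[(i - window + 1):i]), numeric(1)))
}

#' Shipped experiment configurations
#'
#' Builds the demonstration run configurations: the stem-cell niche
#' experiment grid (A-E: constrained vs free increments, objective
#' present, removed, or adaptive, larger total-size budget, replicate
#' averaging, loose kernel width) and the Mock-constrained pattern run.
#' Absolute objective thresholds are not portable across niche simulator
#' implementations, so niche objectives are shipped as adaptive (the
#' threshold is learned online during burn-in) or absent.
#'
#' @param name one of `"A1"`, `"A2"`, `"B1"`, `"B2"`, `"C1"`, `"C2"`,
#'   `"D1"`, `"D2"`, `"E1"`, `"E2"`, `"case2_mock"`.
#' @param seed sampler seed stored in the configuration.
#' @param n_iterations,burnin chain length settings.
#' @return a [run_config()].
#' @export
pope_fixture_config <- function(name, seed = 1, n_iterations = 10000,
                                burnin = 2000) {
  niche_cfg <- function(tau_gd, tau_theta = 400, eps_y = 0.01, M = 1,
                        objective = TRUE) {
    run_config(
      simulator = list(id = "niche", n_target = 300, M = M, D = 8,
                       tau_g1 = 399, tau_gd = tau_gd,
                       tau_theta = tau_theta),
      constraints = list(list(statistic = 1, direction = "LE",
                              threshold = Inf,
                              kernel = "gaussian_one_sided",
                              epsilon = eps_y, epsilon_min = eps_y,
                              objective = objective)),
      sampler = list(mode = "marginal", S = 1,
                     n_iterations = n_iterations, burnin = burnin,
                     proposal_scales = 0.25, seed = seed),
      adaptation = if (objective)
        list(adapt_epsilon = FALSE, adapt_objective = TRUE,
             deterministic = FALSE, gamma = 0.9) else NULL)
  }
  switch(name,
    A1 = niche_cfg(tau_gd = 399),
    A2 = niche_cfg(tau_gd = 10),
    B1 = niche_cfg(tau_gd = 399, objective = FALSE),
    B2 = niche_cfg(tau_gd = 10, objective = FALSE),
    C1 = niche_cfg(tau_gd = 399, tau_theta = 1500, objective = FALSE),
    C2 = niche_cfg(tau_gd = 399, tau_theta = 1500),
    D1 = niche_cfg(tau_gd = 399, M = 10),
    D2 = niche_cfg(tau_gd = 10, M = 10),
    E1 = niche_cfg(tau_gd = 399, eps_y = 0.5),
    E2 = niche_cfg(tau_gd = 10, eps_y = 0.5),
    case2_mock = run_config(
      simulator = list(id = "pattern", n_x = 256, t_final = 8,
                       dt = 5e-4, noise = 0.01, grid_seed = 1),
      constraints = lapply(mock_constraint_specs(), function(s)
        list(statistic = s$statistic, direction = s$direction,
             threshold = as.list(s$threshold), kernel = s$kernel,
             epsilon = s$epsilon, epsilon_min = s$epsilon_min,
             objective = FALSE)),
      sampler = list(mode = "pseudo_marginal", S = 1,
                     n_iterations = n_iterations, burnin = burnin,
                     proposal_scales = 0.15, seed = seed)),
    stop("unknown fixture '", name, "'"))
}

#' @rdname pope_fixture_config
#' @param dir directory the YAML files are written into.
#' @return `pope_fixture_configs` writes all fixtures and returns their
#'   paths.
#' @export
pope_fixture_configs <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  names <- c("A1", "A2", "B1", "B2", "C1", "C2", "D1", "D2", "E1", "E2",
             "case2_mock")
  vapply(names, function(nm) {
    path <- file.path(dir, paste0(nm, ".yaml"))
    write_run_config(pope_fixture_config(nm), path)
    path
  }, character(1))
}
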