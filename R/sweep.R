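# Parameter sweeps over incompatibility strength or dominance, the
# numeric-vs-analytic validation report, and plain-text serialization used by
# the command-line driver.

#' Sweep the gene flow factor over a parameter grid
#'
#' Evaluates the gene flow factor (graph method) along a grid of one swept
#' parameter, optionally tying several coefficients together (e.g.
#' `sweep = c("s1", "s2")` for symmetric MtNI) and across several scenarios
#' (e.g. migrant sex ratios `mf` of 0, 0.5 and 1). This reproduces the
#' standard curve families: factor versus incompatibility level per model and
#' versus dominance at fixed selection.
#'
#' @param model Model id `"A"`--`"D"`.
#' @param sweep Character vector of parameter names that all take the grid
#'   value (must belong to the model).
#' @param grid Numeric grid in `[0, 1]` (default 101 points).
#' @param scenarios Named list; each element is a list of fixed parameter
#'   values defining one scenario. Default: a single unnamed scenario.
#' @param fixed List of parameter values common to all scenarios.
#' @param d_variant Model D variant.
#' @return A long-format data frame with columns `model`, `scenario`,
#'   `param`, `value`, `gene_flow_factor`, `pct_reduction`, `v_male`,
#'   `v_female` (for the unsexed models both columns carry the single
#'   migrant value).
#' @examples
#' run_sweep("A", sweep = c("s1", "s2"), grid = c(0, 0.5, 1),
#'           scenarios = list(females = list(mf = 1), males = list(mf = 0)))
#' @export
run_sweep <- function(model, sweep, grid = seq(0, 1, length.out = 101),
                      scenarios = list(default = list()),
                      fixed = list(), d_variant = "asymmetric") {
  stopifnot(is.character(sweep), length(sweep) >= 1)
  if (!all(grid >= 0 & grid <= 1)) stop("sweep grid must lie within [0, 1]")
  if (is.null(names(scenarios))) names(scenarios) <- paste0("scenario", seq_along(scenarios))
  rows <- list()
  for (sc in names(scenarios)) {
    for (val in grid) {
      args <- c(list(model = model), fixed)
      for (pn in names(scenarios[[sc]])) args[[pn]] <- scenarios[[sc]][[pn]]
      for (pn in sweep) args[[pn]] <- val
      if (model == "D") args$d_variant <- d_variant
      params <- tryCatch(do.call(incompatibility_model, args), error = function(e) {
        stop(sprintf("invalid sweep spec (scenario '%s', %s = %g): %s",
                     sc, paste(sweep, collapse = "/"), val, conditionMessage(e)))
      })
      v <- reproductive_values(fitness_graph(params))
      if (is_sexed(params)) {
        vf <- v[[genotype_label(migrant_genotype(model, "female"))]]
        vm <- v[[genotype_label(migrant_genotype(model, "male"))]]
        gff <- (1 - params$mf) * vm + params$mf * vf
      } else {
        vf <- vm <- v[[genotype_label(migrant_genotype(model))]]
        gff <- vm
      }
      rows[[length(rows) + 1L]] <- data.frame(
        model = model, scenario = sc, param = paste(sweep, collapse = "+"),
        value = val, gene_flow_factor = gff,
        pct_reduction = 100 * (1 - gff),
        v_male = vm, v_female = vf, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Validate the weak-migration limit numerically
#'
#' Draws random parameter sets per model, estimates the gene flow factor from
#' the forward recursion at each migration rate in `m_grid`, and compares the
#' estimate at the smallest rate with the analytic (closed-form) factor.
#'
#' @param models Character vector of model ids to validate.
#' @param m_grid Positive migration rates; the smallest is used for the
#'   pass/fail comparison.
#' @param n_draws Random parameter draws per model.
#' @param seed Integer seed for the parameter draws (recorded in the report).
#' @param rel_tol Pass threshold on the relative error (default 1%).
#' @param ... Passed to [sim_config()].
#' @return An object of class `limit_report`: list with `draws` (one row per
#'   draw and migration rate), `max_rel_error` (over converged runs at the
#'   smallest rate), `pass`, `seed` and `non_converged`.
#' @examples
#' validate_limits(models = "B", m_grid = 1e-3, n_draws = 2, seed = 1)
#' @export
validate_limits <- function(models = c("A", "B", "C", "D"),
                            m_grid = c(1e-3, 1e-4), n_draws = 20, seed = 1,
                            rel_tol = 0.01, ...) {
  stopifnot(all(m_grid > 0), n_draws >= 1)
  m_grid <- sort(m_grid, decreasing = TRUE)
  set.seed(seed)
  rows <- list()
  for (model in models) {
    for (d in seq_len(n_draws)) {
      u <- stats::runif(5)
      params <- switch(model,
        A = incompatibility_model("A", s1 = u[1], s2 = u[2], mf = u[5]),
        B = incompatibility_model("B", sA = u[1], sB = u[2]),
        C = incompatibility_model("C", s1 = u[1], s2 = u[2],
                                  h1 = u[3], h2 = u[4], mf = u[5]),
        D = if (d %% 2 == 1) {
          incompatibility_model("D", sA = u[1], hA = u[3])
        } else {
          incompatibility_model("D", s = u[1], h = u[3], d_variant = "symmetric")
        })
      va <- analytic_gene_flow_factor(params)
      for (m in m_grid) {
        est <- effective_migration_rate(sim_config(params, m = m, ...))
        rows[[length(rows) + 1L]] <- data.frame(
          model = model, draw = d, m = m,
          analytic = va, numeric = est$gene_flow_factor,
          rel_error = abs(est$gene_flow_factor - va) / max(va, 1e-300),
          converged = est$converged, criterion = est$criterion,
          generations = est$generations, stringsAsFactors = FALSE)
      }
    }
  }
  draws <- do.call(rbind, rows)
  at_min <- draws[draws$m == min(m_grid), ]
  usable <- at_min[at_min$converged, ]
  out <- list(draws = draws,
              max_rel_error = if (nrow(usable)) max(usable$rel_error) else NA_real_,
              pass = nrow(usable) > 0 && max(usable$rel_error) < rel_tol,
              rel_tol = rel_tol, seed = seed,
              non_converged = at_min[!at_min$converged, ])
  class(out) <- "limit_report"
  out
}

#' @export
print.limit_report <- function(x, ...) {
  cat(sprintf("Weak-migration limit validation (seed %d): %s\n",
              x$seed, if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  max relative error at smallest m: %.3g (threshold %.3g)\n",
              x$max_rel_error, x$rel_tol))
  if (nrow(x$non_converged)) {
    cat(sprintf("  %d non-converged run(s) excluded:\n", nrow(x$non_converged)))
    print(x$non_converged[c("model", "draw", "m", "generations")])
  }
  invisible(x)
}

#' Write and re-read result tables as CSV
#'
#' Numeric columns are written with 17 significant digits, which round-trips
#' IEEE doubles exactly: reading the file back reproduces the written values
#' bit for bit.
#'
#' @param tab A data frame.
#' @param path Output path.
#' @return `path`, invisibly (`write_result_csv`); the data frame
#'   (`read_result_csv`).
#' @export
write_result_csv <- function(tab, path) {
  fmt <- tab
  for (j in seq_along(fmt)) {
    if (is.double(fmt[[j]])) fmt[[j]] <- sprintf("%.17g", fmt[[j]])
  }
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_result_csv
#' @export
read_result_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a model/simulation configuration from a YAML file
#'
#' The file holds a `model` key, the model's parameters, and optionally
#' `d_variant` and simulation settings (`m`, `q`, `p0`, `t_max`, `tol`,
#' `life_cycle`).
#'
#' @param path Path to a YAML file.
#' @return A list with `params` (an [incompatibility_model()]) and `sim`
#'   (list of simulation settings, possibly empty).
#' @export
read_model_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$model)) stop("config file must contain a 'model' key")
  sim_keys <- c("m", "q", "p0", "t_max", "tol", "life_cycle")
  par_keys <- setdiff(names(raw), sim_keys)
  params <- do.call(incompatibility_model, raw[par_keys])
  list(params = params, sim = raw[intersect(sim_keys, names(raw))])
}

#' Plot a sweep table
#'
#' Convenience layer over the CSV output: gene flow factor versus the swept
#' parameter, one line per scenario. Requires ggplot2.
#'
#' @param tab Output of [run_sweep()].
#' @return A ggplot object.
#' @export
plot_sweep <- function(tab) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_sweep() requires the ggplot2 package")
  }
  value <- gene_flow_factor <- scenario <- NULL # aes() binds columns
  ggplot2::ggplot(tab, ggplot2::aes(x = value, y = gene_flow_factor,
                                    colour = scenario)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = unique(tab$param), y = "gene flow factor (m_e / m)",
                  title = sprintf("Model %s", unique(tab$model)))
}
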