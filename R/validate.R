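# Quantitative validation of a reduction: back-translation of reduced
# trajectories to the original state variables, the per-species relative
# difference epsilon_i(t) = |x_orig - x_red| / x_orig, and parameter
# robustness scans of its summary norms.

#' Back-translate a reduced trajectory to original species
#'
#' Evaluates the fraction-parameter map along a reduced-model trajectory to
#' recover the original state variables without re-simulation. Lump members
#' sum exactly (to arithmetic precision) to their lump's trajectory.
#'
#' @param traj a `Trajectory` of a `ReducedModel` (from [simulate_model()]).
#' @param reduced the `ReducedModel` that produced it.
#' @param species which original species to recover (default: all with a
#'   back-translation; requesting one without raises an error).
#' @return a `Trajectory` over the original species.
#' @export
back_translate <- function(traj, reduced, species = NULL) {
  g <- reduced$fractions$g
  avail <- names(g)
  if (is.null(species)) species <- avail
  missing <- setdiff(species, avail)
  if (length(missing)) {
    stop("non-back-translatable species: ", paste(missing, collapse = ", "))
  }
  p <- attr(traj, "params")
  env <- c(as.list(traj), as.list(reduced$constants), as.list(p))
  env$t <- traj$time
  out <- data.frame(time = traj$time)
  for (s in species) {
    e <- rf_to_expr(g[[s]])
    v <- eval(e, env)
    out[[s]] <- rep_len(v, nrow(traj))
  }
  structure(out, params = p, model_id = paste0(attr(traj, "model_id"),
                                               "-backtranslated"),
            class = c("Trajectory", "data.frame"))
}

#' Relative difference between an original and a back-translated trajectory
#'
#' Computes `eps_i(t) = |x_orig_i(t) - x_red_i(t)| / x_orig_i(t)` for every
#' shared species on the shared time grid, plus the two summary norms used in
#' robustness tables: the maximum over species of the time-mean of eps, and
#' the maximum over species of the time-maximum of eps. Samples where the
#' original state is below `skip_tol` are skipped and logged.
#'
#' @param orig original-model `Trajectory`.
#' @param red_bt back-translated reduced `Trajectory` on the same grid.
#' @param skip_tol denominator threshold below which a sample is skipped.
#' @return a `ComparisonSummary`: per-species table (`species`), the summary
#'   scalars (`max_mean`, `max_inf`), the full eps matrix, and a skip log.
#' @export
relative_difference <- function(orig, red_bt, skip_tol = 1e-9) {
  tt <- intersect(orig$time, red_bt$time)
  if (!length(tt)) stop("trajectories share no time points")
  if (length(tt) < length(orig$time) || length(tt) < length(red_bt$time)) {
    o <- orig[orig$time %in% tt, , drop = FALSE]
    r <- red_bt[red_bt$time %in% tt, , drop = FALSE]
  } else {
    o <- orig; r <- red_bt
  }
  species <- intersect(setdiff(names(o), "time"), setdiff(names(r), "time"))
  if (!length(species)) stop("trajectories share no species")
  eps <- matrix(NA_real_, length(tt), length(species),
                dimnames = list(NULL, species))
  skipped <- data.frame(time = numeric(0), species = character(0))
  for (s in species) {
    xo <- o[[s]]; xr <- r[[s]]
    ok <- abs(xo) > skip_tol
    eps[ok, s] <- abs(xo[ok] - xr[ok]) / xo[ok]
    if (any(!ok)) {
      skipped <- rbind(skipped, data.frame(time = tt[!ok], species = s))
    }
  }
  per_species <- data.frame(
    species = species,
    mean_eps = vapply(species, function(s) mean(eps[, s], na.rm = TRUE),
                      numeric(1)),
    inf_eps = vapply(species, function(s) max(eps[, s], na.rm = TRUE),
                     numeric(1)),
    row.names = NULL)
  structure(list(species = per_species,
                 max_mean = max(per_species$mean_eps),
                 max_inf = max(per_species$inf_eps),
                 eps = eps, time = tt, skipped = skipped,
                 orig = o, reduced = r),
            class = "ComparisonSummary")
}

#' @export
print.ComparisonSummary <- function(x, ...) {
  cat("ComparisonSummary over", length(x$time), "samples:\n")
  print(x$species, row.names = FALSE)
  cat(sprintf("max over species: mean eps = %.4g, inf eps = %.4g\n",
              x$max_mean, x$max_inf))
  if (nrow(x$skipped)) {
    cat(nrow(x$skipped), "sample(s) skipped (original state ~ 0)\n")
  }
  invisible(x)
}

#' Simulate, back-translate and compare a reduction against its original
#'
#' Convenience pipeline: simulates the original model and the reduced model
#' on the sampling grid `seq(t0, t_end, by = dt)` (reduced initial conditions
#' re-derived at the supplied parameters), back-translates, and summarizes
#' the relative difference.
#'
#' @param network the original [reaction_network()].
#' @param reduced a `ReducedModel`.
#' @param t_end horizon; the grid starts at `t0` (default `dt`).
#' @param dt sampling interval.
#' @param t0 first sample.
#' @param params optional parameter overrides applied to both models.
#' @param ic_method initial-condition route (see
#'   [reduced_initial_conditions()]).
#' @param species species to compare (default: all back-translatable).
#' @return a `ComparisonSummary`.
#' @export
compare_models <- function(network, reduced, t_end, dt = 0.1, t0 = dt,
                           params = NULL, ic_method = "fast_eq",
                           species = NULL) {
  grid <- seq(t0, t_end, by = dt)
  orig <- simulate_model(network, grid, params = params)
  l0 <- reduced_initial_conditions(network, reduced, method = ic_method,
                                   horizon = t_end, params = params)
  red <- simulate_model(reduced, grid, params = params, x0 = l0)
  bt <- back_translate(red, reduced, species = species)
  relative_difference(orig, bt)
}

#' Parameter robustness scan of a reduction
#'
#' Re-runs the original/reduced comparison with each listed parameter scaled
#' by each factor (one at a time), plus an `"All"` row where every listed
#' parameter is scaled jointly. Reduced initial conditions are re-derived at
#' the scaled parameters for every cell. Cells whose simulation fails are
#' marked failed and the scan continues.
#'
#' @param network the original [reaction_network()].
#' @param reduced a `ReducedModel`.
#' @param factors positive scale factors (e.g. `10^(-2:2)`).
#' @param targets parameter names to scan; `"All"` is added unless
#'   `all_row = FALSE`.
#' @param t_end,dt,t0 sampling grid (see [compare_models()]).
#' @param all_row include the joint scaling row.
#' @param ic_method initial-condition route.
#' @return long-format data.frame: `param`, `factor`, `mean_eps`, `inf_eps`,
#'   `failed`.
#' @export
robustness_scan <- function(network, reduced, factors, targets,
                            t_end, dt = 0.1, t0 = dt, all_row = TRUE,
                            ic_method = "fast_eq") {
  stopifnot(all(factors > 0))
  rows <- list()
  scan_targets <- c(targets, if (all_row) "All")
  for (tg in scan_targets) {
    for (f in factors) {
      p <- network$parameters
      which_p <- if (tg == "All") targets else tg
      p[which_p] <- p[which_p] * f
      cell <- tryCatch(
        compare_models(network, reduced, t_end = t_end, dt = dt, t0 = t0,
                       params = p, ic_method = ic_method),
        error = function(e) e)
      if (inherits(cell, "error")) {
        rows[[length(rows) + 1]] <- data.frame(
          param = tg, factor = f, mean_eps = NA_real_, inf_eps = NA_real_,
          failed = TRUE)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          param = tg, factor = f, mean_eps = cell$max_mean,
          inf_eps = cell$max_inf, failed = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Overlay plot of original vs back-translated species
#'
#' @param comparison a `ComparisonSummary` from [compare_models()] or
#'   [relative_difference()].
#' @param species subset of species to show.
#' @return a ggplot object (requires the ggplot2 package).
#' @export
plot_comparison <- function(comparison, species = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_comparison requires ggplot2")
  }
  sp <- comparison$species$species
  if (!is.null(species)) sp <- intersect(sp, species)
  long <- do.call(rbind, lapply(sp, function(s) {
    rbind(data.frame(time = comparison$time, value = comparison$orig[[s]],
                     species = s, model = "original"),
          data.frame(time = comparison$time, value = comparison$reduced[[s]],
                     species = s, model = "reduced (back-translated)"))
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$model,
                                     linetype = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time", y = "amount") +
    ggplot2::theme_minimal()
}
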