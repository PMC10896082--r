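#' Simulation configuration for constraint-based analyses
#'
#' @param o2_uptake_max maximum oxygen uptake rate applied to the
#'   oxygen exchange reaction, mmol gDW^-1 h^-1 (aerobic default 20).
#' @param zero_growth_tol absolute growth rate (h^-1) below which a
#'   knockout is called "no growth", hence essential.
#' @param lp_tolerance numerical tolerance for the LP solver and the
#'   steady-state residual check.
#' @param fva_fraction default fraction of the optimum retained during
#'   flux variability analysis.
#' @param room_delta,room_epsilon relative and absolute flux-change
#'   tolerances of ROOM (defaults from the original ROOM formulation).
#' @param room_milp solve ROOM as a MILP by branch-and-bound (default);
#'   `FALSE` uses the LP relaxation.
#' @param room_max_nodes branch-and-bound node cap; past it the best
#'   incumbent is returned.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(o2_uptake_max = 20, zero_growth_tol = 1e-6,
                       lp_tolerance = 1e-9, fva_fraction = 1,
                       room_delta = 0.03, room_epsilon = 0.001,
                       room_milp = TRUE, room_max_nodes = 1000L) {
  stopifnot(o2_uptake_max >= 0, zero_growth_tol > 0, lp_tolerance > 0,
            fva_fraction > 0, fva_fraction <= 1)
  structure(list(o2_uptake_max = o2_uptake_max,
                 zero_growth_tol = zero_growth_tol,
                 lp_tolerance = lp_tolerance, fva_fraction = fva_fraction,
                 room_delta = room_delta, room_epsilon = room_epsilon,
                 room_milp = room_milp,
                 room_max_nodes = as.integer(room_max_nodes)),
            class = "sim_config")
}

# model -> LP pieces, with the aerobic O2 cap applied to the O2 exchange
model_lp <- function(model, config, o2_base = "o2") {
  S <- stoich_matrix(model)
  lb <- vapply(model$reactions, `[[`, numeric(1), "lb")
  ub <- vapply(model$reactions, `[[`, numeric(1), "ub")
  for (r in model$reactions) {
    if (r$kind == "exchange" && met_base(names(r$stoich)) == o2_base) {
      lb[r$id] <- max(lb[r$id], -config$o2_uptake_max)
    }
  }
  obj <- as.numeric(names(model$reactions) == model$objective)
  list(S = S, lb = lb, ub = ub, obj = obj)
}

flux_result <- function(flux, objective_value, status) {
  structure(list(flux = flux, objective_value = objective_value,
                 status = status), class = "flux_result")
}

#' @export
print.flux_result <- function(x, ...) {
  cat("flux_result: status", x$status, "| objective",
      format(x$objective_value), "\n")
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximises the objective (biomass) flux subject to steady state
#' `S v = 0` and the flux bounds. The objective value is deterministic;
#' the flux vector may be one of several alternate optima (verify
#' per-reaction claims with [fva()]).
#'
#' @param model a [metabolic_model()] with an objective reaction.
#' @param config a [sim_config()].
#' @return a `flux_result`: `flux` (named vector), `objective_value`
#'   (growth rate, h^-1) and `status` (`"optimal"`, `"infeasible"` --
#'   with zero-filled fluxes -- or `"unbounded"`).
#' @export
fba <- function(model, config = sim_config()) {
  if (is.na(model$objective)) stop("model has no objective reaction")
  lp <- model_lp(model, config)
  res <- lp_solve_eq(lp$S, rep(0, nrow(lp$S)), lp$obj, lp$lb, lp$ub,
                     maximize = TRUE, tol = config$lp_tolerance)
  rids <- names(model$reactions)
  if (res$status != "optimal") {
    return(flux_result(stats::setNames(rep(0, length(rids)), rids),
                       if (res$status == "infeasible") 0 else NA_real_,
                       res$status))
  }
  v <- stats::setNames(res$x, rids)
  resid <- max(abs(lp$S %*% v))
  if (resid > 1e-6) stop("steady-state residual too large: ", resid)
  flux_result(v, res$objective, "optimal")
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to retaining at least
#' `fraction_of_optimum` of the FBA optimum.
#'
#' @param model a [metabolic_model()].
#' @param fraction_of_optimum fraction in (0, 1].
#' @param config a [sim_config()].
#' @param reactions reaction ids to scan (default: all).
#' @return data.frame with `reaction_id`, `v_min`, `v_max`.
#' @export
fva <- function(model, fraction_of_optimum = NULL, config = sim_config(),
                reactions = NULL) {
  if (is.null(fraction_of_optimum)) fraction_of_optimum <- config$fva_fraction
  stopifnot(fraction_of_optimum > 0, fraction_of_optimum <= 1)
  wt <- fba(model, config)
  if (wt$status != "optimal") stop("FVA needs an optimal FBA solution; status: ",
                                   wt$status)
  lp <- model_lp(model, config)
  n <- length(lp$lb)
  # add slack s >= 0 with  obj'v - s = fraction * optimum
  A <- rbind(cbind(lp$S, 0), c(lp$obj, -1))
  b <- c(rep(0, nrow(lp$S)), fraction_of_optimum * wt$objective_value)
  lbx <- c(lp$lb, 0)
  ubx <- c(lp$ub, Inf)
  rids <- if (is.null(reactions)) names(model$reactions) else reactions
  idx <- match(rids, names(model$reactions))
  if (any(is.na(idx))) stop("unknown reaction id: ", rids[is.na(idx)][1])
  vmin <- vmax <- numeric(length(idx))
  for (k in seq_along(idx)) {
    e <- rep(0, n + 1L)
    e[idx[k]] <- 1
    lo <- lp_solve_eq(A, b, e, lbx, ubx, maximize = FALSE,
                      tol = config$lp_tolerance)
    hi <- lp_solve_eq(A, b, e, lbx, ubx, maximize = TRUE,
                      tol = config$lp_tolerance)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA subproblem not optimal for reaction ", rids[k])
    }
    vmin[k] <- lo$objective
    vmax[k] <- hi$objective
  }
  data.frame(reaction_id = rids, v_min = vmin, v_max = vmax,
             stringsAsFactors = FALSE, row.names = NULL)
}
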