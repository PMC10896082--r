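#' Knockout flux prediction by MOMA
#'
#' Minimisation of metabolic adjustment: among the feasible flux
#' distributions of the knockout model, return the one closest (in
#' squared Euclidean distance) to the wild-type flux. The reported
#' `objective_value` is the biomass flux of that solution -- it is not
#' maximised. Solved as a convex QP (Goldfarb-Idnani dual method).
#'
#' @param model the unperturbed [metabolic_model()].
#' @param wt_flux a `flux_result` for the unperturbed model (the
#'   deterministic FBA reference).
#' @param knockout entity id(s) to remove.
#' @param config a [sim_config()].
#' @param mode `"reaction"` or `"gene"` knockout.
#' @return a `flux_result` with attribute `distance` (squared distance
#'   from wild type); `status = "infeasible"` when the knockout model
#'   admits no steady state.
#' @export
moma <- function(model, wt_flux, knockout, config = sim_config(),
                 mode = c("reaction", "gene")) {
  mode <- match.arg(mode)
  stopifnot(inherits(wt_flux, "flux_result"))
  ko_model <- if (mode == "reaction") delete_reaction(model, knockout)
              else delete_gene(model, knockout)
  lp <- model_lp(ko_model, config)
  n <- ncol(lp$S)
  w <- wt_flux$flux[names(ko_model$reactions)]
  # keep a linearly independent subset of the steady-state rows
  qs <- qr(t(lp$S))
  keep <- qs$pivot[seq_len(qs$rank)]
  Seq <- lp$S[keep, , drop = FALSE]
  Dmat <- diag(2, n)
  dvec <- 2 * w
  Amat <- t(rbind(Seq, diag(n), -diag(n)))
  bvec <- c(rep(0, nrow(Seq)), lp$lb, -lp$ub)
  sol <- tryCatch(
    quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = nrow(Seq)),
    error = function(e) NULL)
  rids <- names(ko_model$reactions)
  if (is.null(sol)) {
    out <- flux_result(stats::setNames(rep(0, n), rids), 0, "infeasible")
    attr(out, "distance") <- NA_real_
    return(out)
  }
  v <- stats::setNames(sol$solution, rids)
  out <- flux_result(v, unname(v[model$objective]), "optimal")
  attr(out, "distance") <- sum((v - w)^2)
  out
}

#' Knockout flux prediction by ROOM
#'
#' Regulatory on/off minimisation: find a feasible flux distribution of
#' the knockout model that minimises the number of reactions whose flux
#' deviates from wild type by more than
#' `room_delta * |v_wt| + room_epsilon`. Binary on/off indicators make
#' this a MILP, solved here by LP-based branch-and-bound with the
#' always-feasible "flag every deviating reaction of the knockout FBA
#' solution" incumbent; `config$room_milp = FALSE` stops after the LP
#' relaxation, and `config$room_max_nodes` caps the search (the best
#' incumbent is returned when the cap is hit).
#'
#' @inheritParams moma
#' @return a `flux_result` with attributes `n_changed` (number of
#'   significantly changed reactions), `changed` (their ids) and
#'   `optimal_milp` (whether branch-and-bound proved optimality).
#' @export
room <- function(model, wt_flux, knockout, config = sim_config(),
                 mode = c("reaction", "gene")) {
  mode <- match.arg(mode)
  stopifnot(inherits(wt_flux, "flux_result"))
  ko_model <- if (mode == "reaction") delete_reaction(model, knockout)
              else delete_gene(model, knockout)
  lp <- model_lp(ko_model, config)
  n <- ncol(lp$S)
  rids <- names(ko_model$reactions)
  w <- as.numeric(wt_flux$flux[rids])
  wu <- w + config$room_delta * abs(w) + config$room_epsilon
  wl <- w - config$room_delta * abs(w) - config$room_epsilon
  ko_fba <- fba(ko_model, config)
  if (ko_fba$status == "infeasible") {
    out <- flux_result(stats::setNames(rep(0, n), rids), 0, "infeasible")
    attr(out, "n_changed") <- NA_integer_
    return(out)
  }
  inc_y <- as.numeric(ko_fba$flux > wu + 1e-9 | ko_fba$flux < wl - 1e-9)
  incumbent <- list(obj = sum(inc_y), v = as.numeric(ko_fba$flux), y = inc_y)
  # variables z = [v (n), y (n)]; min sum(y)
  #   v_j - (ub_j - wu_j) y_j <= wu_j
  #  -v_j + (lb_j - wl_j) y_j <= -wl_j
  au <- pmax(lp$ub - wu, 0)
  al <- pmax(wl - lp$lb, 0)
  A_eq <- cbind(lp$S, matrix(0, nrow(lp$S), n))
  A_ub <- rbind(cbind(diag(n), diag(-au, n)),
                cbind(-diag(n), diag(-al, n)))
  b_ub <- c(wu, -wl)
  obj <- c(rep(0, n), rep(1, n))
  solve_node <- function(y_lb, y_ub) {
    lp_solve(obj, A_eq = A_eq, b_eq = rep(0, nrow(A_eq)),
             A_ub = A_ub, b_ub = b_ub,
             lb = c(lp$lb, y_lb), ub = c(lp$ub, y_ub),
             maximize = FALSE, tol = config$lp_tolerance)
  }
  nodes <- list(list(y_lb = rep(0, n), y_ub = rep(1, n)))
  n_nodes <- 0L
  proved <- TRUE
  while (length(nodes) > 0L && n_nodes < config$room_max_nodes) {
    node <- nodes[[length(nodes)]]
    nodes[[length(nodes)]] <- NULL
    n_nodes <- n_nodes + 1L
    res <- solve_node(node$y_lb, node$y_ub)
    if (res$status != "optimal") next
    if (res$objective >= incumbent$obj - 1e-6) next         # bound prune
    y <- res$x[n + seq_len(n)]
    frac <- which(pmin(y - floor(y), ceiling(y) - y) > 1e-6)
    if (length(frac) == 0L || !config$room_milp) {
      incumbent <- list(obj = sum(round(y)), v = res$x[seq_len(n)],
                        y = round(y))
      if (!config$room_milp) break
      next
    }
    j <- frac[which.max(pmin(y[frac] - floor(y[frac]),
                             ceiling(y[frac]) - y[frac]))]
    up <- node; up$y_lb[j] <- 1
    dn <- node; dn$y_ub[j] <- 0
    nodes <- c(nodes, list(up), list(dn))
  }
  if (length(nodes) > 0L) proved <- FALSE
  v <- stats::setNames(incumbent$v, rids)
  out <- flux_result(v, unname(v[model$objective]), "optimal")
  attr(out, "n_changed") <- as.integer(incumbent$obj)
  attr(out, "changed") <- rids[incumbent$y > 0.5]
  attr(out, "optimal_milp") <- proved && config$room_milp
  out
}
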