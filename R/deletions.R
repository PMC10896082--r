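#' Reaction and gene knockouts
#'
#' `delete_reaction()` returns a copy of the model in which the named
#' reaction(s) cannot carry flux (both bounds constrained to zero); the
#' original model is untouched. `delete_gene()` knocks out gene(s) by
#' evaluating every reaction's GPR with the genes removed and disabling
#' the reactions that become inactive.
#'
#' @param model a [metabolic_model()].
#' @param reaction_id one or more reaction ids.
#' @return the perturbed model.
#' @export
delete_reaction <- function(model, reaction_id) {
  for (rid in reaction_id) {
    if (!rid %in% names(model$reactions)) stop("unknown reaction id: ", rid)
    model$reactions[[rid]]$lb <- 0
    model$reactions[[rid]]$ub <- 0
  }
  model
}

#' @rdname delete_reaction
#' @param gene_id one or more gene ids to knock out.
#' @export
delete_gene <- function(model, gene_id) {
  unknown <- setdiff(gene_id, model_genes(model))
  if (length(unknown) > 0L) {
    stop("unknown gene id: ", paste(unknown, collapse = ", "))
  }
  off <- vapply(model$reactions, function(r) {
    nzchar(r$gpr) && !evaluate_gpr(r$gpr, gene_id)
  }, logical(1))
  if (any(off)) model <- delete_reaction(model, names(model$reactions)[off])
  model
}

#' Essentiality classification
#'
#' An entity is essential when the network cannot support growth
#' without it: knockout growth (clamped at zero if numerically
#' negative) below `config$zero_growth_tol`.
#'
#' @param growth_wt wild-type growth rate, must be positive.
#' @param growth_ko knockout growth rate.
#' @param config a [sim_config()].
#' @return logical.
#' @export
classify_essential <- function(growth_wt, growth_ko, config = sim_config()) {
  if (growth_wt <= 0) stop("wild-type growth must be positive")
  max(growth_ko, 0) < config$zero_growth_tol
}

run_deletions <- function(model, entities, knock, config) {
  wt <- fba(model, config)
  if (wt$status != "optimal" || wt$objective_value <= config$zero_growth_tol) {
    stop("wild-type model does not grow; essentiality is undefined")
  }
  growth_wt <- wt$objective_value
  rows <- lapply(entities, function(e) {
    ko <- fba(knock(model, e), config)
    g <- if (ko$status == "optimal") max(ko$objective_value, 0) else 0
    data.frame(entity_id = e, growth_ko = g, growth_ratio = g / growth_wt,
               essential = classify_essential(growth_wt, g, config),
               status = ko$status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "growth_wt") <- growth_wt
  out
}

#' Single-reaction and single-gene deletion scans
#'
#' Perturbs each reaction (or gene) one at a time, re-runs FBA and
#' classifies the knockout as essential when the biomass flux drops to
#' zero (below `zero_growth_tol`). Infeasible knockouts are reported
#' essential with `status = "infeasible"`.
#'
#' @param model a [metabolic_model()] whose wild type grows.
#' @param config a [sim_config()].
#' @param reactions,genes subset of entities to scan (default: all).
#' @return data.frame with `entity_id`, `growth_ko`, `growth_ratio`,
#'   `essential`, `status`; the wild-type growth rate is attached as
#'   attribute `growth_wt`.
#' @export
single_reaction_deletion <- function(model, config = sim_config(),
                                     reactions = names(model$reactions)) {
  run_deletions(model, reactions, delete_reaction, config)
}

#' @rdname single_reaction_deletion
#' @export
single_gene_deletion <- function(model, config = sim_config(),
                                 genes = model_genes(model)) {
  run_deletions(model, genes, delete_gene, config)
}

#' Write a deletion scan to TSV
#'
#' @param deletions data.frame from [single_reaction_deletion()] or
#'   [single_gene_deletion()].
#' @param path output file.
#' @param model optional model used to annotate each reaction entity
#'   with its compartment(s).
#' @export
write_deletions <- function(deletions, path, model = NULL) {
  out <- deletions
  if (!is.null(model)) {
    out$compartment <- vapply(out$entity_id, function(e) {
      r <- model$reactions[[e]]
      if (is.null(r)) return(NA_character_)
      paste(sort(unique(met_compartment(names(r$stoich)))), collapse = "+")
    }, character(1))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(deletions)
}
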