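#' Stoichiometric metabolic models
#'
#' A `metabolic_model` holds metabolites, reactions with flux bounds and
#' gene-protein-reaction rules, and an objective reaction. Metabolite
#' ids carry their compartment as a bracket suffix, e.g. `"lys-L[c]"`;
#' compartments used in the host-symbiont models are `c` (host
#' bacteriocyte cytosol), `p` (symbiont) and `e` (external/hemolymph).
#' Flux bounds are in mmol gDW^-1 h^-1 (the biomass pseudo-reaction in
#' h^-1).
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns `id`, `name`,
#'   `compartment`; or a character vector of `"base[comp]"` ids.
#' @param reactions list of reactions from [reaction()].
#' @param objective id of the objective (biomass) reaction, or `NA`.
#' @return a validated `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions,
                            objective = NA_character_) {
  if (is.character(metabolites)) {
    metabolites <- data.frame(id = metabolites,
                              name = sub("\\[.*$", "", metabolites),
                              compartment = met_compartment(metabolites),
                              stringsAsFactors = FALSE)
  }
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  model <- structure(list(id = id, metabolites = metabolites,
                          reactions = reactions, objective = objective),
                     class = "metabolic_model")
  validate_model(model)
  model
}

#' @rdname metabolic_model
#' @param stoich named numeric vector: metabolite id to signed
#'   coefficient, negative = consumed. Exchange reactions have a single
#'   metabolite; all other reactions need a non-empty stoichiometry.
#' @param lb,ub flux bounds, `lb <= ub`.
#' @param gpr GPR string (see [parse_gpr()]); empty for spontaneous.
#' @param kind one of `"internal"`, `"transport"`, `"exchange"`,
#'   `"biomass"`.
#' @param name optional human-readable reaction name.
#' @export
reaction <- function(id, stoich, lb = -1000, ub = 1000, gpr = "",
                     kind = "internal", name = id) {
  kind <- match.arg(kind, c("internal", "transport", "exchange", "biomass"))
  if (lb > ub) stop("reaction ", id, ": lower bound exceeds upper bound")
  if (length(stoich) == 0L) stop("reaction ", id, ": empty stoichiometry")
  if (kind == "exchange" && length(stoich) != 1L) {
    stop("exchange reaction ", id, " must touch exactly one metabolite")
  }
  if (is.null(names(stoich)) || any(!nzchar(names(stoich)))) {
    stop("reaction ", id, ": stoichiometry must be named by metabolite id")
  }
  parse_gpr(gpr)  # fail early on malformed rules
  structure(list(id = id, name = name, stoich = stoich,
                 lb = as.numeric(lb), ub = as.numeric(ub),
                 gpr = if (is.na(gpr)) "" else gpr, kind = kind),
            class = "model_reaction")
}

met_compartment <- function(ids) {
  comp <- sub("^.*\\[([^]]+)\\]$", "\\1", ids)
  comp[comp == ids] <- NA_character_
  comp
}

met_base <- function(ids) sub("\\[[^]]+\\]$", "", ids)

#' @rdname metabolic_model
#' @param model a `metabolic_model`.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  mets <- model$metabolites
  if (anyDuplicated(mets$id)) {
    stop("duplicate metabolite id: ", mets$id[duplicated(mets$id)][1])
  }
  if (any(is.na(mets$compartment) | !nzchar(mets$compartment))) {
    stop("metabolite without compartment tag: ",
         mets$id[is.na(mets$compartment) | !nzchar(mets$compartment)][1])
  }
  ids <- vapply(model$reactions, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate reaction id: ", ids[duplicated(ids)][1])
  }
  for (r in model$reactions) {
    dangling <- setdiff(names(r$stoich), mets$id)
    if (length(dangling) > 0L) {
      stop("reaction ", r$id, " references unknown metabolite(s): ",
           paste(dangling, collapse = ", "))
    }
  }
  if (!is.na(model$objective) && !model$objective %in% ids) {
    stop("objective reaction not in model: ", model$objective)
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  s <- model_stats(x)
  cat("metabolic_model '", x$id, "': ", s$n_reactions, " reactions, ",
      s$n_metabolites, " metabolites, ", s$n_genes, " genes",
      if (!is.na(x$objective)) paste0("; objective ", x$objective), "\n",
      sep = "")
  invisible(x)
}

#' Model size statistics
#'
#' @param model a [metabolic_model()].
#' @return list with `n_reactions`, `n_metabolites` and `n_genes` (the
#'   cardinality of the union of all GPR gene sets).
#' @export
model_stats <- function(model) {
  list(n_reactions = length(model$reactions),
       n_metabolites = nrow(model$metabolites),
       n_genes = length(model_genes(model)))
}

#' @rdname model_stats
#' @return `model_genes()`: sorted character vector of all gene ids.
#' @export
model_genes <- function(model) {
  sort(unique(unlist(lapply(model$reactions, function(r) gpr_genes(r$gpr)))))
}

#' Stoichiometric matrix of a model
#'
#' @param model a [metabolic_model()].
#' @return numeric matrix `S` with metabolites in rows and reactions in
#'   columns; `S[i, j]` is the coefficient of metabolite i in reaction
#'   j.
#' @export
stoich_matrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), length(model$reactions),
              dimnames = list(model$metabolites$id,
                              names(model$reactions)))
  for (r in model$reactions) S[names(r$stoich), r$id] <- r$stoich
  S
}

#' Build a biomass pseudo-reaction
#'
#' The biomass reaction consumes growth precursors (here amino acids,
#' ATP and water) in fixed proportions; its flux is the growth rate in
#' h^-1. Stoichiometric coefficients give the relative abundance of
#' each building block per unit biomass.
#'
#' @param spec named numeric vector: precursor base id to positive
#'   coefficient (consumption side). Optionally, `products` names
#'   growth-associated products (e.g. ADP, Pi) with positive
#'   coefficients.
#' @param compartment compartment the precursors are drawn from.
#' @param model optional model used to check that every precursor
#'   exists in that compartment.
#' @param id reaction id.
#' @param products optional named numeric vector of products.
#' @return a `reaction` of kind `"biomass"` with bounds `[0, 1000]`.
#' @export
build_biomass <- function(spec, compartment = "c", model = NULL,
                          id = "BIOMASS", products = NULL) {
  if (length(spec) == 0L) stop("empty biomass specification")
  if (any(spec <= 0)) stop("biomass precursor coefficients must be positive")
  mets <- paste0(names(spec), "[", compartment, "]")
  if (!is.null(model)) {
    missing <- setdiff(mets, model$metabolites$id)
    if (length(missing) > 0L) {
      stop("biomass precursor(s) absent from compartment '", compartment,
           "': ", paste(missing, collapse = ", "))
    }
  }
  stoich <- stats::setNames(-spec, mets)
  if (!is.null(products)) {
    stoich <- c(stoich, stats::setNames(
      products, paste0(names(products), "[", compartment, "]")))
  }
  reaction(id, stoich, lb = 0, ub = 1000, gpr = "", kind = "biomass")
}

#' Attach a reaction (and any new metabolites) to a model
#'
#' @param model a [metabolic_model()].
#' @param rxn a [reaction()].
#' @param objective set the new reaction as the model objective?
#' @return the extended model.
#' @export
add_reaction <- function(model, rxn, objective = FALSE) {
  new_mets <- setdiff(names(rxn$stoich), model$metabolites$id)
  if (length(new_mets) > 0L) {
    model$metabolites <- rbind(model$metabolites,
      data.frame(id = new_mets, name = met_base(new_mets),
                 compartment = met_compartment(new_mets),
                 stringsAsFactors = FALSE))
  }
  model$reactions[[rxn$id]] <- rxn
  if (objective) model$objective <- rxn$id
  validate_model(model)
  model
}

#' Find dead-end metabolites
#'
#' A metabolite is a dead end when no reaction can produce it or no
#' reaction can consume it, taking reversibility from the flux bounds
#' (a reversible reaction both produces and consumes each of its
#' metabolites). Dead ends in a single-compartment model mark the
#' points where symbiosome transport reactions are needed.
#'
#' @param model a [metabolic_model()].
#' @return character vector of dead-end metabolite ids.
#' @export
find_dead_ends <- function(model) {
  producible <- consumable <- stats::setNames(
    rep(FALSE, nrow(model$metabolites)), model$metabolites$id)
  for (r in model$reactions) {
    s <- r$stoich
    fwd <- r$ub > 0
    rev <- r$lb < 0
    prod <- names(s)[(s > 0 & fwd) | (s < 0 & rev)]
    cons <- names(s)[(s < 0 & fwd) | (s > 0 & rev)]
    producible[prod] <- TRUE
    consumable[cons] <- TRUE
  }
  names(producible)[!(producible & consumable)]
}
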