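#' Merge host and symbiont models into a two-compartment model
#'
#' Combines a host single-compartment model (cytosol, compartment `c`)
#' with an endosymbiont model (compartment `p`) the way
#' host-endosymbiont reconstructions are assembled: reaction ids are
#' prefixed per organism; every dead-end metabolite of one compartment
#' that the partner compartment can resolve gets a 1:1 symbiosome
#' transport reaction; dead ends declared external are routed to the
#' hemolymph compartment `e` via a membrane transport plus an exchange
#' reaction (uptake bounded at `-uptake_max..0`, secretion at
#' `0..1000`). The host objective (biomass) becomes the merged
#' objective.
#'
#' @param host,symbiont [metabolic_model()]s with metabolites tagged
#'   `c` and `p` respectively (plus optionally `e`).
#' @param host_prefix,symbiont_prefix distinct reaction-id prefixes,
#'   e.g. `"SSA1_Bt"` and `"SSA1_Por"`.
#' @param externals list with character vectors `uptake` and
#'   `secretion` of metabolite base ids exchanged with the hemolymph.
#' @param transport_bounds bounds for the symbiosome transports
#'   (default reversible, `c(-1000, 1000)`).
#' @param uptake_max maximum uptake rate for external nutrients
#'   (mmol gDW^-1 h^-1).
#' @param id id of the merged model.
#' @return the merged two-compartment `metabolic_model`.
#' @export
merge_host_symbiont <- function(host, symbiont,
                                host_prefix = "SSA1_Bt",
                                symbiont_prefix = "SSA1_Por",
                                externals = list(uptake = character(0),
                                                 secretion = character(0)),
                                transport_bounds = c(-1000, 1000),
                                uptake_max = 1000,
                                id = paste0(host$id, "_", symbiont$id)) {
  if (identical(host_prefix, symbiont_prefix)) {
    stop("host and symbiont prefixes must be distinct")
  }
  if (any(symbiont$metabolites$compartment == "c") ||
      any(host$metabolites$compartment == "p")) {
    stop("compartment tag clash: host must use 'c', symbiont 'p'")
  }
  prefix_rxns <- function(model, prefix) {
    lapply(model$reactions, function(r) { r$id <- paste0(prefix, "_", r$id); r })
  }
  rxns <- c(prefix_rxns(host, host_prefix), prefix_rxns(symbiont, symbiont_prefix))
  ids <- vapply(rxns, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("reaction id collision after prefixing: ", ids[duplicated(ids)][1])
  }
  names(rxns) <- ids
  mets <- unique(rbind(host$metabolites, symbiont$metabolites))
  merged <- metabolic_model(id, mets, rxns,
    objective = if (!is.na(host$objective))
      paste0(host_prefix, "_", host$objective) else NA_character_)

  # symbiosome transports: dead ends resolvable by the partner compartment
  dead <- find_dead_ends(merged)
  dead <- dead[met_compartment(dead) %in% c("c", "p")]
  transported <- character(0)
  for (met in dead) {
    base <- met_base(met)
    comp <- met_compartment(met)
    partner <- if (comp == "c") "p" else "c"
    partner_id <- paste0(base, "[", partner, "]")
    if (partner_id %in% merged$metabolites$id && !base %in% transported) {
      merged <- add_reaction(merged, reaction(
        paste0("TP_", base),
        stats::setNames(c(-1, 1), c(paste0(base, "[p]"), paste0(base, "[c]"))),
        lb = transport_bounds[1], ub = transport_bounds[2],
        kind = "transport"))
      transported <- c(transported, base)
    }
  }
  # hemolymph exchanges for declared externals
  for (role in c("uptake", "secretion")) {
    for (base in externals[[role]]) {
      c_id <- paste0(base, "[c]")
      e_id <- paste0(base, "[e]")
      p_id <- paste0(base, "[p]")
      if (!c_id %in% merged$metabolites$id && p_id %in% merged$metabolites$id &&
          !base %in% transported) {
        # pass-through: hemolymph -> host cytosol -> symbiont
        merged <- add_reaction(merged, reaction(
          paste0("TP_", base), stats::setNames(c(-1, 1), c(p_id, c_id)),
          lb = transport_bounds[1], ub = transport_bounds[2],
          kind = "transport"))
        transported <- c(transported, base)
      }
      if (!c_id %in% merged$metabolites$id) {
        stop("declared external '", base, "' does not occur in the model")
      }
      merged <- add_reaction(merged, reaction(
        paste0("TE_", base), stats::setNames(c(-1, 1), c(e_id, c_id)),
        lb = -1000, ub = 1000, kind = "transport"))
      bounds <- if (role == "uptake") c(-uptake_max, 0) else c(0, 1000)
      merged <- add_reaction(merged, reaction(
        paste0("EX_", base), stats::setNames(-1, e_id),
        lb = bounds[1], ub = bounds[2], kind = "exchange"))
    }
  }
  validate_model(merged)
  merged
}
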