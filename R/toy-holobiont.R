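#' Toy holobiont: a curated host-symbiont metabolic fixture
#'
#' A small deterministic two-compartment model of essential-amino-acid
#' provisioning in a bacteriocyte, with known essentiality answers. The
#' symbiont compartment (`p`) carries the bulk of ten essential
#' amino-acid pathways; the host cytosol (`c`) holds the terminal steps
#' for arginine (argH), lysine (dapF/lysA, with the host-acquired dapB
#' reductase upstream), histidine (hisN/hisD), phenylalanine (the
#' transaminase step, mediated by aspC or the AAT2 isozyme) and the
#' three branched-chain amino acids (a single BCAT transaminase);
#' threonine, methionine and tryptophan finish inside the symbiont.
#' Phenylalanine has the one redundant step: prephenate can be made by
#' the symbiont pheA or the host chorismate mutase CM, so neither gene
#' is essential alone but the double knockout abolishes growth.
#'
#' The fixture is assembled exactly like the real reconstructions:
#' two single-compartment models are built, then
#' [merge_host_symbiont()] inserts symbiosome transports for every
#' dead-end metabolite and hemolymph exchanges for the declared
#' nutrients. Stoichiometries are unit coefficients except the biomass
#' reaction, whose amino-acid coefficients are proportional to
#' realistic precursor export fluxes; oxygen uptake (capped at 20
#' mmol gDW^-1 h^-1 under the aerobic default) limits the ATP supply
#' and hence growth.
#'
#' @return list with elements `model` (the merged two-compartment
#'   model, objective `SSA1_Bt_BIOMASS_holo`), `host` and `symbiont`
#'   (the single-compartment inputs) and `truth`, a list of declared
#'   answers: `optimal_growth`, `essential_genes`,
#'   `nonessential_genes`, `essential_reactions`,
#'   `nonessential_reactions`, `terminal` (amino acid to gene map),
#'   `symbiosis_targets` (the host-targetable selection),
#'   `symbiont_exports`/`symbiont_imports` (the pre-merge dead ends)
#'   and the model size counts.
#' @export
toy_holobiont <- function() {
  irr <- function(id, from, to, gpr, comp = "p") {
    reaction(id, stats::setNames(c(-1, 1), paste0(c(from, to), "[", comp, "]")),
             lb = 0, ub = 1000, gpr = gpr)
  }
  # --- symbiont (compartment p): pathway bulk --------------------------
  p_rxns <- list(
    irr("LYSC", "asp-L", "4pasp", "lysC"),
    irr("ASD", "4pasp", "aspsa", "asd"),
    irr("DAPA", "aspsa", "23dhdp", "dapA"),
    irr("DAPD", "thdp", "s12a6o", "dapD"),
    irr("DAPC", "s12a6o", "s126da", "dapC"),
    irr("DAPE", "s126da", "26dap-LL", "dapE"),
    irr("ARGA", "gln-L", "orn-L", "argA"),
    irr("CARA", "gln-L", "cbp", "carA"),
    reaction("ARGF", c("cbp[p]" = -1, "orn-L[p]" = -1, "citr-L[p]" = 1),
             lb = 0, ub = 1000, gpr = "argF"),
    reaction("ARGG", c("citr-L[p]" = -1, "asp-L[p]" = -1, "argSuc[p]" = 1),
             lb = 0, ub = 1000, gpr = "argG"),
    reaction("AROC", c("e4p[p]" = -1, "pep[p]" = -1, "chor[p]" = 1),
             lb = 0, ub = 1000, gpr = "aroC"),
    irr("PHEA", "chor", "pphn", "pheA"),
    irr("PPNDH", "pphn", "phpyr", "ppndh"),
    irr("TRPE", "chor", "anth", "trpE"),
    irr("TRPD", "anth", "pran", "trpD"),
    irr("TRPF", "pran", "2cpr5p", "trpF"),
    irr("TRPC", "2cpr5p", "3ig3p", "trpC"),
    reaction("TRPB", c("3ig3p[p]" = -1, "ser-L[p]" = -1, "trp-L[p]" = 1),
             lb = 0, ub = 1000, gpr = "trpB"),
    irr("HISG", "r5p", "hisp", "hisG"),
    irr("HOM", "aspsa", "hom-L", "hom"),
    irr("THRC", "hom-L", "thr-L", "thrC"),
    irr("ILVA", "thr-L", "3mop", "ilvA"),
    irr("ILVB", "pyr", "3mob", "ilvB"),
    irr("LEUA", "3mob", "4mop", "leuA"),
    reaction("METE", c("hcys-L[p]" = -1, "5mthf[p]" = -1, "met-L[p]" = 1),
             lb = 0, ub = 1000, gpr = "metE"))
  p_mets <- sort(unique(unlist(lapply(p_rxns, function(r) names(r$stoich)))))
  symbiont <- metabolic_model("toy_portiera", p_mets, p_rxns)

  # --- host (compartment c): terminal steps, respiration, biomass ------
  c_rxns <- list(
    irr("ASPTA", "oaa", "asp-L", "aspC", comp = "c"),
    irr("DAPB", "23dhdp", "thdp", "dapB", comp = "c"),
    irr("DAPF", "26dap-LL", "26dap-M", "dapF", comp = "c"),
    irr("LYSA", "26dap-M", "lys-L", "lysA", comp = "c"),
    irr("ARGH", "argSuc", "arg-L", "argH", comp = "c"),
    irr("CM", "chor", "pphn", "CM", comp = "c"),
    irr("PHETA1", "phpyr", "phe-L", "aspC OR AAT2", comp = "c"),
    irr("HISN", "hisp", "hisol", "hisN", comp = "c"),
    irr("HISD", "hisol", "his-L", "hisD", comp = "c"),
    irr("BCAT_VAL", "3mob", "val-L", "BCAT", comp = "c"),
    irr("BCAT_LEU", "4mop", "leu-L", "BCAT", comp = "c"),
    irr("BCAT_ILE", "3mop", "ile-L", "BCAT", comp = "c"),
    irr("RESP", "o2", "atp", "resp1", comp = "c"))
  # amino-acid coefficients proportional to realistic export fluxes;
  # 50 ATP per unit biomass makes oxygen the binding nutrient
  biomass_spec <- c("arg-L" = 0.371, "his-L" = 0.049, "lys-L" = 0.1599,
                    "phe-L" = 0.2097, "ile-L" = 0.1133, "val-L" = 0.3107,
                    "leu-L" = 0.1653, "thr-L" = 0.101, "met-L" = 0.046,
                    "trp-L" = 0.012, "atp" = 50, "h2o" = 1)
  c_mets <- sort(unique(c(
    unlist(lapply(c_rxns, function(r) names(r$stoich))),
    paste0(names(biomass_spec), "[c]"))))
  host <- metabolic_model("toy_whitefly", c_mets, c_rxns)
  host <- add_reaction(host, build_biomass(biomass_spec, "c", model = host,
                                           id = "BIOMASS_holo"),
                       objective = TRUE)

  nutrients <- c("oaa", "gln-L", "e4p", "pep", "r5p", "ser-L", "pyr",
                 "hcys-L", "5mthf", "o2", "h2o")
  model <- merge_host_symbiont(host, symbiont,
                               host_prefix = "SSA1_Bt",
                               symbiont_prefix = "SSA1_Por",
                               externals = list(uptake = nutrients,
                                                secretion = character(0)),
                               id = "toy_holobiont")

  genes <- model_genes(model)
  nonessential_genes <- c("AAT2", "CM", "pheA")
  nonessential_reactions <- c("SSA1_Bt_CM", "SSA1_Por_PHEA",
                              "TP_chor", "TP_pphn")
  truth <- list(
    optimal_growth = 0.4,
    essential_genes = setdiff(genes, nonessential_genes),
    nonessential_genes = nonessential_genes,
    essential_reactions = setdiff(names(model$reactions),
                                  nonessential_reactions),
    nonessential_reactions = nonessential_reactions,
    terminal = c("arg-L" = "argH", "lys-L" = "lysA", "his-L" = "hisD",
                 "val-L" = "BCAT", "leu-L" = "BCAT", "ile-L" = "BCAT",
                 "phe-L" = "aspC;AAT2", "thr-L" = "thrC", "met-L" = "metE",
                 "trp-L" = "trpB"),
    terminal_compartment = c("arg-L" = "c", "lys-L" = "c", "his-L" = "c",
                             "val-L" = "c", "leu-L" = "c", "ile-L" = "c",
                             "phe-L" = "c", "thr-L" = "p", "met-L" = "p",
                             "trp-L" = "p"),
    symbiosis_targets = c("BCAT", "argH", "aspC", "dapB", "hisD", "lysA"),
    hgt_genes = c("argH", "lysA", "dapB", "dapF", "argG", "CM"),
    symbiont_exports = c("23dhdp", "26dap-LL", "argSuc", "phpyr", "hisp",
                         "trp-L", "3mop", "4mop", "met-L"),
    symbiont_imports = c("asp-L", "thdp", "gln-L", "e4p", "pep", "ser-L",
                         "r5p", "pyr", "hcys-L", "5mthf"),
    n_reactions = 84L, n_metabolites = 82L, n_genes = 36L)
  list(model = model, host = host, symbiont = symbiont, truth = truth)
}
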