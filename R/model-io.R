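#' Read and write metabolic models (tabular TSV and SBML L3 + fbc)
#'
#' Two on-disk dialects are supported. The tabular dialect is a TSV
#' with columns `id`, `equation`, `lb`, `ub`, `gpr`, `kind` and an
#' optional logical `objective` column; equations use bracketed
#' compartment suffixes and decimal coefficients, with `->` for
#' irreversible and `<=>` for reversible reactions, e.g.
#' `"2 A[c] + B[c] -> C[c]"` (an exchange reaction leaves one side
#' empty). The SBML dialect is Level 3 Version 1 with the fbc
#' extension: flux bounds as parameters, GPRs as
#' `geneProductAssociation` trees, the objective as an fbc objective,
#' and reaction roles encoded as SBO terms.
#'
#' @param path file to read or write.
#' @param dialect `"tabular"`, `"sbml"`, or `"auto"` (by file
#'   extension: `.xml`/`.sbml` is SBML, anything else tabular).
#' @param id model id used when the file does not carry one.
#' @return `read_model()`: a validated [metabolic_model()].
#' @export
read_model <- function(path, dialect = c("auto", "tabular", "sbml"),
                       id = sub("\\.[^.]*$", "", basename(path))) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "tabular"
  }
  if (dialect == "tabular") read_model_tabular(path, id) else read_model_sbml(path)
}

#' @rdname read_model
#' @param model a [metabolic_model()] to serialise.
#' @export
write_model <- function(model, path, dialect = c("auto", "tabular", "sbml")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "tabular"
  }
  if (dialect == "tabular") write_model_tabular(model, path) else write_model_sbml(model, path)
  invisible(model)
}

parse_equation <- function(eq, rxn_id) {
  rev <- grepl("<=>", eq, fixed = TRUE)
  sides <- strsplit(eq, if (rev) "<=>" else "->", fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  if (length(sides) != 2L) stop("reaction ", rxn_id, ": unparseable equation: ", eq)
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(stats::setNames(numeric(0), character(0)))
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (term in terms) {
      m <- regmatches(term, regexec(
        "^([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?[[:space:]]+)?([^[:space:]]+)$",
        term))[[1]]
      if (length(m) == 0L) stop("reaction ", rxn_id, ": unparseable term: ", term)
      coef <- if (nzchar(m[2])) as.numeric(trimws(m[2])) else 1
      met <- m[3]
      out[met] <- (if (is.na(out[met])) 0 else out[met]) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  stoich <- c(lhs, rhs[setdiff(names(rhs), names(lhs))])
  for (met in intersect(names(rhs), names(lhs))) stoich[met] <- stoich[met] + rhs[met]
  list(stoich = stoich[stoich != 0], reversible = rev)
}

deparse_equation <- function(rxn) {
  s <- rxn$stoich
  fmt <- function(v) {
    vapply(names(v), function(met) {
      coef <- abs(v[[met]])
      if (coef == 1) met else paste(format(coef, scientific = FALSE), met)
    }, character(1))
  }
  lhs <- paste(fmt(s[s < 0]), collapse = " + ")
  rhs <- paste(fmt(s[s > 0]), collapse = " + ")
  arrow <- if (rxn$lb < 0) "<=>" else "->"
  trimws(paste(lhs, arrow, rhs))
}

read_model_tabular <- function(path, id) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("id", "equation", "lb", "ub")
  if (!all(need %in% names(tab))) {
    stop("tabular model needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$id)) {
    stop("duplicate reaction id: ", tab$id[duplicated(tab$id)][1])
  }
  rxns <- lapply(seq_len(nrow(tab)), function(i) {
    eq <- parse_equation(tab$equation[i], tab$id[i])
    reaction(tab$id[i], eq$stoich, lb = tab$lb[i], ub = tab$ub[i],
             gpr = if ("gpr" %in% names(tab) && !is.na(tab$gpr[i])) tab$gpr[i] else "",
             kind = if ("kind" %in% names(tab) && !is.na(tab$kind[i])) tab$kind[i] else "internal")
  })
  mets <- sort(unique(unlist(lapply(rxns, function(r) names(r$stoich)))))
  objective <- NA_character_
  if ("objective" %in% names(tab)) {
    obj_rows <- which(!is.na(tab$objective) & tab$objective)
    if (length(obj_rows) > 1L) stop("more than one objective reaction flagged")
    if (length(obj_rows) == 1L) objective <- tab$id[obj_rows]
  }
  metabolic_model(id, mets, rxns, objective = objective)
}

write_model_tabular <- function(model, path) {
  tab <- data.frame(
    id = vapply(model$reactions, `[[`, character(1), "id"),
    equation = vapply(model$reactions, deparse_equation, character(1)),
    lb = vapply(model$reactions, `[[`, numeric(1), "lb"),
    ub = vapply(model$reactions, `[[`, numeric(1), "ub"),
    gpr = vapply(model$reactions, `[[`, character(1), "gpr"),
    kind = vapply(model$reactions, `[[`, character(1), "kind"),
    objective = vapply(model$reactions, function(r)
      identical(r$id, model$objective), logical(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# --- SBML (Level 3 Version 1 + fbc v2) ------------------------------------

.sbo_kind <- c(internal = "SBO:0000176", transport = "SBO:0000185",
               exchange = "SBO:0000627", biomass = "SBO:0000629")

sbml_sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  num <- function(x) sprintf("%.15g", x)
  met_sid <- function(id) paste0("M_", sbml_sid(met_base(id)), "_", met_compartment(id))
  genes <- model_genes(model)
  gene_sid <- stats::setNames(paste0("G_", sbml_sid(genes)), genes)
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    sprintf('  <model id="%s" fbc:strict="true">', sbml_sid(model$id)),
    '    <listOfCompartments>',
    sprintf('      <compartment id="%s" constant="true"/>',
            sort(unique(model$metabolites$compartment))),
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    out <- c(out, sprintf(
      '      <species id="%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
      met_sid(m$id), esc(met_base(m$id)), m$compartment))
  }
  out <- c(out, '    </listOfSpecies>', '    <listOfParameters>')
  for (r in model$reactions) {
    rid <- sbml_sid(r$id)
    out <- c(out,
      sprintf('      <parameter id="%s_lower" value="%s" constant="true"/>', rid, num(r$lb)),
      sprintf('      <parameter id="%s_upper" value="%s" constant="true"/>', rid, num(r$ub)))
  }
  out <- c(out, '    </listOfParameters>')
  if (length(genes) > 0L) {
    out <- c(out, '    <fbc:listOfGeneProducts>',
             sprintf('      <fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
                     gene_sid, esc(genes)),
             '    </fbc:listOfGeneProducts>')
  }
  gpr_xml <- function(node, indent) {
    pad <- strrep(" ", indent)
    if (is.character(node)) {
      return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="%s"/>', pad,
                     gene_sid[[node]]))
    }
    tag <- if (node$op == "and") "fbc:and" else "fbc:or"
    c(sprintf("%s<%s>", pad, tag),
      unlist(lapply(node$args, gpr_xml, indent = indent + 2L)),
      sprintf("%s</%s>", pad, tag))
  }
  out <- c(out, '    <listOfReactions>')
  for (r in model$reactions) {
    rid <- sbml_sid(r$id)
    out <- c(out, sprintf(
      '      <reaction id="R_%s" name="%s" reversible="%s" fast="false" sboTerm="%s" fbc:lowerFluxBound="%s_lower" fbc:upperFluxBound="%s_upper">',
      rid, esc(r$id), tolower(r$lb < 0), .sbo_kind[[r$kind]], rid, rid))
    for (side in c("Reactants", "Products")) {
      sel <- if (side == "Reactants") r$stoich < 0 else r$stoich > 0
      if (!any(sel)) next
      out <- c(out, sprintf('        <listOf%s>', side))
      for (met in names(r$stoich)[sel]) {
        out <- c(out, sprintf(
          '          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
          met_sid(met), num(abs(r$stoich[[met]]))))
      }
      out <- c(out, sprintf('        </listOf%s>', side))
    }
    tree <- parse_gpr(r$gpr)
    if (!is.null(tree)) {
      out <- c(out, '        <fbc:geneProductAssociation>',
               gpr_xml(tree, 10L), '        </fbc:geneProductAssociation>')
    }
    out <- c(out, '      </reaction>')
  }
  out <- c(out, '    </listOfReactions>')
  if (!is.na(model$objective)) {
    out <- c(out,
      '    <fbc:listOfObjectives fbc:activeObjective="obj">',
      '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
      '        <fbc:listOfFluxObjectives>',
      sprintf('          <fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="1"/>',
              sbml_sid(model$objective)),
      '        </fbc:listOfFluxObjectives>',
      '      </fbc:objective>',
      '    </fbc:listOfObjectives>')
  }
  out <- c(out, '  </model>', '</sbml>')
  writeLines(out, path)
}

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  model_node <- xml2::xml_find_first(doc, ".//model")
  # species: original base id kept in the name attribute
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sid <- xml2::xml_attr(sp_nodes, "id")
  base <- xml2::xml_attr(sp_nodes, "name")
  comp <- xml2::xml_attr(sp_nodes, "compartment")
  base[is.na(base)] <- sub("_[^_]+$", "", sub("^M_", "", sid[is.na(base)]))
  met_id <- stats::setNames(paste0(base, "[", comp, "]"), sid)
  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                             xml2::xml_attr(params, "id"))
  gp_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='geneProduct']")
  gp_label <- stats::setNames(xml2::xml_attr(gp_nodes, "label"),
                              xml2::xml_attr(gp_nodes, "id"))
  obj_node <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
  obj_rid <- if (inherits(obj_node, "xml_missing")) NA_character_ else
    xml2::xml_attr(obj_node, "reaction")
  sbo_to_kind <- stats::setNames(names(.sbo_kind), .sbo_kind)
  gpr_from_node <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      gid <- xml2::xml_attr(node, "geneProduct")
      lab <- gp_label[[gid]]
      return(if (is.na(lab)) sub("^G_", "", gid) else lab)
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, function(k) {
      sub <- gpr_from_node(k)
      if (grepl(" ", sub)) paste0("(", sub, ")") else sub
    }, character(1))
    paste(parts, collapse = if (nm == "and") " AND " else " OR ")
  }
  rxn_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxns <- lapply(rxn_nodes, function(node) {
    rid_raw <- xml2::xml_attr(node, "id")
    rid <- xml2::xml_attr(node, "name")
    if (is.na(rid)) rid <- sub("^R_", "", rid_raw)
    stoich <- numeric(0)
    for (spec in list(c("listOfReactants/speciesReference", -1),
                      c("listOfProducts/speciesReference", +1))) {
      refs <- xml2::xml_find_all(node, paste0("./", spec[1]))
      for (ref in refs) {
        s <- xml2::xml_attr(ref, "species")
        if (!s %in% names(met_id)) {
          stop("reaction ", rid, " references unknown species: ", s)
        }
        coef <- as.numeric(xml2::xml_attr(ref, "stoichiometry"))
        stoich[met_id[[s]]] <- as.numeric(spec[2]) * coef
      }
    }
    lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(node, "upperFluxBound")
    lb <- if (!is.na(lb_ref)) par_val[[lb_ref]] else
      if (isTRUE(xml2::xml_attr(node, "reversible") == "true")) -1000 else 0
    ub <- if (!is.na(ub_ref)) par_val[[ub_ref]] else 1000
    sbo <- xml2::xml_attr(node, "sboTerm")
    kind <- if (!is.na(sbo) && sbo %in% names(sbo_to_kind)) sbo_to_kind[[sbo]] else "internal"
    gpa <- xml2::xml_find_first(node, "./*[local-name()='geneProductAssociation']")
    gpr <- if (inherits(gpa, "xml_missing")) "" else
      gpr_from_node(xml2::xml_child(gpa))
    reaction(rid, stoich, lb = lb, ub = ub, gpr = gpr, kind = kind)
  })
  rids <- vapply(rxns, `[[`, character(1), "id")
  objective <- NA_character_
  if (!is.na(obj_rid)) {
    objective <- rids[match(obj_rid, paste0("R_", sbml_sid(rids)))]
  }
  metabolic_model(xml2::xml_attr(model_node, "id"),
                  sort(unique(unname(met_id))), rxns, objective = objective)
}
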