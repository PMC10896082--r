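#' Terminal reactions of amino-acid biosynthesis pathways
#'
#' For each amino-acid precursor of the biomass reaction, report the
#' reaction(s) that produce that amino acid (positive stoichiometric
#' coefficient) anywhere in the model, excluding transport and exchange
#' steps, together with the compartment of the terminal step and its
#' GPR gene set. The terminal step matters because it controls the
#' final provisioning of the amino acid; pathways whose terminal
#' reaction sits in the symbiont compartment cannot be hit by
#' host-expressed RNAi.
#'
#' @param model a [metabolic_model()].
#' @param biomass_reaction id of the biomass reaction (default: the
#'   model objective).
#' @param amino_acids optional character vector of amino-acid
#'   metabolite base ids to restrict to; every named id must occur in
#'   the model. Default: all biomass precursors whose base id ends in
#'   `"-L"` (the L-amino-acid convention used throughout).
#' @return data.frame with `amino_acid` (base id), `reaction_id`,
#'   `compartment`, `genes` (`;`-separated, possibly empty); amino
#'   acids with no producing reaction get one row with `NA` reaction.
#' @export
terminal_reactions <- function(model, biomass_reaction = model$objective,
                               amino_acids = NULL) {
  if (is.na(biomass_reaction) || !biomass_reaction %in% names(model$reactions)) {
    stop("biomass reaction not found in model")
  }
  bio <- model$reactions[[biomass_reaction]]
  precursors <- names(bio$stoich)[bio$stoich < 0]
  if (is.null(amino_acids)) {
    aa <- unique(met_base(precursors)[grepl("-L$", met_base(precursors))])
  } else {
    aa <- amino_acids
    absent <- setdiff(aa, met_base(model$metabolites$id))
    if (length(absent) > 0L) {
      stop("amino acid(s) absent from model: ", paste(absent, collapse = ", "))
    }
    aa <- intersect(aa, met_base(precursors))
  }
  rows <- list()
  for (a in aa) {
    prods <- Filter(function(r) {
      r$kind %in% c("internal", "biomass") &&
        any(met_base(names(r$stoich)) == a & r$stoich > 0)
    }, model$reactions)
    if (length(prods) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        amino_acid = a, reaction_id = NA_character_,
        compartment = NA_character_, genes = NA_character_,
        stringsAsFactors = FALSE)
      next
    }
    for (r in prods) {
      met <- names(r$stoich)[met_base(names(r$stoich)) == a & r$stoich > 0]
      rows[[length(rows) + 1L]] <- data.frame(
        amino_acid = a, reaction_id = r$id,
        compartment = met_compartment(met)[1],
        genes = paste(gpr_genes(r$gpr), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(amino_acid = character(0), reaction_id = character(0),
                      compartment = character(0), genes = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$amino_acid, out$reaction_id), , drop = FALSE]
}

#' Reactions mediated by a single gene
#'
#' @param model a [metabolic_model()].
#' @return character vector of reaction ids whose GPR references
#'   exactly one gene.
#' @export
single_gene_reactions <- function(model) {
  names(Filter(function(r) length(gpr_genes(r$gpr)) == 1L, model$reactions))
}

#' Select symbiosis gene targets from a deletion scan
#'
#' Applies the three-criterion rule for nominating essential-amino-acid
#' provisioning targets: (i) the gene is indispensable (essential in
#' the gene-deletion scan), (iii) it mediates a terminal reaction of an
#' amino-acid pathway; criterion (ii) -- the reaction is mediated by a
#' single gene -- is recorded as a flag and only enforced when
#' `policy = "strict"` (the advisory default keeps genes whose terminal
#' reaction has isozymes, mirroring the retention of the
#' multi-gene-mediated phenylalanine transaminase step). Optionally,
#' essential horizontally transferred genes acting upstream (not
#' terminal) in a pathway are admitted under an `upstream_essential_hgt`
#' rule -- this is how a host-acquired dapB-type reductase enters the
#' target list. Genes whose terminal step lies in the symbiont
#' compartment are reported but flagged not host-targetable.
#'
#' @param gene_deletions data.frame from [single_gene_deletion()].
#' @param annotations data.frame from [terminal_reactions()].
#' @param single_gene character vector from [single_gene_reactions()].
#' @param policy `"advisory"` (default) or `"strict"` for criterion
#'   (ii).
#' @param hgt_genes character vector of horizontally transferred gene
#'   ids used for the upstream-essential extension.
#' @param model optional model; needed (with `hgt_genes`) to locate
#'   upstream HGT reactions and their compartments.
#' @param hgt_enrichment optional named numeric vector of bacteriocyte
#'   fold enrichment for the HGT genes; when given, the
#'   upstream-essential extension only admits genes enriched at least
#'   `hgt_fold_min`-fold (an essential but barely expressed HGT copy,
#'   e.g. a dapF-type epimerase, is not a useful RNAi target).
#' @param hgt_fold_min enrichment threshold for the extension.
#' @return data.frame with one row per candidate gene: `gene_id`,
#'   `amino_acids`, `compartment`, `essential`, `single_gene_reaction`,
#'   `terminal_reaction`, `rule`, `host_targetable`, `selected`;
#'   ordered by pathway then gene id.
#' @export
select_symbiosis_targets <- function(gene_deletions, annotations,
                                     single_gene = character(0),
                                     policy = c("advisory", "strict"),
                                     hgt_genes = character(0),
                                     model = NULL,
                                     hgt_enrichment = NULL,
                                     hgt_fold_min = 2) {
  policy <- match.arg(policy)
  ess <- stats::setNames(gene_deletions$essential, gene_deletions$entity_id)
  ann <- annotations[!is.na(annotations$reaction_id) &
                       nzchar(annotations$genes), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(ann))) {
    for (g in strsplit(ann$genes[i], ";", fixed = TRUE)[[1]]) {
      if (!g %in% names(ess)) {
        warning("gene in annotations absent from deletion results, excluded: ", g)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, amino_acid = ann$amino_acid[i],
        compartment = ann$compartment[i],
        reaction_id = ann$reaction_id[i],
        essential = unname(ess[g]),
        single_gene_reaction = ann$reaction_id[i] %in% single_gene,
        rule = "terminal", stringsAsFactors = FALSE)
    }
  }
  # upstream-essential HGT extension (e.g. a host-acquired dapB)
  if (length(hgt_genes) > 0L && !is.null(model)) {
    terminal_genes <- unique(unlist(strsplit(ann$genes, ";", fixed = TRUE)))
    for (g in setdiff(intersect(hgt_genes, names(ess)), terminal_genes)) {
      if (!isTRUE(ess[g])) next
      if (!is.null(hgt_enrichment) &&
          (!g %in% names(hgt_enrichment) ||
           hgt_enrichment[[g]] < hgt_fold_min)) next
      rxns <- Filter(function(r) g %in% gpr_genes(r$gpr), model$reactions)
      comp <- sort(unique(unlist(lapply(rxns, function(r)
        met_compartment(names(r$stoich))))))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, amino_acid = NA_character_,
        compartment = if ("c" %in% comp) "c" else comp[1],
        reaction_id = names(rxns)[1],
        essential = TRUE,
        single_gene_reaction = all(vapply(rxns, function(r)
          r$id %in% single_gene || length(gpr_genes(r$gpr)) == 1L, logical(1))),
        rule = "upstream_essential_hgt", stringsAsFactors = FALSE)
    }
  }
  empty_selection <- function() {
    data.frame(gene_id = character(0), amino_acids = character(0),
               compartment = character(0), essential = logical(0),
               single_gene_reaction = logical(0),
               terminal_reaction = logical(0), rule = character(0),
               host_targetable = logical(0), selected = logical(0),
               stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty_selection())
  long <- do.call(rbind, rows)
  long <- long[long$essential, , drop = FALSE]
  if (nrow(long) == 0L) return(empty_selection())
  per_gene <- lapply(split(long, long$gene_id), function(d) {
    data.frame(
      gene_id = d$gene_id[1],
      amino_acids = paste(sort(unique(stats::na.omit(d$amino_acid))),
                          collapse = ";"),
      compartment = d$compartment[1],
      essential = TRUE,
      single_gene_reaction = all(d$single_gene_reaction),
      terminal_reaction = any(d$rule == "terminal"),
      rule = if (any(d$rule == "terminal")) "terminal" else d$rule[1],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_gene)
  out$host_targetable <- out$compartment == "c"
  out$selected <- out$host_targetable &
    (policy == "advisory" | out$single_gene_reaction)
  out <- out[order(out$amino_acids, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate target genes with horizontal-transfer origin
#'
#' @param targets data.frame with a `gene_id` column (e.g. from
#'   [select_symbiosis_targets()]).
#' @param hgt data.frame with columns `gene_id` (or a `key` column of
#'   your choice), `origin_genus`; duplicate gene rows are an error.
#' @param key column of `hgt` to match `targets$gene_id` against.
#' @return `targets` with added `origin` (`"HGT"` or `"intrinsic"`) and
#'   `source_organism` columns.
#' @export
annotate_origin <- function(targets, hgt, key = "gene_id") {
  if (nrow(hgt) > 0L && anyDuplicated(hgt[[key]])) {
    stop("duplicate gene rows in HGT table: ",
         hgt[[key]][duplicated(hgt[[key]])][1])
  }
  idx <- match(targets$gene_id, hgt[[key]])
  targets$origin <- ifelse(is.na(idx), "intrinsic", "HGT")
  targets$source_organism <- ifelse(is.na(idx), NA_character_,
                                    hgt$origin_genus[idx])
  targets
}

#' Compile the combined osmoregulation + symbiosis target report
#'
#' @param osmo data.frame from [select_osmoregulation_targets()].
#' @param symbiosis data.frame from [select_symbiosis_targets()]
#'   (optionally after [annotate_origin()]).
#' @return data.frame with `gene_id`, `category`, `criteria_met`,
#'   `fold`, `amino_acids`, `origin`, `source_organism`; ordered by
#'   category then gene id. Gene ids may not collide across
#'   categories.
#' @export
compile_report <- function(osmo, symbiosis) {
  blank <- function(n) rep(NA_character_, n)
  o <- data.frame(
    gene_id = osmo$gene_id,
    category = rep("osmoregulation", nrow(osmo)),
    criteria_met = osmo$criteria_met, fold = osmo$fold,
    amino_acids = blank(nrow(osmo)), origin = blank(nrow(osmo)),
    source_organism = blank(nrow(osmo)), stringsAsFactors = FALSE)
  crit <- function(d) {
    paste0("essential",
           ifelse(d$single_gene_reaction, ";single_gene", ""),
           ifelse(d$terminal_reaction, ";terminal", ";upstream_hgt"))
  }
  s <- data.frame(
    gene_id = symbiosis$gene_id,
    category = rep("symbiosis", nrow(symbiosis)),
    criteria_met = if (nrow(symbiosis)) crit(symbiosis) else character(0),
    fold = rep(NA_real_, nrow(symbiosis)),
    amino_acids = symbiosis$amino_acids,
    origin = if ("origin" %in% names(symbiosis)) symbiosis$origin
             else blank(nrow(symbiosis)),
    source_organism = if ("source_organism" %in% names(symbiosis))
      symbiosis$source_organism else blank(nrow(symbiosis)),
    stringsAsFactors = FALSE)
  out <- rbind(o, s)
  if (anyDuplicated(out$gene_id)) {
    stop("gene id appears in both categories: ",
         out$gene_id[duplicated(out$gene_id)][1])
  }
  out <- out[order(out$category, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialise a target report
#'
#' TSV and JSON renderings carry identical content; reading a written
#' TSV back yields the same data.frame.
#'
#' @param report data.frame from [compile_report()].
#' @param path output file; format chosen by extension (`.json` or
#'   TSV otherwise).
#' @export
write_target_report <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(report, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(report)
}
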