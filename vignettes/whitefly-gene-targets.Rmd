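---
title: "Nominating whitefly control gene targets: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nominating whitefly control gene targets: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holotarget)
```

## The problem

Phloem-feeding whiteflies (*Bemisia tabaci*) survive on a diet that is
both osmotically hostile — phloem sap approaches molar sucrose — and
nutritionally incomplete, lacking essential amino acids. Two systems
compensate: the gut, where secreted GH13 alpha-glucosidases (sucrases)
transglycosylate sucrose into longer, less osmotically active sugars
while water-specific aquaporins recycle water across the looped gut; and
the bacteriocyte, where the obligate endosymbiont *Portiera
aleyrodidarum* and a set of horizontally acquired bacterial genes in the
insect genome jointly synthesise the ten essential amino acids. Both
systems are single points of failure and therefore attractive RNAi
targets for managing the cassava whitefly (SSA1-SG1), the vector of the
viruses behind cassava brown streak disease.

`holotarget` reimplements the in-silico part of that target discovery as
a reusable, tested pipeline with three stages: a tissue-enrichment
screen on RNA-seq counts, rule-based protein filters for osmoregulation
candidates, and constraint-based analysis of a two-compartment
host–symbiont metabolic model for symbiosis candidates.

## Stage 1: tissue enrichment

Counts from dissected gut, bacteriocyte and whole-body libraries enter
as a `count_matrix`. `enrichment_test()` normalises library composition
by TMM (trimmed mean of M-values; 30% trim on log-ratios, 5% on average
intensities, reference column by the upper-quartile rule), fits
negative-binomial generalised linear models with a tissue coefficient
and tests it by likelihood ratio, adjusting p-values with the
Benjamini–Hochberg step-up rule. These standard steps are delegated to
edgeR behind the module surface; `bh_adjust()` wraps `p.adjust()`. The
dispersion estimator is the common (shared) GLM dispersion — the count
matrices here have two to three replicates per tissue, too few for
stable per-gene estimates — and is documented as replaceable via
`enrichment_config()`.

Genes are pre-filtered to CPM > 1 in at least two samples (configurable;
the choice only suppresses all-zero and near-zero genes that the NB fit
cannot use). Fold enrichment is reported both as `log_fc` and as linear
`fold = 2^log_fc`, matching how gut screens are usually tabulated.

qPCR validation math is the normalised 2^-ddCq model
(`ddcq_relative_expression()`): the reference combination is the
arithmetic mean of reference-gene Cq values (equivalently, the geometric
mean of their linear quantities). Efficiency correction beyond the
2^-ddCq model is out of scope.

## Stage 2: osmoregulation motif filters

The screen consumes upstream predictor output (SignalP D-scores,
conserved-domain residue calls) as annotation columns rather than
re-running those tools. Two rules:

* **GH13 sucrases** (`gh13_filter()`): keep a gene only if it has a
  predicted signal peptide *and* the intact catalytic dyad — aspartate
  nucleophile, glutamate proton donor. On the bundled gut-enriched
  table this keeps exactly 14 of 23 genes; it excludes the E/R-dyad
  gene and the previously proposed RNAi target that lacks both signal
  peptide and catalytic residues. The D-score decision threshold is
  0.45, which cleanly separates every signal-positive (>= 0.474) from
  every signal-negative (<= 0.428) row of the table.
* **Water-specific aquaporins** (`classify_water_specific()`): both NPA
  boxes present and the ar/R constriction tetrad exactly F/H/A/R
  (helix 2, helix 5, LE1, LE2). The mercury-sensitive cysteine is
  scanned (`scan_npa()`) as supporting evidence: by convention it is
  the residue two positions after the end of the first NPA box, i.e.
  `start + 4`; the offset is stated here because "two residues after
  the box" is ambiguous in prose. Tetrad positions come from
  template-alignment annotation; when a sequence is supplied the
  residues are verified against it rather than re-derived.

All residue positions are 1-based. Annotation ids are treated as opaque
strings throughout. `select_osmoregulation_targets()` joins the filters
with the enrichment table at a configurable `fold_min` (default 2) and
reports which criteria each gene met. Phylogenetic placement against
experimentally validated aphid SUC/AQP proteins — the step that narrows
14 sucrases to the two SUC targets in practice — is deliberately out of
scope, so this package reports the filtered candidate sets rather than a
curated final pair.

## Stage 3: the host–symbiont metabolic model

`metabolic_model` objects hold metabolites (compartment-tagged ids like
`lys-L[c]`), reactions with flux bounds (mmol gDW^-1 h^-1) and boolean
gene–protein–reaction rules, and a biomass objective built by
`build_biomass()` from amino acids, ATP and water. Two on-disk dialects
are supported: a bit-exact tabular TSV (equation strings such as
`2 A[c] + B[c] -> C[c]`, `<=>` for reversible) and SBML Level 3 with the
fbc extension, written/read with xml2 and verified in the test suite by
round-trip identity and by cobrapy independently reproducing model sizes
and the FBA optimum.

`merge_host_symbiont()` assembles the two-compartment model the way the
published host–endosymbiont reconstructions are assembled: reaction ids
take organism prefixes (`SSA1_Bt`, `SSA1_Por`), every dead-end
metabolite (`find_dead_ends()`, reversibility-aware) that the partner
compartment can resolve gets a reversible 1:1 symbiosome transport with
bounds [-1000, 1000], and declared nutrients/secretions are routed
through an explicit hemolymph compartment `e` (membrane transport plus
exchange; uptakes bounded [-uptake_max, 0], secretion [0, 1000]). The
big-M bound of 1000 is the community convention. Dead ends that are
neither partner-resolvable nor declared external are left in place —
they are diagnostic, and silently closing them would hide curation
errors.

### Constraint-based engine

FBA maximises biomass flux subject to `S v = 0` and the bounds, under
aerobic conditions with oxygen uptake capped at 20 mmol gDW^-1 h^-1 by
default (`sim_config()`). The LP kernel is a dense bounded-variable
two-phase primal simplex written for this package (R/lp.R), with
Bland's rule so degenerate networks cannot cycle; it is validated
against brute-force vertex enumeration on random models and against an
independent LP implementation. Only the objective value is contractual
— flux vectors may be one of several alternate optima, so per-reaction
flux claims are first verified unique by FVA (`v_min == v_max`).

Deletions constrain a reaction's bounds to zero (`delete_reaction()`),
or disable every reaction whose GPR evaluates false under a gene
knockout (`delete_gene()`); an entity is essential when knockout growth
falls below `zero_growth_tol = 1e-6` h^-1 (an absolute tolerance,
configurable; results carry `growth_ratio` so other cutoffs can be
applied post hoc). Infeasible knockout models are reported essential
with a status note, distinguishing them from feasible zero growth.

MOMA re-predicts knockout flux as the closest feasible point to the
wild-type flux (quadratic program, solved with the Goldfarb–Idnani dual
method from quadprog; redundant steady-state rows are removed by QR
before the solve). ROOM minimises the *number* of significantly changed
fluxes (|change| beyond `delta * |v_wt| + epsilon`, defaults 0.03 and
0.001 from the original ROOM formulation, which the source analysis
does not restate) as a MILP by LP-based branch-and-bound. The search
starts from an always-feasible incumbent — flag every deviating
reaction of the knockout FBA solution — so a node cap
(`room_max_nodes`) degrades gracefully to a certified-feasible,
possibly suboptimal answer; for essentiality confirmation this is
irrelevant because any feasible solution of a no-growth knockout has
zero biomass. The wild-type reference is the package's own
deterministic FBA solution (fixed variable order), trading elegance for
reproducibility.

### Target selection

`terminal_reactions()` finds, for each amino-acid precursor of biomass,
the non-transport reaction(s) producing it; `single_gene_reactions()`
lists reactions with single-gene GPRs. `select_symbiosis_targets()`
then applies the three-criterion rule: (i) essential, (iii) terminal,
with (ii) single-gene recorded as a flag — advisory by default because
the phenylalanine transaminase step is isozyme-mediated yet its gene is
retained in practice; `policy = "strict"` enforces it. Essential,
enriched, host-compartment HGT genes that sit upstream rather than at a
terminus (the dapB case) are admitted under an explicit
`upstream_essential_hgt` rule; gating that extension on bacteriocyte
enrichment is what keeps the essentially unexpressed dapF epimerase out
of the target list. Pathways whose terminal step lies in the symbiont
are reported but flagged not host-targetable, since host-expressed RNAi
cannot reach them. `annotate_origin()` joins a curated HGT table
(origin genus per gene); `compile_report()` emits the combined
osmoregulation + symbiosis report with per-row criteria provenance,
identically in TSV and JSON.

## Synthetic data: what it emulates, and what it does not

`simulate_counts()` draws gamma-Poisson counts with log-normal
library-size jitter (sigma 0.2) and log-normal gene baselines around
`baseline_mean` (planted genes sit exactly at `baseline_mean` so their
fold is interpretable); defaults are 2,000 genes, three replicates per
tissue, baseline 100, dispersion 0.1 — ordinary bulk RNA-seq scales.
Planted folds default to the 4–53-fold range seen in real gut screens
(tests plant 25-fold). It does not emulate batch effects, gene-length
bias or correlated genes, so passing recovery tests demonstrate
estimator correctness, not robustness to those artefacts.
`synth_proteins()` plants complete aquaporin signatures (NPA at 91 and
210, F/H/A/R tetrad, Cys at 95) and GH13 annotation rows, with every
decoy violating exactly one rule so the filters are tested
diagnostically. `random_viable_model()` guarantees growth by
construction (a producing spine) and keeps all bounds finite so
vertex-enumeration oracles apply.

`toy_holobiont()` is the deterministic centrepiece: host and symbiont
single-compartment models covering the lysine, arginine, phenylalanine,
tryptophan, histidine, branched-chain, threonine and methionine
pathways, merged by the same machinery users run. Its biomass
coefficients are proportional to realistic precursor export fluxes
(e.g. 0.371 for the arginine precursor, 0.3107 for valine's), ATP
demand is 50 per unit biomass so the 20-unit oxygen cap binds, giving
an optimal growth of 0.4 h^-1 — a realistic magnitude, not a claim
about any particular organism's value. Its declared truth (84
reactions, 82 metabolites, 36 genes; 33 essential genes with CM, pheA
and the PHETA1 isozyme dispensable; terminal map; symbiosis target set
{argH, lysA, BCAT, dapB, hisD, aspC}) is verified end-to-end by the
test suite, including the pseudogenization scenario: deleting the
symbiont pheA route makes the host chorismate mutase essential.

## Numerical choices and limitations

* LP/QP tolerances default to 1e-9; steady-state residuals are checked
  after every solve. Problem sizes in the suite stay under ~350
  variables, where a dense simplex is entirely adequate.
* Ties in the simplex are broken by smallest variable index (Bland),
  making flux vectors reproducible across runs on the same platform.
* The reconstruction does not do draft-from-genome model building,
  thermodynamic or mass/charge balancing, double deletions, dynamic
  FBA or flux sampling.
* Deposited supplementary model files from the motivating study are not
  redistributable inside the package, so the reconstruction pipeline is
  exercised on the bundled fixture models; the test suite's structural
  surface (sizes, growth, essentiality, FVA-unique fluxes) is the
  acceptance standard for that pathway.
* The test suite runs the gene/reaction deletion scans on the 84-reaction
  toy (seconds) and the solver oracle on 100 random <= 8-reaction
  models; these sizes are chosen to keep the full suite under a few
  minutes while still covering every code path.

## A worked example

```{r example, eval = FALSE}
toy <- toy_holobiont()
fba(toy$model)$objective_value        # 0.4 h^-1 under the aerobic default
gd <- single_gene_deletion(toy$model)
sum(gd$essential)                     # 33 of 36 genes are indispensable
sel <- select_symbiosis_targets(
  gd, terminal_reactions(toy$model), single_gene_reactions(toy$model),
  hgt_genes = toy$truth$hgt_genes, model = toy$model,
  hgt_enrichment = with(
    subset(hgt_table(), !is.na(gene_symbol) & !duplicated(gene_symbol)),
    setNames(fold, gene_symbol)))
sel$gene_id[sel$selected]             # argH, aspC, BCAT, dapB, hisD, lysA
```
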