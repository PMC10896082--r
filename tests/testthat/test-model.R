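test_that("model construction enforces its invariants", {
  expect_error(reaction("r", c("A[c]" = -1), lb = 5, ub = 1),
               "lower bound")
  expect_error(reaction("r", numeric(0)), "empty stoichiometry")
  expect_error(reaction("EX", c("A[c]" = -1, "B[c]" = 1), kind = "exchange"),
               "exactly one")
  expect_error(metabolic_model("m", c("A[c]"), list(
    reaction("r1", c("A[c]" = -1, "B[c]" = 1)))), "unknown metabolite")
  expect_error(metabolic_model("m", c("A[c]", "B[c]"), list(
    reaction("r1", c("A[c]" = -1, "B[c]" = 1)),
    reaction("r1", c("B[c]" = -1, "A[c]" = 1)))), "duplicate reaction")
  expect_error(metabolic_model("m", c("A[c]"), list(
    reaction("r1", c("A[c]" = -1))), objective = "nope"), "objective")
  empty <- metabolic_model("empty", character(0), list())
  expect_equal(model_stats(empty),
               list(n_reactions = 0L, n_metabolites = 0L, n_genes = 0L))
})

test_that("model stats count the union of GPR gene sets", {
  m <- parallel_model()
  s <- model_stats(m)
  expect_equal(s$n_reactions, 4L)
  expect_equal(s$n_metabolites, 2L)
  expect_equal(s$n_genes, 2L)
  S <- stoich_matrix(m)
  # matrix assembly agrees with the per-reaction dictionaries
  expect_equal(S["A[c]", "P1"], -1)
  expect_equal(S["B[c]", "P1"], 1)
  expect_equal(S["A[c]", "EX_A"], -1)
  expect_equal(sum(S != 0), 6)
})

test_that("biomass construction validates precursors and scales linearly", {
  spec <- c("arg-L" = 0.371, "lys-L" = 0.16, "his-L" = 0.049,
            "phe-L" = 0.21, "ile-L" = 0.11, "val-L" = 0.31,
            "leu-L" = 0.165, "thr-L" = 0.1, "met-L" = 0.046,
            "trp-L" = 0.012, "atp" = 30, "h2o" = 1)
  bio <- build_biomass(spec, "c", id = "BIO")
  expect_equal(length(bio$stoich), 12L)       # 10 amino acids + ATP + water
  expect_true(all(bio$stoich < 0))
  expect_equal(bio$kind, "biomass")
  expect_error(build_biomass(numeric(0)), "empty")
  expect_error(build_biomass(c("arg-L" = -1)), "positive")
  m <- chain_model()
  expect_error(build_biomass(c(Z = 1), "c", model = m), "absent")
  # scaling all coefficients by k scales optimal growth by 1/k
  grow <- function(k) {
    m2 <- chain_model()
    m2$reactions$BIO$stoich <- m2$reactions$BIO$stoich * k
    fba(m2)$objective_value
  }
  expect_equal(grow(2), grow(1) / 2)
  expect_equal(grow(5), grow(1) / 5)
})

test_that("dead-end detection respects reversibility", {
  # a closed reversible loop can both make and consume its members
  loop <- metabolic_model("loop", c("A[c]", "B[c]"), list(
    reaction("r", c("A[c]" = -1, "B[c]" = 1), lb = -10, ub = 10)))
  expect_length(find_dead_ends(loop), 0L)
  # the same reaction made irreversible strands both metabolites
  oneway <- metabolic_model("oneway", c("A[c]", "B[c]"), list(
    reaction("r", c("A[c]" = -1, "B[c]" = 1), lb = 0, ub = 10)))
  expect_setequal(find_dead_ends(oneway), c("A[c]", "B[c]"))
  chainAB <- metabolic_model("c", c("A[c]", "B[c]"), list(
    reaction("in", c("A[c]" = 1), lb = 0, ub = 10),
    reaction("r", c("A[c]" = -1, "B[c]" = 1), lb = 0, ub = 10)))
  expect_equal(find_dead_ends(chainAB), "B[c]")
})

test_that("equation strings parse and deparse faithfully", {
  eq <- parse_equation("2 A[c] + B[c] -> C[c]", "r")
  expect_equal(eq$stoich, c("A[c]" = -2, "B[c]" = -1, "C[c]" = 1))
  expect_false(eq$reversible)
  expect_true(parse_equation("A[c] <=> B[p]", "r")$reversible)
  expect_equal(parse_equation("A[e] ->", "ex")$stoich, c("A[e]" = -1))
  expect_equal(parse_equation("0.371 argSuc[c] -> arg-L[c]", "r")$stoich,
               c("argSuc[c]" = -0.371, "arg-L[c]" = 1))
  expect_error(parse_equation("A[c] -> B[c] -> C[c]", "r"), "unparseable")
  r <- reaction("r", c("A[c]" = -2, "B[c]" = -1, "C[c]" = 1), lb = 0)
  expect_equal(deparse_equation(r), "2 A[c] + B[c] -> C[c]")
})

test_that("models round-trip through both dialects", {
  toy <- get_toy()
  d <- withr::local_tempdir()
  for (f in c("m.tsv", "m.xml")) {
    path <- file.path(d, f)
    write_model(toy$model, path)
    expect_same_model(toy$model, read_model(path))
  }
  # small model with non-trivial GPRs and coefficients
  m <- metabolic_model("mini", c("A[c]", "B[c]", "glx[p]"), list(
    reaction("EX_A", c("A[c]" = -1), lb = -5, ub = 0, kind = "exchange"),
    reaction("R1", c("A[c]" = -2, "B[c]" = 1, "glx[p]" = 0.5),
             lb = -10, ub = 10, gpr = "(g1 AND g2) OR g3"),
    reaction("BIO", c("B[c]" = -1), lb = 0, ub = 100, kind = "biomass")),
    objective = "BIO")
  for (f in c("mini.tsv", "mini.xml")) {
    path <- file.path(d, f)
    write_model(m, path)
    expect_same_model(m, read_model(path))
  }
})

test_that("SBML reader names offending elements on broken files", {
  d <- withr::local_tempdir()
  m <- chain_model()
  path <- file.path(d, "b.xml")
  write_model(m, path)
  txt <- readLines(path)
  txt <- sub('species="M_A_c" stoichiometry="1"',
             'species="M_missing_c" stoichiometry="1"', txt[grepl("", txt)])
  writeLines(txt, path)
  expect_error(read_model(path), "unknown species")
})

test_that("merging host and symbiont inserts transports and exchanges correctly", {
  # toy host (5 rxns) + toy symbiont (4 rxns), 2 dead-end precursors
  host <- metabolic_model(
    "h", c("glc[c]", "pre1[c]", "aa1[c]", "aa2[c]", "bm[c]"), list(
    reaction("U1", c("glc[c]" = 1), lb = 0, ub = 10),
    reaction("H1", c("glc[c]" = -1, "aa1[c]" = 1), lb = 0, ub = 100, gpr = "h1"),
    reaction("H2", c("pre1[c]" = -1, "aa2[c]" = 1), lb = 0, ub = 100, gpr = "h2"),
    reaction("H3", c("aa1[c]" = -1, "aa2[c]" = -1, "bm[c]" = 1),
             lb = 0, ub = 100, gpr = "h3"),
    reaction("BIO", c("bm[c]" = -1), lb = 0, ub = 100, kind = "biomass")),
    objective = "BIO")
  # symbiont: consumes glc-derived sub, produces pre1 and a waste product
  symb <- metabolic_model("s", c("sub[p]", "pre1[p]", "mid[p]", "waste[p]"), list(
    reaction("S0", c("sub[p]" = 1), lb = 0, ub = 10),
    reaction("S1", c("sub[p]" = -1, "mid[p]" = 1), lb = 0, ub = 100, gpr = "s1"),
    reaction("S2", c("mid[p]" = -1, "pre1[p]" = 1), lb = 0, ub = 100, gpr = "s2"),
    reaction("S3", c("mid[p]" = -1, "waste[p]" = 1), lb = 0, ub = 100, gpr = "s3")),
    objective = NA_character_)
  merged <- merge_host_symbiont(host, symb, "Bt", "Por",
                                externals = list(uptake = character(0),
                                                 secretion = "waste"))
  # 5 + 4 + 2 transports (pre1, waste->c pass-through) + exchange chain
  expect_true(all(c("TP_pre1", "TP_waste", "TE_waste", "EX_waste") %in%
                  names(merged$reactions)))
  expect_equal(length(merged$reactions), 5 + 4 + 2 + 2)
  # no transported metabolite stays a dead end
  expect_false(any(c("pre1[c]", "pre1[p]") %in% find_dead_ends(merged)))
  # gene sets are disjoint so counts add
  expect_equal(model_stats(merged)$n_genes,
               model_stats(host)$n_genes + model_stats(symb)$n_genes)
  # stoichiometries preserved up to renaming
  expect_equal(merged$reactions$Bt_H3$stoich, host$reactions$H3$stoich)
  expect_equal(merged$reactions$Por_S2$stoich, symb$reactions$S2$stoich)
  expect_identical(merged$objective, "Bt_BIO")
  expect_error(merge_host_symbiont(host, symb, "X", "X"), "distinct")
  # merging with an empty symbiont adds declared exchanges only
  none <- metabolic_model("none", character(0), list())
  m2 <- merge_host_symbiont(host, none, "Bt", "Por",
                            externals = list(uptake = "pre1",
                                             secretion = character(0)))
  expect_equal(length(m2$reactions), 5 + 2)   # TE_pre1 + EX_pre1
})

test_that("merge rejects compartment clashes", {
  host <- metabolic_model("h", c("A[c]"), list(reaction("r", c("A[c]" = 1))))
  bad <- metabolic_model("s", c("A[c]"), list(reaction("r", c("A[c]" = 1))))
  expect_error(merge_host_symbiont(host, bad, "a", "b"), "compartment")
})

test_that("an independent COBRA implementation reads our SBML and agrees on growth", {
  py <- Sys.which("python")
  expect_true(nzchar(py))
  toy <- get_toy()
  d <- withr::local_tempdir()
  path <- file.path(d, "holo.xml")
  write_model(toy$model, path)
  script <- file.path(d, "check.py")
  writeLines(c(
    "import sys, cobra",
    "m = cobra.io.read_sbml_model(sys.argv[1])",
    "m.reactions.get_by_id('EX_o2').lower_bound = -20",
    "print(len(m.reactions), len(m.metabolites), len(m.genes),",
    "      round(m.slim_optimize(), 9))"), script)
  out <- system2(py, c(script, path), stdout = TRUE, stderr = FALSE)
  vals <- strsplit(tail(out, 1), " +")[[1]]
  expect_equal(as.integer(vals[1:3]),
               c(toy$truth$n_reactions, toy$truth$n_metabolites,
                 toy$truth$n_genes))
  expect_equal(as.numeric(vals[4]), fba(toy$model)$objective_value,
               tolerance = 1e-6)
})
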