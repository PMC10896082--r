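# Independent oracles and shared fixtures. Each oracle is a direct,
# brute-force rendering of the published definition, kept free of the
# package code paths it checks.

# Benjamini-Hochberg step-up by its definition:
# q_i = min over {j : p_j >= p_i} of m * p_j / rank_j, clipped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    min(1, min((m * p[p >= p[i]]) / r[p >= p[i]]))
  }, numeric(1))
}

# naive substring scan for NPA boxes
npa_oracle <- function(s) {
  n <- nchar(s)
  pos <- integer(0)
  for (i in seq_len(max(n - 2L, 0L))) {
    if (substr(s, i, i + 2L) == "NPA") pos <- c(pos, i)
  }
  pos
}

# TMM by direct evaluation of the trimmed weighted mean of M-values
# (trim 30% on M, 5% on A, inverse-variance weights, reference = sample
# whose upper quartile is closest to the mean upper quartile).
tmm_oracle <- function(counts) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2, function(x) stats::quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  one_factor <- function(obs, refv, nO, nR) {
    keep <- obs > 0 & refv > 0
    obs <- obs[keep]; refv <- refv[keep]
    logR <- log2((obs / nO) / (refv / nR))
    absE <- (log2(obs / nO) + log2(refv / nR)) / 2
    v <- (nO - obs) / (nO * obs) + (nR - refv) / (nR * refv)
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * 0.3) + 1; hiL <- n + 1 - loL
    loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
    keep2 <- rank(logR) >= loL & rank(logR) <= hiL &
             rank(absE) >= loS & rank(absE) <= hiS
    2^(sum(logR[keep2] / v[keep2]) / sum(1 / v[keep2]))
  }
  f <- vapply(seq_len(ncol(counts)), function(j) {
    one_factor(counts[, j], counts[, ref], lib[j], lib[ref])
  }, numeric(1))
  f / exp(mean(log(f)))
}

# brute-force FBA: enumerate basic solutions (vertices) of the flux
# polytope {S v = 0, lb <= v <= ub} and take the best objective
vertex_fba_oracle <- function(model, config = sim_config(), tol = 1e-8) {
  S <- stoich_matrix(model)
  lb <- vapply(model$reactions, `[[`, numeric(1), "lb")
  ub <- vapply(model$reactions, `[[`, numeric(1), "ub")
  for (r in model$reactions) {
    if (r$kind == "exchange" &&
        sub("\\[[^]]+\\]$", "", names(r$stoich)) == "o2") {
      lb[r$id] <- max(lb[r$id], -config$o2_uptake_max)
    }
  }
  cc <- as.numeric(names(model$reactions) == model$objective)
  n <- ncol(S)
  r <- qr(S)$rank
  best <- -Inf
  nonb <- n - r
  combs <- if (nonb == 0L) matrix(integer(0), 0, 1) else utils::combn(n, nonb)
  for (k in seq_len(ncol(combs))) {
    N <- combs[, k]
    B <- setdiff(seq_len(n), N)
    SB <- S[, B, drop = FALSE]
    if (qr(SB)$rank < r) next
    grid <- expand.grid(rep(list(1:2), length(N)))
    for (g in seq_len(max(nrow(grid), 1L))) {
      vN <- if (length(N)) ifelse(unlist(grid[g, ]) == 1, lb[N], ub[N]) else numeric(0)
      rhs <- if (length(N)) -S[, N, drop = FALSE] %*% vN else matrix(0, nrow(S), 1)
      vB <- tryCatch(qr.solve(SB, rhs), error = function(e) NULL)
      if (is.null(vB)) next
      v <- numeric(n); v[N] <- vN; v[B] <- vB
      if (max(abs(S %*% v)) > tol) next
      if (all(v >= lb - tol & v <= ub + tol)) best <- max(best, sum(cc * v))
    }
  }
  best
}

# small hand-built networks -------------------------------------------------

# linear chain: uptake (<=10) -> A -> B -> biomass; every step essential
chain_model <- function() {
  metabolic_model("chain", c("A[c]", "B[c]"), list(
    reaction("EX_A", c("A[c]" = -1), lb = -10, ub = 0, kind = "exchange"),
    reaction("R1", c("A[c]" = -1, "B[c]" = 1), lb = 0, ub = 1000, gpr = "g1"),
    reaction("BIO", c("B[c]" = -1), lb = 0, ub = 1000, kind = "biomass")),
    objective = "BIO")
}

# two redundant parallel routes A -> B; neither route is essential
parallel_model <- function() {
  metabolic_model("parallel", c("A[c]", "B[c]"), list(
    reaction("EX_A", c("A[c]" = -1), lb = -10, ub = 0, kind = "exchange"),
    reaction("P1", c("A[c]" = -1, "B[c]" = 1), lb = 0, ub = 1000, gpr = "g1"),
    reaction("P2", c("A[c]" = -1, "B[c]" = 1), lb = 0, ub = 1000, gpr = "g2"),
    reaction("BIO", c("B[c]" = -1), lb = 0, ub = 1000, kind = "biomass")),
    objective = "BIO")
}

# main route plus a one-reaction bypass, for ROOM change counting
bypass_model <- function() {
  metabolic_model("bypass", c("A[c]", "B[c]"), list(
    reaction("EX_A", c("A[c]" = -1), lb = -10, ub = 0, kind = "exchange"),
    reaction("MAIN", c("A[c]" = -1, "B[c]" = 1), lb = 0, ub = 1000, gpr = "g1"),
    reaction("BYP", c("A[c]" = -1, "B[c]" = 1), lb = 0, ub = 5, gpr = "g2"),
    reaction("IDLE", c("A[c]" = -1, "B[c]" = 1), lb = 0, ub = 0, gpr = "g3"),
    reaction("BIO", c("B[c]" = -1), lb = 0, ub = 1000, kind = "biomass")),
    objective = "BIO")
}

# the toy holobiont is deterministic but not free to build; cache it
.toy_cache <- new.env(parent = emptyenv())
get_toy <- function() {
  if (is.null(.toy_cache$toy)) .toy_cache$toy <- toy_holobiont()
  .toy_cache$toy
}
get_toy_gene_scan <- function() {
  if (is.null(.toy_cache$gd)) .toy_cache$gd <- single_gene_deletion(get_toy()$model)
  .toy_cache$gd
}

# id-level model equality used by the round-trip tests
expect_same_model <- function(a, b) {
  expect_setequal(names(a$reactions), names(b$reactions))
  expect_setequal(a$metabolites$id, b$metabolites$id)
  expect_identical(a$objective, b$objective)
  for (id in names(a$reactions)) {
    ra <- a$reactions[[id]]
    rb <- b$reactions[[id]]
    o <- sort(names(ra$stoich))
    expect_equal(ra$stoich[o], rb$stoich[sort(names(rb$stoich))],
                 info = paste("stoich of", id))
    expect_equal(c(ra$lb, ra$ub), c(rb$lb, rb$ub), info = paste("bounds of", id))
    expect_identical(ra$gpr, rb$gpr, info = paste("gpr of", id))
    expect_identical(ra$kind, rb$kind, info = paste("kind of", id))
  }
}
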