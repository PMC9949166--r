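# Independent oracles used across the suite.  None of them share code with
# the package's own solver paths: linear programs are re-solved with
# scipy's HiGHS backend through the system python, and the statistics are
# recomputed by exhaustive enumeration.

# -- scipy LP oracle ---------------------------------------------------------
# Solves a batch of LPs (maximize c'x, A x = b, lb <= x <= ub) in one
# python process.  Returns a list of list(status, objective), with status
# "optimal" or "infeasible".
oracle_lp_batch <- function(problems) {
  script <- '
import sys, json
import numpy as np
from scipy.optimize import linprog
out = []
for d in json.load(sys.stdin):
    A = np.array(d["A"], dtype=float).reshape(d["m"], d["n"])
    res = linprog(-np.array(d["c"], dtype=float), A_eq=A,
                  b_eq=np.array(d["b"], dtype=float),
                  bounds=list(zip(d["lb"], d["ub"])), method="highs")
    out.append({"status": "optimal" if res.status == 0 else "infeasible",
                "objective": (-res.fun) if res.status == 0 else None})
print(json.dumps(out))
'
  payload <- lapply(problems, function(p) list(
    m = nrow(p$A), n = ncol(p$A), A = as.numeric(t(p$A)),
    b = as.numeric(p$b), c = as.numeric(p$obj),
    lb = as.numeric(pmax(p$lb, -1e6)), ub = as.numeric(pmin(p$ub, 1e6))))
  inp <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE)
  res <- system2("python", c("-c", shQuote(script)), input = as.character(inp),
                 stdout = TRUE)
  jsonlite::fromJSON(paste(res, collapse = ""), simplifyVector = FALSE)
}

# FBA objective for a model via the scipy oracle
oracle_fba <- function(model) {
  S <- stoichiometric_matrix(model)
  p <- list(A = S, b = rep(0, nrow(S)),
            obj = model$rxns$objective_coefficient,
            lb = model$rxns$lower_bound, ub = model$rxns$upper_bound)
  oracle_lp_batch(list(p))[[1L]]
}

# -- random toy models -------------------------------------------------------
# Random valid models (<= 12 reactions): 1-3 uptake compounds with random
# yields, occasional secretion, random medium availabilities.
random_toy_model <- function(seed) {
  set.seed(seed)
  k <- sample(1:3, 1)
  cmps <- paste0("m", seq_len(k))
  yields <- stats::setNames(round(stats::runif(k, 0.1, 3), 3), cmps)
  secretion <- NULL
  if (k > 1 && stats::runif(1) < 0.4)
    secretion <- stats::setNames(
      list(stats::setNames(round(stats::runif(1, 0.1, 0.9), 3), "w")),
      cmps[1L])
  model <- generate_species_model(
    species_spec(paste0("R", seed), yields, secretion = secretion))
  med <- medium(stats::setNames(round(stats::runif(k, 0, 20), 3), cmps))
  apply_medium(model, med)
}

# -- exact statistics oracles ------------------------------------------------
# Two-sided Wilcoxon rank-sum p by enumeration of all allocations of the
# pooled ranks (tieless data only).
enum_wilcox_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  alloc <- utils::combn(length(pooled), nx)
  w_all <- apply(alloc, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  p_low <- mean(w_all <= w_obs)
  p_high <- mean(w_all >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# One-sided (enrichment) Fisher p for the 2x2 table [[a, b], [c, d]] by
# hypergeometric enumeration: a drawn in the candidate margin from the
# class margin.
enum_fisher_greater <- function(a, b, c_, d) {
  N <- a + b + c_ + d
  K <- a + c_        # class size
  n <- a + b         # candidate set size
  js <- max(a, 0):min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Mean unique-compound fraction over all communities of a given size
# (exhaustive subset enumeration).
enum_unique_fraction <- function(profiles, size) {
  combos <- utils::combn(length(profiles), size)
  mean(apply(combos, 2, function(idx)
    unique_uptake_compounds(profiles[idx])$fraction_with_unique))
}

# per-subset fractions (for Monte-Carlo SE estimates)
enum_unique_fraction_all <- function(profiles, size) {
  combos <- utils::combn(length(profiles), size)
  apply(combos, 2, function(idx)
    unique_uptake_compounds(profiles[idx])$fraction_with_unique)
}
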