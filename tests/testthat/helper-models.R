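# shared test helpers: tiny models and solution-set comparison

chain_model <- function() {
  metabolic_model(tibble::tribble(
    ~reaction_id, ~equation, ~lb, ~ub, ~cost, ~status,
    "up",   "-> S",    0, 10, 0, "non_targetable",
    "mid",  "S -> P",  0, Inf, 1, "deletable",
    "ex",   "P ->",    0, Inf, 0, "non_targetable"
  ))
}

solution_keys <- function(sets) {
  sort(vapply(sets, function(s)
    paste(paste(s$deletions, collapse = ","), "|",
          paste(s$additions, collapse = ",")), ""))
}

expect_same_solutions <- function(a, b) {
  expect_identical(solution_keys(a), solution_keys(b))
}

# all four compression-flag combinations of the pipeline
pipeline_variants <- function(bundle, max_cost, ...) {
  combos <- expand.grid(gpr = c(TRUE, FALSE), net = c(TRUE, FALSE))
  lapply(seq_len(nrow(combos)), function(i)
    compute_mcs(bundle$model, bundle$targets, bundle$desireds,
                max_cost = max_cost,
                gpr_compression = combos$gpr[i],
                network_compression = combos$net[i], ...)$solutions)
}
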