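test_that("the MILP finds the single essential cut of a chain (no desired)", {
  m <- metabolic_model(tibble::tribble(
    ~reaction_id, ~equation, ~lb, ~ub, ~cost, ~status,
    "up",  "-> S",    0, 10, 1, "non_targetable",
    "mid", "S -> P",  0, Inf, 1, "deletable",
    "ex",  "P ->",    0, Inf, 1, "non_targetable"))
  tg <- flux_region(m, "ex >= 1", role = "target")
  milp <- build_milp(m, tg)
  cs <- solve_smallest(milp)
  expect_equal(cs$deletions, "mid")
  expect_equal(cs$cost, 1)
})

test_that("the block structure has the stated variable count", {
  b <- example_cofeeding()
  milp <- build_milp(b$model, b$targets, rep(b$desireds, 2))
  m <- nrow(stoich_matrix(b$model)); n <- nrow(b$model)
  t_rows <- vapply(b$targets, function(tg)
    length(cutsets:::target_system(b$model, tg)$t), 0)
  n_targetable <- sum(b$model$status %in% c("deletable", "addable"))
  expect_equal(milp$dim$n_vars,
               sum(m + n + t_rows) + 2 * n + 3 * n_targetable)
})

test_that("an untargetable system with a feasible target has no solution", {
  m <- chain_model()
  m$status <- "non_targetable"
  tg <- flux_region(m, "ex >= 1", role = "target")
  expect_error(build_milp(m, tg), "no targetable unit")
})

test_that("a target that is already infeasible yields the empty cut set", {
  m <- chain_model()
  tg <- flux_region(m, "ex >= 99", role = "target")  # above capacity
  milp <- build_milp(m, tg)
  cs <- solve_smallest(milp)
  expect_length(cs$deletions, 0L)
  expect_equal(cs$cost, 0)
  sets <- enumerate_mcs(milp, max_cost = 3)
  expect_length(sets, 1L)
})

test_that("enumeration is complete and cost-monotone on random instances", {
  for (seed in c(3, 8, 13)) {
    b <- random_bundle(seed, n_targets = 1 + seed %% 2)
    milp_model <- b$model
    # reaction-level comparison: strip rules so both routes use reactions
    milp_model$gpr <- ""
    milp_model$status[milp_model$status == "non_targetable" &
                        !milp_model$reaction_id %in% c("s_up", "bm_ex")] <- "deletable"
    milp_model$cost[milp_model$status == "deletable"] <- 1
    attr(milp_model, "genes") <- gene_catalog(tibble::tibble(gene_id = character(0)))
    bundle2 <- b; bundle2$model <- milp_model
    milp <- build_milp(milp_model, b$targets, b$desireds, max_cost = 3)
    sets <- enumerate_mcs(milp, max_cost = 3)
    costs <- vapply(sets, `[[`, 0, "cost")
    expect_true(all(diff(costs) >= -1e-9))  # non-decreasing in optimal order
    orc <- oracle_enumerate(bundle2, max_cost = 3)
    expect_same_solutions(sets, orc)
  }
})

test_that("any_feasible sampling returns verified support-minimal sets", {
  b <- example_gene_mcs()
  res <- compute_mcs(b$model, b$targets, b$desireds, max_cost = 2,
                     mode = "any_feasible", paranoid = TRUE)
  expect_same_solutions(res$solutions, b$expected$gene_mcs)
})

test_that("support minimization drops redundant and zero-cost members", {
  b <- example_cofeeding()
  # documented minimal set plus one redundant deletion
  cand <- cutset(c("r3", "r7", "r9", "r12", "r11"), cost = 5)
  trimmed <- minimize_within_support(b$model, b$targets, b$desireds, cand)
  expect_setequal(trimmed$deletions, c("r3", "r7", "r9", "r12"))
  # a zero-cost free-rider is dropped first
  m2 <- b$model
  m2$cost[m2$reaction_id == "r11"] <- 0
  cand2 <- cutset(c("r3", "r7", "r9", "r12", "r11"), cost = 4)
  trimmed2 <- minimize_within_support(m2, b$targets, b$desireds, cand2)
  expect_setequal(trimmed2$deletions, c("r3", "r7", "r9", "r12"))
  expect_equal(trimmed2$cost, 4)
  # an already minimal candidate is returned unchanged
  again <- minimize_within_support(b$model, b$targets, b$desireds, trimmed)
  expect_equal(again$deletions, trimmed$deletions)
})

test_that("multi-region solutions have witnesses in every desired region", {
  b <- example_cofeeding()
  dg2 <- flux_region(b$model, "p_ex >= 0.2", role = "desired", label = "prod")
  res <- compute_mcs(b$model, b$targets, c(b$desireds, list(dg2)),
                     max_cost = 4)
  expect_gt(length(res$solutions), 0L)
  for (cs in res$solutions) {
    for (dg in c(b$desireds, list(dg2))) {
      expect_true(region_feasible(b$model, dg, cs$deletions,
                                  cs$additions)$feasible)
    }
  }
})
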