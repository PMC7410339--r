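test_that("reaction-lump expansion enumerates targetable members with costs", {
  record <- structure(list(
    lumps = list(rc_1 = tibble::tibble(
      member = c("gA", "pool", "rxn", "gB"),
      scale = c(1, 1, 1, 1),
      cost = c(1, 0, 0, 2),
      status = c("deletable", "non_targetable", "non_targetable", "deletable"))),
    col_map = list(),
    removed_reactions = character(0), removed_metabolites = character(0),
    orig_cost = c(gA = 1, pool = 0, rxn = 0, gB = 2, other = 1),
    orig_status = c(gA = "deletable", pool = "non_targetable",
                    rxn = "non_targetable", gB = "deletable",
                    other = "deletable")), class = "compression_record")
  ex <- expand_reaction_lumps(cutset("rc_1", cost = 1,
                                     level = "compressed_reaction"), record)
  expect_setequal(lapply(ex, `[[`, "deletions"), list("gA", "gB"))
  expect_setequal(vapply(ex, `[[`, 0, "cost"), c(1, 2))
  # minimum expansion cost attains the compressed cost
  expect_equal(min(vapply(ex, `[[`, 0, "cost")), 1)
  # a set without lumped members is its own sole expansion
  ex2 <- expand_reaction_lumps(cutset("other", cost = 1), record)
  expect_length(ex2, 1L)
  expect_equal(ex2[[1]]$deletions, "other")
})

test_that("gene-lump expansion hits every disjunct of the lump expression", {
  catalog <- gene_catalog(tibble::tibble(
    gene_id = c("g1", "g2", "g5", "g7", "g9", "L_and", "L_or"),
    cost = c(1, 1, 1, 1, 1, 1, 2)))
  attr(catalog, "lump_map") <- list(
    L_and = list(c("g1", "g2")),           # g1 AND g2
    L_or = list(c("g5", "g9"), "g7"))      # (g5 AND g9) OR g7
  ex <- expand_gene_lumps(cutset("L_and", cost = 1, level = "gene"), catalog)
  expect_setequal(lapply(ex$expansions, `[[`, "deletions"),
                  list("g1", "g2"))
  expect_true(all(vapply(ex$expansions, `[[`, 0, "cost") == 1))

  ex2 <- expand_gene_lumps(cutset("L_or", cost = 2, level = "gene"), catalog)
  expect_setequal(lapply(ex2$expansions, `[[`, "deletions"),
                  list(c("g5", "g7"), c("g7", "g9")))
  expect_true(all(vapply(ex2$expansions, `[[`, 0, "cost") == 2))

  # budget: with max_cost 1 both expansions of L_or are discarded
  ex3 <- expand_gene_lumps(cutset("L_or", cost = 2, level = "gene"), catalog,
                           max_cost = 1)
  expect_length(ex3$expansions, 0L)
  expect_equal(ex3$discarded_over_budget, 2L)
})

test_that("superset filtering matches the quadratic oracle", {
  expect_equal(
    solution_keys(filter_redundant(list(cutset("a"), cutset(c("a", "b"))))),
    solution_keys(list(cutset("a"))))
  no_pairs <- list(cutset(c("a", "b")), cutset(c("b", "c")), cutset("d"))
  expect_same_solutions(filter_redundant(no_pairs), no_pairs)

  set.seed(5)
  pool <- letters[1:6]
  for (rep in 1:20) {
    sets <- lapply(seq_len(8), function(i)
      cutset(sample(pool, sample(1:3, 1)), cost = 1))
    got <- filter_redundant(sets)
    # brute-force pairwise filter
    keys <- lapply(sets, `[[`, "deletions")
    keep <- vapply(seq_along(sets), function(i) {
      !any(vapply(seq_along(sets), function(j) {
        i != j && all(keys[[j]] %in% keys[[i]]) &&
          length(keys[[j]]) < length(keys[[i]])
      }, TRUE))
    }, TRUE)
    want <- sets[keep]
    want <- want[!duplicated(vapply(want, cutsets:::cutset_key, ""))]
    got <- got[!duplicated(vapply(got, cutsets:::cutset_key, ""))]
    expect_same_solutions(got, want)
  }
})

test_that("additions are preserved through both expansion stages", {
  catalog <- gene_catalog(tibble::tibble(gene_id = "gx", cost = 1))
  ex <- expand_gene_lumps(cutset("gx", additions = "u_up", cost = 1,
                                 level = "gene"),
                          catalog, costs = c(gx = 1, u_up = 0))
  expect_equal(ex$expansions[[1]]$additions, "u_up")
})
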