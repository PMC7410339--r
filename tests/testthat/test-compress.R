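test_that("a linear chain of coupled reactions collapses to one lump", {
  m <- metabolic_model(tibble::tribble(
    ~reaction_id, ~equation, ~lb, ~ub, ~cost, ~status,
    "a", "-> X1",     0, 10, 1, "deletable",
    "b", "X1 -> X2",  0,  7, 2, "deletable",
    "c", "X2 -> ",    0, 99, 3, "deletable"))
  cn <- compress_network(m)
  expect_equal(nrow(cn$model), 1L)        # n - 2
  expect_equal(cn$model$ub, 7)            # tightest member bound
  expect_equal(cn$model$cost, 1)          # cheapest targetable member
  lump <- cn$record$lumps[[cn$model$reaction_id]]
  expect_setequal(lump$member, c("a", "b", "c"))
  expect_equal(lump$scale, rep(1, 3))
})

test_that("stoichiometric scaling in lumps is exact", {
  m <- metabolic_model(tibble::tribble(
    ~reaction_id, ~equation,       ~lb, ~ub,
    "a", "-> 3 X",          0, 10,
    "b", "2 X -> Y",        0, 99,
    "y", "Y ->",            0, 99))
  cn <- compress_network(m)
  expect_equal(nrow(cn$model), 1L)
  lump <- cn$record$lumps[[cn$model$reaction_id]]
  # consumer b runs at 3/2 the rate of a; y at 3/2 the rate of a
  sc <- stats::setNames(lump$scale, lump$member)
  expect_equal(sc[["a"]], 1)
  expect_equal(sc[["b"]], 3 / 2)
  expect_equal(sc[["y"]], 3 / 2)
  # net column: scaled member columns cancel all internal metabolites
  S <- stoich_matrix(m)
  net <- S[, lump$member, drop = FALSE] %*% lump$scale
  expect_true(all(net == 0))
  # bounds map through the scaling: v_b = 1.5 v <= 99  =>  v <= 66
  expect_equal(cn$model$ub, 10)
})

test_that("duplicated metabolite rows are removed as conservation relations", {
  # metabolite D is a strict copy of C (e.g. a conserved moiety pair)
  m <- metabolic_model(tibble::tribble(
    ~reaction_id, ~equation,        ~lb, ~ub,
    "a", "-> C + D",        0, 10,
    "b", "C + D -> P",      0, 99,
    "p", "P ->",            0, 99,
    "q", "C + D -> Q",      0, 99,
    "qx", "Q ->",           0, 99))
  S <- stoich_matrix(m)
  R <- cutsets:::rmat(S)
  expect_equal(cutsets:::dependent_rows(R), which(rownames(S) == "D"))
  cn <- compress_network(m, lump_reactions = FALSE)
  expect_true("D" %in% cn$record$removed_metabolites)
})

test_that("blocked reactions and their dead ends are removed", {
  m <- metabolic_model(tibble::tribble(
    ~reaction_id, ~equation, ~lb, ~ub,
    "up",   "-> S",     0, 10,
    "mid",  "S -> P",   0, Inf,
    "ex",   "P ->",     0, Inf,
    "dead", "W -> P",   0, Inf))
  cn <- compress_network(m)
  expect_true("dead" %in% cn$record$removed_reactions)
  expect_false("W" %in% rownames(stoich_matrix(cn$model)))
})

test_that("regions are rewritten consistently onto the compressed basis", {
  b <- example_cofeeding()
  cn <- compress_network(b$model)
  t1c <- cutsets:::region_to_compressed(b$targets[[1]], cn$model, cn$record)
  # feasibility (and a witness-level quantity) is preserved by compression
  expect_equal(region_feasible(cn$model, t1c)$feasible,
               region_feasible(b$model, b$targets[[1]])$feasible)
  dgc <- cutsets:::region_to_compressed(b$desireds[[1]], cn$model, cn$record)
  expect_true(region_feasible(cn$model, dgc)$feasible)
})

test_that("nothing-to-compress networks come back unchanged", {
  # two parallel routes: no 1-producer/1-consumer metabolite after the fork
  m <- metabolic_model(tibble::tribble(
    ~reaction_id, ~equation, ~lb, ~ub,
    "up", "-> S",    0, 10,
    "p1", "S -> P",  0, Inf,
    "p2", "S -> P",  0, Inf,
    "ex", "P ->",    0, Inf))
  cn <- compress_network(m, lump_reactions = FALSE)
  expect_equal(nrow(cn$model), 4L)
  expect_length(cn$record$lumps, 0L)
})
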