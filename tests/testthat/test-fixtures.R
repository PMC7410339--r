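test_that("random bundles are deterministic per seed and valid", {
  b1 <- random_bundle(4)
  b2 <- random_bundle(4)
  expect_equal(as.data.frame(b1$model), as.data.frame(b2$model))
  expect_equal(b1$targets[[1]]$V, b2$targets[[1]]$V)
  # desired region feasible by construction; targets exclude zero
  expect_true(region_feasible(b1$model, b1$desireds[[1]])$feasible)
  for (tg in b1$targets)
    expect_error(cutsets:::assert_zero_excluded(b1$model, tg), NA)
  # caller RNG state untouched
  set.seed(99); x1 <- stats::runif(1)
  set.seed(99); invisible(random_bundle(5)); x2 <- stats::runif(1)
  expect_equal(x1, x2)
})

test_that("documented co-utilization designs verify and are minimal", {
  b <- example_cofeeding()
  v <- verify_mcs(b$model, b$targets, b$desireds, b$expected)
  expect_true(all(v$sound))
  expect_true(all(v$minimal))
  # dropping any member of the four-knockout design re-opens a target region
  orange <- b$expected$single_substrate
  for (rid in orange$deletions) {
    some_target_open <- any(vapply(b$targets, function(tg)
      region_feasible(b$model, tg,
                      setdiff(orange$deletions, rid))$feasible, TRUE))
    expect_true(some_target_open, info = rid)
  }
  # the co-feeding design needs its addition for the desired region
  blue <- b$expected$co_feeding
  expect_false(region_feasible(b$model, b$desireds[[1]],
                               blue$deletions)$feasible)
})

test_that("the gene-example documented outcomes verify", {
  b <- example_gene_mcs()
  v <- verify_mcs(b$model, b$targets, b$desireds, b$expected$gene_mcs)
  expect_true(all(v$sound))
  expect_true(all(v$minimal))
})

test_that("the exhaustive oracle recovers the documented gene cut sets", {
  b <- example_gene_mcs()
  orc <- oracle_enumerate(b, max_cost = 2)
  expect_same_solutions(orc, b$expected$gene_mcs)
})

test_that("the oracle reports a single cut for a single-route target", {
  m <- metabolic_model(tibble::tribble(
    ~reaction_id, ~equation, ~lb, ~ub, ~cost, ~status,
    "up",  "-> S",    0, 10, 0, "non_targetable",
    "mid", "S -> P",  0, Inf, 1, "deletable",
    "ex",  "P ->",    0, Inf, 0, "non_targetable"))
  bundle <- structure(list(model = m,
                           targets = list(flux_region(m, "ex >= 1",
                                                      role = "target")),
                           desireds = list()), class = "mcs_bundle")
  orc <- oracle_enumerate(bundle, max_cost = 2)
  expect_length(orc, 1L)
  expect_equal(orc[[1]]$deletions, "mid")
})

test_that("bundles export to disk and read back equivalently", {
  b <- example_gene_mcs()
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  m2 <- read_model(file.path(dir, "model.tsv"))
  regions <- read_regions(file.path(dir, "regions.yaml"), m2)
  roles <- vapply(regions, `[[`, "", "role")
  res <- compute_mcs(m2, regions[roles == "target"], regions[roles == "desired"],
                     max_cost = 2)
  expect_same_solutions(res$solutions, b$expected$gene_mcs)
})
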