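test_that("a single-gene rule adds one E, one Q, one g and one p reaction", {
  m <- metabolic_model(tibble::tribble(
    ~reaction_id, ~equation, ~lb, ~ub, ~gpr,
    "up",  "-> S",   0, 10, "",
    "cnv", "S -> P", 0, Inf, "gx",
    "ex",  "P ->",   0, Inf, ""))
  intg <- integrate_gpr(m)
  ext <- intg$model
  expect_equal(nrow(ext), nrow(m) + 2L)  # + gene synthesis + pool filler
  mets <- rownames(stoich_matrix(ext))
  expect_true("E__gx" %in% mets && "Q__cnv" %in% mets)
  # knocking out the gene synthesis reaction blocks the reaction
  dg <- flux_region(ext, "ex >= 1", role = "desired")
  expect_true(region_feasible(ext, dg)$feasible)
  expect_false(region_feasible(ext, dg, deletions = "g__gx")$feasible)
  # the GPR-bearing reaction itself became non-targetable
  expect_equal(ext$status[ext$reaction_id == "cnv"], "non_targetable")
})

test_that("isoenzymes do not inflate the attainable flux", {
  m <- metabolic_model(tibble::tribble(
    ~reaction_id, ~equation, ~lb, ~ub, ~gpr,
    "up",  "-> S",   0, 20, "",
    "cnv", "S -> P", 0, 10, "g1 or g2",
    "ex",  "P ->",   0, Inf, ""))
  ext <- integrate_gpr(m)$model
  f <- fva(ext, reactions = "cnv")
  expect_equal(f$max, 10)
})

test_that("reversible reactions split into two directions sharing the enzyme", {
  m <- metabolic_model(tibble::tribble(
    ~reaction_id, ~equation,  ~lb,  ~ub, ~gpr,
    "up",  "-> S",      0,  10, "",
    "cnv", "S <-> P", -40,  70, "gx",
    "ex",  "P <-> ",  -10, Inf, ""))
  intg <- integrate_gpr(m)
  ext <- intg$model
  sm <- intg$extension$split_map[["cnv"]]
  expect_equal(unname(ext$ub[match(sm, ext$reaction_id)]), c(70, 40))
  expect_equal(unname(ext$lb[match(sm, ext$reaction_id)]), c(0, 0))
  # one enzyme species, two direction pools
  mets <- rownames(stoich_matrix(ext))
  expect_equal(sum(mets == "E__gx"), 1L)
  expect_true(all(paste0("Q__", sm) %in% mets))
  # deleting the gene blocks both directions
  for (rg in list(flux_region(ext, paste(sm[1], ">= 1"), role = "desired"),
                  flux_region(ext, paste(sm[2], ">= 1"), role = "desired"))) {
    expect_true(region_feasible(ext, rg)$feasible)
    expect_false(region_feasible(ext, rg, deletions = "g__gx")$feasible)
  }
})

test_that("integration preserves FVA ranges of all original reactions", {
  # net flux of a split pair is forward - backward
  net_range <- function(ext, extension, rid) {
    sm <- extension$split_map[[rid]]
    if (is.null(sm)) {
      f <- fva(ext, reactions = rid)
      c(f$min, f$max)
    } else {
      S <- stoich_matrix(ext)
      obj <- stats::setNames(numeric(nrow(ext)), ext$reaction_id)
      obj[sm["forward"]] <- 1; obj[sm["backward"]] <- -1
      lo <- cutsets:::lp_solve(obj, S, rep("==", nrow(S)), rep(0, nrow(S)),
                               ext$lb, ext$ub)
      hi <- cutsets:::lp_solve(obj, S, rep("==", nrow(S)), rep(0, nrow(S)),
                               ext$lb, ext$ub, maximize = TRUE)
      c(if (lo$status == "unbounded") -Inf else lo$objval,
        if (hi$status == "unbounded") Inf else hi$objval)
    }
  }
  for (seed in 1:4) {
    b <- random_bundle(seed)
    intg <- integrate_gpr(b$model)
    f0 <- fva(b$model)
    for (i in seq_len(nrow(b$model))) {
      rng <- net_range(intg$model, intg$extension, b$model$reaction_id[i])
      expect_equal(rng[1], f0$min[i], tolerance = 1e-6,
                   info = paste(seed, f0$reaction_id[i]))
      expect_equal(rng[2], f0$max[i], tolerance = 1e-6,
                   info = paste(seed, f0$reaction_id[i]))
    }
  }
})

test_that("an addable reaction with a GPR rule is rejected", {
  m <- metabolic_model(tibble::tibble(
    reaction_id = c("up", "cnv", "ex"),
    equation = c("-> S", "S -> P", "P ->"),
    lb = 0, ub = c(10, 10, 100), gpr = c("", "gx", ""),
    cost = 1, status = c("non_targetable", "addable", "non_targetable")))
  expect_error(integrate_gpr(m), "addable")
})
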