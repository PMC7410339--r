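test_that("yield regions linearize the fractional yield constraint", {
  b <- example_cofeeding()
  # r_P / r_S <= Y  becomes  r_P - Y r_S <= 0
  rg <- make_yield_region(b$model, "p_ex", "s_up", 0.4, "<=", "target",
                          extra_rows = "s_up >= 0.1")
  i <- 1L
  expect_equal(rg$V[i, "p_ex"], 1)
  expect_equal(rg$V[i, "s_up"], -0.4)
  expect_equal(rg$v[i], 0)
  # applying the stored row to a candidate flux vector reproduces the scalar
  # inequality value
  r <- stats::setNames(numeric(nrow(b$model)), b$model$reaction_id)
  r["p_ex"] <- 2; r["s_up"] <- 10
  expect_equal(as.numeric(rg$V[1, ] %*% r), 2 - 0.4 * 10)

  # threshold zero degenerates to r_P <= 0
  rg0 <- make_yield_region(b$model, "p_ex", "s_up", 0, "<=", "target",
                           extra_rows = "s_up >= 0.1")
  expect_equal(unname(rg0$V[1, rg0$V[1, ] != 0]), 1)

  # weighted two-substrate denominator (carbon-weighted combined yield)
  rgw <- make_yield_region(b$model, "p_ex", c(s_up = 6, u_up = 2), 0.3,
                           "<=", "target", extra_rows = "s_up >= 0.1")
  expect_equal(rgw$V[1, c("p_ex", "s_up", "u_up")],
               c(p_ex = 1, s_up = -1.8, u_up = -0.6))
})

test_that("a target region containing the zero flux vector is rejected", {
  m <- chain_model()
  expect_error(flux_region(m, "ex <= 0", role = "target"),
               "zero flux vector")
  # a minimum-uptake row rescues it
  expect_s3_class(flux_region(m, c("ex <= 0", "up >= 0.1"), role = "target"),
                  "flux_region")
  # a network bound excluding zero also rescues it (maintenance-style lb > 0)
  m2 <- m
  m2$lb[m2$reaction_id == "up"] <- 0.5
  expect_s3_class(flux_region(m2, "ex <= 0", role = "target"), "flux_region")
})

test_that("the co-feeding pair pins co-substrate uptake/export to zero", {
  b <- example_cofeeding()
  t1 <- b$targets[[1]]; t2 <- b$targets[[2]]
  # region 1: single-substrate yield, u_up = 0 (two stacked rows)
  expect_equal(t1$V[1, c("p_ex", "s_up")], c(p_ex = 1, s_up = -0.4))
  expect_equal(t1$V[2, "s_up"], -1); expect_equal(t1$v[2], -0.1)
  expect_equal(unname(t1$V[3:4, "u_up"]), c(1, -1))
  expect_equal(t1$v[3:4], c(0, 0))
  # region 2: combined yield, u_ex = 0
  expect_equal(t2$V[1, c("p_ex", "s_up", "u_up")],
               c(p_ex = 1, s_up = -0.4, u_up = -0.4))
  expect_equal(unname(t2$V[3:4, "u_ex"]), c(1, -1))
  # both regions nonempty on the wild type
  expect_true(region_feasible(b$model, t1)$feasible)
  expect_true(region_feasible(b$model, t2, additions = "u_up")$feasible)
})

test_that("a zero-capacity co-substrate uptake is flagged", {
  b <- example_cofeeding()
  m <- b$model
  m$ub[m$reaction_id == "u_up"] <- 0
  expect_warning(
    make_cofeeding_target_pair(m, "p_ex", "s_up", "u_up", "u_ex", 0.4),
    "degenerate")
  expect_error(
    make_cofeeding_target_pair(b$model, "p_ex", "s_up", "nope", "u_ex", 0.4),
    "unknown id")
})

test_that("region_feasible matches a hand-assembled LP and honours deletions", {
  m <- chain_model()
  dg <- flux_region(m, "ex >= 1", role = "desired")
  res <- region_feasible(m, dg)
  expect_true(res$feasible)
  # the witness satisfies steady state and the region row
  S <- stoich_matrix(m)
  expect_equal(as.numeric(S %*% res$witness), rep(0, nrow(S)), tolerance = 1e-7)
  expect_gte(res$witness[["ex"]], 1 - 1e-9)
  # direct LP on the same constraint stack agrees
  direct <- cutsets:::lp_feasible(rbind(S, dg$V),
                                  c(rep("==", nrow(S)), "<="), c(0, 0, -1),
                                  m$lb, m$ub)
  expect_true(direct$feasible)
  # deleting the only route makes it infeasible
  expect_false(region_feasible(m, dg, deletions = "mid")$feasible)
})
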