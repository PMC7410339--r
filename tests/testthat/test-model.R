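test_that("a tabular model is echoed into the right dimensions", {
  m <- metabolic_model(tibble::tribble(
    ~reaction_id, ~equation,      ~lb, ~ub,
    "ra", "A -> B",                 0, Inf,
    "rb", "A + 2 B -> ",            0, Inf,
    "rc", "-> A",                   0, 10))
  S <- stoich_matrix(m)
  expect_equal(dim(S), c(2L, 3L))
  expect_equal(S["B", "ra"], 1)
  expect_equal(S["B", "rb"], -2)
})

test_that("reversibility is defined by the lower bound", {
  m <- metabolic_model(tibble::tibble(
    reaction_id = c("f", "r"), equation = c("A -> B", "A <-> B"),
    lb = c(0, -1000), ub = c(1000, 1000)))
  expect_equal(cutsets:::irreversible(m), "f")
  expect_equal(cutsets:::reversible_rxns(m), "r")
})

test_that("model validation rejects malformed input", {
  expect_error(metabolic_model(tibble::tibble(
    reaction_id = c("a", "a"), equation = c("-> X", "X ->"))),
    "duplicate reaction ids")
  expect_error(metabolic_model(tibble::tibble(
    reaction_id = "a", equation = "-> X", lb = 1, ub = 0)), "lb > ub")
  expect_error(metabolic_model(tibble::tibble(
    reaction_id = "a", equation = "X = Y")), "arrow")
  expect_error(metabolic_model(tibble::tibble(
    reaction_id = "a", equation = "-> X", status = "banana")), "status")
})

test_that("fractional coefficients round-trip through equation text", {
  eq <- cutsets:::format_equation(c(A = -1, B = 7 / 3))
  expect_match(eq, "7/3")
  expect_equal(cutsets:::parse_equation(eq)[["B"]], 7 / 3)
})

test_that("write-then-read of a fixture is the identity", {
  b <- example_cofeeding()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_model(b$model, path)
  m2 <- read_model(path)
  expect_equal(as.data.frame(m2), as.data.frame(b$model))
  expect_equal(stoich_matrix(m2), stoich_matrix(b$model))
})

test_that("interventions rewrite bounds: deletions and absent addables", {
  b <- example_cofeeding()
  m <- apply_interventions(b$model, deletions = "r6")
  expect_equal(m$ub[m$reaction_id == "r6"], 0)
  expect_equal(m$ub[m$reaction_id == "u_up"], 0)   # addable absent by default
  m <- apply_interventions(b$model, additions = "u_up")
  expect_equal(m$ub[m$reaction_id == "u_up"], 10)
  expect_error(apply_interventions(b$model, "nope"), "unknown reaction")
})

test_that("SBML level 3 fbc models are read with bounds and GPR text", {
  sbml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
    'level="3" version="1" fbc:required="false"><model id="toy">',
    '<listOfParameters>',
    '<parameter id="lb0" value="0" constant="true"/>',
    '<parameter id="lbm" value="-1000" constant="true"/>',
    '<parameter id="ub1000" value="1000" constant="true"/>',
    '</listOfParameters>',
    '<listOfSpecies><species id="A" boundaryCondition="false"/>',
    '<species id="B" boundaryCondition="false"/>',
    '<species id="ext" boundaryCondition="true"/></listOfSpecies>',
    '<fbc:listOfGeneProducts>',
    '<fbc:geneProduct fbc:id="G1" fbc:label="gA"/>',
    '<fbc:geneProduct fbc:id="G2" fbc:label="gB"/>',
    '</fbc:listOfGeneProducts>',
    '<listOfReactions>',
    '<reaction id="up" reversible="false" fbc:lowerFluxBound="lb0" ',
    'fbc:upperFluxBound="ub1000">',
    '<listOfReactants><speciesReference species="ext" stoichiometry="1"/>',
    '</listOfReactants>',
    '<listOfProducts><speciesReference species="A" stoichiometry="1"/>',
    '</listOfProducts></reaction>',
    '<reaction id="conv" reversible="true" fbc:lowerFluxBound="lbm" ',
    'fbc:upperFluxBound="ub1000">',
    '<listOfReactants><speciesReference species="A" stoichiometry="1"/>',
    '</listOfReactants>',
    '<listOfProducts><speciesReference species="B" stoichiometry="2"/>',
    '</listOfProducts>',
    '<fbc:geneProductAssociation><fbc:and>',
    '<fbc:geneProductRef fbc:geneProduct="G1"/>',
    '<fbc:geneProductRef fbc:geneProduct="G2"/>',
    '</fbc:and></fbc:geneProductAssociation></reaction>',
    '</listOfReactions></model></sbml>')
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, path)
  m <- read_model(path)
  expect_equal(m$lb, c(0, -1000))
  expect_equal(m$ub, c(1000, 1000))
  expect_true("conv" %in% cutsets:::reversible_rxns(m))
  expect_equal(m$gpr[m$reaction_id == "conv"], "(gA and gB)")
  # boundary species dropped: 'up' is a pure source for A
  expect_equal(rownames(stoich_matrix(m)), c("A", "B"))
})
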