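test_that("GPR parsing yields minimized DNF", {
  expect_setequal(lapply(parse_gpr("(g1 and g2) or g3"), identity),
                  list(c("g1", "g2"), "g3"))
  expect_setequal(lapply(parse_gpr("g1 and (g2 or g3)"), identity),
                  list(c("g1", "g2"), c("g1", "g3")))
  # absorption: g1 or (g1 and g2) == g1
  expect_equal(length(parse_gpr("g1 or (g1 and g2)")), 1L)
  expect_length(parse_gpr(""), 0L)
  expect_error(parse_gpr("(g1 and g2"), "parenthes")
  expect_error(parse_gpr("g1 and and g2"), "unexpected token")
})

test_that("DNF conversion is truth-table equivalent to the input", {
  genes <- paste0("g", 1:6)
  # direct evaluator for infix text, via R's own parser
  eval_text <- function(txt, active) {
    env <- as.list(stats::setNames(genes %in% active, genes))
    txt <- gsub(" and ", " & ", txt)
    txt <- gsub(" or ", " | ", txt)
    eval(parse(text = txt), envir = env)
  }
  set.seed(11)
  rand_expr <- function(depth = 0) {
    if (depth > 2 || stats::runif(1) < 0.4) return(sample(genes, 1))
    op <- sample(c(" and ", " or "), 1)
    paste0("(", rand_expr(depth + 1), op, rand_expr(depth + 1), ")")
  }
  for (k in 1:20) {
    txt <- rand_expr()
    rule <- parse_gpr(txt)
    for (mask in 0:(2^6 - 1)) {
      active <- genes[bitwAnd(mask, 2^(0:5)) > 0]
      expect_equal(eval_gpr(rule, deleted = setdiff(genes, active)),
                   eval_text(txt, active),
                   info = paste(txt, "|", paste(active, collapse = ",")))
    }
  }
})

fig_rules <- function() {
  rules <- lapply(example_gene_mcs()$model$gpr, parse_gpr)
  names(rules) <- example_gene_mcs()$model$reaction_id
  rules[lengths(rules) > 0]
}

test_that("compression of the nine-gene ruleset leaves four gene entities", {
  b <- example_gene_mcs()
  ess <- find_essential(b$model, b$desireds)
  cg <- compress_gpr(fig_rules(), attr(b$model, "genes"),
                     blocked_rxns = character(0), essential_rxns = ess)
  remaining <- cutsets:::rule_genes(cg$rules)
  expect_length(remaining, 4L)
  expect_true(all(c("g3", "g4", "g8") %in% remaining))
  lump <- setdiff(remaining, c("g3", "g4", "g8"))
  expr <- attr(cg$catalog, "lump_map")[[lump]]
  # lump expression is (g5 & g9) | g7 with re-attributed cost 2
  expect_setequal(lapply(expr, identity), list(c("g5", "g9"), "g7"))
  expect_equal(cg$catalog$cost[cg$catalog$gene_id == lump], 2)
  expect_setequal(cg$protected, c("g1", "g2", "g6"))
})

test_that("compression is idempotent and the identity on flat rulesets", {
  b <- example_gene_mcs()
  ess <- find_essential(b$model, b$desireds)
  cg1 <- compress_gpr(fig_rules(), attr(b$model, "genes"),
                      essential_rxns = ess)
  cg2 <- compress_gpr(cg1$rules, cg1$catalog, essential_rxns = ess)
  expect_equal(cg1$rules, cg2$rules)
  # flat single-gene rules, nothing blocked or essential: unchanged
  flat <- list(a = parse_gpr("gx"), b = parse_gpr("gy"))
  cat0 <- gene_catalog(tibble::tibble(gene_id = c("gx", "gy")))
  cg <- compress_gpr(flat, cat0)
  expect_equal(cg$rules, flat)
})

test_that("gene-deletion semantics are preserved by compression", {
  # for every reaction and every deletion set up to size 3, the compressed
  # rule (lumps substituted by their expressions) blocks the reaction iff the
  # original rule does
  set.seed(23)
  genes <- paste0("g", 1:6)
  for (rep in 1:10) {
    rules <- list()
    for (rid in paste0("r", 1:4)) {
      conj <- lapply(seq_len(sample(1:2, 1)), function(i)
        sample(genes, sample(1:2, 1)))
      rules[[rid]] <- structure(cutsets:::minimize_dnf(conj), class = "gpr_rule")
    }
    catalog <- gene_catalog(tibble::tibble(gene_id = genes))
    cg <- compress_gpr(rules, catalog)
    lump_map <- attr(cg$catalog, "lump_map")
    resolve_rule <- function(rule) {
      structure(cutsets:::minimize_dnf(do.call(c, lapply(rule, function(cj)
        Reduce(cutsets:::and_dnf,
               lapply(cj, cutsets:::resolve_gene, lump_map = lump_map))))),
        class = "gpr_rule")
    }
    for (size in 0:3) {
      for (del in utils::combn(genes, size, simplify = FALSE)) {
        for (rid in names(rules)) {
          orig <- eval_gpr(rules[[rid]], deleted = del)
          comp <- if (rid %in% names(cg$rules))
            eval_gpr(resolve_rule(cg$rules[[rid]]), deleted = del)
          else TRUE  # rule dropped => not blockable by gene deletions
          expect_equal(comp, orig, info = paste(rid, paste(del, collapse = ",")))
        }
      }
    }
  }
})

test_that("lump cost equals the cheapest falsifying deletion set", {
  expr <- parse_gpr("(g5 and g9) or g7")
  sets <- min_falsifying_sets(expr)
  expect_setequal(lapply(sets, identity),
                  list(c("g5", "g7"), c("g7", "g9")))
  costs <- c(g5 = 1, g7 = 1, g9 = 1)
  expect_equal(cutsets:::min_falsify_cost(expr, costs), 2)
  # weighted costs pick the cheaper set
  costs2 <- c(g5 = 10, g7 = 1, g9 = 2)
  expect_equal(cutsets:::min_falsify_cost(expr, costs2), 3)
  # an AND lump is falsified by any single member
  expect_equal(cutsets:::min_falsify_cost(parse_gpr("g1 and g2"),
                                          c(g1 = 3, g2 = 5)), 3)
})
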