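#' Integrate GPR rules into the network structure
#'
#' Encodes gene associations as pseudo-metabolites and pseudo-reactions so
#' that gene interventions become reaction interventions, using the
#' enzyme-pool representation that preserves the original flux ranges:
#'
#' * every GPR-bearing reaction direction consumes one unit of its own
#'   reaction-specific pool metabolite `Q`;
#' * each conjunction (enzyme or subunit complex) of the rule becomes one
#'   pool-filling reaction `p` that converts the gene-product species `E` of
#'   all its member genes into `Q`;
#' * each gene becomes one unbounded, irreversible synthesis reaction
#'   producing its `E` species (one species per gene product; a promiscuous
#'   gene product feeds the pool reactions of several reactions).
#'
#' Since every reaction keeps its single flux variable and bounds (reversible
#' reactions are split into forward/backward directions whose bounds map from
#' the original), the feasible projection onto the original reactions is
#' unchanged — no flux inflation through isoenzyme copies.
#'
#' Reactions with a rule become non-targetable (their genes carry the
#' targetability); gene synthesis reactions take cost and status from the
#' gene catalog; pool reactions are non-targetable with zero cost.
#'
#' @param model a [metabolic_model()].
#' @param rules named list of `gpr_rule`s; defaults to parsing the model's
#'   `gpr` column.
#' @param catalog a [gene_catalog()]; defaults to the model's catalog.
#' @return list with the extended `model` and `extension`, a list holding
#'   `split_map` (original id -> c(forward, backward)), `gene_rxns` (gene id
#'   -> synthesis reaction id), `pool_rxns`, and `col_map` (extended id ->
#'   named weights over original ids, for rewriting regions).
#' @export
integrate_gpr <- function(model, rules = NULL, catalog = NULL) {
  if (is.null(rules)) {
    rules <- lapply(model$gpr, parse_gpr)
    names(rules) <- model$reaction_id
    rules <- rules[lengths(rules) > 0L]
  }
  catalog <- catalog %||% attr(model, "genes")
  unknown <- setdiff(names(rules), model$reaction_id)
  if (length(unknown))
    stop("rules refer to unknown reaction(s): ", paste(unknown, collapse = ", "))
  gstat <- stats::setNames(catalog$status, catalog$gene_id)
  gcost <- stats::setNames(catalog$cost, catalog$gene_id)
  miss <- setdiff(rule_genes(rules), catalog$gene_id)
  if (length(miss)) { gstat[miss] <- "deletable"; gcost[miss] <- 1 }

  rows <- list()
  split_map <- list()
  gene_rxns <- character(0)
  pool_rxns <- character(0)
  col_map <- list()
  gene_products <- list()  # gene -> E species it must produce

  add_row <- function(id, eq, lb, ub, cost, status) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      reaction_id = id, equation = eq, lb = lb, ub = ub, gpr = "",
      cost = cost, status = status)
  }

  for (i in seq_len(nrow(model))) {
    rid <- model$reaction_id[i]
    rule <- rules[[rid]]
    if (is.null(rule) || length(rule) == 0L) {
      add_row(rid, model$equation[i], model$lb[i], model$ub[i],
              model$cost[i], model$status[i])
      col_map[[rid]] <- stats::setNames(1, rid)
      next
    }
    if (model$status[i] == "addable")
      stop("reaction '", rid, "' is addable and carries a GPR rule; express ",
           "addability on its genes instead")
    coef <- parse_equation(model$equation[i])
    dirs <- if (model$lb[i] < 0) {
      split_map[[rid]] <- c(forward = paste0(rid, "__fwd"),
                            backward = paste0(rid, "__rev"))
      list(list(id = paste0(rid, "__fwd"), coef = coef,
                lb = 0, ub = max(model$ub[i], 0)),
           list(id = paste0(rid, "__rev"), coef = -coef,
                lb = 0, ub = -model$lb[i]))
    } else {
      list(list(id = rid, coef = coef, lb = model$lb[i], ub = model$ub[i]))
    }
    for (d in dirs) {
      qmet <- paste0("Q__", d$id)
      dcoef <- c(d$coef, stats::setNames(-1, qmet))
      add_row(d$id, format_equation(dcoef), d$lb, d$ub, 0, "non_targetable")
      for (k in seq_along(rule)) {
        cj <- rule[[k]]
        pid <- paste0("p__", d$id, "__", k)
        pool_rxns <- c(pool_rxns, pid)
        pcoef <- c(stats::setNames(rep(-1, length(cj)), paste0("E__", cj)),
                   stats::setNames(1, qmet))
        add_row(pid, format_equation(pcoef), 0, Inf, 0, "non_targetable")
        for (g in cj)
          gene_products[[g]] <- union(gene_products[[g]], paste0("E__", g))
      }
    }
    if (model$lb[i] < 0) {
      col_map[[paste0(rid, "__fwd")]] <- stats::setNames(1, rid)
      col_map[[paste0(rid, "__rev")]] <- stats::setNames(-1, rid)
    } else {
      col_map[[rid]] <- stats::setNames(1, rid)
    }
  }
  for (g in names(gene_products)) {
    gid <- paste0("g__", g)
    if (gid %in% model$reaction_id)
      stop("gene synthesis reaction id collides with a reaction id: ", gid)
    gene_rxns[g] <- gid
    gcoef <- stats::setNames(rep(1, length(gene_products[[g]])), gene_products[[g]])
    add_row(gid, format_equation(gcoef), 0, Inf, gcost[[g]],
            if (gstat[[g]] == "protected") "non_targetable" else gstat[[g]])
    col_map[[gid]] <- stats::setNames(numeric(0), character(0))
  }
  for (p in pool_rxns) col_map[[p]] <- stats::setNames(numeric(0), character(0))

  ext_model <- metabolic_model(dplyr::bind_rows(rows), genes = catalog)
  list(model = ext_model,
       extension = list(split_map = split_map, gene_rxns = gene_rxns,
                        pool_rxns = pool_rxns, col_map = col_map))
}

# rewrite a region over original reactions onto the extended reaction basis
region_to_extended <- function(region, ext_model, extension) {
  # invert col_map: extended column coefficient = sum over original ids it
  # represents; for split pairs the net flux is fwd - rev
  remap_region(region, ext_model$reaction_id, extension$col_map)
}

#' Map gene-level interventions to reaction deletions via GPR rules
#'
#' Evaluates each rule under the given gene deletions and returns the ids of
#' reactions whose rule is falsified. Used by the exhaustive oracle, which
#' works on the original (non-integrated) network.
#'
#' @param rules named list of `gpr_rule`s.
#' @param deleted_genes character vector of deleted genes.
#' @return character vector of blocked reaction ids.
#' @export
blocked_by_gene_deletion <- function(rules, deleted_genes) {
  names(rules)[!vapply(rules, eval_gpr, TRUE, deleted = deleted_genes)]
}
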