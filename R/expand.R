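#' Expand cut sets from the compressed-reaction level to the reaction level
#'
#' A deletion of a lumped reaction blocks the whole coupled chain, so it is
#' realized by deleting any one *targetable* member; each combination of
#' member choices yields one expansion. Costs are recomputed from the
#' original member costs, so at least one expansion attains the compressed
#' cost and none is cheaper.
#'
#' @param cs a [cutset()] at `compressed_reaction` level.
#' @param record a `compression_record` from [compress_network()].
#' @return list of [cutset()]s at `reaction` level (duplicates removed).
#' @export
expand_reaction_lumps <- function(cs, record) {
  choice_sets <- lapply(cs$deletions, function(id) {
    lump <- record$lumps[[id]]
    if (is.null(lump)) return(id)
    cands <- lump$member[lump$status == "deletable"]
    if (length(cands) == 0L)
      stop("lump '", id, "' is in a deletion role but has no targetable member")
    cands
  })
  combos <- if (length(choice_sets)) expand.grid(choice_sets,
                                                 stringsAsFactors = FALSE)
            else data.frame(row.names = 1)
  out <- list()
  for (i in seq_len(nrow(combos))) {
    dels <- unique(unlist(combos[i, ], use.names = FALSE))
    cost <- sum(record$orig_cost[dels]) + sum(record$orig_cost[cs$additions])
    out[[length(out) + 1L]] <- cutset(dels, cs$additions, cost, "reaction")
  }
  out[!duplicated(vapply(out, cutset_key, ""))]
}

#' Expand cut sets from the reaction level to the gene level
#'
#' Every lumped pseudo-gene in a cut set is replaced by each minimal
#' gene-deletion set falsifying its recorded Boolean expression; choices are
#' combined across lumps, costs recomputed on the union of the resulting
#' genes, expansions exceeding `max_cost` discarded and the rest minimized
#' and deduplicated. Members that are not lumped pseudo-genes (original genes
#' or gene-free reactions such as an oxygen uptake) pass through unchanged.
#'
#' @param cs a [cutset()] whose deletions are gene entities (plus possibly
#'   reaction ids without GPR).
#' @param catalog a [gene_catalog()] carrying the lump expressions.
#' @param max_cost discard expansions above this total cost.
#' @param costs named cost vector covering all member ids (defaults to the
#'   catalog's gene costs).
#' @return list with `expansions` (list of gene-level [cutset()]s) and
#'   `discarded_over_budget` (count).
#' @export
expand_gene_lumps <- function(cs, catalog, max_cost = Inf, costs = NULL) {
  lump_map <- attr(catalog, "lump_map") %||% list()
  costs <- costs %||% stats::setNames(catalog$cost, catalog$gene_id)
  choice_sets <- lapply(cs$deletions, function(id) {
    expr <- lump_map[[id]]
    if (is.null(expr)) return(list(id))
    min_falsifying_sets(expr)
  })
  grid <- if (length(choice_sets)) do.call(expand.grid, c(
    lapply(choice_sets, seq_along), list(stringsAsFactors = FALSE)))
  else data.frame(row.names = 1)
  out <- list(); discarded <- 0L
  for (i in seq_len(nrow(grid))) {
    dels <- unique(unlist(lapply(seq_along(choice_sets), function(k)
      choice_sets[[k]][[grid[i, k]]]), use.names = FALSE))
    cost <- sum(costs[dels]) + sum(costs[cs$additions])
    if (cost > max_cost + 1e-9) { discarded <- discarded + 1L; next }
    out[[length(out) + 1L]] <- cutset(dels, cs$additions, cost, "gene")
  }
  out <- out[!duplicated(vapply(out, cutset_key, ""))]
  list(expansions = filter_redundant(out), discarded_over_budget = discarded)
}

#' Filter redundant (superset) cut sets
#'
#' Removes every cut set that is a strict superset of another in the list
#' (on deletions and additions jointly). With zero-cost interventions the
#' MILP can report equal-cost sets differing only by free members; filtering
#' keeps the support-minimal representatives. Output is stably ordered by
#' (cost, cardinality, members).
#'
#' @param sets list of [cutset()]s at one level.
#' @return filtered, sorted list.
#' @export
filter_redundant <- function(sets) {
  if (length(sets) <= 1L) return(sort_cutsets(sets))
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) {
    if (!keep[i]) next
    for (j in seq_along(sets)) {
      if (i == j || !keep[j]) next
      sub_del <- all(sets[[i]]$deletions %in% sets[[j]]$deletions)
      sub_add <- all(sets[[i]]$additions %in% sets[[j]]$additions)
      strictly <- length(cutset_members(sets[[i]])) < length(cutset_members(sets[[j]]))
      if (sub_del && sub_add && strictly) keep[j] <- FALSE
    }
  }
  sort_cutsets(sets[keep])
}
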