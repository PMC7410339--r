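#' Compute minimal cut sets (full pipeline)
#'
#' Runs the complete intervention-design workflow on a model with one or
#' more target (undesired) and desired regions:
#'
#' 1. FVA of the full model (blocked reactions) and of each desired region
#'    (essential reactions);
#' 2. GPR rule compression (when the model carries gene associations);
#' 3. integration of the (compressed) rules as enzyme-pool pseudo-reactions;
#' 4. network compression (blocked reactions, conservation relations,
#'    lumping of coupled reactions, protection of essential reactions);
#' 5. cut-set enumeration with the duality MILP;
#' 6. decompression of lumped reactions;
#' 7. decompression of lumped genes.
#'
#' With `gene_level = FALSE` (or a model without GPR rules) steps 2, 3 and 7
#' are skipped and classical reaction cut sets are returned. Both
#' compressions and the superset filter can be toggled; results are
#' identical either way (compression is lossless), only runtime differs.
#'
#' @param model a [metabolic_model()].
#' @param targets,desireds [flux_region()]s (single or list). Desireds may
#'   be empty, e.g. for synthetic-lethal enumeration.
#' @param max_cost enumerate cut sets up to this total intervention cost.
#' @param max_solutions stop after this many solutions (compressed level).
#' @param mode MILP search mode, see [enumerate_mcs()].
#' @param gene_level compute gene-based cut sets? Default: automatic (TRUE
#'   iff the model has GPR rules).
#' @param gpr_compression,network_compression,filter_supersets pipeline
#'   toggles (all default on).
#' @param M,flux_M MILP constants, see [build_milp()].
#' @param paranoid re-verify every expanded solution with the LP oracle on
#'   the uncompressed network (slower; expansion is provably sound when the
#'   compression invariants hold, so this is off by default).
#' @return an `mcs_result`: solutions plus per-step counts. Use [tidy()] for
#'   the solution table, [glance()] for the counts.
#' @export
compute_mcs <- function(model, targets, desireds = list(), max_cost = Inf,
                        max_solutions = Inf,
                        mode = c("optimal_order", "any_feasible"),
                        gene_level = NULL, gpr_compression = TRUE,
                        network_compression = TRUE, filter_supersets = TRUE,
                        M = 1000, flux_M = 1000, paranoid = FALSE) {
  mode <- match.arg(mode)
  if (inherits(targets, "flux_region")) targets <- list(targets)
  if (inherits(desireds, "flux_region")) desireds <- list(desireds)
  rules_orig <- lapply(model$gpr, parse_gpr)
  names(rules_orig) <- model$reaction_id
  rules_orig <- rules_orig[lengths(rules_orig) > 0L]
  if (is.null(gene_level)) gene_level <- length(rules_orig) > 0L
  catalog0 <- attr(model, "genes") %||% gene_catalog(tibble::tibble(gene_id = character(0)))
  counts <- list(n_reactions = nrow(model),
                 n_species = nrow(stoich_matrix(model)),
                 n_genes = nrow(catalog0),
                 n_rules = length(rules_orig))

  # (1) FVA: blocked + essential
  blocked <- find_blocked(model)
  essential <- if (length(desireds)) find_essential(model, desireds) else character(0)
  counts$n_blocked <- length(blocked)
  counts$n_essential <- length(essential)

  # (2) GPR compression, (3) integration
  catalog <- catalog0
  work_model <- model
  work_targets <- targets
  work_desireds <- desireds
  extension <- NULL
  if (gene_level && length(rules_orig)) {
    rules <- rules_orig
    if (gpr_compression) {
      cg <- compress_gpr(rules, catalog, blocked, essential)
      rules <- cg$rules
      catalog <- cg$catalog
    }
    counts$n_genes_compressed <- length(rule_genes(rules))
    counts$n_rules_compressed <- length(rules)
    intg <- integrate_gpr(model, rules, catalog)
    work_model <- intg$model
    extension <- intg$extension
    work_targets <- lapply(targets, region_to_extended, ext_model = work_model,
                           extension = extension)
    work_desireds <- lapply(desireds, region_to_extended, ext_model = work_model,
                            extension = extension)
  }
  counts$n_reactions_integrated <- nrow(work_model)
  counts$n_species_integrated <- nrow(stoich_matrix(work_model))

  # protect essential reactions (they can never be part of a sound cut set)
  ess_here <- intersect(essential, work_model$reaction_id)
  work_model$status[work_model$reaction_id %in% ess_here &
                      work_model$status == "deletable"] <- "non_targetable"

  # (4) network compression
  record <- NULL
  comp_model <- work_model
  comp_targets <- work_targets
  comp_desireds <- work_desireds
  if (network_compression) {
    cn <- compress_network(work_model,
                           blocked = if (gene_level && length(rules_orig)) NULL else blocked)
    comp_model <- cn$model
    record <- cn$record
    comp_targets <- lapply(work_targets, region_to_compressed, comp_model, record)
    comp_desireds <- lapply(work_desireds, region_to_compressed, comp_model, record)
  }
  counts$n_reactions_compressed <- nrow(comp_model)
  counts$n_species_compressed <- nrow(stoich_matrix(comp_model))
  counts$n_targetable <- sum(comp_model$status %in% c("deletable", "addable"))

  # (5) MILP enumeration; with nothing targetable the solution set is empty
  # unless the targets are already blocked in the wild type
  if (!any(comp_model$status %in% c("deletable", "addable"))) {
    wt_blocked <- all(vapply(comp_targets, function(tg)
      !region_feasible(comp_model, tg)$feasible, TRUE))
    counts$n_targetable <- 0L
    counts$n_mcs_compressed <- as.integer(wt_blocked)
    counts$n_mcs_reaction <- counts$n_mcs_compressed
    counts$n_mcs <- counts$n_mcs_compressed
    counts$n_discarded_over_budget <- 0L
    sols <- if (wt_blocked) list(cutset(cost = 0, level = "reaction")) else list()
    return(structure(list(
      solutions = sols, counts = counts, compressed_solutions = sols,
      record = record, catalog = catalog,
      settings = list(max_cost = max_cost, max_solutions = max_solutions,
                      mode = mode, gene_level = gene_level,
                      gpr_compression = gpr_compression,
                      network_compression = network_compression,
                      filter_supersets = filter_supersets, M = M,
                      flux_M = flux_M)),
      class = "mcs_result"))
  }
  milp <- build_milp(comp_model, comp_targets, comp_desireds,
                     max_cost = max_cost, M = M, flux_M = flux_M)
  level5 <- if (network_compression) "compressed_reaction" else "reaction"
  compressed_sets <- enumerate_mcs(milp, max_cost = max_cost,
                                   max_solutions = max_solutions,
                                   mode = mode, level = level5)
  counts$n_mcs_compressed <- length(compressed_sets)

  # (6) decompression of lumped reactions
  if (network_compression && !is.null(record)) {
    rx_sets <- do.call(c, lapply(compressed_sets, expand_reaction_lumps,
                                 record = record)) %||% list()
    rx_sets <- rx_sets[!duplicated(vapply(rx_sets, cutset_key, ""))]
    if (paranoid) {
      ok <- vapply(rx_sets, function(cs)
        verify_cutset(work_model, work_targets, work_desireds, cs), TRUE)
      if (!all(ok)) stop("expanded reaction-level solution failed verification")
    }
  } else {
    rx_sets <- compressed_sets
  }
  rx_sets <- if (filter_supersets) filter_redundant(rx_sets) else sort_cutsets(rx_sets)
  counts$n_mcs_reaction <- length(rx_sets)

  # (7) decompression of lumped genes
  discarded <- 0L
  if (gene_level && length(rules_orig)) {
    gene_rxn_ids <- unname(extension$gene_rxns)
    to_entity <- stats::setNames(as.character(names(extension$gene_rxns)),
                                 gene_rxn_ids)
    costs <- c(stats::setNames(catalog$cost, catalog$gene_id),
               stats::setNames(model$cost, model$reaction_id))
    final <- list()
    for (cs in rx_sets) {
      dels <- ifelse(cs$deletions %in% gene_rxn_ids,
                     to_entity[cs$deletions], cs$deletions)
      adds <- ifelse(cs$additions %in% gene_rxn_ids,
                     to_entity[cs$additions], cs$additions)
      gcs <- cutset(unname(dels), unname(adds), cs$cost, "gene")
      ex <- expand_gene_lumps(gcs, catalog, max_cost = max_cost, costs = costs)
      discarded <- discarded + ex$discarded_over_budget
      final <- c(final, ex$expansions)
    }
    final <- final[!duplicated(vapply(final, cutset_key, ""))]
    if (paranoid) {
      ok <- vapply(final, function(cs) {
        gene_dels <- intersect(cs$deletions, catalog0$gene_id)
        rxn_dels <- setdiff(cs$deletions, gene_dels)
        off <- union(rxn_dels, blocked_by_gene_deletion(rules_orig, gene_dels))
        all(vapply(targets, function(tg)
          !region_feasible(model, tg, off, cs$additions)$feasible, TRUE)) &&
          all(vapply(desireds, function(dg)
            region_feasible(model, dg, off, cs$additions)$feasible, TRUE))
      }, TRUE)
      if (!all(ok)) stop("expanded gene-level solution failed verification")
    }
    solutions <- if (filter_supersets) filter_redundant(final) else sort_cutsets(final)
  } else {
    solutions <- rx_sets
  }
  counts$n_mcs <- length(solutions)
  counts$n_discarded_over_budget <- discarded

  structure(list(
    solutions = solutions,
    counts = counts,
    compressed_solutions = compressed_sets,
    record = record,
    catalog = catalog,
    settings = list(max_cost = max_cost, max_solutions = max_solutions,
                    mode = mode, gene_level = gene_level,
                    gpr_compression = gpr_compression,
                    network_compression = network_compression,
                    filter_supersets = filter_supersets, M = M,
                    flux_M = flux_M)),
    class = "mcs_result")
}

#' @export
print.mcs_result <- function(x, ...) {
  cat(sprintf("# %d minimal cut set(s)", x$counts$n_mcs))
  if (!is.null(x$counts$n_mcs_compressed))
    cat(sprintf(" (%d at the compressed level)", x$counts$n_mcs_compressed))
  cat("\n")
  if (x$counts$n_mcs > 0) print(cutset_table(x$solutions))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the solutions of a cut-set computation
#'
#' @param x an `mcs_result`.
#' @param ... unused.
#' @return tibble with one row per cut set (`rank`, `cost`, `size`,
#'   `deletions`, `additions`, `level`).
#' @export
tidy.mcs_result <- function(x, ...) cutset_table(x$solutions)

#' One-row summary of a cut-set computation
#'
#' @param x an `mcs_result`.
#' @param ... unused.
#' @return one-row tibble with problem-size and solution counts mirroring
#'   the pipeline stages.
#' @export
glance.mcs_result <- function(x, ...) {
  cnt <- x$counts
  tibble::as_tibble(cnt[!vapply(cnt, is.null, TRUE)])
}

#' Plot the cost/size distribution of the found cut sets
#'
#' @param object an `mcs_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mcs_result <- function(object, ...) {
  tb <- cutset_table(object$solutions)
  ggplot2::ggplot(tb, ggplot2::aes(x = factor(.data$cost),
                                   fill = factor(.data$size))) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "intervention cost", y = "number of minimal cut sets",
                  fill = "interventions") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot FVA flux ranges
#'
#' @param fva_tbl result of [fva()].
#' @param cap finite display cap for unbounded ranges.
#' @return a ggplot with one range per reaction.
#' @export
plot_fva_ranges <- function(fva_tbl, cap = 100) {
  tb <- dplyr::mutate(fva_tbl,
                      min = pmax(.data$min, -cap), max = pmin(.data$max, cap))
  ggplot2::ggplot(tb, ggplot2::aes(y = .data$reaction_id)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$min, xend = .data$max,
                                       yend = .data$reaction_id,
                                       colour = .data$blocked),
                          linewidth = 2) +
    ggplot2::labs(x = "attainable flux", y = NULL, colour = "blocked") +
    ggplot2::theme_minimal()
}

#' Verify cut sets against a model and regions
#'
#' Re-runs the LP oracle for each cut set and reports whether it is sound
#' (all targets infeasible, all desireds feasible) and minimal (every single-
#' member removal breaks soundness). Gene members are applied through the
#' model's GPR rules.
#'
#' @param model a [metabolic_model()].
#' @param targets,desireds [flux_region()]s.
#' @param sets list of [cutset()]s, or a data frame in the format written by
#'   [write_cutsets()].
#' @return tibble with `deletions`, `additions`, `sound`, `minimal`.
#' @export
verify_mcs <- function(model, targets, desireds, sets) {
  if (inherits(targets, "flux_region")) targets <- list(targets)
  if (inherits(desireds, "flux_region")) desireds <- list(desireds)
  if (is.data.frame(sets)) {
    split_ids <- function(s) if (is.na(s) || s == "") character(0)
                             else strsplit(s, ",")[[1]]
    sets <- lapply(seq_len(nrow(sets)), function(i)
      cutset(split_ids(sets$deletions[i]), split_ids(sets$additions[i]),
             level = if ("level" %in% names(sets)) sets$level[i] else "reaction"))
  }
  rules <- lapply(model$gpr, parse_gpr)
  names(rules) <- model$reaction_id
  rules <- rules[lengths(rules) > 0L]
  catalog <- attr(model, "genes")
  known <- c(model$reaction_id, catalog$gene_id)
  sound1 <- function(dels, adds) {
    unknown <- setdiff(c(dels, adds), known)
    if (length(unknown)) stop("unknown id(s): ", paste(unknown, collapse = ", "))
    gene_dels <- intersect(dels, catalog$gene_id)
    off <- union(setdiff(dels, gene_dels),
                 blocked_by_gene_deletion(rules, gene_dels))
    all(vapply(targets, function(tg)
      !region_feasible(model, tg, off, adds)$feasible, TRUE)) &&
      all(vapply(desireds, function(dg)
        region_feasible(model, dg, off, adds)$feasible, TRUE))
  }
  res <- lapply(sets, function(cs) {
    s <- sound1(cs$deletions, cs$additions)
    members <- cutset_members(cs)
    minimal <- s && all(vapply(members, function(mb)
      !sound1(setdiff(cs$deletions, mb), setdiff(cs$additions, mb)), TRUE))
    tibble::tibble(
      deletions = paste(cs$deletions, collapse = ","),
      additions = paste(cs$additions, collapse = ","),
      sound = s, minimal = minimal)
  })
  dplyr::bind_rows(res) %||%
    tibble::tibble(deletions = character(0), additions = character(0),
                   sound = logical(0), minimal = logical(0))
}

#' @importFrom rlang .data
NULL
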