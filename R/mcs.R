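#' Cut sets
#'
#' A cut set is one intervention set: reaction/gene `deletions` plus
#' `additions`, with its total `cost` under the active intervention costs and
#' the `level` it lives at (`"compressed_reaction"`, `"reaction"` or
#' `"gene"`).
#'
#' @param deletions,additions character vectors of unit ids (disjoint).
#' @param cost total intervention cost.
#' @param level one of `"compressed_reaction"`, `"reaction"`, `"gene"`.
#' @return object of class `cutset`.
#' @export
cutset <- function(deletions = character(), additions = character(),
                   cost = NA_real_, level = "reaction") {
  if (length(intersect(deletions, additions)))
    stop("deletions and additions overlap")
  structure(list(deletions = sort(unique(deletions)),
                 additions = sort(unique(additions)),
                 cost = cost, level = level),
            class = "cutset")
}

#' @export
print.cutset <- function(x, ...) {
  del <- if (length(x$deletions)) paste0("-", x$deletions) else character(0)
  add <- if (length(x$additions)) paste0("+", x$additions) else character(0)
  cat(sprintf("<cutset cost=%g level=%s> {%s}\n", x$cost, x$level,
              paste(c(del, add), collapse = ", ")))
  invisible(x)
}

#' @export
format.cutset <- function(x, ...) {
  paste(c(paste0("-", x$deletions),
          if (length(x$additions)) paste0("+", x$additions)), collapse = ",")
}

cutset_key <- function(cs)
  paste(paste(cs$deletions, collapse = ","), "|",
        paste(cs$additions, collapse = ","))

cutset_members <- function(cs) c(cs$deletions, cs$additions)

#' Verify a cut set against the LP oracle
#'
#' A cut set is *sound* iff every target region becomes LP-infeasible and
#' every desired region stays LP-feasible under the intervention. This check
#' is independent of the MILP and is applied to every reported solution.
#'
#' @param model a [metabolic_model()].
#' @param targets,desireds lists of [flux_region()]s.
#' @param cs a [cutset()].
#' @return logical.
#' @export
verify_cutset <- function(model, targets, desireds, cs) {
  if (inherits(targets, "flux_region")) targets <- list(targets)
  if (inherits(desireds, "flux_region")) desireds <- list(desireds)
  for (tg in targets)
    if (region_feasible(model, tg, cs$deletions, cs$additions)$feasible)
      return(FALSE)
  for (dg in desireds)
    if (!region_feasible(model, dg, cs$deletions, cs$additions)$feasible)
      return(FALSE)
  TRUE
}

#' Reduce a cut set to a support-minimal one
#'
#' Greedily removes members whose removal keeps the cut set sound (zero-cost
#' members first, so cost-free redundancies such as a superfluous oxygen-
#' uptake deletion are dropped), iterating to a fixed point. The result is a
#' subset of the candidate that no single member can leave without breaking
#' soundness.
#'
#' @inheritParams verify_cutset
#' @param cs a sound [cutset()].
#' @param costs named cost vector for the members (defaults to the model's).
#' @return a support-minimal [cutset()].
#' @export
minimize_within_support <- function(model, targets, desireds, cs, costs = NULL) {
  costs <- costs %||% stats::setNames(model$cost, model$reaction_id)
  repeat {
    members <- c(cs$deletions, cs$additions)
    members <- members[order(costs[members])]  # cheap (free) members first
    dropped <- FALSE
    for (mb in members) {
      cand <- cutset(setdiff(cs$deletions, mb), setdiff(cs$additions, mb),
                     level = cs$level)
      if (verify_cutset(model, targets, desireds, cand)) {
        cs <- cand
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  cs$cost <- sum(costs[c(cs$deletions, cs$additions)])
  cs
}

# extract the intervention set from an integral MILP point
milp_point_to_cutset <- function(milp, x, level = "reaction") {
  on <- milp$units[x[milp$z_cols] > 0.5]
  cutset(deletions = on[milp$unit_type[on] == "del"],
         additions = on[milp$unit_type[on] == "add"],
         cost = sum(milp$cost[on]), level = level)
}

#' Smallest (cheapest) cut set of a MILP
#'
#' Solves the MILP for a minimum-cost intervention set, verifies it against
#' the LP oracle and reduces it to minimal support.
#'
#' @param milp a [build_milp()] problem.
#' @param cost_cap discard solutions costing more than this.
#' @param level level tag for the returned [cutset()].
#' @return a [cutset()], or `NULL` when no solution exists within the cap.
#' @export
solve_smallest <- function(milp, cost_cap = Inf, level = "reaction") {
  res <- solve_milp(milp, cost_cap = cost_cap)
  if (is.null(res$x) || res$cost > cost_cap + 1e-7) return(NULL)
  cs <- milp_point_to_cutset(milp, res$x, level)
  if (!verify_cutset(milp$model, milp$targets, milp$desireds, cs))
    stop("MILP solution failed LP verification; increase the big-M constant ",
         "(M = ", milp$M, ")")
  minimize_within_support(milp$model, milp$targets, milp$desireds, cs)
}

#' Enumerate minimal cut sets via integer cuts
#'
#' Repeatedly solves the MILP, excluding each found solution (and its
#' supersets) with an integer-cut row. In `optimal_order` mode every iterate
#' is cost-minimal, so costs are reported in non-decreasing order and the
#' enumeration up to `max_cost` is complete. In `any_feasible` mode the first
#' incumbent found is accepted and reduced to minimal support before being
#' recorded — a faster way to sample many (not necessarily cheapest) cut
#' sets. Every recorded set passes the LP verification and is
#' support-minimal.
#'
#' @param milp a [build_milp()] problem.
#' @param max_cost enumerate solutions up to this total cost.
#' @param max_solutions stop after this many solutions.
#' @param mode `"optimal_order"` or `"any_feasible"`.
#' @param level level tag for returned [cutset()]s.
#' @return list of [cutset()]s.
#' @export
enumerate_mcs <- function(milp, max_cost = Inf, max_solutions = Inf,
                          mode = c("optimal_order", "any_feasible"),
                          level = "reaction") {
  mode <- match.arg(mode)
  out <- list()
  repeat {
    if (length(out) >= max_solutions) break
    res <- solve_milp(milp, cost_cap = max_cost,
                      first_feasible = mode == "any_feasible")
    if (is.null(res$x) || res$cost > max_cost + 1e-7) break
    cs <- milp_point_to_cutset(milp, res$x, level)
    if (!verify_cutset(milp$model, milp$targets, milp$desireds, cs))
      stop("MILP solution failed LP verification; increase the big-M constant ",
           "(M = ", milp$M, ")")
    cs <- minimize_within_support(milp$model, milp$targets, milp$desireds, cs)
    out[[length(out) + 1L]] <- cs
    members <- cutset_members(cs)
    if (length(members) == 0L) break  # empty cut set: nothing left to exclude
    milp <- add_integer_cut(milp, members)
  }
  sort_cutsets(out)
}

sort_cutsets <- function(sets) {
  if (length(sets) <= 1L) return(sets)
  key <- vapply(sets, cutset_key, "")
  ord <- order(vapply(sets, `[[`, 0, "cost"),
               lengths(lapply(sets, cutset_members)), key)
  sets[ord]
}

#' Tabulate a list of cut sets
#'
#' @param sets list of [cutset()]s.
#' @return tibble with `rank`, `cost`, `size`, `deletions`, `additions`
#'   (comma-joined ids) and `level`.
#' @export
cutset_table <- function(sets) {
  tibble::tibble(
    rank = seq_along(sets),
    cost = vapply(sets, `[[`, 0, "cost"),
    size = lengths(lapply(sets, cutset_members)),
    deletions = vapply(sets, function(s) paste(s$deletions, collapse = ","), ""),
    additions = vapply(sets, function(s) paste(s$additions, collapse = ","), ""),
    level = vapply(sets, `[[`, "", "level"))
}

#' Write cut sets to a TSV file
#'
#' @param sets list of [cutset()]s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cutsets <- function(sets, path) {
  utils::write.table(as.data.frame(cutset_table(sets)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
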