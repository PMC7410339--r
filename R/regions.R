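#' Target and desired flux regions
#'
#' A flux region is a polyhedron of steady-state flux vectors, written as a
#' linear inequality system `V r <= v` over the reaction rates of a model,
#' combined implicitly with the network constraints (steady state, bounds,
#' global extra constraints). Regions play one of two roles in cut-set
#' computation:
#'
#' * **target**: undesired behaviour; every flux vector in the region must be
#'   made infeasible by the interventions. A target region must not contain
#'   the zero flux vector (nothing can eliminate it), which is checked at
#'   construction.
#' * **desired**: wanted behaviour; at least one flux vector of the region
#'   must remain feasible after the interventions.
#'
#' @param model a [metabolic_model()].
#' @param constraints character vector of linear constraints over reaction
#'   ids, e.g. `c("p_ex - 0.4 s_up <= 0", "s_up >= 0.1")`. Supported
#'   operators: `<=`, `>=`, `=`/`==` (an equality becomes two inequalities).
#' @param role `"target"`, `"desired"` or `"constraint"` (the latter for
#'   global extra constraints attached to a model).
#' @param label short name used in messages and outputs.
#' @param check_zero for target regions, verify that the zero flux vector is
#'   excluded (default `TRUE`).
#'
#' @return object of class `flux_region`: a list with the coefficient matrix
#'   `V` (rows x reactions, with column names), right-hand side `v`, `role`
#'   and `label`.
#' @examples
#' m <- metabolic_model(tibble::tribble(
#'   ~reaction_id, ~equation, ~lb, ~ub,
#'   "s_up", "-> S",  0, 10,
#'   "conv", "S -> P", 0, Inf,
#'   "p_ex", "P ->",  0, Inf
#' ))
#' flux_region(m, c("p_ex - 0.4 s_up <= 0", "s_up >= 0.1"), role = "target")
#' @export
flux_region <- function(model, constraints, role = c("target", "desired", "constraint"),
                        label = role, check_zero = TRUE) {
  role <- match.arg(role)
  rxn_ids <- model$reaction_id
  rows <- lapply(constraints, parse_constraint, rxn_ids = rxn_ids)
  V <- do.call(rbind, lapply(rows, `[[`, "coef"))
  v <- unlist(lapply(rows, `[[`, "rhs"), use.names = FALSE)
  colnames(V) <- rxn_ids
  region <- structure(list(V = V, v = v, role = role, label = label),
                      class = "flux_region")
  if (role == "target" && check_zero) assert_zero_excluded(model, region)
  region
}

#' @export
print.flux_region <- function(x, ...) {
  cat(sprintf("# %s region '%s' (%d constraint rows)\n", x$role, x$label,
              nrow(x$V)))
  for (i in seq_len(nrow(x$V))) {
    nz <- which(x$V[i, ] != 0)
    terms <- paste(sprintf("%+g %s", unname(x$V[i, nz]), colnames(x$V)[nz]),
                   collapse = " ")
    cat(" ", terms, "<=", x$v[i], "\n")
  }
  invisible(x)
}

# parse "1 p_ex - 0.4 s_up <= 0" into list(coef = named row vector, rhs)
# (equalities yield two stacked rows)
parse_constraint <- function(txt, rxn_ids) {
  op <- regmatches(txt, regexpr("<=|>=|==|=", txt))
  if (length(op) == 0L) stop("constraint lacks a relational operator: ", txt)
  parts <- strsplit(txt, "<=|>=|==|=")[[1]]
  if (length(parts) != 2L) stop("cannot parse constraint: ", txt)
  rhs <- suppressWarnings(as.numeric(trimws(parts[2])))
  if (is.na(rhs)) stop("right-hand side is not a number: ", txt)
  coef <- parse_lincomb(trimws(parts[1]), rxn_ids, txt)
  if (op == ">=") {
    coef <- -coef; rhs <- -rhs; op <- "<="
  }
  if (op %in% c("=", "==")) {
    return(list(coef = rbind(coef, -coef), rhs = c(rhs, -rhs)))
  }
  list(coef = rbind(coef), rhs = rhs)
}

# linear combination "p_ex - 0.4 s_up + 2*r3" -> full-length coefficient row
parse_lincomb <- function(txt, rxn_ids, ctx = txt) {
  coef <- stats::setNames(numeric(length(rxn_ids)), rxn_ids)
  # normalize signs into term separators
  s <- gsub("-", "+-", txt, fixed = TRUE)
  terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
  terms <- terms[terms != ""]
  for (tm in terms) {
    m <- regmatches(tm, regexec(
      "^(-)?\\s*([0-9]+(?:\\.[0-9]+)?(?:/[0-9]+)?(?:[eE][+-]?[0-9]+)?)?[ *]*([^ *]*)$", tm))[[1]]
    sign <- if (m[2] == "-") -1 else 1
    if (m[4] == "") stop("cannot parse term '", tm, "' in constraint: ", ctx)
    co <- if (m[3] == "") 1 else parse_coef(m[3])
    id <- m[4]
    if (!id %in% rxn_ids) stop("unknown reaction id '", id, "' in constraint: ", ctx)
    coef[id] <- coef[id] + sign * co
  }
  coef
}

# error when the zero flux vector satisfies the region together with the
# network bounds and extra constraints (such a target can never be blocked)
assert_zero_excluded <- function(model, region) {
  tol <- 1e-9
  zero_ok_region <- all(region$v >= -tol)
  zero_ok_bounds <- all(model$lb <= tol & model$ub >= -tol)
  zero_ok_extra <- TRUE
  ec <- attr(model, "extra_constraints")
  if (!is.null(ec)) zero_ok_extra <- all(ec$v >= -tol)
  if (zero_ok_region && zero_ok_bounds && zero_ok_extra)
    stop("target region '", region$label, "' contains the zero flux vector; ",
         "add a row excluding it (e.g. a minimum substrate uptake)")
  invisible(TRUE)
}

# rewrite a region's coefficient matrix onto a new reaction basis via a
# column map: list(new_id -> named numeric of old-id weights)
remap_region <- function(region, new_ids, col_map) {
  V2 <- matrix(0, nrow(region$V), length(new_ids),
               dimnames = list(NULL, new_ids))
  for (nid in new_ids) {
    w <- col_map[[nid]]
    if (is.null(w) || length(w) == 0L) next
    keep <- intersect(names(w), colnames(region$V))
    if (length(keep))
      V2[, nid] <- as.vector(region$V[, keep, drop = FALSE] %*% w[keep])
  }
  structure(list(V = V2, v = region$v, role = region$role, label = region$label),
            class = "flux_region")
}

#' Construct a yield-threshold region
#'
#' Builds the linearized yield constraint commonly used in growth-coupled
#' strain design. For a product P, substrates S_k with weights w_k (e.g.
#' carbon atom counts) and threshold Y, the fractional yield constraint
#' \deqn{r_P / \sum_k w_k r_{S_k} \;\{\le,\ge\}\; Y}
#' is linearized to \deqn{r_P - Y \sum_k w_k r_{S_k} \le 0} (sense `"<="`;
#' negated for `">="`). Additional rows (e.g. a minimum substrate uptake to
#' exclude the zero flux vector from a target region) can be supplied as
#' constraint text.
#'
#' @param model a [metabolic_model()].
#' @param product_rxn reaction id of product formation/export.
#' @param substrate_rxns substrate uptake reaction ids; either a character
#'   vector (unit weights) or a named numeric vector of weights.
#' @param threshold yield threshold Y (finite).
#' @param sense `"<="`: flux vectors *below* the threshold (typical target);
#'   `">="`: above (typical desired).
#' @param extra_rows optional character vector of extra constraints.
#' @inheritParams flux_region
#' @return a [flux_region()].
#' @export
make_yield_region <- function(model, product_rxn, substrate_rxns, threshold,
                              sense = c("<=", ">="), role = c("target", "desired"),
                              extra_rows = character(), label = NULL,
                              check_zero = TRUE) {
  sense <- match.arg(sense); role <- match.arg(role)
  if (!is.finite(threshold)) stop("yield threshold must be finite")
  if (is.character(substrate_rxns))
    substrate_rxns <- stats::setNames(rep(1, length(substrate_rxns)), substrate_rxns)
  if (any(substrate_rxns <= 0)) stop("substrate weights must be positive")
  ids <- c(product_rxn, names(substrate_rxns))
  unknown <- setdiff(ids, model$reaction_id)
  if (length(unknown)) stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  terms <- paste(sprintf("- %.17g %s", threshold * unname(substrate_rxns),
                         names(substrate_rxns)), collapse = " ")
  row <- paste(product_rxn, terms, "<= 0")
  if (sense == ">=") {
    terms <- paste(sprintf("+ %.17g %s", threshold * unname(substrate_rxns),
                           names(substrate_rxns)), collapse = " ")
    row <- paste0("-", product_rxn, " ", terms, " <= 0")
  }
  flux_region(model, c(row, extra_rows), role = role,
              label = label %||% paste0("yield_", role), check_zero = check_zero)
}

#' Construct the two target regions of a co-feeding design
#'
#' When a metabolite U can either be excreted as a by-product or supplied as
#' an (addable) co-substrate, a single yield constraint cannot express the
#' design goal: with the uptake active, the uptake/excretion cycle can
#' inflate the substrate term of the yield, and excretion cannot be banned
#' outright. The standard remedy is a pair of target regions:
#'
#' 1. the single-substrate case — yield over the primary substrate only, with
#'    co-substrate uptake fixed to zero;
#' 2. the co-feeding case — combined yield over both substrates, with
#'    co-substrate excretion fixed to zero.
#'
#' Both regions carry a minimum primary-uptake row that excludes the zero
#' flux vector.
#'
#' @param model a [metabolic_model()].
#' @param product_rxn product export reaction id.
#' @param primary_substrate primary substrate uptake reaction id.
#' @param co_substrate_uptake,co_substrate_export uptake/export reaction ids
#'   of the co-substrate.
#' @param threshold yield threshold defining *undesired* (low-yield) states.
#' @param min_primary_uptake minimum primary substrate uptake rate.
#' @param weights optional named numeric weights for the yield denominator
#'   (defaults to unit weights for both substrates).
#' @return list of two target [flux_region()]s.
#' @export
make_cofeeding_target_pair <- function(model, product_rxn, primary_substrate,
                                       co_substrate_uptake, co_substrate_export,
                                       threshold, min_primary_uptake = 0.1,
                                       weights = NULL) {
  ids <- c(product_rxn, primary_substrate, co_substrate_uptake, co_substrate_export)
  unknown <- setdiff(ids, model$reaction_id)
  if (length(unknown))
    stop("the co-substrate needs both an uptake and an export reaction; ",
         "unknown id(s): ", paste(unknown, collapse = ", "))
  if (is.null(weights))
    weights <- stats::setNames(c(1, 1), c(primary_substrate, co_substrate_uptake))
  ub_up <- model$ub[model$reaction_id == co_substrate_uptake]
  if (ub_up <= 0)
    warning("co-substrate uptake '", co_substrate_uptake,
            "' has a zero upper bound; the co-feeding target region is degenerate")
  min_row <- sprintf("%s >= %.17g", primary_substrate, min_primary_uptake)
  t1 <- make_yield_region(
    model, product_rxn, weights[primary_substrate], threshold, "<=", "target",
    extra_rows = c(min_row, paste(co_substrate_uptake, "= 0")),
    label = "single_substrate")
  t2 <- make_yield_region(
    model, product_rxn, weights, threshold, "<=", "target",
    extra_rows = c(min_row, paste(co_substrate_export, "= 0")),
    label = "co_feeding")
  list(t1, t2)
}

#' LP feasibility of a flux region
#'
#' Solves the linear program over the network constraints (steady state,
#' bounds with interventions applied, global extra constraints) plus the
#' region rows, and reports feasibility with a witness flux vector. This is
#' the ground-truth oracle for cut-set semantics: a cut set is sound iff all
#' target regions are infeasible and all desired regions feasible.
#'
#' @param model a [metabolic_model()].
#' @param region a [flux_region()].
#' @param deletions,additions intervention applied before solving (see
#'   [apply_interventions()]).
#' @return list with `feasible` (logical) and `witness` (named flux vector or
#'   `NULL`).
#' @export
region_feasible <- function(model, region, deletions = character(),
                            additions = character()) {
  if (ncol(region$V) != nrow(model))
    stop("region dimension does not match the model")
  model2 <- apply_interventions(model, deletions, additions)
  A <- rbind(stoich_matrix(model2), region$V)
  rel <- c(rep("==", nrow(A) - nrow(region$V)), rep("<=", nrow(region$V)))
  rhs <- c(rep(0, nrow(A) - nrow(region$V)), region$v)
  ec <- attr(model, "extra_constraints")
  if (!is.null(ec)) {
    A <- rbind(A, ec$V)
    rel <- c(rel, rep("<=", nrow(ec$V)))
    rhs <- c(rhs, ec$v)
  }
  res <- lp_feasible(A, rel, rhs, model2$lb, model2$ub)
  list(feasible = res$feasible,
       witness = if (res$feasible) stats::setNames(res$x, model$reaction_id) else NULL)
}

# target system (T, t): region rows + extra constraints + finite bound rows.
# Pure irreversibility rows (lb = 0) are omitted: the dual handles them via
# the sign structure of v. Addable activation bounds must include zero so the
# absorbed rows stay valid when the reaction is absent.
target_system <- function(model, region) {
  n <- nrow(model)
  Tm <- region$V
  tv <- region$v
  ec <- attr(model, "extra_constraints")
  if (!is.null(ec)) { Tm <- rbind(Tm, ec$V); tv <- c(tv, ec$v) }
  add <- model$status == "addable"
  if (any(add & (model$lb > 0 | model$ub < 0)))
    stop("addable reactions must have activation bounds that include zero: ",
         paste(model$reaction_id[add & (model$lb > 0 | model$ub < 0)], collapse = ", "))
  for (i in seq_len(n)) {
    if (is.finite(model$ub[i])) {
      row <- numeric(n); row[i] <- 1
      Tm <- rbind(Tm, row); tv <- c(tv, model$ub[i])
    }
    if (is.finite(model$lb[i]) && model$lb[i] != 0) {
      row <- numeric(n); row[i] <- -1
      Tm <- rbind(Tm, row); tv <- c(tv, -model$lb[i])
    }
  }
  colnames(Tm) <- model$reaction_id
  rownames(Tm) <- NULL
  list(T = Tm, t = tv)
}

# desired system (D, d): region rows + extra constraints; bounds stay
# separate (they are gated per intervention indicator in the MILP)
desired_system <- function(model, region) {
  D <- region$V; d <- region$v
  ec <- attr(model, "extra_constraints")
  if (!is.null(ec)) { D <- rbind(D, ec$V); d <- c(d, ec$v) }
  rownames(D) <- NULL
  list(D = D, d = d)
}
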