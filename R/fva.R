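#' Flux variability analysis
#'
#' Computes, for every reaction, the attainable flux range under the network
#' constraints, optionally restricted to a flux region. FVA drives two
#' preprocessing steps of cut-set computation: on the plain network it
#' detects *blocked* reactions (range `{0}`), and on each desired region it
#' detects *essential* reactions (range excluding zero).
#'
#' @param model a [metabolic_model()].
#' @param region optional [flux_region()] added to the constraints.
#' @param reactions reaction ids to analyze (default: all).
#' @param tol absolute tolerance used for the `blocked` flag.
#' @param addables `"absent"`: addable reactions carry zero flux (the
#'   wild-type state); `"present"`: they may be active at their stated bounds.
#'   Preprocessing that decides what can *never* carry flux (blocked) or what
#'   *must always* carry flux (essential) has to allow additions, otherwise
#'   addition-based designs are lost.
#' @return tibble with `reaction_id`, `min`, `max`, `blocked`. Unbounded
#'   directions are reported as `-Inf`/`Inf`.
#' @examples
#' m <- metabolic_model(tibble::tribble(
#'   ~reaction_id, ~equation, ~lb, ~ub,
#'   "up",  "-> S",    0, 10,
#'   "conv", "S -> P", 0, Inf,
#'   "ex",  "P ->",    0, Inf
#' ))
#' fva(m)
#' @export
fva <- function(model, region = NULL, reactions = NULL, tol = 1e-6,
                addables = c("absent", "present")) {
  addables <- match.arg(addables)
  S <- stoich_matrix(model)
  A <- S; rel <- rep("==", nrow(S)); rhs <- rep(0, nrow(S))
  ec <- attr(model, "extra_constraints")
  if (!is.null(ec)) { A <- rbind(A, ec$V); rel <- c(rel, rep("<=", nrow(ec$V))); rhs <- c(rhs, ec$v) }
  if (!is.null(region)) {
    A <- rbind(A, region$V); rel <- c(rel, rep("<=", nrow(region$V))); rhs <- c(rhs, region$v)
  }
  n <- nrow(model)
  reactions <- reactions %||% model$reaction_id
  idx <- match(reactions, model$reaction_id)
  if (anyNA(idx)) stop("unknown reaction id(s): ",
                       paste(reactions[is.na(idx)], collapse = ", "))
  lb <- model$lb; ub <- model$ub
  if (addables == "absent") {
    off <- model$status == "addable"
    lb[off] <- 0; ub[off] <- 0
  }

  feas <- lp_feasible(A, rel, rhs, lb, ub)
  if (!feas$feasible)
    stop("FVA system is infeasible",
         if (!is.null(region)) paste0(" under region '", region$label, "'") else "")

  one <- function(i, maximize) {
    obj <- numeric(n); obj[i] <- 1
    res <- lp_solve(obj, A, rel, rhs, lb, ub, maximize = maximize)
    if (res$status == "unbounded") return(if (maximize) Inf else -Inf)
    if (res$status != "optimal") stop("unexpected LP status in FVA: ", res$status)
    res$objval
  }
  lo <- vapply(idx, one, 0, maximize = FALSE)
  hi <- vapply(idx, one, 0, maximize = TRUE)
  tibble::tibble(reaction_id = reactions, min = lo, max = hi,
                 blocked = abs(lo) < tol & abs(hi) < tol)
}

#' Blocked reactions of a model
#'
#' Reactions that cannot carry flux in any steady state of the (wild-type)
#' network; their columns and GPR rules are irrelevant for cut-set
#' computation and are removed during compression.
#'
#' @inheritParams fva
#' @return character vector of reaction ids.
#' @export
find_blocked <- function(model, tol = 1e-6) {
  f <- fva(model, tol = tol, addables = "present")
  f$reaction_id[f$blocked]
}

#' Essential reactions under desired regions
#'
#' A reaction is essential if, for at least one desired region, its FVA
#' interval excludes zero (both endpoints nonzero with the same sign): every
#' flux vector of that region uses the reaction, so no sound intervention set
#' may block it.
#'
#' @param model a [metabolic_model()].
#' @param desired_regions list of desired [flux_region()]s.
#' @param tol tolerance for "nonzero".
#' @return character vector of reaction ids (union over regions).
#' @export
find_essential <- function(model, desired_regions, tol = 1e-6) {
  if (inherits(desired_regions, "flux_region"))
    desired_regions <- list(desired_regions)
  ess <- character(0)
  for (reg in desired_regions) {
    f <- fva(model, region = reg, tol = tol, addables = "present")
    hit <- (f$min > tol & f$max > tol) | (f$min < -tol & f$max < -tol)
    ess <- union(ess, f$reaction_id[hit])
  }
  ess
}
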