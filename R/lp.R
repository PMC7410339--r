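#' Solve a small dense linear program
#'
#' Internal workhorse behind feasibility probes, flux variability analysis and
#' the relaxations of the cut-set MILP. Solves
#' \deqn{\min / \max \; c^\top x \quad \textrm{s.t.}\quad A x \;\{\le,=,\ge\}\; b,
#'   \quad lb \le x \le ub}
#' with a dense two-phase simplex. Bounds may be infinite.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A constraint matrix (m x n); may have zero rows.
#' @param rel character vector of row senses: `"<="`, `"=="`/`"="`, `">="`.
#' @param rhs numeric right-hand sides.
#' @param lb,ub variable bounds; default `-Inf`/`Inf`.
#' @param maximize maximize instead of minimize?
#'
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"maxiter"`), `x` (solution or `NULL`) and `objval`.
#' @keywords internal
lp_solve <- function(obj, A, rel, rhs, lb = rep(-Inf, length(obj)),
                     ub = rep(Inf, length(obj)), maximize = FALSE) {
  n <- length(obj)
  A <- as.matrix(A)
  if (nrow(A) == 0L) A <- matrix(0, 0L, n)
  stopifnot(ncol(A) == n, nrow(A) == length(rel), length(rel) == length(rhs),
            length(lb) == n, length(ub) == n)
  rel_code <- match(rel, c("<=", "==", ">="), nomatch = 0L) - 2L
  rel_code[rel == "="] <- 0L
  if (any(rel_code == -2L & rel != "="))
    stop("unknown relational operator: ", paste(setdiff(rel, c("<=", "==", "=", ">=")), collapse = ", "))
  res <- .lp_solve_cpp(as.numeric(obj), A, as.integer(rel_code), as.numeric(rhs),
                       as.numeric(lb), as.numeric(ub), isTRUE(maximize))
  status <- c("optimal", "infeasible", "unbounded", "maxiter")[res$status + 1L]
  if (status == "maxiter")
    stop("LP solver hit its iteration limit; the system is numerically degenerate")
  list(status = status, x = res$x, objval = res$objval)
}

#' LP feasibility probe
#'
#' @inheritParams lp_solve
#' @return list with logical `feasible` and, when feasible, a witness `x`.
#' @keywords internal
lp_feasible <- function(A, rel, rhs, lb, ub) {
  res <- lp_solve(rep(0, length(lb)), A, rel, rhs, lb, ub)
  list(feasible = res$status == "optimal", x = res$x)
}
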