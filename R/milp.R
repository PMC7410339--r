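#' Build the duality-based cut-set MILP
#'
#' Assembles the mixed-integer program whose feasible points are exactly the
#' intervention sets (reaction/gene deletions and additions) that block every
#' target region while keeping every desired region feasible.
#'
#' **Target blocks (dual).** A target region, with the network's finite flux
#' bounds and global constraints absorbed into its inequality system
#' `T r <= t`, is infeasible iff a Farkas certificate exists:
#' \deqn{N^\top u + v + T^\top w = 0,\qquad t^\top w \le -c,\qquad w \ge 0}
#' with `c = 1`. The per-reaction multiplier `v_i` encodes the intervention
#' state: for a reaction present in the mutant, `v_i = 0` if reversible and
#' `v_i <= 0` if irreversible (the multiplier of its irreversibility
#' constraint); `v_i` is free exactly when the reaction is removed (deleted,
#' or an addable not added), which corresponds to the extra constraint
#' `r_i = 0` in the primal. Each target region contributes one such block;
#' all blocks share the intervention indicators.
#'
#' **Indicator linking.** Binary `z_i` marks an intervention on targetable
#' unit `i`. Sign markers `z_p`/`z_n` gate `v`: `v_i <= M z_{p,i}` and, for
#' reversible reactions only, `-v_i <= M z_{n,i}` (negative `v` never counts
#' for irreversible reactions), with `z_p + z_n <= z_i` for deletable and
#' `z_p + z_n <= 1 - z_i` for addable units. Non-targetable reactions keep
#' `v` fixed to its present-state sign structure.
#'
#' **Desired blocks (primal).** Each desired region contributes an explicit
#' flux vector `r` with `N r = 0`, `D r <= d`, and indicator-gated bounds:
#' `lb(1-z) <= r <= ub(1-z)` for deletable and `z lb <= r <= z ub` for
#' addable units (infinite deletable bounds are replaced by `flux_M`).
#'
#' The objective minimizes the weighted intervention cost `sum p_i z_i`; an
#' optional budget `sum z_i <= max_cuts` bounds the intervention count.
#'
#' @param model a [metabolic_model()]; `status`/`cost` columns define the
#'   intervenable units.
#' @param targets,desireds lists of [flux_region()]s (a single region may be
#'   passed bare). At least one target is required; desireds may be empty
#'   (e.g. synthetic-lethal computation).
#' @param max_cuts optional bound on the number of interventions.
#' @param max_cost optional bound on the total intervention cost.
#' @param M big-M constant linking dual multipliers to indicators. Too small
#'   an M can only hide solutions, never fabricate them (every feasible point
#'   carries explicit certificates and witnesses); solutions are nevertheless
#'   re-verified by LP.
#' @param flux_M cap used to gate deletable reactions with infinite bounds in
#'   desired blocks.
#' @return object of class `cutset_milp`.
#' @export
build_milp <- function(model, targets, desireds = list(), max_cuts = Inf,
                       max_cost = Inf, M = 1000, flux_M = 1000) {
  if (inherits(targets, "flux_region")) targets <- list(targets)
  if (inherits(desireds, "flux_region")) desireds <- list(desireds)
  if (length(targets) == 0L) stop("at least one target region is required")
  for (tg in targets) assert_zero_excluded(model, tg)

  n <- nrow(model)
  S <- stoich_matrix(model)
  m <- nrow(S)
  rxn <- model$reaction_id
  irrev <- model$lb >= 0
  targetable <- model$status %in% c("deletable", "addable")
  if (!any(targetable)) stop("no targetable unit: every reaction is non_targetable")
  units <- rxn[targetable]
  unit_type <- ifelse(model$status[targetable] == "addable", "add", "del")
  names(unit_type) <- units
  p_cost <- stats::setNames(model$cost[targetable], units)
  addable <- model$status == "addable"
  if (any(addable & (!is.finite(model$lb) | !is.finite(model$ub))))
    stop("addable reactions need finite activation bounds: ",
         paste(rxn[addable & (!is.finite(model$lb) | !is.finite(model$ub))],
               collapse = ", "))

  vn <- character(0); lb <- numeric(0); ub <- numeric(0)
  newvars <- function(names, lo, hi) {
    vn <<- c(vn, names)
    lb <<- c(lb, rep_len(lo, length(names)))
    ub <<- c(ub, rep_len(hi, length(names)))
    length(vn) - length(names) + seq_along(names)
  }
  tsys <- lapply(targets, function(tg) target_system(model, tg))
  dsys <- lapply(desireds, function(dg) desired_system(model, dg))

  u_cols <- v_cols <- w_cols <- list()
  for (j in seq_along(targets)) {
    u_cols[[j]] <- newvars(paste0("u", j, "_", rownames(S)), -Inf, Inf)
    vlb <- ifelse(irrev, -Inf, 0)
    vub <- rep(0, n)
    vlb[targetable & !irrev] <- -M
    vub[targetable] <- M
    v_cols[[j]] <- newvars(paste0("v", j, "_", rxn), vlb, vub)
    tj <- length(tsys[[j]]$t)
    w_cols[[j]] <- newvars(paste0("w", j, "_", seq_len(tj)), 0, Inf)
  }
  r_cols <- list()
  for (k in seq_along(desireds)) {
    rlb <- ifelse(targetable, pmin(model$lb, 0), model$lb)
    rub <- ifelse(targetable, pmax(model$ub, 0), model$ub)
    r_cols[[k]] <- newvars(paste0("r", k, "_", rxn), rlb, rub)
  }
  z_cols <- newvars(paste0("z_", units), 0, 1)
  zp_cols <- newvars(paste0("zp_", units), 0, 1)
  zn_cols <- newvars(paste0("zn_", units), 0, 1)
  names(z_cols) <- names(zp_cols) <- names(zn_cols) <- units

  nv <- length(vn)
  rows <- list(); rel <- character(0); rhs <- numeric(0)
  add_rows <- function(mat, relop, b) {
    rows[[length(rows) + 1L]] <<- mat
    rel <<- c(rel, rep(relop, nrow(mat)))
    rhs <<- c(rhs, b)
  }

  for (j in seq_along(targets)) {
    Tm <- tsys[[j]]$T; tv <- tsys[[j]]$t
    # column balance: N^T u + v + T^T w = 0   (one row per reaction)
    bal <- matrix(0, n, nv)
    bal[, u_cols[[j]]] <- t(S)
    bal[cbind(seq_len(n), v_cols[[j]])] <- 1
    bal[, w_cols[[j]]] <- t(Tm)
    add_rows(bal, "==", rep(0, n))
    # infeasibility certificate: t' w <= -1
    cert <- matrix(0, 1, nv)
    cert[1, w_cols[[j]]] <- tv
    add_rows(cert, "<=", -1)
    # indicator linking of this block's v to the shared sign markers
    for (i in which(targetable)) {
      uid <- rxn[i]
      rowp <- matrix(0, 1, nv)
      rowp[1, v_cols[[j]][i]] <- 1
      rowp[1, zp_cols[[uid]]] <- -M
      add_rows(rowp, "<=", 0)
      if (!irrev[i]) {
        rown <- matrix(0, 1, nv)
        rown[1, v_cols[[j]][i]] <- -1
        rown[1, zn_cols[[uid]]] <- -M
        add_rows(rown, "<=", 0)
      }
    }
  }
  # sign-marker budget: zp + zn <= z (deletable), zp + zn <= 1 - z (addable)
  for (uid in units) {
    rowz <- matrix(0, 1, nv)
    rowz[1, zp_cols[[uid]]] <- 1
    rowz[1, zn_cols[[uid]]] <- 1
    if (unit_type[[uid]] == "del") {
      rowz[1, z_cols[[uid]]] <- -1
      add_rows(rowz, "<=", 0)
    } else {
      rowz[1, z_cols[[uid]]] <- 1
      add_rows(rowz, "<=", 1)
    }
  }
  for (k in seq_along(desireds)) {
    Dk <- dsys[[k]]$D; dk <- dsys[[k]]$d
    bal <- matrix(0, m, nv)
    bal[, r_cols[[k]]] <- S
    add_rows(bal, "==", rep(0, m))
    if (nrow(Dk)) {
      dmat <- matrix(0, nrow(Dk), nv)
      dmat[, r_cols[[k]]] <- Dk
      add_rows(dmat, "<=", dk)
    }
    for (i in which(targetable)) {
      uid <- rxn[i]
      rc <- r_cols[[k]][i]
      if (unit_type[[uid]] == "del") {
        ubi <- if (is.finite(model$ub[i])) model$ub[i] else flux_M
        lbi <- if (is.finite(model$lb[i])) model$lb[i] else -flux_M
        if (ubi != 0) {  # r <= ub (1 - z)
          rw <- matrix(0, 1, nv); rw[1, rc] <- 1; rw[1, z_cols[[uid]]] <- ubi
          add_rows(rw, "<=", ubi)
        }
        if (lbi != 0) {  # r >= lb (1 - z)
          rw <- matrix(0, 1, nv); rw[1, rc] <- -1; rw[1, z_cols[[uid]]] <- -lbi
          add_rows(rw, "<=", -lbi)
        }
      } else {  # addable: z lb <= r <= z ub
        rw <- matrix(0, 1, nv); rw[1, rc] <- 1; rw[1, z_cols[[uid]]] <- -model$ub[i]
        add_rows(rw, "<=", 0)
        rw <- matrix(0, 1, nv); rw[1, rc] <- -1; rw[1, z_cols[[uid]]] <- model$lb[i]
        add_rows(rw, "<=", 0)
      }
    }
  }
  if (is.finite(max_cuts)) {
    rw <- matrix(0, 1, nv); rw[1, z_cols] <- 1
    add_rows(rw, "<=", max_cuts)
  }
  if (is.finite(max_cost)) {
    rw <- matrix(0, 1, nv); rw[1, z_cols] <- p_cost[units]
    add_rows(rw, "<=", max_cost)
  }

  obj <- numeric(nv)
  obj[z_cols] <- p_cost[units]
  structure(list(
    A = do.call(rbind, rows), rel = rel, rhs = rhs, lb = lb, ub = ub,
    obj = obj, var_names = vn,
    z_cols = z_cols, zp_cols = zp_cols, zn_cols = zn_cols,
    units = units, unit_type = unit_type, cost = p_cost,
    model = model, targets = targets, desireds = desireds,
    M = M, flux_M = flux_M,
    dim = list(n_vars = nv,
               n_continuous = nv - 3L * length(units),
               n_binary = 3L * length(units),
               block_sizes = list(
                 target = vapply(seq_along(targets),
                                 function(j) m + n + length(tsys[[j]]$t), 0),
                 desired = rep(n, length(desireds))))),
    class = "cutset_milp")
}

#' @export
print.cutset_milp <- function(x, ...) {
  cat(sprintf(paste0("# cut-set MILP: %d variables (%d binary), %d rows; ",
                     "%d target / %d desired region(s), %d targetable units\n"),
              x$dim$n_vars, x$dim$n_binary, nrow(x$A),
              length(x$targets), length(x$desireds), length(x$units)))
  invisible(x)
}

# append an integer cut excluding a found solution and all its supersets
add_integer_cut <- function(milp, unit_ids) {
  rw <- matrix(0, 1, ncol(milp$A))
  rw[1, milp$z_cols[unit_ids]] <- 1
  milp$A <- rbind(milp$A, rw)
  milp$rel <- c(milp$rel, "<=")
  milp$rhs <- c(milp$rhs, length(unit_ids) - 1)
  milp
}

# depth-first branch and bound over the z indicators (z_p/z_n inherit
# integrality from integral z: see the methods vignette)
solve_milp <- function(milp, cost_cap = Inf, first_feasible = FALSE) {
  zc <- milp$z_cols
  eps <- 1e-6
  best <- list(cost = Inf, x = NULL)
  stack <- list(list(fix = integer(0), val = integer(0)))
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    lb <- milp$lb; ub <- milp$ub
    if (length(node$fix)) {
      lb[zc[node$fix]] <- node$val
      ub[zc[node$fix]] <- node$val
    }
    res <- lp_solve(milp$obj, milp$A, milp$rel, milp$rhs, lb, ub)
    if (res$status != "optimal") next
    if (res$objval > min(best$cost, cost_cap) + 1e-7) next
    zv <- res$x[zc]
    frac <- abs(zv - round(zv))
    if (all(frac < eps)) {
      if (res$objval < best$cost - 1e-9) best <- list(cost = res$objval, x = res$x)
      if (first_feasible) return(best)
      next
    }
    b <- which.max(frac)
    near <- as.integer(round(zv[b]))
    # LIFO: push the less promising child first
    stack[[length(stack) + 1L]] <-
      list(fix = c(node$fix, b), val = c(node$val, 1L - near))
    stack[[length(stack) + 1L]] <-
      list(fix = c(node$fix, b), val = c(node$val, near))
  }
  best
}
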