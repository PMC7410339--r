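#' Lossless network compression
#'
#' Shrinks a model before cut-set computation without changing the reachable
#' flux projection or losing any minimal cut set:
#'
#' 1. removal of blocked reactions (and metabolites left unconnected);
#' 2. removal of conservation relations (linearly dependent stoichiometry
#'    rows, detected by exact rational row reduction);
#' 3. iterative lumping of reaction pairs coupled through a metabolite with
#'    exactly one producer and one consumer, scaling the consumer to cancel
#'    the metabolite. Real reactions and GPR pseudo-reactions are lumped
#'    alike. A lump's bounds are the intersection of its members' bounds
#'    mapped through the scaling; its cost is the minimum cost over its
#'    targetable members (deleting any one member blocks the whole coupled
#'    chain) and it is non-targetable only if no member is targetable.
#'
#' All arithmetic is exact rational (inputs rationalized at tolerance 1e-9).
#' Addable reactions are never lumped: absence/presence semantics do not
#' commute with coupling. The returned `record` inverts the mapping: it
#' carries member lists with scaling factors, re-attributed costs, and the
#' column map used to rewrite flux regions onto the compressed basis.
#'
#' @param model a [metabolic_model()].
#' @param protected reaction ids to mark non-targetable before compression
#'   (typically essential reactions).
#' @param blocked precomputed blocked reaction ids; computed by FVA when
#'   `NULL`.
#' @param lump_reactions,remove_conservation toggles for the individual passes.
#' @return list with the compressed `model` and the `record` (class
#'   `compression_record`).
#' @export
compress_network <- function(model, protected = character(), blocked = NULL,
                             lump_reactions = TRUE, remove_conservation = TRUE) {
  if (length(protected))
    model$status[model$reaction_id %in% protected & model$status == "deletable"] <-
      "non_targetable"
  S <- stoich_matrix(model)
  R <- rmat(S)
  ids <- colnames(S)
  mets <- rownames(S)
  # per-column bookkeeping (members carry original cost/status for expansion)
  cols <- lapply(seq_along(ids), function(j) {
    list(members = ids[j], scale = 1,
         cost = model$cost[j], status = model$status[j],
         lb = model$lb[j], ub = model$ub[j])
  })
  names(cols) <- ids
  removed_rxns <- character(0)

  drop_col <- function(j) {
    R$n <<- R$n[, -j, drop = FALSE]; R$d <<- R$d[, -j, drop = FALSE]
    cols[[j]] <<- NULL
  }
  drop_row <- function(k) {
    R$n <<- R$n[-k, , drop = FALSE]; R$d <<- R$d[-k, , drop = FALSE]
  }

  if (is.null(blocked)) blocked <- find_blocked(model)
  if (length(blocked)) {
    keep <- !(names(cols) %in% blocked)
    removed_rxns <- names(cols)[!keep]
    R$n <- R$n[, keep, drop = FALSE]; R$d <- R$d[, keep, drop = FALSE]
    cols <- cols[keep]
  }
  # unconnected metabolite rows
  live <- rowSums(R$n != 0) > 0
  R$n <- R$n[live, , drop = FALSE]; R$d <- R$d[live, , drop = FALSE]

  if (remove_conservation && nrow(R$n) > 1L) {
    dep <- dependent_rows(R)
    if (length(dep)) {
      R$n <- R$n[-dep, , drop = FALSE]; R$d <- R$d[-dep, , drop = FALSE]
    }
  }

  if (lump_reactions) {
    repeat {
      changed <- FALSE
      k <- 1L
      while (k <= nrow(R$n)) {
        nz <- which(R$n[k, ] != 0)
        if (length(nz) == 1L) {
          # dead-end metabolite: the single connected reaction is forced to zero
          j <- nz
          if (cols[[j]]$lb > 1e-12 || cols[[j]]$ub < -1e-12)
            stop("network is infeasible: reaction '",
                 paste(cols[[j]]$members, collapse = "+"),
                 "' is forced nonzero but dead-ended")
          removed_rxns <- c(removed_rxns, cols[[j]]$members)
          drop_col(j); drop_row(k)
          changed <- TRUE
          next
        }
        if (length(nz) == 2L && !isTRUE(R$n[k, nz[1]] * R$n[k, nz[2]] > 0)) {
          i <- nz[which(R$n[k, nz] > 0)]; j <- nz[which(R$n[k, nz] < 0)]
          ci <- cols[[i]]; cj <- cols[[j]]
          if (!any(ci$status == "addable") && !any(cj$status == "addable")) {
            # consumer j runs at s * (flux of i), s = a / (-b) > 0, exactly
            s <- rat_div(R$n[k, i], R$d[k, i], -R$n[k, j], R$d[k, j])
            sval <- s$n / s$d
            lb <- max(ci$lb, cj$lb / sval)
            ub <- min(ci$ub, cj$ub / sval)
            if (lb > ub + 1e-9)
              stop("inconsistent bounds while lumping coupled reactions ",
                   paste(c(ci$members, cj$members), collapse = ", "))
            # column_i <- column_i + s * column_j, rationally
            for (r in seq_len(nrow(R$n))) {
              if (R$n[r, j] == 0) next
              t <- rat_mul(s$n, s$d, R$n[r, j], R$d[r, j])
              a <- rat_add(R$n[r, i], R$d[r, i], t$n, t$d)
              R$n[r, i] <- a$n; R$d[r, i] <- a$d
            }
            cols[[i]] <- list(
              members = c(ci$members, cj$members),
              scale = c(ci$scale, cj$scale * sval),
              cost = c(ci$cost, cj$cost),
              status = c(ci$status, cj$status),
              lb = lb, ub = ub)
            drop_col(j); drop_row(k)
            changed <- TRUE
            next
          }
        }
        k <- k + 1L
      }
      if (!changed) break
    }
  }

  # rebuild the model table; multi-member columns get deterministic lump ids
  lump_counter <- 0L
  out_rows <- vector("list", length(cols))
  lumps <- list()
  col_map <- list()
  for (j in seq_along(cols)) {
    cl <- cols[[j]]
    multi <- length(cl$members) > 1L
    id <- if (multi) {
      lump_counter <- lump_counter + 1L
      paste0("rc_", lump_counter)
    } else cl$members
    coef <- R$n[, j] / R$d[, j]
    names(coef) <- rownames(R$n)
    coef <- coef[coef != 0]
    status <- if (any(cl$status == "deletable")) "deletable"
              else if (any(cl$status == "addable")) "addable"
              else "non_targetable"
    cost <- if (status == "deletable") {
      suppressWarnings(min(cl$cost[cl$status == "deletable"]))
    } else if (length(cl$cost) == 1L) cl$cost else 0
    out_rows[[j]] <- tibble::tibble(
      reaction_id = id,
      equation = format_equation(coef, reversible = cl$lb < 0),
      lb = cl$lb, ub = cl$ub, gpr = "", cost = cost, status = status)
    col_map[[id]] <- stats::setNames(cl$scale, cl$members)
    if (multi)
      lumps[[id]] <- tibble::tibble(member = cl$members, scale = cl$scale,
                                    cost = cl$cost, status = cl$status)
  }
  compressed <- metabolic_model(dplyr::bind_rows(out_rows),
                                genes = attr(model, "genes"))
  ec <- attr(model, "extra_constraints")
  if (!is.null(ec))
    attr(compressed, "extra_constraints") <-
      remap_region(ec, compressed$reaction_id, col_map)
  record <- structure(list(
    lumps = lumps, col_map = col_map,
    removed_reactions = removed_rxns,
    removed_metabolites = setdiff(mets, rownames(R$n)),
    orig_cost = stats::setNames(model$cost, model$reaction_id),
    orig_status = stats::setNames(model$status, model$reaction_id)),
    class = "compression_record")
  list(model = compressed, record = record)
}

#' @export
print.compression_record <- function(x, ...) {
  cat(sprintf("# compression record: %d lumps, %d blocked reactions removed, %d metabolites removed\n",
              length(x$lumps), length(x$removed_reactions),
              length(x$removed_metabolites)))
  invisible(x)
}

#' Serialize a compression record to JSON
#'
#' @param record a `compression_record`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_compression_record <- function(record, path) {
  out <- list(
    lumps = lapply(record$lumps, function(l) as.list(l)),
    removed_reactions = record$removed_reactions,
    removed_metabolites = record$removed_metabolites)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# rewrite a region over the pre-compression basis onto the compressed one
region_to_compressed <- function(region, compressed_model, record) {
  remap_region(region, compressed_model$reaction_id, record$col_map)
}
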