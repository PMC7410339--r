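#' Metabolic model as a reaction table
#'
#' A `metabolic_model` is a tibble with one row per reaction and columns
#' `reaction_id`, `equation`, `lb`, `ub`, `gpr`, `cost`, `status`. The
#' stoichiometric matrix, metabolite set and reversibility are derived from
#' the `equation` and `lb` columns, so the table itself is the single source
#' of truth and round-trips losslessly through the tabular file format.
#'
#' * `equation` uses the dialect `"A + 2 B -> C"`; an empty side denotes an
#'   exchange with the environment (`"-> S"` is an uptake, `"P ->"` an
#'   export). Coefficients may be decimals or fractions (`"7/3 Q"`).
#' * `lb`/`ub` are flux bounds in mmol/gDW/h by convention; `-Inf`/`Inf`
#'   denote unbounded directions. A reaction is irreversible iff `lb >= 0`.
#' * `gpr` holds the Boolean gene association as text (`""` = spontaneous).
#' * `status` is one of `"deletable"`, `"addable"`, `"non_targetable"` and
#'   `cost` is the nonnegative intervention cost (used when the reaction
#'   itself is the intervention unit; gene costs live in the gene catalog,
#'   see [gene_catalog()]).
#'
#' Optional attributes: `genes` (a gene catalog), `extra_constraints`
#' (a constraint table of class `flux_region`, interpreted as global
#' inequalities over the flux vector).
#'
#' @param reactions data frame with at least `reaction_id` and `equation`;
#'   missing columns get defaults (`lb = 0`, `ub = Inf`, `gpr = ""`,
#'   `cost = 1`, `status = "deletable"`).
#' @param genes optional gene catalog (see [gene_catalog()]); built from the
#'   `gpr` column if absent.
#' @param extra_constraints optional global linear constraints, given as
#'   character expressions like `"1 r1 - 0.4 r2 <= 0"`.
#'
#' @return a `metabolic_model` tibble.
#' @examples
#' m <- metabolic_model(tibble::tribble(
#'   ~reaction_id, ~equation,  ~lb, ~ub,
#'   "up",         "-> A",     0,   10,
#'   "conv",       "A -> B",   0,   Inf,
#'   "ex",         "B ->",     0,   Inf
#' ))
#' stoich_matrix(m)
#' @export
metabolic_model <- function(reactions, genes = NULL, extra_constraints = NULL) {
  rx <- tibble::as_tibble(reactions)
  if (!all(c("reaction_id", "equation") %in% names(rx)))
    stop("reactions must have at least 'reaction_id' and 'equation' columns")
  if (!"lb" %in% names(rx)) rx$lb <- 0
  if (!"ub" %in% names(rx)) rx$ub <- Inf
  if (!"gpr" %in% names(rx)) rx$gpr <- ""
  if (!"cost" %in% names(rx)) rx$cost <- 1
  if (!"status" %in% names(rx)) rx$status <- "deletable"
  rx$gpr[is.na(rx$gpr)] <- ""
  rx <- rx[, c("reaction_id", "equation", "lb", "ub", "gpr", "cost", "status")]
  rx$lb <- as.numeric(rx$lb); rx$ub <- as.numeric(rx$ub)
  rx$cost <- as.numeric(rx$cost)

  if (anyDuplicated(rx$reaction_id))
    stop("duplicate reaction ids: ",
         paste(unique(rx$reaction_id[duplicated(rx$reaction_id)]), collapse = ", "))
  if (any(rx$lb > rx$ub))
    stop("lb > ub for reaction(s): ",
         paste(rx$reaction_id[rx$lb > rx$ub], collapse = ", "))
  bad <- setdiff(unique(rx$status), c("deletable", "addable", "non_targetable"))
  if (length(bad)) stop("unknown status value(s): ", paste(bad, collapse = ", "))
  if (any(rx$cost < 0)) stop("intervention costs must be nonnegative")

  # parse now so malformed equations fail at construction
  parsed <- lapply(rx$equation, parse_equation)
  mets <- unique(unlist(lapply(parsed, names), use.names = FALSE))
  if (anyDuplicated(mets)) stop("internal: duplicate metabolites")

  out <- structure(rx, class = c("metabolic_model", class(tibble::tibble())))
  if (is.null(genes)) genes <- infer_gene_catalog(rx$gpr)
  attr(out, "genes") <- genes
  if (!is.null(extra_constraints)) {
    if (is.character(extra_constraints))
      extra_constraints <- flux_region(out, extra_constraints,
                                       role = "constraint", label = "extra")
    attr(out, "extra_constraints") <- extra_constraints
  }
  out
}

# parse "2 A + B -> 0.5 C" into a named numeric vector of net coefficients
parse_equation <- function(eq) {
  if (is.na(eq)) stop("equation is NA")
  arrow <- regmatches(eq, regexpr("<->|<=>|->|=>", eq))
  if (length(arrow) == 0L) stop("equation lacks an arrow ('->' or '<->'): ", eq)
  sides <- strsplit(eq, "<->|<=>|->|=>")[[1]]
  lhs <- if (length(sides) >= 1L) sides[1] else ""
  rhs <- if (length(sides) >= 2L) sides[2] else ""
  coef <- c(parse_side(lhs, -1, eq), parse_side(rhs, +1, eq))
  if (length(coef) == 0L) return(stats::setNames(numeric(0), character(0)))
  tapply_sum <- tapply(coef, names(coef), sum)
  out <- as.numeric(tapply_sum)
  names(out) <- names(tapply_sum)
  out[out != 0]
}

parse_side <- function(side, sign, eq) {
  side <- trimws(side)
  if (side == "") return(stats::setNames(numeric(0), character(0)))
  terms <- trimws(strsplit(side, "\\+")[[1]])
  terms <- terms[terms != ""]
  out <- numeric(0)
  for (tm in terms) {
    m <- regmatches(tm, regexec("^([0-9]+(?:\\.[0-9]+)?(?:/[0-9]+)?)?[ *]*([^ *]+)$", tm))[[1]]
    if (length(m) == 0L || m[3] == "") stop("cannot parse term '", tm, "' in equation: ", eq)
    co <- if (m[2] == "") 1 else parse_coef(m[2])
    out <- c(out, stats::setNames(sign * co, m[3]))
  }
  out
}

parse_coef <- function(s) {
  if (grepl("/", s, fixed = TRUE)) {
    p <- as.numeric(strsplit(s, "/", fixed = TRUE)[[1]])
    p[1] / p[2]
  } else as.numeric(s)
}

# inverse of parse_equation; coefficients rendered as fractions when exact
format_equation <- function(coef, reversible = FALSE) {
  fmt <- function(v, met) {
    if (isTRUE(all.equal(v, 1, tolerance = 1e-12))) return(met)
    fr <- rat_approx(v)
    cs <- if (fr$den == 1) format(fr$num, scientific = FALSE)
          else paste0(fr$num, "/", fr$den)
    paste(cs, met)
  }
  lhs <- names(coef)[coef < 0]
  rhs <- names(coef)[coef > 0]
  l <- paste(vapply(lhs, function(mt) fmt(-coef[[mt]], mt), ""), collapse = " + ")
  r <- paste(vapply(rhs, function(mt) fmt(coef[[mt]], mt), ""), collapse = " + ")
  paste0(l, if (reversible) " <-> " else " -> ", r)
}

#' Stoichiometric matrix of a model
#'
#' @param model a [metabolic_model()].
#' @return numeric matrix, metabolites x reactions, with dimnames.
#' @export
stoich_matrix <- function(model) {
  parsed <- lapply(model$equation, parse_equation)
  mets <- unique(unlist(lapply(parsed, names), use.names = FALSE))
  S <- matrix(0, length(mets), nrow(model),
              dimnames = list(mets, model$reaction_id))
  for (j in seq_along(parsed)) {
    co <- parsed[[j]]
    if (length(co)) S[names(co), j] <- co
  }
  S
}

#' @export
print.metabolic_model <- function(x, ...) {
  S <- stoich_matrix(x)
  cat(sprintf("# A metabolic model: %d reactions x %d metabolites\n",
              ncol(S), nrow(S)))
  ng <- nrow(attr(x, "genes") %||% tibble::tibble())
  if (ng > 0) cat(sprintf("# %d genes with GPR associations\n", ng))
  NextMethod()
}

metabolites <- function(model) rownames(stoich_matrix(model))

irreversible <- function(model) model$reaction_id[model$lb >= 0]

reversible_rxns <- function(model) model$reaction_id[model$lb < 0]

#' Apply an intervention set to the bounds of a model
#'
#' Deletions force a zero flux; addable reactions that are not added are
#' absent (zero flux); added reactions become active at their stated bounds.
#'
#' @param model a [metabolic_model()].
#' @param deletions,additions character vectors of reaction ids.
#' @return the model with modified `lb`/`ub`.
#' @export
apply_interventions <- function(model, deletions = character(),
                                additions = character()) {
  unknown <- setdiff(c(deletions, additions), model$reaction_id)
  if (length(unknown))
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  off <- model$reaction_id %in% deletions |
    (model$status == "addable" & !model$reaction_id %in% additions)
  model$lb[off] <- 0
  model$ub[off] <- 0
  model
}

#' Read a metabolic model from a file
#'
#' Two formats are supported: the package's tabular dialect (TSV with columns
#' `reaction_id`, `equation`, `lb`, `ub`, `gpr`, `cost`, `status`) and SBML
#' Level 3 with the fbc package (gene associations are returned in the `gpr`
#' column as rule text).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tabular"` or `"sbml"`.
#' @return a [metabolic_model()].
#' @export
read_model <- function(path, format = c("auto", "tabular", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "tabular"
  if (format == "sbml") return(read_sbml_model(path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = character(0))
  need <- c("reaction_id", "equation")
  if (!all(need %in% names(tab)))
    stop("tabular model file must have columns 'reaction_id' and 'equation': ", path)
  metabolic_model(tab)
}

#' Write a metabolic model to the tabular dialect
#'
#' @param model a [metabolic_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  utils::write.table(as.data.frame(model), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
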