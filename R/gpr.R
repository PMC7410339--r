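#' Parse a gene-protein-reaction (GPR) rule
#'
#' Parses Boolean gene-association text (isoenzymes = OR, enzyme
#' subunits/complexes = AND; `and`/`&`/`&&` and `or`/`|`/`||` are accepted,
#' with parentheses) and returns the rule in minimized disjunctive normal
#' form: a list of conjunctions, each a character vector of gene ids.
#' Duplicate and superset conjunctions are absorbed. An empty rule text
#' yields the constant-true rule (an empty list): the reaction needs no
#' enzyme and cannot be blocked by gene deletions.
#'
#' DNF conversion can blow up exponentially for adversarial inputs; a
#' conjunction-count cap (option `cutsets.dnf_cap`, default 10000) aborts
#' with an error rather than degrade silently.
#'
#' @param text rule text, e.g. `"(g1 and g2) or g3"`.
#' @return object of class `gpr_rule` (list of character vectors).
#' @examples
#' parse_gpr("g1 and (g2 or g3)")
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || is.na(text) || trimws(text) == "")
    return(structure(list(), class = "gpr_rule"))
  s <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  toks <- unname(vapply(toks, function(tk) {
    if (tk %in% c("and", "AND", "And", "&", "&&")) "&"
    else if (tk %in% c("or", "OR", "Or", "|", "||")) "|"
    else tk
  }, ""))
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { pos <<- pos + 1L }
  cap <- getOption("cutsets.dnf_cap", 10000L)

  parse_factor <- function() {
    tk <- peek()
    if (is.na(tk)) stop("unexpected end of GPR rule: ", text)
    if (tk == "(") {
      advance()
      e <- parse_expr()
      if (!identical(peek(), ")")) stop("unbalanced parentheses in GPR rule: ", text)
      advance()
      e
    } else if (tk %in% c(")", "&", "|")) {
      stop("unexpected token '", tk, "' in GPR rule: ", text)
    } else {
      advance()
      list(tk)  # DNF with a single one-gene conjunction
    }
  }
  parse_term <- function() {  # factor (& factor)*
    dnf <- parse_factor()
    while (identical(peek(), "&")) {
      advance()
      rhs <- parse_factor()
      prod <- vector("list", length(dnf) * length(rhs))
      k <- 0L
      for (a in dnf) for (b in rhs) {
        k <- k + 1L
        prod[[k]] <- union(a, b)
      }
      if (length(prod) > cap)
        stop("DNF conversion exceeded the conjunction cap (",
             cap, "); see option 'cutsets.dnf_cap'")
      dnf <- prod
    }
    dnf
  }
  parse_expr <- function() {  # term (| term)*
    dnf <- parse_term()
    while (identical(peek(), "|")) {
      advance()
      dnf <- c(dnf, parse_term())
      if (length(dnf) > cap)
        stop("DNF conversion exceeded the conjunction cap (",
             cap, "); see option 'cutsets.dnf_cap'")
    }
    dnf
  }
  dnf <- parse_expr()
  if (!is.na(peek())) stop("trailing tokens in GPR rule: ", text)
  structure(minimize_dnf(dnf), class = "gpr_rule")
}

# absorption: drop duplicate conjunctions and strict supersets
minimize_dnf <- function(dnf) {
  if (length(dnf) <= 1L) return(lapply(dnf, sort))
  dnf <- lapply(dnf, sort)
  dnf <- dnf[!duplicated(lapply(dnf, paste, collapse = "\r"))]
  ord <- order(lengths(dnf))
  dnf <- dnf[ord]
  keep <- rep(TRUE, length(dnf))
  for (i in seq_along(dnf)) {
    if (!keep[i]) next
    for (j in seq_along(dnf)) {
      if (j == i || !keep[j]) next
      if (length(dnf[[i]]) <= length(dnf[[j]]) && all(dnf[[i]] %in% dnf[[j]]))
        keep[j] <- FALSE
    }
  }
  dnf[keep]
}

#' Render a GPR rule as text
#'
#' @param rule a `gpr_rule` (DNF list).
#' @return rule text such as `"(g1 and g2) or g3"`; `""` for constant true.
#' @export
gpr_to_text <- function(rule) {
  if (length(rule) == 0L) return("")
  conj <- vapply(rule, function(cj) {
    s <- paste(cj, collapse = " and ")
    if (length(cj) > 1L && length(rule) > 1L) paste0("(", s, ")") else s
  }, "")
  paste(conj, collapse = " or ")
}

#' Evaluate a GPR rule under a set of gene deletions
#'
#' @param rule a `gpr_rule`.
#' @param deleted character vector of deleted gene ids.
#' @return `TRUE` when the reaction remains catalyzed.
#' @export
eval_gpr <- function(rule, deleted = character()) {
  if (length(rule) == 0L) return(TRUE)
  for (cj in rule) if (!any(cj %in% deleted)) return(TRUE)
  FALSE
}

rule_genes <- function(rules) unique(unlist(rules, use.names = FALSE)) %||% character(0)

#' Gene catalog
#'
#' Per-gene intervention metadata: `gene_id`, `cost` (nonnegative, default 1)
#' and `status` (`"deletable"`, `"addable"`, `"protected"`). The catalog also
#' carries a `lump_map` attribute: for every lumped pseudo-gene created by
#' [compress_gpr()], the Boolean expression (DNF over original gene ids) it
#' stands for. Lumped pseudo-genes carry the minimum total deletion cost that
#' falsifies their expression, so cut-set costs are preserved under
#' compression.
#'
#' @param genes data frame with `gene_id` and optional `cost`, `status`.
#' @return a `gene_catalog` tibble.
#' @export
gene_catalog <- function(genes) {
  g <- tibble::as_tibble(genes)
  if (!"gene_id" %in% names(g)) stop("gene catalog needs a 'gene_id' column")
  if (!"cost" %in% names(g)) g$cost <- 1
  if (!"status" %in% names(g)) g$status <- "deletable"
  bad <- setdiff(unique(g$status), c("deletable", "addable", "protected"))
  if (length(bad)) stop("unknown gene status: ", paste(bad, collapse = ", "))
  if (any(g$cost < 0)) stop("gene costs must be nonnegative")
  if (anyDuplicated(g$gene_id)) stop("duplicate gene ids in catalog")
  out <- g[, c("gene_id", "cost", "status")]
  attr(out, "lump_map") <- attr(genes, "lump_map") %||% list()
  class(out) <- c("gene_catalog", class(tibble::tibble()))
  out
}

infer_gene_catalog <- function(gpr_texts) {
  rules <- lapply(gpr_texts, parse_gpr)
  gene_catalog(tibble::tibble(gene_id = sort(rule_genes(rules))))
}

# resolve a gene entity to its DNF over original genes
resolve_gene <- function(g, lump_map) {
  expr <- lump_map[[g]]
  if (is.null(expr)) list(g) else expr
}

# AND of DNFs: cross product of conjunctions, then absorption
and_dnf <- function(a, b) {
  out <- list()
  for (x in a) for (y in b) out <- c(out, list(union(x, y)))
  minimize_dnf(out)
}

#' Minimal falsifying gene-deletion sets of a Boolean expression
#'
#' A deletion set falsifies a DNF expression iff it hits (intersects) every
#' conjunction. Returns all inclusion-minimal hitting sets; used to expand
#' lumped pseudo-genes and to price them (the lump's cost is the minimum
#' summed cost over these sets).
#'
#' @param dnf list of character vectors (conjunctions over gene ids).
#' @param max_genes guard against pathological inputs (lump expressions are
#'   small by construction).
#' @return list of character vectors, each a minimal falsifying set.
#' @export
min_falsifying_sets <- function(dnf, max_genes = 20L) {
  genes <- unique(unlist(dnf, use.names = FALSE))
  if (length(genes) > max_genes)
    stop("expression has ", length(genes), " genes; refusing exhaustive ",
         "hitting-set search above ", max_genes)
  if (length(dnf) == 0L) return(list())  # constant true cannot be falsified
  out <- list()
  recurse <- function(remaining, current) {
    remaining <- remaining[!vapply(remaining, function(cj) any(cj %in% current), TRUE)]
    if (length(remaining) == 0L) {
      out[[length(out) + 1L]] <<- sort(current)
      return(invisible())
    }
    for (g in remaining[[1L]]) recurse(remaining, c(current, g))
  }
  recurse(dnf, character(0))
  out <- out[!duplicated(vapply(out, paste, "", collapse = "\r"))]
  # minimality filter
  ord <- order(lengths(out))
  out <- out[ord]
  keep <- rep(TRUE, length(out))
  for (i in seq_along(out)) {
    if (!keep[i]) next
    for (j in seq_along(out)) {
      if (j == i || !keep[j]) next
      if (all(out[[i]] %in% out[[j]])) keep[j] <- FALSE
    }
  }
  out[keep]
}

min_falsify_cost <- function(dnf, costs) {
  sets <- min_falsifying_sets(dnf)
  if (length(sets) == 0L) return(Inf)
  min(vapply(sets, function(s) sum(costs[s]), 0))
}

#' Compress GPR rules
#'
#' Reduces a ruleset before network integration, without losing any gene cut
#' set, using seven steps: (1) drop rules of blocked reactions; (2) protect
#' genes occurring exclusively in rules of essential reactions; (3) protect
#' genes essential for at least one essential reaction (present in every
#' conjunction of its rule); (4) drop rules with a conjunction consisting
#' solely of protected genes (such reactions cannot be blocked by gene
#' deletions); (5) remove protected genes from the remaining conjunctions;
#' (6) minimize the DNFs (absorption); (7) lump genes that always co-occur in
#' conjunctions into pseudo-genes, then lump rule-local disjunctions whose
#' genes occur nowhere else, re-attributing the minimal falsifying cost to
#' each lump.
#'
#' Deletion candidates and addition candidates are lumped separately; lump
#' ids are deterministic functions of the sorted member ids.
#'
#' @param rules named list of `gpr_rule`s (names = reaction ids).
#' @param catalog a [gene_catalog()].
#' @param blocked_rxns,essential_rxns reaction id sets from FVA (see
#'   [find_blocked()], [find_essential()]).
#' @return list with compressed `rules`, updated `catalog` (lumps appended,
#'   protected genes marked) and `protected` (the protected gene ids).
#' @export
compress_gpr <- function(rules, catalog, blocked_rxns = character(),
                         essential_rxns = character()) {
  lump_map <- attr(catalog, "lump_map") %||% list()
  costs <- stats::setNames(catalog$cost, catalog$gene_id)
  status <- stats::setNames(catalog$status, catalog$gene_id)

  # (1) blocked reactions; constant-true rules are irrelevant for gene MCS
  rules <- rules[!names(rules) %in% blocked_rxns]
  rules <- rules[lengths(rules) > 0L]

  occ <- function(g) names(rules)[vapply(rules, function(r) g %in% unlist(r), TRUE)]
  genes <- rule_genes(rules)

  # (2) genes occurring exclusively in essential-reaction rules
  protected <- genes[vapply(genes, function(g) {
    o <- occ(g); length(o) > 0L && all(o %in% essential_rxns)
  }, TRUE)]
  # (3) genes essential for an essential reaction
  for (rid in intersect(names(rules), essential_rxns)) {
    r <- rules[[rid]]
    in_all <- Reduce(intersect, r)
    protected <- union(protected, in_all)
  }
  # (4) rules with an all-protected conjunction cannot be blocked
  blocked_by_protection <- vapply(rules, function(r)
    any(vapply(r, function(cj) all(cj %in% protected), TRUE)), TRUE)
  rules <- rules[!blocked_by_protection]
  # (5) drop protected genes from conjunctions, (6) minimize
  rules <- lapply(rules, function(r)
    structure(minimize_dnf(lapply(r, setdiff, protected)), class = "gpr_rule"))
  rules <- rules[lengths(rules) > 0L]

  # (7a) lump globally co-occurring genes (same status only). Pseudo-genes
  # from earlier lumping rounds are left alone, so recompression is a no-op.
  conj_list <- unlist(lapply(rules, function(r) r), recursive = FALSE)
  genes <- setdiff(rule_genes(rules), names(lump_map))
  sig <- vapply(genes, function(g)
    paste(which(vapply(conj_list, function(cj) g %in% cj, TRUE)), collapse = ","), "")
  grp <- split(genes, paste(sig, status[genes]))
  for (members in grp) {
    if (length(members) < 2L) next
    members <- sort(members)
    lump_id <- paste0("(", paste(members, collapse = "&"), ")")
    expr <- Reduce(and_dnf, lapply(members, resolve_gene, lump_map = lump_map))
    lump_map[[lump_id]] <- expr
    costs[lump_id] <- min_falsify_cost(expr, costs)
    status[lump_id] <- status[[members[1]]]
    rules <- lapply(rules, function(r) {
      structure(minimize_dnf(lapply(r, function(cj) {
        if (all(members %in% cj)) sort(union(setdiff(cj, members), lump_id)) else cj
      })), class = "gpr_rule")
    })
  }

  # (7b) rule-local disjunction lumping, iterated to a fixed point
  repeat {
    changed <- FALSE
    all_genes_by_rule <- lapply(rules, function(r) unique(unlist(r)))
    for (rid in names(rules)) {
      r <- rules[[rid]]
      if (length(r) < 2L) next
      common <- Reduce(intersect, r)
      resid <- lapply(r, setdiff, common)
      rg <- unique(unlist(resid))
      if (length(rg) == 0L) next
      elsewhere <- unlist(all_genes_by_rule[setdiff(names(rules), rid)])
      if (any(rg %in% elsewhere)) next
      st <- unique(status[rg])
      if (length(st) != 1L || st == "protected") next
      if (any(lengths(resid) == 0L)) next
      members <- sort(rg)
      lump_id <- paste0("(", paste(vapply(resid, paste, "", collapse = "&"),
                                   collapse = "|"), ")")
      expr <- minimize_dnf(do.call(c, lapply(resid, function(cj)
        Reduce(and_dnf, lapply(cj, resolve_gene, lump_map = lump_map)))))
      lump_map[[lump_id]] <- expr
      costs[lump_id] <- min_falsify_cost(expr, costs)
      status[lump_id] <- st
      rules[[rid]] <- structure(list(sort(c(common, lump_id))), class = "gpr_rule")
      changed <- TRUE
    }
    if (!changed) break
  }

  new_ids <- union(rule_genes(rules), catalog$gene_id)
  cat2 <- tibble::tibble(
    gene_id = new_ids,
    cost = unname(costs[new_ids]),
    status = ifelse(new_ids %in% protected, "protected", unname(status[new_ids])))
  attr(cat2, "lump_map") <- lump_map
  list(rules = rules, catalog = gene_catalog(cat2), protected = protected)
}
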