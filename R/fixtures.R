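#' Example network: substrate co-utilization design
#'
#' A small production network around a main substrate S and a metabolite U
#' that is both a potential by-product and a potential (addable) co-substrate.
#' Carbon enters via `r1` (S -> A); ATP generation (`r2`) is stoichiometrically
#' coupled to a by-metabolite Z that can only be drained by product synthesis
#' (`r4`), so ATP demand entails product formation. Biomass is made either
#' from the S-derived precursor B (`r5`) or directly from imported U (`r8`);
#' B also feeds the low-yield escape routes (`r3`: Z-free ATP, `r7`/`r9`:
#' by-products Q/R, `r12`: U excretion). Exchange reactions are spontaneous
#' (non-targetable); the U uptake `u_up` is an addable intervention with zero
#' cost (a medium change).
#'
#' With the two-region co-feeding target construction (see
#' [make_cofeeding_target_pair()]; yield threshold 0.4, minimum substrate
#' uptake 0.1) and the desired region `bm_ex >= 0.1`, two qualitatively
#' different designs are minimal cut sets and are documented in the bundle:
#' the four-knockout single-substrate design `{r3, r7, r9, r12}` and the
#' co-feeding design `{r6}` plus addition of `u_up` (cost 1, since the
#' addition is free).
#'
#' The stoichiometry is a transcription fixed by these documented solutions:
#' coefficients (2 ATP in `r3`, 3 ATP per biomass in `r5`/`r8`) are chosen so
#' that all residual flux distributions have product yield above the
#' threshold (worst case 3/7) while each documented knockout is individually
#' necessary.
#'
#' @return an `mcs_bundle`: list with `model`, `targets`, `desireds`,
#'   `expected` (documented solutions) and `label`.
#' @export
example_cofeeding <- function() {
  model <- metabolic_model(tibble::tribble(
    ~reaction_id, ~equation,            ~lb,  ~ub,  ~cost, ~status,
    "s_up",  "-> S",                      0,   10,  0, "non_targetable",
    "u_up",  "-> U",                      0,   10,  0, "addable",
    "r1",    "S -> A",                    0,  100,  1, "deletable",
    "r2",    "A -> ATP + Z",              0,  100,  1, "deletable",
    "r3",    "B -> 2 ATP",                0,  100,  1, "deletable",
    "r4",    "A + Z -> P",                0,  100,  1, "deletable",
    "r5",    "B + 3 ATP -> BM",           0,  100,  1, "deletable",
    "r6",    "A -> B",                    0,  100,  1, "deletable",
    "r7",    "B -> Q",                    0,  100,  1, "deletable",
    "r8",    "U + 3 ATP -> BM",           0,  100,  1, "deletable",
    "r9",    "B -> R",                    0,  100,  1, "deletable",
    "r10",   "ATP ->",                    0,  100,  0, "non_targetable",
    "r11",   "Q <-> R",                -100,  100,  1, "deletable",
    "r12",   "B -> U",                    0,  100,  1, "deletable",
    "p_ex",  "P ->",                      0,  100,  0, "non_targetable",
    "q_ex",  "Q ->",                      0,  100,  0, "non_targetable",
    "r_ex",  "R ->",                      0,  100,  0, "non_targetable",
    "u_ex",  "U ->",                      0,  100,  0, "non_targetable",
    "bm_ex", "BM ->",                     0,  100,  0, "non_targetable"
  ))
  targets <- make_cofeeding_target_pair(
    model, product_rxn = "p_ex", primary_substrate = "s_up",
    co_substrate_uptake = "u_up", co_substrate_export = "u_ex",
    threshold = 0.4, min_primary_uptake = 0.1)
  desired <- flux_region(model, "bm_ex >= 0.1", role = "desired",
                         label = "growth")
  structure(list(
    model = model, targets = targets, desireds = list(desired),
    expected = list(
      single_substrate = cutset(c("r3", "r7", "r9", "r12"), cost = 4),
      co_feeding = cutset("r6", additions = "u_up", cost = 1)),
    label = "cofeeding"), class = "mcs_bundle")
}

#' Example network: gene-level cut sets through the full pipeline
#'
#' A nine-gene network used to exercise every stage of gene cut-set
#' computation: GPR compression, enzyme-pool integration, network
#' compression, the MILP, and the two decompression steps. Substrate S is
#' converted to biomass (via the essential `r1`, `r2`) and, through an
#' intermediate X, to a wanted product P and an unwanted product D. The
#' design goal documented in the bundle is to abolish D production
#' (target `d_ex >= 1`) while keeping growth possible (desired
#' `bm_ex >= 1`), by gene knockouts only.
#'
#' The GPR structure is chosen so that compression is informative:
#' `g1`, `g2`, `g6` become protected (they only support essential
#' reactions), `g5`/`g9` co-occur and lump, and the rule of `rD` collapses
#' to `g4 and ((g5 and g9) or g7)` whose disjunction lumps into a pseudo-gene
#' with re-attributed cost 2. After compression four gene entities remain
#' (`g3`, `g4`, `g8` and the lump). Documented outcomes: the compressed MILP
#' yields exactly two solutions (knockout of `g8`, or of the lumped reaction
#' containing the `g4`/lump synthesis chain), which decompress to the four
#' gene cut sets `{g8}`, `{g4}`, `{g5,g7}`, `{g7,g9}`.
#'
#' @return an `mcs_bundle` (see [example_cofeeding()]); `expected` also
#'   documents the essential core reactions and compression counts.
#' @export
example_gene_mcs <- function() {
  model <- metabolic_model(tibble::tribble(
    ~reaction_id, ~equation,  ~lb, ~ub, ~gpr,                               ~cost, ~status,
    "s_up",  "-> S",       0,  10, "",                                  0, "non_targetable",
    "r1",    "S -> A",     0, 100, "g1 and g2",                         0, "non_targetable",
    "r2",    "A -> BM",    0, 100, "g6",                                0, "non_targetable",
    "rB",    "A -> X",     0, 100, "g8",                                0, "non_targetable",
    "rP",    "X -> P",     0, 100, "(g2 and g3) or g8",                 0, "non_targetable",
    "rD",    "X -> D",     0, 100, "g4 and ((g5 and g9) or g7)",        0, "non_targetable",
    "bm_ex", "BM ->",      0, 100, "",                                  0, "non_targetable",
    "p_ex",  "P ->",       0, 100, "",                                  0, "non_targetable",
    "d_ex",  "D ->",       0, 100, "",                                  0, "non_targetable"
  ))
  target <- flux_region(model, "d_ex >= 1", role = "target",
                        label = "D_production")
  desired <- flux_region(model, "bm_ex >= 1", role = "desired",
                         label = "growth")
  structure(list(
    model = model, targets = list(target), desireds = list(desired),
    expected = list(
      essential_core = c("r1", "r2"),
      n_genes_before = 9L,
      n_genes_after_compression = 4L,
      n_compressed_solutions = 2L,
      gene_mcs = list(
        cutset("g8", cost = 1, level = "gene"),
        cutset("g4", cost = 1, level = "gene"),
        cutset(c("g5", "g7"), cost = 2, level = "gene"),
        cutset(c("g7", "g9"), cost = 2, level = "gene"))),
    label = "gene_mcs"), class = "mcs_bundle")
}

#' Random small network bundle for property testing
#'
#' Generates a mass-balanced random network with a guaranteed substrate-to-
#' biomass path (a linear backbone), random extra conversions, by-product
#' exports and optional addable uptakes, sparse random GPR rules, one or two
#' target regions (a minimum flux through a randomly chosen reaction, which
#' excludes the zero flux vector) and a growth desired region that is
#' LP-feasible by construction. Draws that fail the validity checks are
#' resampled a bounded number of times. Deterministic per seed; the caller's
#' RNG state is left untouched.
#'
#' @param seed integer seed.
#' @param n_mets,n_rxns,n_genes,n_targets sizes (internal metabolites,
#'   internal reactions, genes, target regions). Sizes are meant for the
#'   exhaustive oracle: keep `n_rxns <= 10`.
#' @param p_gpr probability that an internal deletable reaction gets a rule.
#' @param p_addable probability of including one addable uptake reaction.
#' @return an `mcs_bundle`.
#' @export
random_bundle <- function(seed, n_mets = 5, n_rxns = 8, n_genes = 4,
                          n_targets = 1, p_gpr = 0.5, p_addable = 0.25) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (attempt in seq_len(40L)) {
    set.seed(seed * 1000L + attempt)
    b <- try(random_bundle_draw(n_mets, n_rxns, n_genes, n_targets,
                                p_gpr, p_addable), silent = TRUE)
    if (!inherits(b, "try-error") && !is.null(b)) {
      b$label <- paste0("random_", seed)
      return(b)
    }
  }
  stop("could not draw a valid random bundle for seed ", seed)
}

random_bundle_draw <- function(n_mets, n_rxns, n_genes, n_targets,
                               p_gpr, p_addable) {
  mets <- c(paste0("M", seq_len(max(2, n_mets - 1L))), "BM")
  nm <- length(mets) - 1L
  rows <- list(
    tibble::tibble(reaction_id = "s_up", equation = "-> M1", lb = 0, ub = 10,
                   gpr = "", cost = 0, status = "non_targetable"))
  backbone <- min(nm, 3L)
  for (i in seq_len(backbone - 1L))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      reaction_id = paste0("b", i),
      equation = paste0("M", i, " -> M", i + 1L),
      lb = 0, ub = 100, gpr = "", cost = 1, status = "deletable")
  rows[[length(rows) + 1L]] <- tibble::tibble(
    reaction_id = "grw", equation = paste0("M", backbone, " -> BM"),
    lb = 0, ub = 100, gpr = "", cost = 1, status = "deletable")
  n_extra <- max(0L, n_rxns - backbone - 1L)
  for (k in seq_len(n_extra)) {
    kind <- sample(c("conv", "export"), 1, prob = c(0.6, 0.4))
    if (kind == "conv") {
      ab <- sample(nm, 2L)
      rev <- stats::runif(1) < 0.25
      rows[[length(rows) + 1L]] <- tibble::tibble(
        reaction_id = paste0("x", k),
        equation = paste0("M", ab[1], if (rev) " <-> M" else " -> M", ab[2]),
        lb = if (rev) -100 else 0, ub = 100, gpr = "", cost = 1,
        status = "deletable")
    } else {
      a <- sample(nm, 1L)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        reaction_id = paste0("ex", k), equation = paste0("M", a, " ->"),
        lb = 0, ub = 100, gpr = "", cost = 1, status = "deletable")
    }
  }
  rows[[length(rows) + 1L]] <- tibble::tibble(
    reaction_id = "bm_ex", equation = "BM ->", lb = 0, ub = 100,
    gpr = "", cost = 0, status = "non_targetable")
  if (stats::runif(1) < p_addable) {
    a <- sample(2:nm, 1L)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      reaction_id = "add_up", equation = paste0("-> M", a), lb = 0, ub = 5,
      gpr = "", cost = 1, status = "addable")
  }
  tab <- dplyr::bind_rows(rows)
  # sparse random GPR rules on internal deletable reactions
  genes <- paste0("g", seq_len(n_genes))
  internal <- tab$status == "deletable"
  for (i in which(internal)) {
    if (stats::runif(1) >= p_gpr) next
    shape <- sample(c("one", "or", "and"), 1, prob = c(0.5, 0.3, 0.2))
    gs <- sample(genes, 2L, replace = FALSE)
    tab$gpr[i] <- switch(shape, one = gs[1],
                         or = paste(gs[1], "or", gs[2]),
                         and = paste(gs[1], "and", gs[2]))
    tab$status[i] <- "non_targetable"
    tab$cost[i] <- 0
  }
  model <- metabolic_model(tab)
  desired <- flux_region(model, "bm_ex >= 0.1", role = "desired",
                         label = "growth")
  # wild-type check: growth must be feasible
  if (!region_feasible(model, desired)$feasible) return(NULL)
  # target(s): minimum flux through reactions that can carry it
  f <- fva(model)
  cand <- f$reaction_id[f$max >= 0.6 &
                          !f$reaction_id %in% c("s_up", "bm_ex")]
  if (length(cand) < n_targets) return(NULL)
  tids <- sample(cand, n_targets)
  targets <- lapply(seq_along(tids), function(j)
    flux_region(model, paste(tids[j], ">= 0.5"), role = "target",
                label = paste0("t", j)))
  structure(list(model = model, targets = targets, desireds = list(desired),
                 expected = list(), label = "random"), class = "mcs_bundle")
}

#' Exhaustive cut-set oracle
#'
#' Independent correctness standard for the MILP pipeline: enumerates every
#' subset of the targetable intervention units (genes for GPR-bearing
#' reactions, the reactions themselves otherwise, addable reactions as
#' additions) up to `max_cost`, in order of increasing cardinality, and
#' tests each with the LP feasibility oracle only — gene deletions are
#' applied by evaluating the original GPR rules on the original network, so
#' no integration, compression or MILP machinery is involved. Supersets of
#' recorded cut sets are skipped, which makes every recorded set minimal.
#'
#' @param bundle an `mcs_bundle` (model, targets, desireds).
#' @param max_cost total cost bound.
#' @param max_subsets refuse instances needing more subset probes than this.
#' @return list of [cutset()]s.
#' @export
oracle_enumerate <- function(bundle, max_cost, max_subsets = 2e5) {
  model <- bundle$model
  rules <- lapply(model$gpr, parse_gpr)
  names(rules) <- model$reaction_id
  rules <- rules[lengths(rules) > 0L]
  catalog <- attr(model, "genes")
  units <- tibble::tibble(
    id = c(catalog$gene_id[catalog$status == "deletable"],
           model$reaction_id[model$status == "deletable" & model$gpr == ""],
           model$reaction_id[model$status == "addable"]),
    kind = c(rep("gene", sum(catalog$status == "deletable")),
             rep("del", sum(model$status == "deletable" & model$gpr == "")),
             rep("add", sum(model$status == "addable"))),
    cost = c(catalog$cost[catalog$status == "deletable"],
             model$cost[model$status == "deletable" & model$gpr == ""],
             model$cost[model$status == "addable"]))
  level <- if (any(units$kind == "gene")) "gene" else "reaction"
  # largest cardinality affordable under the budget
  cs_sorted <- sort(units$cost)
  max_size <- if (nrow(units)) max(which(cumsum(cs_sorted) <= max_cost + 1e-9), 0L) else 0L

  sound <- function(gene_del, rxn_del, adds) {
    rxn_off <- union(rxn_del, blocked_by_gene_deletion(rules, gene_del))
    for (tg in bundle$targets)
      if (region_feasible(model, tg, rxn_off, adds)$feasible) return(FALSE)
    for (dg in bundle$desireds)
      if (!region_feasible(model, dg, rxn_off, adds)$feasible) return(FALSE)
    TRUE
  }
  found <- list()
  n_probe <- 0L
  for (size in 0:max_size) {
    idx_sets <- if (size == 0L) list(integer(0))
                else utils::combn(nrow(units), size, simplify = FALSE)
    for (ix in idx_sets) {
      if (sum(units$cost[ix]) > max_cost + 1e-9) next
      ids <- units$id[ix]
      is_super <- any(vapply(found, function(f)
        all(c(f$deletions, f$additions) %in% ids), TRUE))
      if (is_super) next
      n_probe <- n_probe + 1L
      if (n_probe > max_subsets)
        stop("oracle instance too large (> ", max_subsets, " subset probes)")
      gene_del <- ids[units$kind[ix] == "gene"]
      rxn_del <- ids[units$kind[ix] == "del"]
      adds <- ids[units$kind[ix] == "add"]
      if (sound(gene_del, rxn_del, adds)) {
        found[[length(found) + 1L]] <- cutset(
          c(gene_del, rxn_del), adds, sum(units$cost[ix]), level)
      }
    }
  }
  sort_cutsets(found)
}
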