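#' Read flux regions from a YAML config
#'
#' The config is a YAML list; each entry has `role` (`target`/`desired`),
#' an optional `label`, and `constraints`, a list of linear constraint
#' strings over reaction ids (see [flux_region()]):
#'
#' ```yaml
#' - role: target
#'   label: low_yield
#'   constraints:
#'     - "p_ex - 0.4 s_up <= 0"
#'     - "s_up >= 0.1"
#' - role: desired
#'   constraints: ["bm_ex >= 0.1"]
#' ```
#'
#' @param path YAML file path.
#' @param model the [metabolic_model()] the regions refer to.
#' @return list of [flux_region()]s.
#' @export
read_regions <- function(path, model) {
  entries <- yaml::read_yaml(path)
  lapply(seq_along(entries), function(i) {
    en <- entries[[i]]
    if (is.null(en$role) || !en$role %in% c("target", "desired"))
      stop("region entry ", i, " needs role 'target' or 'desired'")
    flux_region(model, unlist(en$constraints), role = en$role,
                label = en$label %||% paste0(en$role, "_", i))
  })
}

region_to_text <- function(region) {
  vapply(seq_len(nrow(region$V)), function(i) {
    nz <- which(region$V[i, ] != 0)
    terms <- paste(sprintf("%.17g %s", unname(region$V[i, nz]),
                           colnames(region$V)[nz]), collapse = " + ")
    terms <- gsub("+ -", "- ", terms, fixed = TRUE)
    paste(terms, "<=", format(region$v[i], digits = 17))
  }, "")
}

#' Write flux regions to a YAML config
#'
#' Inverse of [read_regions()] (all rows normalized to `<=`).
#'
#' @param regions list of [flux_region()]s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  if (inherits(regions, "flux_region")) regions <- list(regions)
  out <- lapply(regions, function(rg)
    list(role = rg$role, label = rg$label,
         constraints = as.list(region_to_text(rg))))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Export an example bundle to disk
#'
#' Writes the model (tabular dialect), the region config (YAML) and the
#' documented expected solutions (TSV) of a fixture bundle, so command-line
#' runs can reproduce library results byte-for-byte.
#'
#' @param bundle an `mcs_bundle` (see [example_cofeeding()]).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_model(bundle$model, file.path(dir, "model.tsv"))
  write_regions(c(bundle$targets, bundle$desireds),
                file.path(dir, "regions.yaml"))
  exp <- bundle$expected
  exp_sets <- Filter(function(x) inherits(x, "cutset"),
                     c(exp, if (!is.null(exp$gene_mcs)) exp$gene_mcs))
  if (length(exp_sets))
    write_cutsets(exp_sets, file.path(dir, "expected_mcs.tsv"))
  invisible(dir)
}
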