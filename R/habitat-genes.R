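#' Select habitat-specific CDS by ordination score
#'
#' CDS whose score on the given constrained axis has the requested sign and a
#' magnitude exceeding the cutoff are called specific to the habitat the axis
#' separates. CDS whose scores stay within the cutoff band on *every* axis
#' are reported separately as "core-like" (neutral to all habitat contrasts,
#' as housekeeping genes are expected to be).
#'
#' @param cds_scores CDS x axis score matrix (e.g. `fit$cds_scores`).
#' @param axis Axis index.
#' @param sign `"positive"` or `"negative"`.
#' @param habitat Habitat label to attach to the call set.
#' @param cutoff Score magnitude below which a CDS is considered neutral
#'   (default 0.15, in the fitted scaling).
#' @return A list of class `habitat_calls`: `habitat`, `method = "cca_axis"`,
#'   `cds` (character vector), `core_like` (CDS neutral on all axes) and
#'   `rule`.
#' @export
select_axis_cds <- function(cds_scores, axis, sign = c("positive", "negative"),
                            habitat, cutoff = 0.15) {
  sign <- match.arg(sign)
  stopifnot(cutoff > 0)
  if (axis < 1 || axis > ncol(cds_scores)) stop("axis out of range: ", axis)
  s <- cds_scores[, axis]
  sel <- if (sign == "positive") s > cutoff else s < -cutoff
  core_like <- rownames(cds_scores)[apply(abs(cds_scores) <= cutoff, 1, all)]
  structure(list(habitat = habitat, method = "cca_axis",
                 cds = rownames(cds_scores)[sel], core_like = core_like,
                 rule = list(axis = axis, sign = sign, cutoff = cutoff)),
            class = "habitat_calls")
}

#' @export
print.habitat_calls <- function(x, ...) {
  cat(sprintf("%s calls for habitat '%s': %d CDS\n", x$method, x$habitat,
              length(x$cds)))
  invisible(x)
}

#' Habitat-exclusive CDS calls
#'
#' `strict`: a CDS is called for habitat h when present in *all* genomes of h
#' and absent from every genome outside h. `any`: present in at least one
#' genome of h and absent outside (used when within-habitat strain diversity
#' prevents universally shared genes, as for sponge symbionts).
#'
#' @param pa A `presence_absence` matrix.
#' @param design Named habitat vector covering all genomes of `pa`.
#' @param mode `"strict"` or `"any"`.
#' @return Named list of `habitat_calls`, one per habitat.
#' @export
call_exclusive_cds <- function(pa, design, mode = c("strict", "any")) {
  mode <- match.arg(mode)
  pa <- as.matrix(unclass(pa))
  if (!all(rownames(pa) %in% names(design)))
    stop("habitat missing for genome(s): ",
         paste(setdiff(rownames(pa), names(design)), collapse = ", "))
  design <- factor(as.character(design[rownames(pa)]))
  if (any(table(design) == 0)) stop("habitat with zero genomes")
  out <- lapply(levels(design), function(h) {
    inside <- pa[design == h, , drop = FALSE]
    outside <- pa[design != h, , drop = FALSE]
    inside_ok <- if (mode == "strict") colSums(inside) == nrow(inside)
                 else colSums(inside) >= 1L
    outside_ok <- if (nrow(outside)) colSums(outside) == 0L else TRUE
    structure(list(habitat = h,
                   method = paste0("exclusive_", mode),
                   cds = colnames(pa)[inside_ok & outside_ok],
                   provenance = list(n_inside = nrow(inside),
                                     n_outside = nrow(outside))),
              class = "habitat_calls")
  })
  stats::setNames(out, levels(design))
}

#' KEGG-module completeness call
#'
#' A module is a list of component blocks, each a set of interchangeable
#' ortholog ids. A component is satisfied when any of its orthologs is
#' observed; the module is called `"present"` when at most one component is
#' unsatisfied. Single-component modules require their component to be
#' observed (the at-most-one-missing rule would otherwise declare empty
#' evidence present).
#'
#' @param observed_orthologs Character vector of observed ortholog ids.
#' @param module List with `module_id` and `components` (list of character
#'   vectors), or just the components list.
#' @return `"present"` or `"absent"`.
#' @export
module_completeness <- function(observed_orthologs, module) {
  components <- if (is.list(module) && !is.null(module$components))
    module$components else module
  if (!length(components)) stop("empty module definition")
  satisfied <- vapply(components,
                      function(block) any(block %in% observed_orthologs),
                      logical(1))
  missing <- sum(!satisfied)
  allowed <- if (length(components) == 1L) 0L else 1L
  if (missing <= allowed) "present" else "absent"
}

#' Habitat x function presence table
#'
#' Summarises habitat-specific calls into the paper-style function table: a
#' function is marked with a filled symbol when supported by CCA-axis or
#' strict-exclusive calls, with an open (triangle) symbol when supported only
#' by relaxed any-mode exclusivity, and left blank otherwise. CDS without an
#' annotation are counted under `"hypothetical"`.
#'
#' @param calls_by_method List of `habitat_calls` objects (any mix of
#'   methods/habitats).
#' @param annotation_table Data.frame with columns `cds_id` and
#'   `function_label` (externally produced annotations).
#' @return A character matrix, functions in rows and habitats in columns,
#'   with entries `"\u25cb"` (strong), `"\u0394"` (relaxed-only) or `""`,
#'   plus attribute `hypothetical_counts` (unannotated CDS per habitat).
#' @export
build_table4 <- function(calls_by_method, annotation_table) {
  stopifnot(all(c("cds_id", "function_label") %in% names(annotation_table)))
  ann <- stats::setNames(as.character(annotation_table$function_label),
                         annotation_table$cds_id)
  calls <- if (inherits(calls_by_method, "habitat_calls"))
    list(calls_by_method) else calls_by_method
  calls <- unlist(lapply(calls, function(x)
    if (inherits(x, "habitat_calls")) list(x) else x), recursive = FALSE)
  habs <- unique(vapply(calls, `[[`, "", "habitat"))
  funs <- unique(stats::na.omit(ann[unlist(lapply(calls, `[[`, "cds"))]))
  tab <- matrix("", nrow = length(funs), ncol = length(habs),
                dimnames = list(funs, habs))
  hypo <- stats::setNames(integer(length(habs)), habs)
  for (cl in calls) {
    labels <- ann[cl$cds]
    hypo[cl$habitat] <- hypo[cl$habitat] + sum(is.na(labels))
    labels <- unique(stats::na.omit(labels))
    if (!length(labels)) next
    strong <- cl$method %in% c("cca_axis", "exclusive_strict")
    for (f in labels) {
      cur <- tab[f, cl$habitat]
      tab[f, cl$habitat] <- if (strong) "\u25cb"
        else if (cur == "\u25cb") cur else "\u0394"
    }
  }
  attr(tab, "hypothetical_counts") <- hypo
  tab
}

#' Write the habitat x function table as TSV
#' @param tab Matrix from [build_table4()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table4 <- function(tab, path) {
  df <- data.frame(fn = rownames(tab), tab, check.names = FALSE)
  names(df)[1] <- "function"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
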