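#' Run the full delineation + forcing analysis pipeline
#'
#' Orchestrates the analysis stages on already-materialised inputs:
#' similarity-matrix delineation against a reference grouping, pangenome CCA
#' against a habitat design, and habitat-specific gene calling. Stages whose
#' inputs are not supplied are skipped. Every parameter is echoed into the
#' run report, which is machine-readable and sufficient to reproduce the run.
#'
#' @param similarity Optional `similarity_matrix` (or path to its TSV).
#' @param reference Optional reference partition (list, named vector, or path
#'   to a two-column TSV genome/group).
#' @param pa Optional `presence_absence` matrix (or path: `.csv` parsed as
#'   roary_csv, otherwise tsv_binary).
#' @param habitats Optional habitat design (named vector or path to TSV);
#'   required when `pa` is given.
#' @param cutoff Score-magnitude cutoff for axis-based habitat calls.
#' @param scaling CCA score scaling.
#' @param out_dir Optional directory for stage outputs (candidates.tsv,
#'   dendrogram newick, eigenvalues.tsv, scores, fractions.json, report.json).
#' @param quiet Suppress progress messages (warnings always shown).
#' @return A list of class `run_report`: `config`, `version`, and per-stage
#'   summaries (`delineation`, `cca`, `habitat_calls`, `warnings`).
#' @export
run_full <- function(similarity = NULL, reference = NULL, pa = NULL,
                     habitats = NULL, cutoff = 0.15,
                     scaling = "symmetric", out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[taxoforce] ", ...)
  warns <- character(0)
  catch_warn <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
  })
  config <- list(cutoff = cutoff, scaling = scaling,
                 has_similarity = !is.null(similarity),
                 has_reference = !is.null(reference), has_pa = !is.null(pa))
  if (is.character(similarity)) similarity <- read_similarity_matrix(similarity)
  if (is.character(reference)) {
    df <- utils::read.table(reference, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    reference <- stats::setNames(df[[2]], df[[1]])
  }
  if (is.character(pa)) {
    dialect <- if (grepl("\\.csv$", pa)) "roary_csv" else "tsv_binary"
    pa <- parse_presence_absence(pa, dialect)
  }
  if (!is.null(pa)) {
    if (is.null(habitats)) stop("[cca] habitat design required when pa is given")
    if (is.character(habitats)) {
      if (!file.exists(habitats)) stop("[cca] habitat file not found: ", habitats)
      habitats <- read_habitats(habitats)
    }
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  report <- list(version = as.character(utils::packageVersion("taxoforce")),
                 config = config)

  if (!is.null(similarity)) {
    say("delineate: ", nrow(similarity), " genomes")
    fit <- catch_warn(delineate_genera(similarity, reference))
    report$delineation <- list(
      n_genomes = nrow(similarity),
      n_intervals = nrow(fit$intervals),
      optimal = if (!is.null(fit$optimal)) as.list(fit$optimal[1, ]) else NULL)
    if (!is.null(out_dir)) {
      tab <- if (!is.null(fit$candidates)) fit$candidates else fit$intervals
      utils::write.table(as.data.frame(tab), file.path(out_dir, "candidates.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      export_dendrogram(similarity, file.path(out_dir, "dendrogram.nwk"))
    }
  }

  if (!is.null(pa)) {
    say("cca: ", nrow(pa), " genomes x ", ncol(pa), " CDS clusters")
    fit <- catch_warn(cca_fit(pa, habitats, scaling = scaling))
    vp <- variance_partition(fit)
    report$cca <- list(
      n_genomes = length(fit$row_mass), n_cds = length(fit$col_mass),
      n_habitats = nlevels(fit$design), n_axes = length(fit$eigenvalues),
      total_inertia = fit$total_inertia,
      env_fraction = unname(vp["env_fraction"]),
      phylo_fraction = unname(vp["phylo_fraction"]),
      axis_fractions = as.list(fit$axis_fractions),
      scaling = scaling)
    say("habitat calls at cutoff ", cutoff)
    strict <- call_exclusive_cds(pa, habitats, "strict")
    any_m <- call_exclusive_cds(pa, habitats, "any")
    axis_calls <- if (length(fit$eigenvalues)) axis_calls_by_habitat(fit, cutoff)
                  else list()
    report$habitat_calls <- list(
      cutoff = cutoff,
      strict = lapply(strict, function(x) length(x$cds)),
      any = lapply(any_m, function(x) length(x$cds)),
      cca_axis = lapply(axis_calls, function(x) length(x$cds)))
    if (!is.null(out_dir)) {
      utils::write.table(data.frame(axis = names(fit$eigenvalues),
                                    eigenvalue = fit$eigenvalues,
                                    fraction = fit$axis_fractions),
                         file.path(out_dir, "eigenvalues.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      for (nm in c("site_scores", "cds_scores", "habitat_scores", "habitat_axis_r"))
        if (!is.null(fit[[nm]]))
          utils::write.table(data.frame(id = rownames(fit[[nm]]), fit[[nm]]),
                             file.path(out_dir, paste0(nm, ".tsv")),
                             sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(list(env_fraction = fit$env_fraction,
                                phylo_fraction = fit$phylo_fraction),
                           file.path(out_dir, "fractions.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  report$warnings <- warns
  class(report) <- "run_report"
  if (!is.null(out_dir))
    jsonlite::write_json(unclass_recursive(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  report
}

# axis-based calls for every habitat: each habitat is assigned the axis (and
# sign) on which its indicator correlates most strongly.
axis_calls_by_habitat <- function(fit, cutoff = 0.15) {
  r <- fit$habitat_axis_r
  out <- lapply(rownames(r), function(h) {
    j <- which.max(abs(r[h, ]))
    select_axis_cds(fit$cds_scores, axis = j,
                    sign = if (r[h, j] >= 0) "positive" else "negative",
                    habitat = h, cutoff = cutoff)
  })
  stats::setNames(out, rownames(r))
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else unclass(x)
}

#' @export
print.run_report <- function(x, ...) {
  cat("taxoforce run report (version ", x$version, ")\n", sep = "")
  if (!is.null(x$delineation)) {
    d <- x$delineation
    cat(sprintf("  delineation: %d genomes, %d stable intervals\n",
                d$n_genomes, d$n_intervals))
    if (!is.null(d$optimal))
      cat(sprintf("    optimal [%.2f-%.2f]: %d groups, ARI %.3f\n",
                  d$optimal$lower, d$optimal$upper, d$optimal$n_clusters,
                  d$optimal$ari))
  }
  if (!is.null(x$cca)) {
    cat(sprintf("  cca: %d x %d, %d habitats, %d axes; env %.1f%% / phylo %.1f%%\n",
                x$cca$n_genomes, x$cca$n_cds, x$cca$n_habitats, x$cca$n_axes,
                100 * x$cca$env_fraction, 100 * x$cca$phylo_fraction))
  }
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}
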