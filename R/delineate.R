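#' Single-linkage partition of genomes at a similarity threshold
#'
#' Genomes are the vertices of a graph with an edge wherever the pairwise
#' similarity is at least `t` (inclusive); the partition is the set of
#' connected components. This is single-linkage clustering cut at `t`.
#'
#' @param S A `similarity_matrix` (see [as_similarity_matrix()]).
#' @param t Threshold in percent, in (0, 100\].
#' @return A list of character vectors (genome labels), sorted by first
#'   member; class `genome_partition`.
#' @export
cluster_at_threshold <- function(S, t) {
  stopifnot(t > 0, t <= 100)
  m <- unclass(S)
  adj <- m >= t
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  as_partition(split(rownames(m), comp))
}

as_partition <- function(blocks) {
  blocks <- lapply(blocks, function(b) sort(as.character(b)))
  blocks <- blocks[order(vapply(blocks, `[`, "", 1L))]
  names(blocks) <- NULL
  structure(blocks, class = "genome_partition")
}

#' @export
print.genome_partition <- function(x, ...) {
  cat(length(x), "blocks over", sum(lengths(x)), "genomes\n")
  for (b in x) cat(" {", paste(b, collapse = ", "), "}\n")
  invisible(x)
}

# canonical string form for fast partition comparison
partition_key <- function(p) {
  paste(vapply(p, paste, "", collapse = ","), collapse = ";")
}

#' Enumerate all threshold-stable partitions of a similarity matrix
#'
#' Off-diagonal values are rounded to 2 decimals (the precision of published
#' AAI tables), sorted and deduplicated; the single-linkage partition is
#' evaluated at every value, and maximal runs of identical partitions are
#' merged into stable intervals. `lower`/`upper` are the observed values
#' bounding each run, displayed "[lower-upper]". `t_open` is the largest
#' observed value below the run (`-Inf` for the first): any threshold t with
#' `t_open < t <= upper` yields the interval's partition.
#'
#' @param S A `similarity_matrix` with at least 2 genomes.
#' @return A data.frame of class `stable_intervals` with columns `lower`,
#'   `upper`, `t_open`, `n_clusters`, and a list-column `partition`.
#' @export
enumerate_stable_intervals <- function(S) {
  m <- round(unclass(S), 2)
  if (nrow(m) < 2) {
    return(structure(
      data.frame(lower = numeric(), upper = numeric(), t_open = numeric(),
                 n_clusters = integer()),
      partition = list(), class = c("stable_intervals", "data.frame")))
  }
  vals <- sort(unique(m[upper.tri(m)]))
  S2 <- as_similarity_matrix(m, attr(S, "index_kind"))
  parts <- lapply(vals, function(v) cluster_at_threshold(S2, v))
  keys <- vapply(parts, partition_key, "")
  run_id <- cumsum(c(TRUE, keys[-1] != keys[-length(keys)]))
  lower <- tapply(vals, run_id, min)
  upper <- tapply(vals, run_id, max)
  first_idx <- match(unique(run_id), run_id)
  out <- data.frame(lower = as.numeric(lower), upper = as.numeric(upper),
                    t_open = c(-Inf, as.numeric(upper[-length(upper)])),
                    n_clusters = vapply(parts[first_idx], length, 1L))
  attr(out, "partition") <- parts[first_idx]
  class(out) <- c("stable_intervals", "data.frame")
  out
}

#' @export
print.stable_intervals <- function(x, ...) {
  cat(nrow(x), "stable threshold intervals:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  [%.2f-%.2f]  %d clusters\n", x$lower[i], x$upper[i],
                x$n_clusters[i]))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Standard Hubert-Arabie ARI from the contingency table of the two
#' clusterings; 1 iff the partitions are identical, 0 expected under random
#' labelings, can be negative.
#'
#' @param p,q Partitions (lists of genome-label vectors) over the same genome
#'   set.
#' @return A single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(p, q) {
  gp <- unlist(p); gq <- unlist(q)
  if (!setequal(gp, gq)) stop("partitions cover different genome sets")
  lab_p <- rep(seq_along(p), lengths(p))[order(gp)]
  lab_q <- rep(seq_along(q), lengths(q))[order(gq)]
  tab <- table(lab_p, lab_q)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(gp)
  expected <- sum_a * sum_b / ch2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_idx - expected)
}

#' Score candidate threshold intervals against a reference grouping
#'
#' Each stable interval's partition is compared to the reference partition on
#' their common genomes. Intervals are ranked by: adjusted Rand index
#' (descending), number of violated forbidden-merge constraints (ascending),
#' number of singleton blocks (ascending), then interval width (descending).
#'
#' @param intervals A `stable_intervals` object.
#' @param reference Reference partition: a list of genome-label vectors, or a
#'   named vector genome -> group label.
#' @param forbidden_merge_pairs Optional 2-column matrix/data.frame of genome
#'   pairs that must not share a block.
#' @param max_singleton_fraction Intervals whose partition has more than this
#'   fraction of singleton blocks are flagged `excess_singletons` (they still
#'   participate in ranking).
#' @return A data.frame of class `candidate_evaluation` with columns `lower`,
#'   `upper`, `n_clusters`, `ari`, `exact_match`, `n_singletons`,
#'   `forbidden_merges`, `excess_singletons`, `rank`, ordered by rank.
#' @export
evaluate_candidates <- function(intervals, reference,
                                forbidden_merge_pairs = NULL,
                                max_singleton_fraction = 0.5) {
  parts <- attr(intervals, "partition")
  if (!is.list(reference))
    reference <- split(names(reference), as.character(reference))
  reference <- as_partition(reference)
  ref_genomes <- unlist(reference)
  mat_genomes <- unlist(parts[[1L]])
  common <- intersect(mat_genomes, ref_genomes)
  if (!length(common)) stop("reference shares no genomes with the matrix")
  restrict <- function(p) {
    p <- lapply(p, intersect, common)
    as_partition(p[lengths(p) > 0])
  }
  ref_r <- restrict(reference)
  n <- nrow(intervals)
  ari <- numeric(n); n_singl <- integer(n); n_forb <- integer(n); exact <- logical(n)
  for (i in seq_len(n)) {
    pr <- restrict(parts[[i]])
    ari[i] <- adjusted_rand_index(pr, ref_r)
    exact[i] <- identical(partition_key(pr), partition_key(ref_r))
    n_singl[i] <- sum(lengths(parts[[i]]) == 1L)
    if (!is.null(forbidden_merge_pairs)) {
      fp <- as.matrix(forbidden_merge_pairs)
      block_of <- stats::setNames(rep(seq_along(parts[[i]]), lengths(parts[[i]])),
                                  unlist(parts[[i]]))
      n_forb[i] <- sum(block_of[fp[, 1L]] == block_of[fp[, 2L]], na.rm = TRUE)
    }
  }
  width <- intervals$upper - intervals$lower
  ord <- order(-ari, n_forb, n_singl, -width)
  out <- data.frame(lower = intervals$lower, upper = intervals$upper,
                    t_open = intervals$t_open,
                    n_clusters = intervals$n_clusters,
                    ari = ari, exact_match = exact, n_singletons = n_singl,
                    forbidden_merges = n_forb,
                    excess_singletons =
                      n_singl / intervals$n_clusters > max_singleton_fraction)
  out$rank <- match(seq_len(n), ord)
  out <- out[ord, , drop = FALSE]
  attr(out, "partition") <- parts[ord]
  rownames(out) <- NULL
  class(out) <- c("candidate_evaluation", "data.frame")
  out
}

#' Delineate genera from a similarity matrix
#'
#' The fitting entry point of the threshold-delineation workflow: enumerates
#' all threshold-stable single-linkage partitions of `S`, scores each
#' candidate interval against a reference grouping (typically a phylogenomic
#' clustering), and selects the optimal threshold interval.
#'
#' @param S A `similarity_matrix`.
#' @param reference Reference partition (list of genome vectors or named
#'   genome -> group vector). When `NULL`, intervals are enumerated but not
#'   ranked.
#' @param forbidden_merge_pairs,max_singleton_fraction Passed to
#'   [evaluate_candidates()].
#' @return An object of class `genus_delineation` with elements `S`,
#'   `intervals`, `candidates` (or `NULL`), `optimal` (rank-1 row or `NULL`),
#'   `partition` (the optimal partition) and `reference`.
#' @seealso [cluster_at_threshold()], [enumerate_stable_intervals()],
#'   [export_dendrogram()]
#' @export
delineate_genera <- function(S, reference = NULL, forbidden_merge_pairs = NULL,
                             max_singleton_fraction = 0.5) {
  intervals <- enumerate_stable_intervals(S)
  candidates <- NULL; optimal <- NULL; partition <- NULL
  if (!is.null(reference) && nrow(intervals)) {
    candidates <- evaluate_candidates(intervals, reference,
                                      forbidden_merge_pairs,
                                      max_singleton_fraction)
    optimal <- candidates[1L, , drop = FALSE]
    partition <- attr(candidates, "partition")[[1L]]
  }
  structure(list(S = S, intervals = intervals, candidates = candidates,
                 optimal = optimal, partition = partition,
                 reference = reference),
            class = "genus_delineation")
}

#' @export
print.genus_delineation <- function(x, ...) {
  cat("Genus delineation by threshold-stable single-linkage clustering\n")
  cat(sprintf("  %d genomes, %s matrix, %d stable intervals\n",
              nrow(x$S), attr(x$S, "index_kind"), nrow(x$intervals)))
  if (!is.null(x$optimal)) {
    cat(sprintf("  optimal interval [%.2f-%.2f]: %d groups, ARI %.3f%s\n",
                x$optimal$lower, x$optimal$upper, x$optimal$n_clusters,
                x$optimal$ari,
                if (x$optimal$exact_match) " (exact match to reference)" else ""))
  }
  invisible(x)
}

#' @export
#' @method summary genus_delineation
summary.genus_delineation <- function(object, ...) {
  cat("Stable intervals and candidate ranking:\n")
  if (!is.null(object$candidates)) print.data.frame(object$candidates, digits = 4)
  else print(object$intervals)
  invisible(object)
}

#' @export
#' @method plot genus_delineation
plot.genus_delineation <- function(x, ...) {
  hc <- delineation_hclust(x$S)
  plot(hc, ylab = "100 - similarity", main = "Single-linkage merge tree",
       sub = "", xlab = "", ...)
  if (!is.null(x$optimal))
    graphics::abline(h = 100 - mean(c(max(x$optimal$t_open, x$optimal$lower),
                                      x$optimal$upper)), lty = 2)
  invisible(x)
}

delineation_hclust <- function(S) {
  d <- stats::as.dist(100 - unclass(S))
  stats::hclust(d, method = "single")
}

#' Export the single-linkage merge tree as a newick string
#'
#' The tree is ultrametric with merge heights 100 minus similarity (leaf
#' depths half that, per the usual ultrametric display convention, so two
#' genomes at similarity 80 sit on branches of length 10). Cutting the
#' underlying hclust tree at height 100 - t reproduces
#' [cluster_at_threshold()] at t.
#'
#' @param S A `similarity_matrix` with at least 2 genomes.
#' @param path Optional file to write the tree to.
#' @return The newick string, invisibly when `path` is given.
#' @export
export_dendrogram <- function(S, path = NULL) {
  if (nrow(S) < 2) stop("need at least 2 genomes")
  phy <- ape::as.phylo(delineation_hclust(S))
  nwk <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
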