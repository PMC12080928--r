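#' Canonical correspondence analysis of a pangenome against habitat
#'
#' Fits a constrained correspondence analysis of a binary gene
#' presence/absence matrix (genomes x CDS clusters) on habitat categories,
#' partitioning gene-content variation into an environmentally explained
#' (constrained) part and a residual, lineage-explained part.
#'
#' The chi-square residual matrix is \eqn{Q_{ij} = (P_{ij} - r_i c_j) /
#' \sqrt{r_i c_j}} where \eqn{P = Y / y_{++}} and r, c are row and column
#' masses. Habitat indicator columns are weighted-centred with the row
#' masses, the rows of Q are projected onto their span under row-mass
#' weighting, and the fitted matrix is decomposed by SVD. Squared singular
#' values are the constrained eigenvalues; with h habitats at most h - 1
#' constrained axes exist. The environmental fraction is the constrained
#' inertia over the total inertia \eqn{\sum Q_{ij}^2}.
#'
#' Scores are reported in a vegan-compatible scaling (default symmetric):
#' CDS scores \eqn{v_{jk} \lambda_k^{1/4} / \sqrt{c_j}} and site
#' (linear-combination) scores \eqn{u_{ik} \lambda_k^{1/4} / \sqrt{r_i}}.
#' Axis signs are fixed by forcing the largest-magnitude habitat centroid
#' score positive on each axis. All-zero (or all-one mass-less) rows and
#' columns are dropped with a warning, never imputed.
#'
#' @param Y A `presence_absence` matrix (see [as_presence_absence()]), or any
#'   binary matrix with genome row names and cluster column names.
#' @param design Named factor/character vector mapping every genome of `Y` to
#'   a habitat category.
#' @param scaling `"symmetric"` (default), `"sites"` or `"species"`.
#' @return An object of class `pangenome_cca` with elements `eigenvalues`,
#'   `total_inertia`, `constrained_inertia`, `env_fraction`, `phylo_fraction`,
#'   `axis_fractions`, `site_scores`, `cds_scores`, `habitat_scores`,
#'   `habitat_axis_r`, `design`, `scaling`, `row_mass`, `col_mass`.
#' @export
cca_fit <- function(Y, design, scaling = c("symmetric", "sites", "species")) {
  scaling <- match.arg(scaling)
  Y <- as.matrix(unclass(Y))
  if (is.null(rownames(Y))) stop("Y needs genome row names")
  if (!all(rownames(Y) %in% names(design)))
    stop("habitat missing for genome(s): ",
         paste(setdiff(rownames(Y), names(design)), collapse = ", "))
  design <- factor(as.character(design[rownames(Y)]))
  zero_col <- colSums(Y) == 0
  if (any(zero_col)) {
    warning(sum(zero_col), " all-zero CDS column(s) dropped")
    Y <- Y[, !zero_col, drop = FALSE]
  }
  zero_row <- rowSums(Y) == 0
  if (any(zero_row)) {
    warning(sum(zero_row), " all-zero genome row(s) dropped")
    Y <- Y[!zero_row, , drop = FALSE]
    design <- droplevels(design[!zero_row])
  }
  tot <- sum(Y)
  P <- Y / tot
  r <- rowSums(P); cm <- colSums(P)
  Q <- (P - outer(r, cm)) / sqrt(outer(r, cm))
  total_inertia <- sum(Q^2)
  n_hab <- nlevels(design)

  if (n_hab < 2) {
    warning("single habitat category: zero constrained axes")
    model <- list(eigenvalues = numeric(0), total_inertia = total_inertia,
                  constrained_inertia = 0, env_fraction = 0, phylo_fraction = 1,
                  axis_fractions = numeric(0),
                  site_scores = NULL, cds_scores = NULL, habitat_scores = NULL,
                  habitat_axis_r = NULL, design = design, scaling = scaling,
                  row_mass = r, col_mass = cm)
    class(model) <- "pangenome_cca"
    return(model)
  }

  X <- stats::model.matrix(~ design - 1)
  colnames(X) <- levels(design)
  Xc <- sweep(X, 2, colSums(r * X))        # weighted-centre with row masses
  Sw <- sqrt(r) * Xc                        # rows scaled into chi-square metric
  # row-mass-weighted least squares of Q on the centred dummies
  qrS <- qr(Sw)
  rank <- qrS$rank
  Qfit <- qr.fitted(qrS, Q)
  sv <- svd(Qfit)
  keep <- which(sv$d^2 > max(sv$d^2, 0) * 1e-12 & sv$d^2 > 1e-12)
  keep <- utils::head(keep, min(n_hab - 1L, rank))
  ev <- sv$d[keep]^2
  k <- length(keep)
  if (k == 0) {
    warning("constrained component is null")
    ev <- numeric(0)
  }
  constrained <- sum(ev)

  axis_names <- if (k) paste0("CCA", seq_len(k)) else character(0)
  site_scores <- cds_scores <- habitat_scores <- habitat_axis_r <- NULL
  if (k) {
    U <- sv$u[, keep, drop = FALSE]
    V <- sv$v[, keep, drop = FALSE]
    u_raw <- sweep(U, 1, sqrt(r), "/")     # LC site scores, unit weighted norm
    v_raw <- sweep(V, 1, sqrt(cm), "/")
    mult <- switch(scaling,
      symmetric = list(site = ev^0.25, cds = ev^0.25),
      sites     = list(site = sqrt(ev / total_inertia) * total_inertia^0.25,
                       cds = rep(total_inertia^0.25, k)),
      species   = list(site = rep(total_inertia^0.25, k),
                       cds = sqrt(ev / total_inertia) * total_inertia^0.25))
    site_scores <- sweep(u_raw, 2, mult$site, "*")
    cds_scores <- sweep(v_raw, 2, mult$cds, "*")
    dimnames(site_scores) <- list(rownames(Y), axis_names)
    dimnames(cds_scores) <- list(colnames(Y), axis_names)
    # habitat centroids of site scores, weighted by row mass
    habitat_scores <- apply(site_scores, 2, function(s)
      tapply(r * s, design, sum) / tapply(r, design, sum))
    habitat_scores <- matrix(habitat_scores, nrow = n_hab,
                             dimnames = list(levels(design), axis_names))
    # fix axis signs: largest-|centroid| habitat positive on each axis
    for (j in seq_len(k)) {
      lead <- which.max(abs(habitat_scores[, j]))
      if (habitat_scores[lead, j] < 0) {
        site_scores[, j] <- -site_scores[, j]
        cds_scores[, j] <- -cds_scores[, j]
        habitat_scores[, j] <- -habitat_scores[, j]
      }
    }
    habitat_axis_r <- habitat_axis_correlation_matrix(site_scores, design, r)
  }

  model <- list(
    eigenvalues = stats::setNames(ev, axis_names),
    total_inertia = total_inertia, constrained_inertia = constrained,
    env_fraction = constrained / total_inertia,
    phylo_fraction = 1 - constrained / total_inertia,
    axis_fractions = stats::setNames(ev / total_inertia, axis_names),
    site_scores = site_scores, cds_scores = cds_scores,
    habitat_scores = habitat_scores, habitat_axis_r = habitat_axis_r,
    design = design, scaling = scaling, row_mass = r, col_mass = cm)
  class(model) <- "pangenome_cca"
  model
}

# weighted Pearson correlation between habitat indicators and axis scores
habitat_axis_correlation_matrix <- function(site_scores, design, w) {
  wcor <- function(x, y) {
    mx <- sum(w * x) / sum(w); my <- sum(w * y) / sum(w)
    vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
    if (vx <= 0 || vy <= 0) return(NA_real_)
    sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
  }
  out <- matrix(NA_real_, nlevels(design), ncol(site_scores),
                dimnames = list(levels(design), colnames(site_scores)))
  for (h in levels(design)) {
    ind <- as.numeric(design == h)
    for (j in seq_len(ncol(site_scores)))
      out[h, j] <- wcor(ind, site_scores[, j])
  }
  out
}

#' Habitat-axis correlation table of a fitted CCA
#'
#' Row-mass-weighted Pearson correlations between each habitat indicator and
#' each constrained axis's site scores; values lie in \[-1, 1\], `NA` for a
#' zero-variance indicator.
#'
#' @param model A `pangenome_cca` fit.
#' @return Habitat x axis correlation matrix (`NULL` for a null design).
#' @export
habitat_axis_correlation <- function(model) {
  stopifnot(inherits(model, "pangenome_cca"))
  model$habitat_axis_r
}

#' Environmental vs phylogenetic variance partition
#'
#' @param model A `pangenome_cca` fit.
#' @return Named numeric vector `c(env_fraction, phylo_fraction)`; the
#'   constrained share of total inertia and its complement.
#' @export
variance_partition <- function(model) {
  stopifnot(inherits(model, "pangenome_cca"))
  c(env_fraction = model$env_fraction, phylo_fraction = model$phylo_fraction)
}

#' Permutation null for the environmental fraction
#'
#' Refits the CCA with habitat labels permuted across genomes and returns the
#' null distribution of the environmental fraction.
#'
#' @param Y Presence/absence matrix.
#' @param design Habitat design.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return Numeric vector of length `n_perm` of permuted env fractions.
#' @export
env_fraction_null <- function(Y, design, n_perm = 99L, seed = 0L) {
  design <- design[rownames(Y)]
  set.seed(seed)
  vapply(seq_len(n_perm), function(i) {
    d <- stats::setNames(sample(as.character(design)), names(design))
    suppressWarnings(cca_fit(Y, d)$env_fraction)
  }, 0)
}

#' @export
print.pangenome_cca <- function(x, ...) {
  cat("Constrained correspondence analysis of pangenome presence/absence\n")
  cat(sprintf("  %d genomes, %d CDS clusters, %d habitat categories\n",
              length(x$row_mass), length(x$col_mass), nlevels(x$design)))
  cat(sprintf("  total inertia %.4f; constrained %.4f over %d axes\n",
              x$total_inertia, x$constrained_inertia, length(x$eigenvalues)))
  cat(sprintf("  environmental forcing %.1f%%, phylogenetic forcing %.1f%%\n",
              100 * x$env_fraction, 100 * x$phylo_fraction))
  invisible(x)
}

#' @export
#' @method summary pangenome_cca
summary.pangenome_cca <- function(object, ...) {
  print(object)
  if (length(object$eigenvalues)) {
    cat("\nConstrained axes:\n")
    print(round(rbind(eigenvalue = object$eigenvalues,
                      fraction_of_total = object$axis_fractions), 4))
    cat("\nHabitat centroids:\n")
    print(round(object$habitat_scores, 3))
    cat("\nHabitat-axis correlations:\n")
    print(round(object$habitat_axis_r, 3))
  }
  invisible(object)
}

#' @export
#' @method coef pangenome_cca
coef.pangenome_cca <- function(object, ...) object$eigenvalues

#' Biplot of a fitted pangenome CCA
#'
#' Plots CDS clusters (points), genomes (open circles) and habitat centroids
#' (labels) on two constrained axes.
#'
#' @param x A `pangenome_cca` fit.
#' @param axes Which two axes to show.
#' @param ... Passed to [graphics::plot()].
#' @export
#' @method plot pangenome_cca
plot.pangenome_cca <- function(x, axes = c(1, 2), ...) {
  if (length(x$eigenvalues) < max(axes)) stop("not enough constrained axes")
  cs <- x$cds_scores[, axes, drop = FALSE]
  ss <- x$site_scores[, axes, drop = FALSE]
  hs <- x$habitat_scores[, axes, drop = FALSE]
  lim <- range(cs, ss, hs)
  plot(cs, pch = 3, col = "grey60", xlim = lim, ylim = lim,
       xlab = sprintf("%s (%.1f%%)", colnames(cs)[1], 100 * x$axis_fractions[axes[1]]),
       ylab = sprintf("%s (%.1f%%)", colnames(cs)[2], 100 * x$axis_fractions[axes[2]]),
       ...)
  graphics::points(ss, pch = 1)
  graphics::text(hs, labels = rownames(hs), col = "red3", font = 2)
  graphics::abline(h = 0, v = 0, lty = 3)
  invisible(x)
}
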