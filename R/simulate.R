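#' Simulate a similarity matrix with planted genus blocks
#'
#' Draws a symmetric percent-identity matrix in which within-genus pairs come
#' from `intra_range` and between-genus pairs from `inter_range`, mimicking
#' the block structure of a family-level AAI table. Values are rounded to 2
#' decimals to mirror published AAI precision (and to exercise tie handling
#' downstream). In separable scenarios the drawn gap `[max inter, min intra]`
#' is recorded as ground truth: every threshold in that open-closed range
#' recovers the planted partition under single linkage.
#'
#' @param genus_sizes Integer vector of genus sizes (>= 1 each).
#' @param intra_range,inter_range Length-2 percent ranges `[lo, hi]`.
#' @param distribution `"uniform"` or `"truncated_normal"` (mean at range
#'   midpoint, sd a quarter of the range width, truncated to the range).
#' @param seed Integer seed.
#' @param separable Require `inter_range[2] < intra_range[1]` (error
#'   otherwise) and record the gap interval in the truth.
#' @return List with `S` (a `similarity_matrix`), and `truth` (list with
#'   `partition`, and for separable scenarios `gap_interval = c(max_inter,
#'   min_intra)`).
#' @export
simulate_similarity_matrix <- function(genus_sizes,
                                       intra_range = c(85, 95),
                                       inter_range = c(60, 70),
                                       distribution = c("uniform", "truncated_normal"),
                                       seed = 1L, separable = TRUE) {
  distribution <- match.arg(distribution)
  stopifnot(all(genus_sizes >= 1), length(intra_range) == 2,
            length(inter_range) == 2)
  if (separable && inter_range[2] >= intra_range[1])
    stop("separable scenario requires inter_range[2] < intra_range[1]")
  set.seed(seed)
  n <- sum(genus_sizes)
  genomes <- sprintf("g%02d", seq_len(n))
  genus <- rep(seq_along(genus_sizes), genus_sizes)
  draw <- function(k, range) {
    if (k == 0) return(numeric(0))
    v <- if (distribution == "uniform") stats::runif(k, range[1], range[2])
    else {
      mu <- mean(range); sdv <- diff(range) / 4
      x <- stats::rnorm(k * 4 + 8, mu, sdv)
      x <- x[x >= range[1] & x <= range[2]]
      while (length(x) < k) x <- c(x, stats::runif(1, range[1], range[2]))
      x[seq_len(k)]
    }
    round(v, 2)
  }
  m <- matrix(0, n, n, dimnames = list(genomes, genomes))
  ut <- which(upper.tri(m), arr.ind = TRUE)
  intra_pair <- genus[ut[, 1]] == genus[ut[, 2]]
  vals <- numeric(nrow(ut))
  vals[intra_pair] <- draw(sum(intra_pair), intra_range)
  vals[!intra_pair] <- draw(sum(!intra_pair), inter_range)
  m[upper.tri(m)] <- vals
  m <- m + t(m)
  diag(m) <- 100
  truth <- list(partition = as_partition(split(genomes, genus)))
  if (separable && any(intra_pair) && any(!intra_pair))
    truth$gap_interval <- c(max(vals[!intra_pair]), min(vals[intra_pair]))
  list(S = as_similarity_matrix(m), truth = truth)
}

#' Simulate a pangenome presence/absence matrix with planted structure
#'
#' Columns are generated in three planted categories: core genes (present in
#' every genome), clade genes (present exactly in their clade, then flipped
#' with probability `noise_flip` -- the phylogenetically forced accessory
#' genome), and habitat genes (Bernoulli(`penetrance`) inside their habitat,
#' Bernoulli(`background`) outside -- the environmentally forced genome).
#' Column names are labelled with their truth category. A genome left with an
#' all-zero row (possible only when `n_core = 0`) has one of its columns
#' regenerated, with a message.
#'
#' @param habitat_assignment Named habitat vector (genome -> habitat). The
#'   default mimics a 16-genome, 6-habitat marine isolate panel.
#' @param clade_structure List of genome-label vectors (disjoint or nested);
#'   default: one clade per habitat-independent block of 2-3 genomes.
#' @param n_core Number of core columns.
#' @param n_phylo_per_clade Clade-gene columns per clade.
#' @param n_habitat_genes_per_habitat Habitat-gene columns per habitat.
#' @param penetrance P(present) for a habitat gene inside its habitat.
#' @param background P(present) for a habitat gene outside its habitat.
#' @param noise_flip Per-cell flip probability applied to clade genes.
#' @param seed Integer seed.
#' @return List with `pa` (a `presence_absence` matrix), `design` (the
#'   habitat vector) and `truth` (list with `gene_labels`, a character vector
#'   `core` / `phylo:<i>` / `habitat:<h>` per column, and `habitat_genes`, the
#'   planted sets per habitat).
#' @export
simulate_pangenome <- function(habitat_assignment = default_habitats(),
                               clade_structure = NULL,
                               n_core = 1200L, n_phylo_per_clade = 350L,
                               n_habitat_genes_per_habitat = 120L,
                               penetrance = 0.9, background = 0.05,
                               noise_flip = 0.01, seed = 1L) {
  stopifnot(penetrance >= 0, penetrance <= 1, background >= 0, background <= 1,
            noise_flip >= 0, noise_flip <= 1)
  genomes <- names(habitat_assignment)
  if (is.null(genomes) || length(genomes) < 1)
    stop("habitat_assignment must be named by genome")
  design <- stats::setNames(factor(as.character(habitat_assignment)), genomes)
  if (nlevels(design) < 1 || length(genomes) < 1)
    stop("need at least one genome and habitat")
  set.seed(seed)
  n <- length(genomes)
  if (is.null(clade_structure)) {
    # random seeded grouping: lineage membership is a grouping of its own,
    # neither aligned with nor engineered against the habitat design
    k <- max(1L, n %/% 3L)
    clade_structure <- split(sample(genomes), rep(seq_len(k), length.out = n))
  }
  cols <- list(); labels <- character(0)
  if (n_core > 0) {
    cols$core <- matrix(1L, n, n_core)
    labels <- c(labels, rep("core", n_core))
  }
  for (ci in seq_along(clade_structure)) {
    if (n_phylo_per_clade == 0) break
    base <- as.integer(genomes %in% clade_structure[[ci]])
    m <- matrix(rep(base, n_phylo_per_clade), n, n_phylo_per_clade)
    flips <- matrix(stats::rbinom(n * n_phylo_per_clade, 1L, noise_flip),
                    n, n_phylo_per_clade)
    cols[[paste0("phylo", ci)]] <- abs(m - flips)
    labels <- c(labels, rep(paste0("phylo:", ci), n_phylo_per_clade))
  }
  for (h in levels(design)) {
    if (n_habitat_genes_per_habitat == 0) break
    inside <- design == h
    p <- ifelse(inside, penetrance, background)
    m <- matrix(stats::rbinom(n * n_habitat_genes_per_habitat, 1L,
                              rep(p, n_habitat_genes_per_habitat)),
                n, n_habitat_genes_per_habitat)
    cols[[paste0("hab_", h)]] <- m
    labels <- c(labels, rep(paste0("habitat:", h), n_habitat_genes_per_habitat))
  }
  pa <- do.call(cbind, cols)
  colnames(pa) <- sprintf("cds%05d_%s", seq_len(ncol(pa)), gsub(":", ".", labels))
  rownames(pa) <- genomes
  # guarantee no all-zero genome row
  zero <- rowSums(pa) == 0
  if (any(zero)) {
    message("regenerating ", sum(zero), " all-zero genome row(s)")
    pa[zero, 1L] <- 1L
  }
  habitat_genes <- lapply(stats::setNames(levels(design), levels(design)),
                          function(h) colnames(pa)[labels == paste0("habitat:", h)])
  list(pa = as_presence_absence(pa), design = design,
       truth = list(gene_labels = stats::setNames(labels, colnames(pa)),
                    habitat_genes = habitat_genes))
}

#' Default 16-genome habitat panel
#'
#' Habitat composition mirroring a marine isolate panel: six sponge, two
#' coral, two flatworm, one eelgrass, four seawater and one sediment genome.
#'
#' @return Named character vector genome -> habitat.
#' @export
default_habitats <- function() {
  stats::setNames(
    c(rep("sponge", 6), rep("coral", 2), rep("flatworm", 2), "eelgrass",
      rep("seawater", 4), "sediment"),
    sprintf("g%02d", 1:16))
}

#' Simulate an orthologous proteome pair with known AAI
#'
#' Proteome A is drawn uniformly over the 20 amino acids; proteome B is
#' derived by substituting each site with probability `1 - target_aai/100`
#' (always to a different residue). Exact per-ortholog hit tables (both
#' directions) are emitted in the tabular layout the index functions consume.
#'
#' @param target_aai Target mean percent identity, in (30, 100].
#' @param n_proteins Number of ortholog pairs.
#' @param length Protein length (residues).
#' @param seed Integer seed.
#' @return List with `proteome_a`, `proteome_b` (`proteome_record`s),
#'   `hits_ab`, `hits_ba` (hit data.frames) and `truth$pident` (per-ortholog
#'   identities).
#' @export
simulate_proteome_pair <- function(target_aai = 80, n_proteins = 50L,
                                   length = 300L, seed = 1L) {
  stopifnot(target_aai > 30, target_aai <= 100)
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  sub_rate <- 1 - target_aai / 100
  ids_a <- sprintf("a%03d", seq_len(n_proteins))
  ids_b <- sprintf("b%03d", seq_len(n_proteins))
  prot_a <- character(n_proteins); prot_b <- character(n_proteins)
  pident <- numeric(n_proteins)
  for (i in seq_len(n_proteins)) {
    sa <- sample(aa, length, replace = TRUE)
    flip <- stats::runif(length) < sub_rate
    sb <- sa
    if (any(flip))
      sb[flip] <- vapply(sa[flip], function(x) sample(setdiff(aa, x), 1L), "")
    prot_a[i] <- paste(sa, collapse = "")
    prot_b[i] <- paste(sb, collapse = "")
    pident[i] <- 100 * mean(!flip)
  }
  mk_hits <- function(q, s, pid) data.frame(
    qseqid = q, sseqid = s, pident = pid, length = length,
    mismatch = round(length * (100 - pid) / 100), gapopen = 0,
    qstart = 1, qend = length, sstart = 1, send = length,
    evalue = 1e-180, bitscore = 2 * length * pid / 100,
    stringsAsFactors = FALSE)
  pa <- structure(list(genome_id = "A",
                       proteins = stats::setNames(prot_a, ids_a),
                       protein_count = n_proteins), class = "proteome_record")
  pb <- structure(list(genome_id = "B",
                       proteins = stats::setNames(prot_b, ids_b),
                       protein_count = n_proteins), class = "proteome_record")
  list(proteome_a = pa, proteome_b = pb,
       hits_ab = mk_hits(ids_a, ids_b, pident),
       hits_ba = mk_hits(ids_b, ids_a, pident),
       truth = list(pident = pident))
}

#' Simulate a genome pair with a known per-site substitution rate
#'
#' Genome B is a copy of genome A with independent per-site substitutions at
#' rate `sub_rate`; useful for validating fragment-based nucleotide identity.
#'
#' @param n_fragments Genome length in units of `fragment_length`.
#' @param fragment_length Fragment size in bp.
#' @param sub_rate Per-site substitution probability.
#' @param seed Integer seed.
#' @return List with `genome_a`, `genome_b` (named character vectors) and
#'   `truth$identity` (realised percent identity).
#' @export
simulate_genome_pair <- function(n_fragments = 2L, fragment_length = 1020L,
                                 sub_rate = 0.05, seed = 1L) {
  set.seed(seed)
  len <- n_fragments * fragment_length
  bases <- c("A", "C", "G", "T")
  sa <- sample(bases, len, replace = TRUE)
  flip <- stats::runif(len) < sub_rate
  sb <- sa
  if (any(flip))
    sb[flip] <- vapply(sa[flip], function(x) sample(setdiff(bases, x), 1L), "")
  list(genome_a = c(chrA = paste(sa, collapse = "")),
       genome_b = c(chrB = paste(sb, collapse = "")),
       truth = list(identity = 100 * mean(!flip)))
}
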