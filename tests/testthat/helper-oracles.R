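# Independent oracles used across the suite. These deliberately take
# different computational routes than the package functions they check.

# Connected components at threshold t by boolean reachability closure.
oracle_partition <- function(S, t) {
  m <- unclass(S)
  A <- (m >= t)
  diag(A) <- TRUE
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  groups <- apply(A, 1, function(row) paste(which(row), collapse = ","))
  blocks <- split(rownames(m), groups)
  blocks <- lapply(blocks, sort)
  blocks <- blocks[order(vapply(blocks, `[`, "", 1L))]
  names(blocks) <- NULL
  blocks
}

partition_key <- function(p) {
  p <- lapply(p, sort)
  p <- p[order(vapply(p, `[`, "", 1L))]
  paste(vapply(p, paste, "", collapse = ","), collapse = ";")
}

# TRUE iff p refines q (every block of p inside one block of q)
is_refinement <- function(p, q) {
  block_of <- stats::setNames(rep(seq_along(q), lengths(q)), unlist(q))
  all(vapply(p, function(b) length(unique(block_of[b])) == 1L, logical(1)))
}

random_similarity <- function(n, seed, round_digits = 1) {
  set.seed(seed)
  m <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
  v <- round(runif(n * (n - 1) / 2, 40, 100), round_digits)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  diag(m) <- 100
  as_similarity_matrix(m)
}

# Constrained eigenvalues via the generalized eigenproblem
# (X'WX)^-1 X'W Q Q' W X  (different route than the SVD of the projection).
oracle_cca_eigen <- function(Y, design) {
  Y <- as.matrix(unclass(Y))
  design <- factor(as.character(design[rownames(Y)]))
  tot <- sum(Y); P <- Y / tot
  r <- rowSums(P); cm <- colSums(P)
  Q <- (P - outer(r, cm)) / sqrt(outer(r, cm))
  X <- stats::model.matrix(~ design - 1)
  Xc <- sweep(X, 2, colSums(r * X))
  Sw <- sqrt(r) * Xc
  M <- MASS::ginv(crossprod(Sw)) %*% t(Sw) %*% Q %*% t(Q) %*% Sw
  ev <- sort(Re(eigen(M, only.values = TRUE)$values), decreasing = TRUE)
  list(eigenvalues = ev[ev > 1e-10], total_inertia = sum(Q^2))
}

random_binary_matrix <- function(n, p, seed, prob = 0.45) {
  set.seed(seed)
  Y <- matrix(rbinom(n * p, 1L, prob), n, p,
              dimnames = list(sprintf("g%02d", 1:n), sprintf("c%03d", 1:p)))
  Y[rowSums(Y) == 0, 1L] <- 1L
  Y <- Y[, colSums(Y) > 0, drop = FALSE]
  Y
}

toy_hits <- function(q, s, pident = 90, bitscore = 100, evalue = 1e-30,
                     len = 100) {
  data.frame(qseqid = q, sseqid = s, pident = pident, length = len,
             mismatch = round(len * (100 - pident) / 100), gapopen = 0,
             qstart = 1, qend = len, sstart = 1, send = len,
             evalue = evalue, bitscore = bitscore, stringsAsFactors = FALSE)
}

# Loop-based best-hit + reciprocity oracle (definitional, no vectorisation)
oracle_rbh <- function(hits_ab, hits_ba, filters) {
  ok <- function(h) h$pident >= filters$min_pident & h$evalue <= filters$max_evalue
  hits_ab <- hits_ab[ok(hits_ab), , drop = FALSE]
  hits_ba <- hits_ba[ok(hits_ba), , drop = FALSE]
  best <- function(hits, q) {
    rows <- hits[hits$qseqid == q, , drop = FALSE]
    if (!nrow(rows)) return(NA_character_)
    rows <- rows[order(-rows$bitscore, rows$evalue, rows$sseqid), , drop = FALSE]
    rows$sseqid[1L]
  }
  pairs <- character(0)
  for (q in unique(hits_ab$qseqid)) {
    b <- best(hits_ab, q)
    if (!is.na(b) && identical(best(hits_ba, b), q))
      pairs <- c(pairs, paste(q, b))
  }
  sort(pairs)
}
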