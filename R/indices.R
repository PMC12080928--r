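#' Default filters for reciprocal-best-hit searches
#'
#' AAI reciprocal-best-hit defaults follow the common AAI-calculator
#' convention: percent identity >= 30, alignment covering >= 70% of the query,
#' E-value <= 1e-3. POCP uses E-value <= 1e-5, identity >= 50% and alignable
#' region >= 50% of the query, the classical conserved-protein definition.
#'
#' @param min_pident Minimum percent identity.
#' @param min_cov Minimum fraction of the query covered by the alignment
#'   (applied only when query lengths are available).
#' @param max_evalue Maximum E-value.
#' @return A list of filter settings.
#' @export
hit_filters <- function(min_pident = 30, min_cov = 0.7, max_evalue = 1e-3) {
  stopifnot(min_pident >= 0, min_pident <= 100, min_cov >= 0, min_cov <= 1,
            max_evalue >= 0)
  list(min_pident = min_pident, min_cov = min_cov, max_evalue = max_evalue)
}

# Apply filters to a hits data.frame. qlen: named vector of query lengths
# (optional; coverage filter skipped when absent for a query).
filter_hits <- function(hits, filters, qlen = NULL) {
  keep <- hits$pident >= filters$min_pident & hits$evalue <= filters$max_evalue
  if (!is.null(qlen) && filters$min_cov > 0) {
    ql <- qlen[hits$qseqid]
    cov <- hits$length / ql
    keep <- keep & (is.na(cov) | cov >= filters$min_cov)
  }
  hits[keep, , drop = FALSE]
}

# Best hit per query: max bitscore, ties -> lower evalue, then lexicographic
# subject id (determinism across search backends).
best_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  ord <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid)
  h <- hits[ord, , drop = FALSE]
  h[!duplicated(h$qseqid), , drop = FALSE]
}

#' Reciprocal best hits between two protein sets
#'
#' A pair (p, q) is reported iff q is p's best filtered hit in the A-vs-B
#' search and p is q's best filtered hit in the B-vs-A search. Best hit means
#' maximal bitscore; ties are broken by lower E-value, then lexicographic
#' subject id.
#'
#' @param hits_ab,hits_ba Hit tables (see [parse_hits_table()]) for the
#'   forward and reverse searches.
#' @param filters Filter list from [hit_filters()].
#' @param qlen_a,qlen_b Optional named vectors of protein lengths used for the
#'   coverage filter.
#' @return A data.frame with columns `protein_a`, `protein_b`, `pident`
#'   (mean of the two directions), `aln_length`, `qcov_a`, `qcov_b`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, filters = hit_filters(),
                                 qlen_a = NULL, qlen_b = NULL) {
  fab <- best_hits(filter_hits(hits_ab, filters, qlen_a))
  fba <- best_hits(filter_hits(hits_ba, filters, qlen_b))
  if (!nrow(fab) || !nrow(fba)) {
    return(data.frame(protein_a = character(), protein_b = character(),
                      pident = numeric(), aln_length = numeric(),
                      qcov_a = numeric(), qcov_b = numeric()))
  }
  back <- stats::setNames(fba$sseqid, fba$qseqid)
  keep <- !is.na(back[fab$sseqid]) & back[fab$sseqid] == fab$qseqid
  fab <- fab[keep, , drop = FALSE]
  rev_rows <- fba[match(fab$sseqid, fba$qseqid), , drop = FALSE]
  data.frame(
    protein_a = fab$qseqid, protein_b = fab$sseqid,
    pident = (fab$pident + rev_rows$pident) / 2,
    aln_length = fab$length,
    qcov_a = if (is.null(qlen_a)) rep(NA_real_, nrow(fab))
             else fab$length / qlen_a[fab$qseqid],
    qcov_b = if (is.null(qlen_b)) rep(NA_real_, nrow(fab))
             else rev_rows$length / qlen_b[rev_rows$qseqid],
    row.names = NULL)
}

pair_index_result <- function(genome_a, genome_b, index_kind, value, support,
                              sd = NA_real_, flag = NA_character_) {
  structure(list(genome_a = genome_a, genome_b = genome_b,
                 index_kind = index_kind, value = value, support = support,
                 sd = sd, flag = flag),
            class = "pair_index")
}

#' @export
print.pair_index <- function(x, ...) {
  cat(sprintf("%s(%s, %s) = %s%s\n", x$index_kind, x$genome_a, x$genome_b,
              if (is.na(x$value)) "NA" else sprintf("%.2f", x$value),
              if (is.na(x$flag)) "" else sprintf(" [%s]", x$flag)))
  invisible(x)
}

#' Average amino acid identity from reciprocal best hits
#'
#' AAI is the unweighted mean percent identity over reciprocal-best-hit
#' ortholog pairs between two proteomes.
#'
#' @param rbh Data.frame from [reciprocal_best_hits()].
#' @param genome_a,genome_b Genome labels for the result.
#' @return A `pair_index` object with `value` (percent), `support$n` (ortholog
#'   pair count) and `sd` (sample standard deviation; `NA` for a single pair).
#' @export
compute_aai <- function(rbh, genome_a = "A", genome_b = "B") {
  if (!nrow(rbh)) {
    return(pair_index_result(genome_a, genome_b, "AAI", NA_real_,
                             list(n = 0L), flag = "no_orthologs"))
  }
  pair_index_result(genome_a, genome_b, "AAI", mean(rbh$pident),
                    list(n = nrow(rbh)),
                    sd = if (nrow(rbh) > 1) stats::sd(rbh$pident) else NA_real_)
}

#' Percentage of conserved proteins
#'
#' POCP = 100 * (C1 + C2) / (T1 + T2), where Ci is the number of proteins of
#' genome i with at least one qualifying hit in the other genome and Ti its
#' proteome size. A hit qualifies when E-value <= 1e-5, identity >= 50% and
#' (when protein lengths are supplied) the alignable region covers >= 50% of
#' the query.
#'
#' @param hits_ab,hits_ba Hit tables for the two search directions.
#' @param t1,t2 Proteome sizes of genomes A and B.
#' @param filters Filter list; defaults to the POCP convention.
#' @param qlen_a,qlen_b Optional named protein-length vectors for the coverage
#'   filter.
#' @param genome_a,genome_b Genome labels.
#' @return A `pair_index` object with `support` counts C1, C2, T1, T2.
#' @export
compute_pocp <- function(hits_ab, hits_ba, t1, t2,
                         filters = hit_filters(min_pident = 50, min_cov = 0.5,
                                               max_evalue = 1e-5),
                         qlen_a = NULL, qlen_b = NULL,
                         genome_a = "A", genome_b = "B") {
  if (t1 + t2 == 0) stop("both proteomes empty (T1 + T2 = 0)")
  c1 <- length(unique(filter_hits(hits_ab, filters, qlen_a)$qseqid))
  c2 <- length(unique(filter_hits(hits_ba, filters, qlen_b)$qseqid))
  pair_index_result(genome_a, genome_b, "POCP", 100 * (c1 + c2) / (t1 + t2),
                    list(C1 = c1, C2 = c2, T1 = t1, T2 = t2))
}

#' Cut an assembly into consecutive fragments
#'
#' Each sequence is cut into consecutive non-overlapping fragments of
#' `fragment_length`; trailing remainders are discarded. Fragments are named
#' `<seqid>|<index>`.
#'
#' @param seqs Named character vector of nucleotide sequences (or a
#'   `genome_record`).
#' @param fragment_length Fragment size in bp (OrthoANI convention: 1020).
#' @return Named character vector of fragments.
#' @export
fragment_genome <- function(seqs, fragment_length = 1020L) {
  if (inherits(seqs, "genome_record")) seqs <- seqs$sequences
  out <- character(0)
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    n <- nchar(s) %/% fragment_length
    if (n == 0) next
    starts <- (seq_len(n) - 1L) * fragment_length + 1L
    frs <- substring(s, starts, starts + fragment_length - 1L)
    names(frs) <- paste0(names(seqs)[i], "|", seq_len(n))
    out <- c(out, frs)
  }
  out
}

#' Built-in exact pairwise aligner
#'
#' Aligns every query fragment against every subject fragment with a global
#' Needleman-Wunsch alignment (via Biostrings) and emits hits in the tabular
#' layout of [parse_hits_table()]. Intended for toy/test scale; production
#' runs consume externally produced tabular searches.
#'
#' @param query,subject Named character vectors of sequences.
#' @return A hits data.frame.
#' @export
exact_aligner <- function(query, subject) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                                     baseOnly = FALSE)
  rows <- vector("list", length(query) * length(subject))
  k <- 0L
  for (qi in seq_along(query)) for (si in seq_along(subject)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(query[[qi]]), Biostrings::DNAString(subject[[si]]),
      type = "global", substitutionMatrix = submat,
      gapOpening = 10, gapExtension = 4)
    wid <- Biostrings::nchar(aln)
    nm <- Biostrings::nmatch(aln)
    pident <- 100 * nm / wid
    k <- k + 1L
    rows[[k]] <- data.frame(
      qseqid = names(query)[qi], sseqid = names(subject)[si],
      pident = pident, length = wid, mismatch = wid - nm, gapopen = 0,
      qstart = 1, qend = nchar(query[[qi]]), sstart = 1,
      send = nchar(subject[[si]]), evalue = 0,
      bitscore = 2 * nm, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' OrthoANI-style average nucleotide identity
#'
#' Both assemblies are cut into consecutive non-overlapping fragments of
#' `fragment_length` (trailing remainders discarded), fragments are searched
#' in both directions with the supplied aligner, reciprocal best fragment
#' pairs passing the published OrthoANI filters (identity >= 35% over >= 35%
#' fragment coverage) are retained, and the index is the mean percent identity
#' over those reciprocal pairs.
#'
#' @param genome_a,genome_b Named character vectors of sequences or
#'   `genome_record`s.
#' @param aligner Function `(query_fragments, subject_fragments) -> hits
#'   data.frame`; defaults to the built-in [exact_aligner()].
#' @param fragment_length Fragment size in bp.
#' @param genome_a_id,genome_b_id Genome labels.
#' @return A `pair_index` object; `support$n_pairs` counts reciprocal fragment
#'   pairs. Flagged `"below_detection"` when no reciprocal pair survives.
#' @export
orthoani <- function(genome_a, genome_b, aligner = exact_aligner,
                     fragment_length = 1020L,
                     genome_a_id = "A", genome_b_id = "B") {
  fa <- fragment_genome(genome_a, fragment_length)
  fb <- fragment_genome(genome_b, fragment_length)
  if (!length(fa) || !length(fb)) {
    return(pair_index_result(genome_a_id, genome_b_id, "ANI", NA_real_,
                             list(n_pairs = 0L), flag = "below_detection"))
  }
  filters <- hit_filters(min_pident = 35, min_cov = 0.35, max_evalue = Inf)
  qlen_a <- stats::setNames(nchar(fa), names(fa))
  qlen_b <- stats::setNames(nchar(fb), names(fb))
  rbh <- reciprocal_best_hits(aligner(fa, fb), aligner(fb, fa),
                              filters, qlen_a, qlen_b)
  if (!nrow(rbh)) {
    return(pair_index_result(genome_a_id, genome_b_id, "ANI", NA_real_,
                             list(n_pairs = 0L), flag = "below_detection"))
  }
  pair_index_result(genome_a_id, genome_b_id, "ANI", mean(rbh$pident),
                    list(n_pairs = nrow(rbh)),
                    sd = if (nrow(rbh) > 1) stats::sd(rbh$pident) else NA_real_)
}

#' Species verdict from ANI and (optionally) dDDH
#'
#' Applies the standard species boundaries: ANI 95-96% and dDDH 70%. The call
#' is `same_species` when ANI >= 96 (and dDDH >= 70 when available),
#' `different_species` when ANI < 95 (and dDDH < 70 when available), and
#' `ambiguous` inside the 95-96 ANI band or when the two indices disagree.
#'
#' @param ani ANI value in \[0, 100\].
#' @param ddh Optional dDDH value in \[0, 100\] (consumed from GGDC output,
#'   never computed here).
#' @return A list of class `species_call` with `ani_value`, `ddh_value` and
#'   `verdict`.
#' @export
species_call <- function(ani, ddh = NULL) {
  stopifnot(ani >= 0, ani <= 100)
  ani_verdict <- if (ani >= 96) "same_species" else
    if (ani < 95) "different_species" else "ambiguous"
  verdict <- ani_verdict
  if (!is.null(ddh)) {
    ddh_verdict <- if (ddh >= 70) "same_species" else "different_species"
    verdict <- if (ani_verdict == "ambiguous") "ambiguous"
      else if (ani_verdict == ddh_verdict) ani_verdict else "ambiguous"
  }
  structure(list(ani_value = ani,
                 ddh_value = if (is.null(ddh)) NA_real_ else ddh,
                 verdict = verdict),
            class = "species_call")
}

#' @export
print.species_call <- function(x, ...) {
  cat(sprintf("ANI %.2f%s -> %s\n", x$ani_value,
              if (is.na(x$ddh_value)) "" else sprintf(", dDDH %.2f", x$ddh_value),
              x$verdict))
  invisible(x)
}
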