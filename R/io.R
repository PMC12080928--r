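#' Read a nucleotide FASTA assembly
#'
#' Parses a (possibly line-wrapped, possibly gzipped) nucleotide FASTA file
#' into a genome record. Sequence identifiers are taken as the first
#' whitespace-delimited token of each header and must be unique; sequences are
#' uppercased.
#'
#' @param path Path to a FASTA file.
#' @param genome_id Label for the genome; defaults to the file name without
#'   extension.
#' @return An object of class `genome_record`: a list with `genome_id`,
#'   `sequences` (named character vector), `total_length` and `gc_percent`.
#' @export
read_genome <- function(path, genome_id = NULL) {
  seqs <- read_fasta(path, alphabet = "dna")
  if (is.null(genome_id)) genome_id <- sub("\\.[^.]*$", "", basename(path))
  gs <- genome_stats(seqs)
  structure(
    list(genome_id = genome_id, sequences = seqs,
         total_length = gs[["total_length"]], gc_percent = gs[["gc_percent"]]),
    class = "genome_record")
}

#' Read a protein FASTA proteome
#'
#' @param path Path to a protein FASTA file.
#' @param genome_id Label for the genome the proteome belongs to; defaults to
#'   the file name without extension.
#' @return An object of class `proteome_record`: a list with `genome_id`,
#'   `proteins` (named character vector of amino-acid sequences) and
#'   `protein_count` (the proteome size T used by POCP).
#' @export
read_proteome <- function(path, genome_id = NULL) {
  seqs <- read_fasta(path, alphabet = "protein")
  if (is.null(genome_id)) genome_id <- sub("\\.[^.]*$", "", basename(path))
  structure(
    list(genome_id = genome_id, proteins = seqs, protein_count = length(seqs)),
    class = "proteome_record")
}

# Shared FASTA reader; returns a named character vector (uppercased).
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(
    if (alphabet == "dna") Biostrings::readBStringSet(path)
    else Biostrings::readBStringSet(path),
    error = function(e) stop("cannot parse FASTA ", path, ": ", conditionMessage(e)))
  if (length(set) == 0L) stop("no records in ", path)
  seqs <- toupper(as.character(set))
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, "", 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sequence id in ", path, ": ", dup[1L])
  names(seqs) <- ids
  legal <- if (alphabet == "dna") "ACGTUMRWSYKVHDBN." else
    paste0(paste(setdiff(Biostrings::AA_ALPHABET, c("-", "+")), collapse = ""), "X")
  bad <- regexpr(sprintf("[^%s*.-]", gsub("[*.-]", "", legal)), seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("illegal character in record '", ids[i], "' at position ", bad[i])
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences, or a `genome_record` /
#'   `proteome_record`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "genome_record")) seqs <- seqs$sequences
  if (inherits(seqs, "proteome_record")) seqs <- seqs$proteins
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Genome length and G+C content
#'
#' G+C percent is computed over unambiguous bases only: ambiguity codes (N, R,
#' Y, ...) and gaps are excluded from both numerator and denominator, so the
#' statistic is invariant under gap runs, sequence reordering and
#' reverse-complementation.
#'
#' @param x A `genome_record` or a (named) character vector of nucleotide
#'   sequences.
#' @return Named numeric vector with `total_length` (bases) and `gc_percent`.
#' @export
genome_stats <- function(x) {
  if (inherits(x, "genome_record")) x <- x$sequences
  all <- paste(toupper(x), collapse = "")
  counts <- table(strsplit(all, "")[[1]])
  n <- function(b) sum(counts[names(counts) %in% b], na.rm = TRUE)
  acgt <- n(c("A", "C", "G", "T", "U"))
  if (acgt == 0) stop("no unambiguous bases; cannot compute G+C percent")
  gc <- n(c("G", "C"))
  c(total_length = sum(nchar(x)), gc_percent = 100 * gc / acgt)
}

#' Parse a BLAST tabular (outfmt 6) hits file
#'
#' Reads the standard 12-column tab-separated layout (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore). Lines
#' starting with `#` are ignored. Row order is preserved. Coordinates are kept
#' 1-based inclusive as in the source dialect.
#'
#' @param path Path to a tabular hits file.
#' @return A data.frame with one row per hit and the 12 standard columns.
#' @export
parse_hits_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    stop("expected 12 tab-separated columns, got ", nf[nf != 12L][1L],
         " at line ", which(nf != 12L)[1L], " of ", path)
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) stop("unparsable ", what, " at line ", which(is.na(v))[1L], " of ", path)
    v
  }
  hits <- data.frame(
    qseqid = m[, 1L], sseqid = m[, 2L],
    pident = num(3L, "pident"), length = num(4L, "length"),
    mismatch = num(5L, "mismatch"), gapopen = num(6L, "gapopen"),
    qstart = num(7L, "qstart"), qend = num(8L, "qend"),
    sstart = num(9L, "sstart"), send = num(10L, "send"),
    evalue = num(11L, "evalue"), bitscore = num(12L, "bitscore"),
    stringsAsFactors = FALSE)
  validate_hits(hits)
  hits
}

empty_hits <- function() {
  data.frame(qseqid = character(), sseqid = character(), pident = numeric(),
             length = numeric(), mismatch = numeric(), gapopen = numeric(),
             qstart = numeric(), qend = numeric(), sstart = numeric(),
             send = numeric(), evalue = numeric(), bitscore = numeric(),
             stringsAsFactors = FALSE)
}

validate_hits <- function(hits) {
  stopifnot(all(hits$pident >= 0 & hits$pident <= 100),
            all(hits$evalue >= 0), all(hits$qstart <= hits$qend))
  invisible(hits)
}

#' Write hits in BLAST tabular layout
#' @param hits A hits data.frame as returned by [parse_hits_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_table <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Parse a gene presence/absence matrix
#'
#' Two dialects are supported. `roary_csv` is the layout of Roary's
#' `gene_presence_absence.csv`: one row per gene cluster, fixed metadata
#' columns, then one column per genome where any non-empty cell (including
#' cells listing several paralogous locus tags) counts as presence.
#' `tsv_binary` is a plain tab-separated 0/1 matrix with gene labels in the
#' first column and genome ids in the header.
#'
#' @param path Path to the matrix file.
#' @param dialect `"roary_csv"` or `"tsv_binary"`.
#' @return A binary matrix (genomes in rows, CDS clusters in columns) of class
#'   `presence_absence`.
#' @export
parse_presence_absence <- function(path, dialect = c("roary_csv", "tsv_binary")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "roary_csv") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
    meta <- c("Gene", "Non-unique Gene name", "Annotation", "No. isolates",
              "No. sequences", "Avg sequences per isolate", "Genome Fragment",
              "Order within Fragment", "Accessory Fragment",
              "Accessory Order with Fragment", "QC", "Min group size nuc",
              "Max group size nuc", "Avg group size nuc")
    if (!"Gene" %in% names(df)) stop("roary_csv dialect requires a 'Gene' column")
    genome_cols <- setdiff(names(df), meta)
    if (!length(genome_cols)) stop("no genome columns found in ", path)
    genes <- df[["Gene"]]
    if (anyDuplicated(genes)) {
      warning("duplicate gene labels; suffix-disambiguating")
      genes <- make.unique(genes, sep = "_dup")
    }
    m <- t(vapply(seq_len(nrow(df)),
                  function(i) as.integer(nzchar(trimws(unlist(df[i, genome_cols])))),
                  integer(length(genome_cols))))
    pa <- t(m)  # genomes in rows
    dimnames(pa) <- list(genome_cols, genes)
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                            row.names = 1L)
    pa <- t(as.matrix(df))  # file rows are clusters; flip to genomes x clusters
    if (!all(pa %in% c(0, 1))) stop("tsv_binary matrix must contain only 0/1")
    storage.mode(pa) <- "integer"
  }
  as_presence_absence(pa)
}

#' Construct a presence/absence matrix object
#' @param m Binary matrix, genomes in rows, CDS clusters in columns.
#' @return The matrix with class `presence_absence`.
#' @export
as_presence_absence <- function(m) {
  m <- as.matrix(m)
  if (!all(m %in% c(0, 1))) stop("presence/absence values must be 0/1")
  storage.mode(m) <- "integer"
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("presence/absence matrix needs genome row names and cluster column names")
  if (anyDuplicated(colnames(m))) stop("duplicate CDS cluster labels")
  if (any(rowSums(m) == 0)) stop("all-zero genome row(s): ",
                                 paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  class(m) <- c("presence_absence", class(m))
  m
}

#' Write a presence/absence matrix as a binary TSV
#' @param pa A `presence_absence` matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_presence_absence <- function(pa, path) {
  df <- data.frame(cluster = colnames(pa), t(unclass(pa)), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a habitat design table
#'
#' Expects a two-column tab-separated file (`genome_id<TAB>habitat`, no
#' header or with header).
#'
#' @param path Path to the TSV.
#' @return Named factor mapping genome id to habitat category.
#' @export
read_habitats <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, col.names = c("genome_id", "habitat"))
  if (df$genome_id[1L] %in% c("genome_id", "genome")) df <- df[-1L, ]
  if (anyDuplicated(df$genome_id)) stop("duplicate genome id in habitat table")
  stats::setNames(factor(df$habitat), df$genome_id)
}

#' Write a habitat design table
#' @param design Named factor/character vector genome -> habitat.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_habitats <- function(design, path) {
  utils::write.table(data.frame(names(design), as.character(design)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a symmetric similarity matrix from TSV
#'
#' The file must carry genome ids both as header and as first column. Values
#' are percent identities; the diagonal is ignored (treated as 100).
#'
#' @param path Path to the TSV.
#' @param index_kind One of `"AAI"`, `"ANI"`, `"POCP"` (metadata only).
#' @return A `similarity_matrix` object.
#' @export
read_similarity_matrix <- function(path, index_kind = "AAI") {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          row.names = 1L)
  as_similarity_matrix(as.matrix(df), index_kind = index_kind)
}

#' Construct a similarity matrix object
#'
#' @param m Square numeric matrix with identical row/column genome labels;
#'   must be symmetric with off-diagonal values in \[0, 100\].
#' @param index_kind One of `"AAI"`, `"ANI"`, `"POCP"`.
#' @return `m` with class `similarity_matrix` and attribute `index_kind`.
#' @export
as_similarity_matrix <- function(m, index_kind = "AAI") {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("similarity matrix must be square")
  if (is.null(rownames(m))) rownames(m) <- colnames(m)
  if (is.null(rownames(m))) stop("similarity matrix needs genome labels")
  if (!identical(rownames(m), colnames(m))) stop("row/column labels differ")
  off <- m[row(m) != col(m)]
  if (any(off < 0 | off > 100)) stop("off-diagonal similarities must lie in [0, 100]")
  if (max(abs(m - t(m))) > 1e-8) stop("similarity matrix must be symmetric")
  diag(m) <- 100
  structure(m, index_kind = index_kind,
            class = c("similarity_matrix", "matrix", "array"))
}

#' Write a similarity matrix as TSV
#' @param S A `similarity_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(S, path) {
  df <- data.frame(genome = rownames(S), unclass(S)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("%s similarity matrix: %d genomes\n",
              attr(x, "index_kind"), nrow(x)))
  off <- x[row(x) != col(x)]
  if (length(off))
    cat(sprintf("off-diagonal range: %.2f-%.2f\n", min(off), max(off)))
  invisible(x)
}
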