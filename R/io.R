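#' @useDynLib otsentry, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median p.adjust phyper quantile rbinom rnorm rpois runif
#' @importFrom utils read.delim write.table head adist
#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# lower weighted median (deterministic representative position)
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  as.integer(x[which(cw >= sum(w) / 2)[1]])
}

# Evaluate `code` under a private RNG stream, restoring global RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Read a reference genome from FASTA
#' @param path FASTA file (plain or gzipped).
#' @return Named character vector of contig sequences.
#' @export
read_fasta_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a reference genome to FASTA
#' @param seqs Named character vector of contig sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_genome <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Write reads as FASTQ (Phred+33)
#' @param ids,seqs,quals Equal-length character vectors (read ids,
#'   sequences, quality strings).
#' @param path Output path (`.gz` triggers compression).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(ids, seqs, quals, path) {
  stopifnot(length(ids) == length(seqs), length(seqs) == length(quals))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (length(ids)) {
    rec <- paste0("@", ids, "\n", seqs, "\n+\n", quals)
    writeLines(rec, con, sep = "\n")
  }
  invisible(path)
}

#' Read a FASTQ file into a data frame
#' @param path FASTQ file (plain or gzipped).
#' @return Data frame with `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ (truncated record) in ", path, call. = FALSE)
  n <- length(lines) / 4
  ids <- sub("^@", "", lines[seq(1, by = 4, length.out = n)])
  ids <- sub("\\s.*$", "", ids)
  seqs <- lines[seq(2, by = 4, length.out = n)]
  quals <- lines[seq(4, by = 4, length.out = n)]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop("malformed FASTQ: sequence/quality length mismatch at record ",
         bad[1], " of ", path, call. = FALSE)
  data.frame(id = ids, seq = seqs, qual = quals, stringsAsFactors = FALSE)
}

#' Write intervals as BED6
#'
#' Coordinates are 0-based half-open, BED's native convention.
#' @param df Data frame with columns contig, start, end, name, score, strand.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(df, path) {
  need <- c("contig", "start", "end", "name", "score", "strand")
  miss <- setdiff(need, names(df))
  if ("name" %in% miss) df$name <- "."
  if ("score" %in% miss) df$score <- 0
  if ("strand" %in% miss) df$strand <- "."
  out <- df[, need]
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

# Gene models: data frame with columns
#   name, contig, tx_start, tx_end, strand and list columns
#   exon_starts, exon_ends (0-based half-open).
# GFF-lite on disk: tab-separated gene/exon feature rows, 1-based inclusive.
write_gff_lite <- function(genes, path) {
  rows <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    rows <- c(rows, paste(g$contig, "otsentry", "transcript",
                          g$tx_start + 1L, g$tx_end, ".", g$strand, ".",
                          paste0("gene=", g$name), sep = "\t"))
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    for (k in seq_along(es)) {
      rows <- c(rows, paste(g$contig, "otsentry", "exon",
                            es[k] + 1L, ee[k], ".", g$strand, ".",
                            paste0("gene=", g$name), sep = "\t"))
    }
  }
  writeLines(rows, path)
  invisible(path)
}

#' Read a GFF-lite gene-model file
#'
#' Expects `transcript` and `exon` feature rows with a `gene=` attribute, as
#' written by [make_reference()]. Returns the internal 0-based half-open
#' representation.
#' @param path GFF-lite file.
#' @return Gene-model data frame with list columns `exon_starts`/`exon_ends`.
#' @export
read_gff_lite <- function(path) {
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("contig", "src", "type", "start", "end",
                                  "score", "strand", "frame", "attr"))
  raw$gene <- sub("^gene=", "", raw$attr)
  tx <- raw[raw$type == "transcript", ]
  genes <- data.frame(name = tx$gene, contig = tx$contig,
                      tx_start = tx$start - 1L, tx_end = tx$end,
                      strand = tx$strand, stringsAsFactors = FALSE)
  genes$exon_starts <- lapply(genes$name, function(g) {
    e <- raw[raw$type == "exon" & raw$gene == g, ]
    sort(e$start - 1L)
  })
  genes$exon_ends <- lapply(genes$name, function(g) {
    e <- raw[raw$type == "exon" & raw$gene == g, ]
    sort(e$end)
  })
  genes
}

phred_string <- function(q) {
  q <- pmin(pmax(as.integer(round(q)), 2L), 41L)
  vapply(split(q, rep(seq_along(q), 1)), function(x)
    rawToChar(as.raw(x + 33L)), character(1), USE.NAMES = FALSE)
}

# vectorised: one quality string per read given a matrix-free representation
phred_strings <- function(qlist) {
  vapply(qlist, function(q) {
    q <- pmin(pmax(as.integer(round(q)), 2L), 41L)
    rawToChar(as.raw(q + 33L))
  }, character(1), USE.NAMES = FALSE)
}
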