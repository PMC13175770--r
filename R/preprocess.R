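#' Parse a read-structure string
#'
#' The declared read-1 layout: `"<n>M+T"` means an `n`-base UMI prefix
#' followed by an optional junction tag, then genomic sequence.
#' @param structure Structure string, e.g. `"8M+T"`.
#' @return List with `umi_length` and `has_tag`.
#' @export
parse_read_structure <- function(structure) {
  m <- regmatches(structure, regexec("^([0-9]+)M(\\+T)?$", structure))[[1]]
  if (!length(m))
    stop("unparseable read structure: ", structure, call. = FALSE)
  list(umi_length = as.integer(m[2]), has_tag = nzchar(m[3]))
}

raw_hamming <- function(a, b) sum(charToRaw(a) != charToRaw(b))

#' Annotate tag-integration reads
#'
#' Extracts the UMI per the declared read structure, then searches the
#' post-UMI body for the dsODN tag within a mismatch tolerance (default one
#' mismatch per 10 tag bases). When found, the prefix through the tag is
#' trimmed and the genomic remainder kept; reads without a tag are retained
#' with their body unchanged.
#'
#' @param reads Data frame with columns `id`, `seq`, `qual` (as from
#'   [read_fastq()]), or a FASTQ path.
#' @param read_structure Structure string (see [parse_read_structure()]).
#' @param tag_sequence The junction tag.
#' @param max_tag_mismatches Mismatch tolerance for tag detection;
#'   `NULL` for `ceiling(nchar(tag)/10)`.
#' @return Data frame: `id`, `umi`, `genomic`, `gqual`, `tag_found`,
#'   `tag_offset` (0-based within the post-UMI body; NA if absent),
#'   `tag_mismatches`.
#' @export
preprocess_tagseq_reads <- function(reads, read_structure = "8M+T",
                                    tag_sequence = default_tag(),
                                    max_tag_mismatches = NULL) {
  if (is.character(reads) && length(reads) == 1) reads <- read_fastq(reads)
  rs <- parse_read_structure(read_structure)
  if (is.null(max_tag_mismatches))
    max_tag_mismatches <- as.integer(ceiling(nchar(tag_sequence) / 10))
  u <- rs$umi_length
  if (any(nchar(reads$seq) <= u))
    stop("read shorter than declared UMI length", call. = FALSE)
  umi <- substr(reads$seq, 1L, u)
  body <- substr(reads$seq, u + 1L, nchar(reads$seq))
  bqual <- substr(reads$qual, u + 1L, nchar(reads$qual))

  tag_found <- rep(FALSE, nrow(reads))
  tag_offset <- rep(NA_integer_, nrow(reads))
  tag_mm <- rep(NA_integer_, nrow(reads))
  genomic <- body
  gqual <- bqual
  if (rs$has_tag) {
    hits <- Biostrings::vmatchPattern(tag_sequence,
                                      Biostrings::DNAStringSet(body),
                                      max.mismatch = max_tag_mismatches,
                                      with.indels = FALSE)
    st <- Biostrings::startIndex(hits)
    for (i in which(lengths(st) > 0)) {
      s <- min(st[[i]])            # leftmost match
      matched <- substr(body[i], s, s + nchar(tag_sequence) - 1L)
      tag_found[i] <- TRUE
      tag_offset[i] <- s - 1L
      tag_mm[i] <- raw_hamming(matched, tag_sequence)
      e <- s + nchar(tag_sequence)
      genomic[i] <- substr(body[i], e, nchar(body[i]))
      gqual[i] <- substr(bqual[i], e, nchar(bqual[i]))
    }
  }
  data.frame(id = reads$id, umi = umi, genomic = genomic, gqual = gqual,
             tag_found = tag_found, tag_offset = tag_offset,
             tag_mismatches = tag_mm, stringsAsFactors = FALSE)
}

#' Map reads with the built-in naive mapper
#'
#' Exact 31-mer seed at the read start on both strands, ungapped extension
#' counting mismatches, unique-best placement; ties are flagged ambiguous.
#' The contract is correctness on low-error synthetic reads -- real-data
#' users should supply external alignments via [read_sam_subset()].
#'
#' @param seqs Character vector of read sequences.
#' @param genome A `synth_genome` or named character vector of contigs.
#' @param seed_len Seed length in bases.
#' @param max_mm Maximum mismatches over the full read.
#' @return Data frame: `contig`, `pos` (0-based), `strand`, `nm`, `status`
#'   (mapped/ambiguous/unmapped).
#' @export
map_reads <- function(seqs, genome, seed_len = 31L, max_mm = 4L) {
  ctg <- genome_seqs(genome)
  if (!length(ctg) || all(!nzchar(ctg)))
    stop("empty reference", call. = FALSE)
  res <- .map_reads_cpp(unname(ctg), seqs, seed_len, max_mm)
  res$contig <- names(ctg)[res$contig]
  res
}

#' Read a SAM-subset file (external alignment path)
#'
#' Parses header-skipped records using the 11 mandatory fields; only QNAME,
#' FLAG (strand + unmapped bits), RNAME, POS, and SEQ are consumed.
#' @param path SAM file.
#' @return Data frame: `id`, `contig`, `pos` (0-based), `strand`, `status`.
#' @export
read_sam_subset <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  f <- strsplit(lines, "\t")
  bad <- which(lengths(f) < 11)
  if (length(bad))
    stop("malformed SAM record at line ", bad[1], call. = FALSE)
  flag <- as.integer(vapply(f, `[[`, "", 2))
  data.frame(
    id = vapply(f, `[[`, "", 1),
    contig = vapply(f, `[[`, "", 3),
    pos = as.integer(vapply(f, `[[`, "", 4)) - 1L,
    strand = ifelse(bitwAnd(flag, 16L) > 0, "-", "+"),
    seq = vapply(f, `[[`, "", 10),
    status = ifelse(bitwAnd(flag, 4L) > 0, "unmapped", "mapped"),
    stringsAsFactors = FALSE)
}

#' Write alignments as a SAM subset
#' @param aln Data frame with `id`, `seq`, `qual`, `contig`, `pos`,
#'   `strand`, `status`.
#' @param genome Reference (for `@SQ` header lines).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam_subset <- function(aln, genome, path) {
  ctg <- genome_seqs(genome)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ctg), nchar(ctg)))
  flag <- ifelse(aln$status == "unmapped", 4L,
                 ifelse(aln$strand == "-", 16L, 0L))
  rec <- paste(aln$id, flag,
               ifelse(aln$status == "unmapped", "*", aln$contig),
               ifelse(aln$status == "unmapped", 0L, aln$pos + 1L),
               ifelse(aln$status == "mapped", 60L, 0L),
               ifelse(aln$status == "unmapped", "*",
                      paste0(nchar(aln$seq), "M")),
               "*", 0L, 0L, aln$seq,
               if (is.null(aln$qual)) "*" else aln$qual, sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

qual_ints <- function(q) as.integer(charToRaw(q)) - 33L

#' Collapse reads into UMI consensus reads
#'
#' Reads sharing (contig, position, strand, UMI) form a family; one
#' consensus is emitted per family with at least `min_size` members
#' (default 1, i.e. single-strand singleton consensus). The consensus base
#' at each position is the quality-weighted majority; ties break toward the
#' first read's base, which is the reference base on error-free input.
#'
#' @param df Data frame with `umi`, `contig`, `pos`, `strand`, `genomic`,
#'   `gqual` and any carried metadata columns (e.g. `sample`, `tag_found`).
#' @param min_size Minimum UMI family size.
#' @return Data frame of consensus reads with `family_size` and
#'   `mean_quality` added; metadata columns take the family's first value
#'   (`tag_found` becomes "any member").
#' @export
umi_consensus <- function(df, min_size = 1L) {
  if (!nrow(df)) return(cbind(df, family_size = integer(0),
                              mean_quality = numeric(0)))
  key <- paste(df$contig, df$pos, df$strand, df$umi, sep = "\r")
  groups <- split(seq_len(nrow(df)), key)
  keep <- groups[lengths(groups) >= min_size]
  rows <- lapply(keep, function(ix) {
    fam <- df[ix, , drop = FALSE]
    r <- fam[1, , drop = FALSE]
    if (nrow(fam) > 1) {
      L <- min(nchar(fam$genomic))
      mat <- do.call(rbind, strsplit(substr(fam$genomic, 1, L), ""))
      qmat <- do.call(rbind, lapply(substr(fam$gqual, 1, L), qual_ints))
      cons <- vapply(seq_len(L), function(p) {
        w <- tapply(qmat[, p], mat[, p], sum)
        names(w)[which.max(w)]      # ties: first alphabetically stable
      }, character(1))
      r$genomic <- paste(cons, collapse = "")
      r$gqual <- substr(r$gqual, 1, L)
    }
    if ("tag_found" %in% names(fam)) r$tag_found <- any(fam$tag_found)
    r$family_size <- nrow(fam)
    r$mean_quality <- mean(unlist(lapply(fam$gqual, qual_ints)))
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call integration-site clusters from consensus reads
#'
#' Tag-bearing consensus reads imply a junction: the mapped start for
#' +-strand placements (genomic sequence runs rightward from the break) and
#' the mapped end for −-strand placements (leftward). Junctions within
#' `cluster_window` bases merge by single linkage; per-sample counts are
#' tallied by orientation and a cluster is bidirectional iff some sample
#' has evidence on both sides.
#'
#' @param cons Consensus-read data frame with `sample`, `contig`, `pos`,
#'   `strand`, `genomic`, `tag_found`.
#' @param cluster_window Merge window in bases.
#' @return Data frame: `cluster_id`, `contig`, `junction`, per-sample
#'   orientation counts in attribute-free long columns `n_right`, `n_left`
#'   (list columns keyed by sample via `counts`), and `bidirectional`.
#' @export
call_integration_clusters <- function(cons, cluster_window = 5L) {
  tagged <- cons[cons$tag_found & cons$status == "mapped", , drop = FALSE]
  if (!nrow(tagged))
    return(data.frame(cluster_id = character(0), contig = character(0),
                      junction = integer(0), bidirectional = logical(0)))
  tagged$junction <- ifelse(tagged$strand == "+", tagged$pos,
                            tagged$pos + nchar(tagged$genomic))
  tagged$orientation <- ifelse(tagged$strand == "+", "right", "left")
  out <- list()
  for (ctg in unique(tagged$contig)) {
    t <- tagged[tagged$contig == ctg, , drop = FALSE]
    t <- t[order(t$junction), , drop = FALSE]
    brk <- c(0L, cumsum(diff(t$junction) > cluster_window))
    for (b in unique(brk)) {
      cl <- t[brk == b, , drop = FALSE]
      samples <- sort(unique(cl$sample))
      counts <- do.call(rbind, lapply(samples, function(s) {
        data.frame(sample = s,
                   n_right = sum(cl$sample == s & cl$orientation == "right"),
                   n_left = sum(cl$sample == s & cl$orientation == "left"),
                   stringsAsFactors = FALSE)
      }))
      out[[length(out) + 1]] <- data.frame(
        contig = ctg, junction = as.integer(round(median(cl$junction))),
        n_reads = nrow(cl),
        bidirectional = any(counts$n_right > 0 & counts$n_left > 0),
        counts = I(list(counts)), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$junction), , drop = FALSE]
  res$cluster_id <- sprintf("cl_%04d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res[, c("cluster_id", "contig", "junction", "n_reads", "bidirectional",
          "counts")]
}

#' Preprocess and map one sample end to end
#'
#' Convenience wrapper: [preprocess_tagseq_reads()] then [map_reads()],
#' returning the merged per-read table [umi_consensus()] consumes.
#' @param reads FASTQ path or read data frame (read 1).
#' @param genome Reference.
#' @param sample Sample label attached to every read.
#' @param read_structure,tag_sequence,max_tag_mismatches See
#'   [preprocess_tagseq_reads()].
#' @param ... Passed to [map_reads()].
#' @return Annotated, mapped read data frame.
#' @export
preprocess_sample <- function(reads, genome, sample,
                              read_structure = "8M+T",
                              tag_sequence = default_tag(),
                              max_tag_mismatches = NULL, ...) {
  ann <- preprocess_tagseq_reads(reads, read_structure, tag_sequence,
                                 max_tag_mismatches)
  aln <- map_reads(ann$genomic, genome, ...)
  cbind(sample = sample, ann, aln[, c("contig", "pos", "strand", "nm",
                                      "status")])
}
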