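#' In silico genome-wide off-target search
#'
#' Mismatch- and indel-tolerant scan for the guide over both strands of
#' every contig. A compiled semi-global DP computes, for every end
#' position, the best edit distance of the spacer against a window ending
#' there (complete by construction -- no seeding heuristics); candidate
#' ends are verified with the glocal aligner, gated on the PAM rule, and
#' same-strand hits within 3 bp collapse to the best-distance one.
#'
#' @param genome A `synth_genome` or named character vector.
#' @param guide A [guide_spec()].
#' @param max_distance Maximum Levenshtein distance reported.
#' @param pam_mode `"strict"` (guide PAM), `"relaxed"` (NGG|NAG) or
#'   `"none"`.
#' @return Data frame of hits: `contig`, `start`, `end` (protospacer,
#'   0-based half-open, genome + strand), `strand`, `sequence`,
#'   `levenshtein`, `mismatches`, `insertions`, `deletions`, `pam`,
#'   `population_dependent` (FALSE here), `variant_ids` (NA).
#' @export
search_genome <- function(genome, guide, max_distance = 5L,
                          pam_mode = c("strict", "relaxed", "none")) {
  pam_mode <- match.arg(pam_mode)
  seqs <- genome_seqs(genome)
  if (!length(seqs) || all(!nzchar(seqs)))
    stop("empty genome", call. = FALSE)
  if (max_distance > nchar(guide$spacer))
    stop("max_distance exceeds spacer length", call. = FALSE)
  pams <- switch(pam_mode, strict = guide$pam, relaxed = c("NGG", "NAG"),
                 none = NULL)
  n <- nchar(guide$spacer)
  plen <- nchar(guide$pam)
  hits <- list()
  for (ctg in names(seqs)) {
    fwd <- seqs[[ctg]]
    L <- nchar(fwd)
    for (strand in c("+", "-")) {
      txt <- if (strand == "+") fwd else revcomp(fwd)
      dists <- .scan_text_cpp(guide$spacer, txt)
      cand <- which(dists <= max_distance)          # 1-based end positions
      for (e in cand) {
        pam_seq <- substr(txt, e + 1L, e + plen)
        if (!is.null(pams) &&
            !any(vapply(pams, function(p) pam_matches(pam_seq, p),
                        logical(1)))) next
        ws <- max(0L, e - n - max_distance)
        a <- .glocal_align_cpp(guide$spacer, substr(txt, ws + 1L, e),
                               anchor_end = TRUE)
        s_txt <- ws + a$start; e_txt <- e                 # scan-orientation
        if (strand == "+") { gs <- s_txt; ge <- e_txt }
        else { gs <- L - e_txt; ge <- L - s_txt }
        hits[[length(hits) + 1]] <- data.frame(
          contig = ctg, start = gs, end = ge, strand = strand,
          sequence = substr(txt, s_txt + 1L, e_txt),
          levenshtein = a$distance, mismatches = a$mismatches,
          insertions = a$insertions, deletions = a$deletions,
          pam = pam_seq, end_scan = e_txt, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(empty_hits())
  out <- do.call(rbind, hits)
  out <- collapse_hits(out, within = 3L)
  out$end_scan <- NULL
  out$population_dependent <- FALSE
  out$variant_ids <- NA_character_
  rownames(out) <- NULL
  out[order(out$contig, out$start, out$strand), ]
}

empty_hits <- function() {
  data.frame(contig = character(0), start = integer(0), end = integer(0),
             strand = character(0), sequence = character(0),
             levenshtein = integer(0), mismatches = integer(0),
             insertions = integer(0), deletions = integer(0),
             pam = character(0), population_dependent = logical(0),
             variant_ids = character(0), stringsAsFactors = FALSE)
}

# Same-strand hits whose alignment ends (in scan orientation) lie within
# `within` bp collapse to the best-distance (ties: leftmost-end)
# representative.
collapse_hits <- function(hits, within = 3L) {
  if (is.null(hits$end_scan)) hits$end_scan <- hits$end
  key <- paste(hits$contig, hits$strand)
  out <- lapply(split(hits, key), function(h) {
    h <- h[order(h$end_scan), , drop = FALSE]
    brk <- c(0L, cumsum(diff(h$end_scan) > within))
    do.call(rbind, lapply(split(h, brk), function(g) {
      g[order(g$levenshtein, g$end_scan), , drop = FALSE][1, , drop = FALSE]
    }))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a minimal VCF of population variants
#'
#' Parses the SNV/short-indel subset with an `AF=` INFO field (maximum
#' allele frequency across populations precomputed upstream).
#' @param path VCF file (plain text).
#' @return Data frame: `id`, `contig`, `pos` (0-based), `ref`, `alt`, `af`.
#' @export
read_population_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(id = character(0), contig = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), af = numeric(0)))
  f <- strsplit(lines, "\t")
  bad <- which(lengths(f) < 8)
  if (length(bad))
    stop("malformed VCF record at data line ", bad[1], call. = FALSE)
  info <- vapply(f, `[[`, "", 8)
  af_raw <- regmatches(info, regexec("(?:^|;)AF=([0-9.eE+-]+)", info))
  no_af <- which(vapply(af_raw, length, integer(1)) < 2)
  if (length(no_af)) {
    id0 <- vapply(f, `[[`, "", 3)
    stop("VCF record without AF field: ", id0[no_af[1]], call. = FALSE)
  }
  data.frame(
    id = vapply(f, `[[`, "", 3),
    contig = vapply(f, `[[`, "", 1),
    pos = as.integer(vapply(f, `[[`, "", 2)) - 1L,
    ref = vapply(f, `[[`, "", 4),
    alt = vapply(f, `[[`, "", 5),
    af = as.numeric(vapply(af_raw, `[[`, "", 2)),
    stringsAsFactors = FALSE)
}

#' Variant-aware expansion of the in silico search
#'
#' For every qualifying variant (allele frequency above `af_threshold`),
#' the local neighborhood is rebuilt on the alternate allele and
#' re-searched; hits reachable only through the alternate sequence are
#' reported as population dependent, with the supporting variant recorded.
#'
#' @param genome Reference.
#' @param vcf Variant data frame from [read_population_vcf()] or a VCF
#'   path.
#' @param guide A [guide_spec()].
#' @param max_distance,pam_mode As in [search_genome()].
#' @param af_threshold Minimum allele frequency (default 0.01, i.e. >1%).
#' @param reference_hits Hits from [search_genome()] on the reference;
#'   computed if missing (used to decide which alternate hits are new).
#' @return Data frame of additional, population-dependent hits (same shape
#'   as [search_genome()] output).
#' @export
expand_with_variants <- function(genome, vcf, guide, max_distance = 5L,
                                 pam_mode = "strict", af_threshold = 0.01,
                                 reference_hits = NULL) {
  if (is.character(vcf) && length(vcf) == 1) vcf <- read_population_vcf(vcf)
  seqs <- genome_seqs(genome)
  if (is.null(reference_hits))
    reference_hits <- search_genome(genome, guide, max_distance, pam_mode)
  vcf <- vcf[vcf$af > af_threshold, , drop = FALSE]
  n <- nchar(guide$spacer)
  halo <- n + nchar(guide$pam) + max_distance + 5L
  out <- empty_hits()
  for (i in seq_len(nrow(vcf))) {
    v <- vcf[i, ]
    if (!v$contig %in% names(seqs)) next
    ctg <- seqs[[v$contig]]
    ref_here <- substr(ctg, v$pos + 1L, v$pos + nchar(v$ref))
    if (ref_here != v$ref) next       # stale record; skip defensively
    a <- max(0L, v$pos - halo)
    b <- min(nchar(ctg), v$pos + nchar(v$ref) + halo)
    alt_local <- paste0(substr(ctg, a + 1L, v$pos),
                        v$alt,
                        substr(ctg, v$pos + nchar(v$ref) + 1L, b))
    mini <- stats::setNames(alt_local, v$contig)
    alt_hits <- search_genome(mini, guide, max_distance, pam_mode)
    if (!nrow(alt_hits)) next
    # a hit is new if no reference hit sits at the matching locus
    shift <- nchar(v$alt) - nchar(v$ref)
    for (j in seq_len(nrow(alt_hits))) {
      h <- alt_hits[j, ]
      # map local coordinate back to the reference frame (approximately:
      # positions right of the variant shift by the allele-length delta)
      gstart <- a + h$start - if (h$start > (v$pos - a)) shift else 0L
      near <- reference_hits$contig == v$contig &
        reference_hits$strand == h$strand &
        abs(reference_hits$start - gstart) <= 3L
      if (any(near)) next
      h$contig <- v$contig
      h$start <- gstart
      h$end <- gstart + (h$end - alt_hits$start[j])
      h$population_dependent <- TRUE
      h$variant_ids <- v$id
      out <- rbind(out, h)
    }
  }
  rownames(out) <- NULL
  out
}
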