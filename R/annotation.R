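#' Annotate a genomic site against gene models
#'
#' Classifies a site as exonic, intronic, 5'/3' flanking, or intergenic
#' with precedence exonic > intronic > flanking > intergenic across all
#' overlapping genes (order-independent with respect to gene-model file
#' order). Intron ordinals respect gene strand: "intron 1 of 4" is the
#' intron following the first exon in transcription order.
#'
#' @param contig,start,end Site interval (0-based half-open); a point site
#'   may pass `end = start + 1`.
#' @param genes Gene-model data frame (see [read_gff_lite()]).
#' @param flanking_width Width of the 5'/3' flanking regions, in bases.
#' @return List of class `genomic_annotation`: `class`, `gene`, `detail`,
#'   `distance_to_gene`, `overlapping_genes`.
#' @export
annotate_interval <- function(contig, start, end, genes,
                              flanking_width = 2000L) {
  g <- genes[genes$contig == contig, , drop = FALSE]
  known <- unique(genes$contig)
  if (!contig %in% known && nrow(genes))
    stop("site on unknown contig: ", contig, call. = FALSE)
  best <- list(class = "intergenic", gene = NA_character_,
               detail = NA_character_, distance_to_gene = NA_real_,
               overlapping_genes = character(0))
  rank <- c(exonic = 4, intronic = 3, flanking_5prime = 2,
            flanking_3prime = 2, intergenic = 1)
  dists <- numeric(0)
  for (i in seq_len(nrow(g))) {
    es <- sort(g$exon_starts[[i]]); ee <- sort(g$exon_ends[[i]])
    cls <- NULL; detail <- NA_character_
    if (start < g$tx_end[i] && end > g$tx_start[i]) {
      best$overlapping_genes <- c(best$overlapping_genes, g$name[i])
      if (any(start < ee & end > es)) {
        cls <- "exonic"
        ex <- which(start < ee & end > es)[1]
        ord <- if (g$strand[i] == "+") ex else length(es) - ex + 1L
        detail <- sprintf("exon %d of %d", ord, length(es))
      } else {
        cls <- "intronic"
        # intron k lies between exon k and k+1 in genomic order
        k <- if (any(ee <= start)) max(which(ee <= start)) else 1L
        n_introns <- length(es) - 1L
        ord <- if (g$strand[i] == "+") k else n_introns - k + 1L
        detail <- sprintf("intron %d of %d", ord, n_introns)
      }
      d <- 0
    } else {
      d <- if (end <= g$tx_start[i]) g$tx_start[i] - end + 1L
           else start - g$tx_end[i] + 1L
      if (d <= flanking_width) {
        upstream <- end <= g$tx_start[i]
        five_prime <- (upstream && g$strand[i] == "+") ||
          (!upstream && g$strand[i] == "-")
        cls <- if (five_prime) "flanking_5prime" else "flanking_3prime"
        detail <- sprintf("%d bp %s of %s", d,
                          if (five_prime) "5'" else "3'", g$name[i])
      }
    }
    dists <- c(dists, d)
    if (!is.null(cls) && rank[[cls]] > rank[[best$class]]) {
      best$class <- cls; best$gene <- g$name[i]; best$detail <- detail
      best$distance_to_gene <- d
    }
  }
  if (best$class == "intergenic")
    best$distance_to_gene <- if (length(dists)) min(dists) else NA_real_
  class(best) <- "genomic_annotation"
  best
}

#' Annotate a table of sites
#' @param sites Data frame with `contig` and `cut` (or `start`/`end`).
#' @param genes Gene models.
#' @param flanking_width See [annotate_interval()].
#' @return `sites` with `annotation`, `gene`, `annotation_detail` columns.
#' @export
annotate_sites <- function(sites, genes, flanking_width = 2000L) {
  if (!nrow(sites)) {
    sites$annotation <- character(0); sites$gene <- character(0)
    sites$annotation_detail <- character(0)
    return(sites)
  }
  s0 <- if ("start" %in% names(sites)) sites$start else sites$cut
  e0 <- if ("end" %in% names(sites)) sites$end else sites$cut + 1L
  ann <- lapply(seq_len(nrow(sites)), function(i)
    annotate_interval(sites$contig[i], s0[i], e0[i], genes, flanking_width))
  sites$annotation <- vapply(ann, `[[`, "", "class")
  sites$gene <- vapply(ann, `[[`, "", "gene")
  sites$annotation_detail <- vapply(ann, `[[`, "", "detail")
  sites
}

#' Annotation composition of a site set
#'
#' @param classes Character vector of annotation classes (or a data frame
#'   with an `annotation` column).
#' @return Data frame of class counts and full-precision fractions.
#' @export
annotation_summary <- function(classes) {
  if (is.data.frame(classes)) classes <- classes$annotation
  if (!length(classes))
    return(data.frame(class = character(0), count = integer(0),
                      fraction = numeric(0)))
  tab <- table(classes)
  data.frame(class = names(tab), count = as.integer(tab),
             fraction = as.integer(tab) / length(classes),
             stringsAsFactors = FALSE, row.names = NULL)
}
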