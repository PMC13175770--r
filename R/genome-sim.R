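#' Configure a synthetic reference genome
#'
#' Describes the substrate the simulators write: random contigs with a
#' controlled GC content, homopolymer tracts planted verbatim (the error
#' model treats them as elevated-indel-error motifs, as such tracts are for
#' short-read sequencers), and simple gene models used by the annotation
#' classifier.
#'
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig, in bases.
#' @param gc_fraction GC content of the random background, in (0,1).
#' @param homopolymer_tracts Data frame with columns `contig` (1-based
#'   index), `start` (0-based), `base`, `length`; may be `NULL`.
#' @param gene_models Gene-model data frame (columns `name`, `contig`,
#'   `tx_start`, `tx_end`, `strand`, list columns `exon_starts`,
#'   `exon_ends`; 0-based half-open); `NULL` for a default three-gene layout.
#' @param seed Integer seed; identical config + seed gives a byte-identical
#'   genome.
#' @return An object of class `synth_genome_config`.
#' @export
synth_genome_config <- function(n_contigs = 1L, contig_length = 1e6,
                                gc_fraction = 0.41,
                                homopolymer_tracts = NULL,
                                gene_models = NULL, seed = 1L) {
  stopifnot(n_contigs >= 1, contig_length >= 100,
            gc_fraction > 0, gc_fraction < 1)
  if (is.null(gene_models))
    gene_models <- default_gene_models(n_contigs, contig_length)
  validate_gene_models(gene_models, n_contigs, contig_length)
  if (!is.null(homopolymer_tracts)) {
    ht <- homopolymer_tracts
    if (any(ht$contig < 1 | ht$contig > n_contigs))
      stop("homopolymer tract on unknown contig", call. = FALSE)
    if (any(ht$start < 0 | ht$start + ht$length > contig_length))
      stop("homopolymer tract out of contig bounds", call. = FALSE)
  }
  structure(list(n_contigs = as.integer(n_contigs),
                 contig_length = as.integer(contig_length),
                 gc_fraction = gc_fraction,
                 homopolymer_tracts = homopolymer_tracts,
                 gene_models = gene_models, seed = as.integer(seed)),
            class = "synth_genome_config")
}

default_gene_models <- function(n_contigs, contig_length) {
  # three genes on contig 1: multi-exon +, multi-exon -, two-exon +
  L <- contig_length
  at <- function(f) as.integer(round(f * L))
  g <- data.frame(
    name = c("GENE_A", "GENE_B", "GENE_C"),
    contig = "contig_1",
    tx_start = c(at(0.10), at(0.40), at(0.70)),
    tx_end = c(at(0.16), at(0.46), at(0.73)),
    strand = c("+", "-", "+"),
    stringsAsFactors = FALSE)
  span <- g$tx_end - g$tx_start
  g$exon_starts <- list(
    g$tx_start[1] + as.integer(round(span[1] * c(0, 0.3, 0.6, 0.9))),
    g$tx_start[2] + as.integer(round(span[2] * c(0, 0.35, 0.7))),
    g$tx_start[3] + as.integer(round(span[3] * c(0, 0.8))))
  g$exon_ends <- list(
    g$tx_start[1] + as.integer(round(span[1] * c(0.1, 0.4, 0.7, 1.0))),
    g$tx_start[2] + as.integer(round(span[2] * c(0.1, 0.45, 1.0))),
    g$tx_start[3] + as.integer(round(span[3] * c(0.1, 1.0))))
  g
}

validate_gene_models <- function(genes, n_contigs, contig_length) {
  for (i in seq_len(nrow(genes))) {
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    if (length(es) != length(ee) || any(ee <= es))
      stop("gene ", genes$name[i], ": malformed exon intervals", call. = FALSE)
    if (any(es < genes$tx_start[i]) || any(ee > genes$tx_end[i]))
      stop("gene ", genes$name[i],
           ": exon outside transcript interval", call. = FALSE)
    if (genes$tx_start[i] < 0 || genes$tx_end[i] > contig_length)
      stop("gene ", genes$name[i], ": outside contig bounds", call. = FALSE)
  }
  invisible(TRUE)
}

#' Generate the synthetic reference genome
#'
#' Draws random contigs at the configured GC content, plants the requested
#' homopolymer tracts verbatim, and attaches the gene models. Deterministic
#' under the config seed.
#'
#' @param config A [synth_genome_config()].
#' @param outdir Optional directory; when given, writes `reference.fa`,
#'   `genes.gff`, and `tracts.bed`.
#' @return A `synth_genome` list with elements `seqs` (named character
#'   vector), `genes`, `tracts`, and `config`.
#' @export
make_reference <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "synth_genome_config"))
  seqs <- with_seed(config$seed, {
    vapply(seq_len(config$n_contigs), function(i)
      random_dna(config$contig_length, config$gc_fraction), character(1))
  })
  names(seqs) <- paste0("contig_", seq_len(config$n_contigs))
  ht <- config$homopolymer_tracts
  if (!is.null(ht)) {
    for (i in seq_len(nrow(ht))) {
      s <- seqs[[ht$contig[i]]]
      substr(s, ht$start[i] + 1L, ht$start[i] + ht$length[i]) <-
        strrep(ht$base[i], ht$length[i])
      seqs[[ht$contig[i]]] <- s
    }
  }
  genome <- structure(list(seqs = seqs, genes = config$gene_models,
                           tracts = ht, config = config),
                      class = "synth_genome")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fasta_genome(seqs, file.path(outdir, "reference.fa"))
    write_gff_lite(config$gene_models, file.path(outdir, "genes.gff"))
    if (!is.null(ht)) {
      bed <- data.frame(contig = names(seqs)[ht$contig], start = ht$start,
                        end = ht$start + ht$length,
                        name = paste0("tract_", ht$base, ht$length),
                        score = 0, strand = ".")
      write_bed6(bed, file.path(outdir, "tracts.bed"))
    }
  }
  genome
}

genome_seqs <- function(genome) {
  if (inherits(genome, "synth_genome")) genome$seqs
  else if (is.character(genome) && !is.null(names(genome))) genome
  else stop("expected a synth_genome or a named character vector",
            call. = FALSE)
}

# Mutate `seq` into a variant at exactly `d` Levenshtein edits (verified
# against the DP distance, since random edits can cancel).
variant_at_distance <- function(seq, d, max_tries = 200L) {
  if (d == 0) return(seq)
  if (d > nchar(seq)) stop("requested edit distance exceeds spacer length",
                           call. = FALSE)
  bases <- c("A", "C", "G", "T")
  for (try in seq_len(max_tries)) {
    v <- strsplit(seq, "")[[1]]
    for (k in seq_len(d)) {
      op <- sample(c("sub", "ins", "del"), 1, prob = c(0.7, 0.15, 0.15))
      i <- sample(length(v), 1)
      if (op == "sub") v[i] <- sample(setdiff(bases, v[i]), 1)
      else if (op == "ins") v <- append(v, sample(bases, 1), after = i)
      else if (length(v) > 1) v <- v[-i]
    }
    cand <- paste(v, collapse = "")
    if (adist(seq, cand) == d) return(cand)
  }
  stop("could not realize requested edit distance ", d, call. = FALSE)
}

region_class_of <- function(genes, contig, start, end) {
  g <- genes[genes$contig == contig, , drop = FALSE]
  cls <- "intergenic"
  for (i in seq_len(nrow(g))) {
    if (end <= g$tx_start[i] || start >= g$tx_end[i]) next
    es <- g$exon_starts[[i]]; ee <- g$exon_ends[[i]]
    if (any(start < ee & end > es)) return("exonic")
    cls <- "intronic"
  }
  cls
}

#' Plant off-target protospacers in a synthetic genome
#'
#' Writes protospacer variants at controlled Levenshtein distances from the
#' guide spacer (plus a concrete NGG PAM) into requested region classes, and
#' records the ground truth. The realized distance of every planted
#' protospacer is re-verified with an independent dynamic-programming edit
#' distance before it is accepted.
#'
#' @param genome A `synth_genome` from [make_reference()].
#' @param guide A [guide_spec()].
#' @param requests Data frame with columns `distance` and `region_class`
#'   (exonic/intronic/intergenic); optional columns `strand`,
#'   `integration_rate`, `editing_fraction`.
#' @param seed Integer seed for placement and variant generation.
#' @return List with the updated `genome` and `truth`, a data frame of
#'   planted sites (0-based half-open loci, strand, planted protospacer+PAM,
#'   verified edit distance, rates).
#' @export
plant_offtarget_sites <- function(genome, guide, requests, seed = 1L) {
  stopifnot(inherits(genome, "synth_genome"), inherits(guide, "guide_spec"))
  if (any(requests$distance > nchar(guide$spacer)))
    stop("requested edit distance exceeds spacer length", call. = FALSE)
  if (is.null(requests$strand)) requests$strand <- NA
  if (is.null(requests$integration_rate)) requests$integration_rate <- 0.01
  if (is.null(requests$editing_fraction)) requests$editing_fraction <- 0.005
  pam_concrete <- "TGG"     # a concrete NGG

  out <- with_seed(seed, {
    seqs <- genome$seqs
    genes <- genome$genes
    placed <- data.frame()
    occupied <- list()
    for (i in seq_len(nrow(requests))) {
      d <- requests$distance[i]
      cls <- requests$region_class[i]
      proto <- variant_at_distance(guide$spacer, d)
      site_len <- nchar(proto) + nchar(pam_concrete)
      strand <- requests$strand[i]
      if (is.na(strand)) strand <- sample(c("+", "-"), 1)
      ok <- FALSE
      for (try in seq_len(500L)) {
        contig <- sample(names(seqs), 1)
        L <- nchar(seqs[[contig]])
        pos <- sample(L - site_len - 10L, 1)
        if (region_class_of(genes, contig, pos, pos + site_len) != cls) next
        hit <- FALSE
        for (o in occupied)
          if (o$contig == contig && pos < o$end + 50 && pos + site_len >
              o$start - 50) { hit <- TRUE; break }
        if (hit) next
        cassette <- paste0(proto, pam_concrete)
        if (strand == "-") cassette <- revcomp(cassette)
        s <- seqs[[contig]]
        substr(s, pos + 1L, pos + site_len) <- cassette
        seqs[[contig]] <- s
        # protospacer interval excludes PAM
        if (strand == "+") {
          ps <- pos; pe <- pos + nchar(proto)
        } else {
          ps <- pos + nchar(pam_concrete); pe <- pos + site_len
        }
        placed <- rbind(placed, data.frame(
          site_id = sprintf("OT_%02d", i), contig = contig,
          start = ps, end = pe, strand = strand,
          planted_sequence = paste0(proto, pam_concrete),
          edit_distance = as.integer(adist(guide$spacer, proto)),
          region_class = cls,
          integration_rate = requests$integration_rate[i],
          editing_fraction = requests$editing_fraction[i],
          stringsAsFactors = FALSE))
        occupied[[length(occupied) + 1]] <-
          list(contig = contig, start = pos, end = pos + site_len)
        ok <- TRUE
        break
      }
      if (!ok) stop("no room for request ", i, " in region class ", cls,
                    call. = FALSE)
    }
    list(seqs = seqs, truth = placed)
  })
  genome$seqs <- out$seqs
  list(genome = genome, truth = out$truth)
}

#' Assemble a simulation truth table
#'
#' Combines the on-target site, planted off-target sites, and a sample plan
#' (biological-triplicate treatment/control by default) into the ground
#' truth the read simulators and recovery tests consume.
#'
#' @param on_target One-row truth data frame for the on-target site (as
#'   produced by [plant_offtarget_sites()] with distance 0).
#' @param sites Truth data frame of planted off-target sites (may be empty).
#' @param n_treatment,n_control Replicate counts (default 3 + 3).
#' @param depth Read pairs per sample.
#' @return An object of class `truth_table`.
#' @export
truth_table <- function(on_target, sites,
                        n_treatment = 3L, n_control = 3L, depth = 50000L) {
  stopifnot(nrow(on_target) == 1, n_treatment >= 1, n_control >= 1)
  plan <- data.frame(
    sample = c(sprintf("treat_%d", seq_len(n_treatment)),
               sprintf("ctrl_%d", seq_len(n_control))),
    role = rep(c("treatment", "control"), c(n_treatment, n_control)),
    replicate = c(seq_len(n_treatment), seq_len(n_control)),
    depth = as.integer(depth), stringsAsFactors = FALSE)
  on_target$site_id <- "ON"
  structure(list(on_target = on_target, sites = sites, sample_plan = plan),
            class = "truth_table")
}

all_truth_sites <- function(truth) {
  rbind(truth$on_target, truth$sites)
}
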