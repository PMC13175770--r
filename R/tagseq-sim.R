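#' Simulate a tag-integration (dsODN) sequencing run
#'
#' Emulates a GUIDE-seq-style experiment: in treatment samples a fraction of
#' read pairs derive from double-strand-break junctions at the on-target and
#' planted off-target loci, carrying the dsODN tag at the junction in either
#' orientation; the remainder (and all control-sample reads) are random
#' genomic background fragments. Read 1 follows the declared structure:
#' UMI, then tag (junction reads only), then genomic sequence.
#'
#' @param genome A `synth_genome`.
#' @param truth A [truth_table()].
#' @param guide A [guide_spec()].
#' @param em An [error_model()].
#' @param tag_sequence The dsODN junction tag carried by break-derived reads.
#' @param umi_length UMI length in bases (read-1 prefix).
#' @param read_length Read length after the UMI+tag prefix is included.
#' @param mispriming_rate Fraction of control/background reads that carry a
#'   spurious tag (stress-test knob; default 0).
#' @param seed Integer seed; output is byte-identical under a fixed seed.
#' @param outdir Optional directory; writes `<sample>_R1.fastq`,
#'   `<sample>_R2.fastq` and `truth_integrations.tsv`.
#' @return A `tagseq_run` list: per-sample reads (`id`, `r1`, `q1`, `r2`,
#'   `q2`) and the per-sample, per-site truth integration table.
#' @export
simulate_tagseq_run <- function(genome, truth, guide, em = error_model(),
                                tag_sequence = default_tag(),
                                umi_length = 8L, read_length = 150L,
                                mispriming_rate = 0, seed = 1L,
                                outdir = NULL) {
  stopifnot(inherits(truth, "truth_table"), nzchar(tag_sequence))
  if (any(truth$sample_plan$depth <= 0))
    stop("sample depth must be positive", call. = FALSE)
  seqs <- genome_seqs(genome)
  sites <- all_truth_sites(truth)
  sites$cut <- cut_position(sites$start, sites$end, sites$strand, guide)
  glen <- read_length - umi_length - nchar(tag_sequence)
  if (glen < 31L)
    stop("read_length too short for UMI + tag + mappable genomic part",
         call. = FALSE)

  run <- with_seed(seed, {
    samples <- list()
    truth_rows <- data.frame()
    for (si in seq_len(nrow(truth$sample_plan))) {
      plan <- truth$sample_plan[si, ]
      depth <- plan$depth
      is_treat <- plan$role == "treatment"
      n_site <- if (is_treat) round(depth * sites$integration_rate)
                else rep(0L, nrow(sites))
      n_site <- pmin(n_site, depth)
      if (sum(n_site) > depth) n_site <- floor(n_site * depth / sum(n_site))
      n_bg <- depth - sum(n_site)

      r1 <- character(0); origin <- character(0)
      # junction reads
      for (k in seq_len(nrow(sites))) {
        n <- n_site[k]
        if (n == 0) next
        ctg <- seqs[[sites$contig[k]]]
        j <- sites$cut[k]
        ori <- sample(c("right", "left"), n, replace = TRUE)
        gpart <- character(n)
        right <- ori == "right"
        if (any(right))
          gpart[right] <- substr(rep(ctg, sum(right)), j + 1L, j + glen)
        if (any(!right))
          gpart[!right] <- revcomp(substr(rep(ctg, sum(!right)),
                                          j - glen + 1L, j))
        umis <- random_dna_vec(n, umi_length)
        r1 <- c(r1, paste0(umis, tag_sequence, gpart))
        origin <- c(origin, rep(sites$site_id[k], n))
      }
      # background fragments
      if (n_bg > 0) {
        ctgn <- sample(names(seqs), n_bg, replace = TRUE)
        lens <- nchar(seqs)[ctgn]
        pos <- floor(runif(n_bg) * (lens - read_length - 1)) + 1L
        frag <- substr(seqs[ctgn], pos, pos + read_length - 1L)
        flip <- runif(n_bg) < 0.5
        frag[flip] <- revcomp(frag[flip])
        umis <- random_dna_vec(n_bg, umi_length)
        mis <- runif(n_bg) < mispriming_rate
        body <- ifelse(mis,
                       paste0(tag_sequence, substr(frag, 1L, glen)),
                       substr(frag, 1L, read_length - umi_length))
        r1 <- c(r1, paste0(umis, body))
        origin <- c(origin, rep("background", n_bg))
      }
      # mate: genomic continuation (not used downstream, format fidelity)
      r2 <- revcomp(substr(r1, umi_length + 1L, nchar(r1)))
      r1 <- apply_substitutions(r1, em$substitution_rate)
      r2 <- apply_substitutions(r2, em$substitution_rate)
      ids <- sprintf("%s_read_%06d", plan$sample, seq_along(r1))
      q1 <- draw_quality_strings(nchar(r1), em)
      q2 <- draw_quality_strings(nchar(r2), em)
      samples[[plan$sample]] <- list(id = ids, r1 = r1, q1 = q1,
                                     r2 = r2, q2 = q2, origin = origin)
      tr <- data.frame(sample = plan$sample, role = plan$role,
                       site_id = sites$site_id, contig = sites$contig,
                       cut = sites$cut,
                       expected_reads = if (is_treat)
                         round(depth * sites$integration_rate) else 0L,
                       realized_reads = n_site, stringsAsFactors = FALSE)
      truth_rows <- rbind(truth_rows, tr)
    }
    list(samples = samples, truth_integrations = truth_rows)
  })
  run$tag_sequence <- tag_sequence
  run$umi_length <- umi_length
  class(run) <- "tagseq_run"
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (s in names(run$samples)) {
      x <- run$samples[[s]]
      write_fastq(x$id, x$r1, x$q1, file.path(outdir, paste0(s, "_R1.fastq")))
      write_fastq(x$id, x$r2, x$q2, file.path(outdir, paste0(s, "_R2.fastq")))
    }
    write_tsv(run$truth_integrations,
              file.path(outdir, "truth_integrations.tsv"))
  }
  run
}

#' Default dsODN tag sequence
#'
#' The study does not print its dsODN; this 16-mer is the package's
#' documented, configurable default junction tag.
#' @return A character scalar.
#' @export
default_tag <- function() "ACGTCTGAGTCGGAGC"
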