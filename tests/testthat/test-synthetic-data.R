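test_that("make_reference plants tracts verbatim and is deterministic", {
  tr <- data.frame(contig = 1L, start = 5000L, base = "A", length = 12L)
  cfg <- synth_genome_config(n_contigs = 1L, contig_length = 100000L,
                             homopolymer_tracts = tr, seed = 5L)
  g1 <- make_reference(cfg)
  g2 <- make_reference(cfg)
  expect_identical(g1$seqs, g2$seqs)
  expect_equal(substr(g1$seqs[["contig_1"]], 5001, 5012), strrep("A", 12))
  expect_equal(nchar(g1$seqs[["contig_1"]]), 100000L)

  # written FASTA bytes are identical too
  d1 <- tempfile(); d2 <- tempfile()
  make_reference(cfg, outdir = d1); make_reference(cfg, outdir = d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "reference.fa"))),
                   unname(tools::md5sum(file.path(d2, "reference.fa"))))
})

test_that("invalid gene models and tracts are rejected", {
  genes <- data.frame(name = "G", contig = "contig_1", tx_start = 100L,
                      tx_end = 200L, strand = "+", stringsAsFactors = FALSE)
  genes$exon_starts <- list(c(100L))
  genes$exon_ends <- list(c(300L))     # exon beyond transcript
  expect_error(synth_genome_config(contig_length = 1000L,
                                   gene_models = genes),
               "exon outside transcript")
  expect_error(synth_genome_config(
    contig_length = 1000L,
    homopolymer_tracts = data.frame(contig = 1L, start = 990L, base = "A",
                                    length = 20L)),
    "out of contig bounds")
})

test_that("planted off-target distances are verified by an independent DP oracle", {
  genome <- tiny_genome(40000L)
  g <- demo_guide()
  req <- data.frame(distance = c(0L, 2L, 4L),
                    region_class = c("intergenic", "intronic", "intergenic"))
  res <- plant_offtarget_sites(genome, g, req, seed = 3L)
  expect_equal(nrow(res$truth), 3)
  for (i in 1:3) {
    t <- res$truth[i, ]
    proto <- substr(t$planted_sequence, 1, nchar(t$planted_sequence) - 3)
    expect_equal(drop(adist(g$spacer, proto)), req$distance[i])
    expect_equal(t$edit_distance, req$distance[i])
    # the genome really contains the cassette at the recorded locus
    ctg <- res$genome$seqs[[t$contig]]
    span <- if (t$strand == "+")
      substr(ctg, t$start + 1, t$end + 3)
    else as.character(Biostrings::reverseComplement(Biostrings::DNAString(
      substr(ctg, t$start - 2, t$end))))
    expect_equal(span, t$planted_sequence)
  }
  # distance-0 plant is spacer + NGG verbatim
  t0 <- res$truth[1, ]
  expect_equal(substr(t0$planted_sequence, 1, 20), g$spacer)
  # intronic request landed in an intron
  t2 <- res$truth[2, ]
  ann <- annotate_interval(t2$contig, t2$start, t2$end, genome$genes)
  expect_equal(ann$class, "intronic")
})

test_that("impossible planting requests error", {
  genome <- tiny_genome(20000L)
  g <- demo_guide()
  expect_error(plant_offtarget_sites(
    genome, g, data.frame(distance = 25L, region_class = "intergenic")),
    "exceeds spacer length")
})

test_that("tag-integration simulation is deterministic and respects rates", {
  genome <- tiny_genome(30000L)
  g <- demo_guide()
  res <- plant_offtarget_sites(
    genome, g,
    data.frame(distance = c(0L, 2L), region_class = "intergenic",
               integration_rate = c(0.05, 0)), seed = 2L)
  truth <- truth_table(res$truth[1, ], res$truth[2, ],
                       n_treatment = 1L, n_control = 1L, depth = 500L)
  em0 <- error_model(substitution_rate = 0, base_indel_error_rate = 0)
  r1 <- simulate_tagseq_run(res$genome, truth, g, em0, seed = 9L)
  r2 <- simulate_tagseq_run(res$genome, truth, g, em0, seed = 9L)
  expect_identical(r1$samples, r2$samples)

  tr <- r1$truth_integrations
  # zero-rate site gets no reads; controls get none at all
  expect_equal(tr$realized_reads[tr$site_id == "OT_02" &
                                   tr$role == "treatment"], 0L)
  expect_true(all(tr$realized_reads[tr$role == "control"] == 0L))
  # read counts conserve the sample plan depth
  expect_equal(unname(vapply(r1$samples, function(s) length(s$r1),
                             integer(1))),
               truth$sample_plan$depth)
  # written FASTQ bytes identical under the same seed
  d1 <- tempfile(); d2 <- tempfile()
  simulate_tagseq_run(res$genome, truth, g, em0, seed = 9L, outdir = d1)
  simulate_tagseq_run(res$genome, truth, g, em0, seed = 9L, outdir = d2)
  f <- list.files(d1)
  expect_identical(unname(tools::md5sum(file.path(d1, f))),
                   unname(tools::md5sum(file.path(d2, f))))
  expect_error(simulate_tagseq_run(
    res$genome,
    truth_table(res$truth[1, ], res$truth[2, ], depth = 0L), g, em0),
    "depth")
})

test_that("amplicon counts follow the stated binomial", {
  assays <- data.frame(site_id = sprintf("s%03d", 1:1000),
                       tract_overlap = FALSE)
  em <- error_model(base_indel_error_rate = 0.001)
  f <- matrix(0.01, 1000, 1)
  counts <- simulate_amplicon_assay(assays, f, depths = 500L, em = em,
                                    mode = "counts", seed = 21L)
  p <- 0.01 + 0.001
  # chi-square goodness of fit against Binomial(500, p), pooled tails
  ks <- 0:15
  probs <- dbinom(ks, 500, p)
  obs <- tabulate(pmin(counts$indel, 15) + 1, nbins = 16)
  probs[16] <- 1 - sum(probs[1:15])
  keep <- probs * 1000 >= 5
  chi <- sum((obs[keep] - 1000 * probs[keep])^2 / (1000 * probs[keep]))
  pval <- pchisq(chi, sum(keep) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("homopolymer sites show multiplied background", {
  em <- error_model(base_indel_error_rate = 0.001,
                    homopolymer_multiplier = 5)
  assays <- data.frame(site_id = sprintf("s%03d", 1:1000),
                       tract_overlap = rep(c(TRUE, FALSE), 500))
  counts <- simulate_amplicon_assay(assays, matrix(0, 1000, 1),
                                    depths = 2000L, em = em,
                                    mode = "counts", seed = 33L)
  tract <- counts$indel[assays$tract_overlap] / 2000
  plain <- counts$indel[!assays$tract_overlap] / 2000
  expect_equal(mean(tract) / mean(plain), 5, tolerance = 0.15)
})

test_that("reads-mode extremes behave", {
  assay <- data.frame(site_id = "s1",
                      seq = paste0(strrep("ACGT", 30), "T",
                                   strrep("GTCA", 30)),
                      cut = 60L, tract_overlap = FALSE)
  em0 <- error_model(substitution_rate = 0, base_indel_error_rate = 0)
  reads <- simulate_amplicon_assay(assay, matrix(1, 1, 1), depths = 100L,
                                   em = em0, mode = "reads", seed = 4L)
  q <- quantify_amplicon_indels(reads[["s1"]][[1]], assay)
  expect_equal(q$indel, 100L)
  expect_equal(q$frequency, 1)
  expect_error(simulate_amplicon_assay(assay, matrix(1, 1, 1), 10L,
                                       mode = "bogus"),
               "arg")
})

test_that("ddPCR droplet counts conserve and track the true KO", {
  d <- simulate_ddpcr_plate(1.0, droplets_per_well = 10000L, seed = 1L)
  expect_equal(d$wt_positive, 0L)
  expect_true(all(d$ref_positive <= d$total_droplets))
  expect_error(simulate_ddpcr_plate(0.5, droplets_per_well = 0L), "positive")
  expect_error(simulate_ddpcr_plate(1.5), "\\[0, 1\\]")

  # true_ko 0: WT and reference concentrations agree over 100 wells
  d0 <- simulate_ddpcr_plate(0, droplets_per_well = 20000L, n_wells = 100L,
                             seed = 8L)
  lam_wt <- mean(poisson_concentration(d0$wt_positive, d0$total_droplets))
  lam_ref <- mean(poisson_concentration(d0$ref_positive, d0$total_droplets))
  expect_equal(lam_wt / lam_ref, 1, tolerance = 0.01)
})
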