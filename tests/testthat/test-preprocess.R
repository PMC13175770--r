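tag <- default_tag()

test_that("UMI and tag extraction follows the declared read structure", {
  genomic <- "TTACGGATCCAGGTTACCAGGAGTAACCT"
  rd <- data.frame(id = "r1",
                   seq = paste0("ACGTACGT", tag, genomic),
                   qual = strrep("I", 8 + nchar(tag) + nchar(genomic)),
                   stringsAsFactors = FALSE)
  ann <- preprocess_tagseq_reads(rd, "8M+T", tag)
  expect_equal(ann$umi, "ACGTACGT")
  expect_true(ann$tag_found)
  expect_equal(ann$tag_offset, 0L)
  expect_equal(ann$tag_mismatches, 0L)
  expect_equal(ann$genomic, genomic)
  expect_equal(nchar(ann$gqual), nchar(genomic))
})

test_that("reads without a tag keep their body minus the UMI", {
  body <- "TTACGGATCCAGGTTACCAGGAGTAACCTAGGACCAGATT"
  rd <- data.frame(id = "r1", seq = paste0("AAAACCCC", body),
                   qual = strrep("I", 8 + nchar(body)),
                   stringsAsFactors = FALSE)
  ann <- preprocess_tagseq_reads(rd, "8M+T", tag)
  expect_false(ann$tag_found)
  expect_equal(ann$genomic, body)
})

test_that("tag detection tolerates mismatches and reports their count", {
  tag1 <- tag
  substr(tag1, 5, 5) <- if (substr(tag1, 5, 5) == "A") "C" else "A"
  rd <- data.frame(id = "r1",
                   seq = paste0("ACGTACGT", tag1, "TTACGGATCCAGGTTACCAG"),
                   qual = strrep("I", 8 + nchar(tag1) + 20),
                   stringsAsFactors = FALSE)
  ann <- preprocess_tagseq_reads(rd, "8M+T", tag, max_tag_mismatches = 1L)
  expect_true(ann$tag_found)
  expect_equal(ann$tag_mismatches, 1L)
  # exhaustive-scan oracle: at tolerance 0 the same read has no hit
  ann0 <- preprocess_tagseq_reads(rd, "8M+T", tag, max_tag_mismatches = 0L)
  expect_false(ann0$tag_found)
})

test_that("malformed FASTQ errors name the record", {
  p <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "III"), p)    # qual too short
  expect_error(read_fastq(p), "record 1")
  writeLines(c("@r1", "ACGT", "+"), p)
  expect_error(read_fastq(p), "truncated")
})

test_that("naive mapper places unique reads and flags repeats", {
  genome <- tiny_genome(10000L, seed = 2L)
  ctg <- genome$seqs[["contig_1"]]
  rd <- substr(ctg, 2001, 2080)
  aln <- map_reads(rd, genome)
  expect_equal(aln$status, "mapped")
  expect_equal(aln$pos, 2000L)
  expect_equal(aln$strand, "+")

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rd)))
  aln2 <- map_reads(rc, genome)
  expect_equal(aln2$strand, "-")
  expect_equal(aln2$pos, 2000L)

  # duplicate the locus elsewhere -> ambiguous
  dup <- genome
  s <- dup$seqs[["contig_1"]]
  substr(s, 8001, 8080) <- rd
  dup$seqs[["contig_1"]] <- s
  expect_equal(map_reads(rd, dup)$status, "ambiguous")
  expect_error(map_reads(rd, stats::setNames("", "c")), "empty reference")
})

test_that("mapper placements match exhaustive full-scan alignment for unique reads", {
  genome <- tiny_genome(8000L, seed = 13L)
  ctg <- genome$seqs[["contig_1"]]
  set.seed(31)
  starts <- sample(7000L, 40)
  reads <- substr(rep(ctg, 40), starts, starts + 79L)
  flip <- seq_along(reads) %% 2 == 0
  reads[flip] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads[flip])))
  aln <- map_reads(reads, genome)
  for (i in seq_along(reads)) {
    # oracle: exhaustive match on both strands via Biostrings
    fwd <- Biostrings::matchPattern(reads[i], ctg)
    rev <- Biostrings::matchPattern(as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(reads[i]))), ctg)
    n_hits <- length(fwd) + length(rev)
    if (n_hits == 1) {
      expect_equal(aln$status[i], "mapped")
      pos <- if (length(fwd)) Biostrings::start(fwd) else
        Biostrings::start(rev)
      expect_equal(aln$pos[i], pos - 1L)
      expect_equal(aln$strand[i], if (length(fwd)) "+" else "-")
    }
  }
})

test_that("UMI consensus keeps singletons, applies weighted majority, conserves reads", {
  df <- data.frame(
    sample = "s", umi = c("AAAA", "AAAA", "AAAA", "CCCC", "GGGG"),
    contig = "c1", pos = c(10L, 10L, 10L, 10L, 50L), strand = "+",
    genomic = c("ACGT", "ACGT", "AGGT", "ACGT", "TTTT"),
    gqual = c("IIII", "IIII", "I+II", "IIII", "IIII"),  # discordant low qual
    tag_found = TRUE, status = "mapped", stringsAsFactors = FALSE)
  cons <- umi_consensus(df, min_size = 1L)
  expect_equal(nrow(cons), 3)                 # 3 distinct families
  expect_lte(nrow(cons), nrow(df))
  fam <- cons[cons$umi == "AAAA", ]
  expect_equal(fam$family_size, 3L)
  # majority base at position 2: C (quals 40+40 vs G at 10)
  expect_equal(substr(fam$genomic, 2, 2), "C")
  # singleton survives at min_size 1, dropped at min_size 2
  expect_true("GGGG" %in% cons$umi)
  cons2 <- umi_consensus(df, min_size = 2L)
  expect_equal(nrow(cons2), 1)
  # conservation: families partition the input
  expect_equal(sum(cons$family_size), nrow(df))
})

test_that("integration clusters merge within the window and track orientation", {
  cons <- data.frame(
    sample = c("t1", "t1", "t2", "t2"),
    contig = "c1", pos = c(100L, 103L, 100L, 500L),
    strand = c("+", "+", "-", "+"),
    genomic = strrep("A", 30), gqual = strrep("I", 30),
    tag_found = TRUE, status = "mapped", stringsAsFactors = FALSE)
  # minus-strand read: junction = pos + len = 130 (not near 100) -> adjust
  cons$pos[3] <- 70L
  cl <- call_integration_clusters(cons, cluster_window = 5L)
  expect_equal(nrow(cl), 2)
  c1 <- cl[cl$junction < 200, ]
  # right evidence in t1, left only in t2: no single sample has both
  expect_false(c1$bidirectional)
  c2 <- cl[cl$junction >= 400, ]
  expect_false(c2$bidirectional)    # right-orientation only
  # give t1 a left-orientation read too -> bidirectional
  cons2 <- rbind(cons, data.frame(sample = "t1", contig = "c1", pos = 72L,
                                  strand = "-", genomic = strrep("A", 30),
                                  gqual = strrep("I", 30), tag_found = TRUE,
                                  status = "mapped",
                                  stringsAsFactors = FALSE))
  clb <- call_integration_clusters(cons2, cluster_window = 5L)
  expect_true(clb$bidirectional[clb$junction < 200])
})

test_that("junctions at p and p+3 merge with window 5", {
  cons <- data.frame(sample = "t1", contig = "c1", pos = c(100L, 103L),
                     strand = "+", genomic = "ACGTACGT", gqual = "IIIIIIII",
                     tag_found = TRUE, status = "mapped",
                     stringsAsFactors = FALSE)
  cl <- call_integration_clusters(cons, cluster_window = 5L)
  expect_equal(nrow(cl), 1)
  # junction gap of 3 exceeds a window of 2: separate clusters
  cl2 <- call_integration_clusters(cons, cluster_window = 2L)
  expect_equal(nrow(cl2), 2)
})

test_that("bidirectional flag requires both orientations in one sample", {
  cons <- data.frame(sample = c("t1", "t2"), contig = "c1",
                     pos = c(100L, 70L), strand = c("+", "-"),
                     genomic = strrep("A", 30), gqual = strrep("I", 30),
                     tag_found = TRUE, status = "mapped",
                     stringsAsFactors = FALSE)
  cl <- call_integration_clusters(cons, cluster_window = 5L)
  expect_equal(nrow(cl), 1)
  expect_false(cl$bidirectional)    # left in t2, right in t1, never both
})

test_that("zero-error end-to-end recovers exactly the planted integration sites", {
  genome <- tiny_genome(60000L, seed = 17L)
  g <- demo_guide()
  res <- plant_offtarget_sites(
    genome, g,
    data.frame(distance = c(0L, 2L, 4L), region_class = "intergenic",
               integration_rate = c(0.03, 0.02, 0)), seed = 5L)
  truth <- truth_table(res$truth[1, ], res$truth[-1, ],
                       n_treatment = 2L, n_control = 1L, depth = 3000L)
  em0 <- error_model(substitution_rate = 0, base_indel_error_rate = 0)
  run <- simulate_tagseq_run(res$genome, truth, g, em0, seed = 23L)
  cons_all <- do.call(rbind, lapply(names(run$samples), function(s) {
    x <- run$samples[[s]]
    df <- preprocess_sample(
      data.frame(id = x$id, seq = x$r1, qual = x$q1,
                 stringsAsFactors = FALSE), res$genome, s)
    umi_consensus(df[df$status == "mapped", , drop = FALSE])
  }))
  cl <- call_integration_clusters(cons_all)
  truth_sites <- all_truth_sites(truth)
  truth_sites$cut <- cut_position(truth_sites$start, truth_sites$end,
                                  truth_sites$strand, g)
  expected <- truth_sites[truth_sites$integration_rate > 0, ]
  expect_equal(nrow(cl), nrow(expected))
  expect_true(all(vapply(expected$cut, function(cutpos)
    any(cl$contig == "contig_1" & abs(cl$junction - cutpos) <= 2),
    logical(1))))
})

test_that("SAM subset round-trips through write and read", {
  aln <- data.frame(id = c("a", "b"), seq = c("ACGT", "GGTT"),
                    qual = c("IIII", "IIII"), contig = "contig_1",
                    pos = c(10L, 20L), strand = c("+", "-"),
                    status = "mapped", stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".sam")
  write_sam_subset(aln, stats::setNames(strrep("A", 100), "contig_1"), p)
  back <- read_sam_subset(p)
  expect_equal(back$pos, aln$pos)
  expect_equal(back$strand, aln$strand)
  expect_equal(back$seq, aln$seq)
})
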