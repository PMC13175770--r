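test_that("planted protospacers are found at their planted distance", {
  genome <- tiny_genome(30000L, seed = 29L)
  g <- demo_guide()
  res <- plant_offtarget_sites(
    genome, g, data.frame(distance = c(0L, 2L), region_class = "intergenic",
                          strand = c("+", "-")), seed = 11L)
  hits <- search_genome(res$genome, g, max_distance = 3L)
  for (i in 1:2) {
    t <- res$truth[i, ]
    near <- hits$contig == t$contig & abs(hits$start - t$start) <= 3 &
      hits$strand == t$strand
    expect_true(any(near), info = paste("site", i))
    expect_equal(min(hits$levenshtein[near]), t$edit_distance)
  }
})

test_that("strict PAM mode excludes non-NGG plants", {
  g <- demo_guide()
  set.seed(55)
  bg <- rand_seq(3000)
  seq <- paste0(substr(bg, 1, 1000), g$spacer, "TTT",
                substr(bg, 1001, 3000))
  genome <- stats::setNames(seq, "c1")
  hits <- search_genome(genome, g, max_distance = 1L)
  expect_false(any(abs(hits$start - 1000) <= 3 & hits$strand == "+"))
  hits_nopam <- search_genome(genome, g, max_distance = 1L,
                              pam_mode = "none")
  expect_true(any(abs(hits_nopam$start - 1000) <= 3))
})

test_that("search equals the brute-force scan (completeness, both strands)", {
  genome <- tiny_genome(15000L, seed = 37L)
  g <- demo_guide()
  res <- plant_offtarget_sites(
    genome, g,
    data.frame(distance = c(0L, 1L, 2L, 3L, 4L), region_class = "intergenic",
               strand = c("+", "-", "+", "-", "+")), seed = 13L)
  for (d in c(2L, 4L)) {
    hits <- search_genome(res$genome, g, max_distance = d)
    oracle <- brute_force_search(res$genome, g, d)
    expect_equal(nrow(hits), nrow(oracle), info = paste("d =", d))
    key_h <- paste(hits$contig, hits$strand,
                   ifelse(hits$strand == "+", hits$end,
                          nchar(res$genome$seqs[[1]]) - hits$start))
    key_o <- paste(oracle$contig, oracle$strand, oracle$end_txt)
    expect_setequal(key_h, key_o)
    expect_equal(sort(hits$levenshtein), sort(oracle$dist))
  }
})

test_that("hit sets grow monotonically with max_distance and mirror under revcomp", {
  genome <- tiny_genome(12000L, seed = 41L)
  g <- demo_guide()
  res <- plant_offtarget_sites(
    genome, g, data.frame(distance = c(1L, 3L), region_class = "intergenic"),
    seed = 17L)
  prev <- NULL
  for (d in 0:4) {
    hits <- search_genome(res$genome, g, max_distance = d)
    if (!is.null(prev)) {
      key_p <- paste(prev$contig, prev$start, prev$strand)
      key_h <- paste(hits$contig, hits$start, hits$strand)
      expect_true(all(key_p %in% key_h), info = paste("d =", d))
    }
    prev <- hits
  }
  # strand symmetry: reverse-complemented genome gives the mirrored set
  L <- nchar(res$genome$seqs[[1]])
  rc <- stats::setNames(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(res$genome$seqs[[1]]))), "contig_1")
  h1 <- search_genome(res$genome$seqs, g, max_distance = 3L)
  h2 <- search_genome(rc, g, max_distance = 3L)
  mirrored <- data.frame(start = L - h2$end, end = L - h2$start,
                         strand = ifelse(h2$strand == "+", "-", "+"))
  expect_setequal(paste(h1$start, h1$end, h1$strand),
                  paste(mirrored$start, mirrored$end, mirrored$strand))
  expect_setequal(h1$levenshtein, h2$levenshtein)
})

test_that("variant expansion finds PAM-creating alleles above the AF threshold", {
  g <- demo_guide()
  set.seed(77)
  bg <- rand_seq(4000)
  # distance-1 protospacer (one substitution) with an NGA pseudo-PAM
  proto <- g$spacer
  substr(proto, 10, 10) <- if (substr(proto, 10, 10) == "A") "G" else "A"
  seqv <- paste0(substr(bg, 1, 2000), proto, "TGA", substr(bg, 2001, 4000))
  genome <- stats::setNames(seqv, "c1")
  # the SNP turns position 2023 (1-based; PAM base 3) from A to G
  vcf <- data.frame(id = c("rs1", "rs2", "rs3"),
                    contig = "c1", pos = c(2022L, 2022L, 3500L),
                    ref = "A", alt = "G", af = c(0.02, 0.005, 0.5),
                    stringsAsFactors = FALSE)
  vcf$ref[3] <- substr(seqv, 3501, 3501)       # far-away variant
  ref_hits <- search_genome(genome, g, max_distance = 3L)
  expect_false(any(abs(ref_hits$start - 2000) <= 3 & ref_hits$strand == "+"))

  new1 <- expand_with_variants(genome, vcf[1, ], g, max_distance = 3L,
                               reference_hits = ref_hits)
  expect_equal(nrow(new1), 1)
  expect_true(new1$population_dependent)
  expect_equal(new1$variant_ids, "rs1")
  expect_equal(new1$levenshtein, 1)

  # same SNP below threshold: nothing
  new2 <- expand_with_variants(genome, vcf[2, ], g, max_distance = 3L,
                               reference_hits = ref_hits)
  expect_equal(nrow(new2), 0)
  # distant variant: unchanged
  new3 <- expand_with_variants(genome, vcf[3, ], g, max_distance = 3L,
                               reference_hits = ref_hits)
  expect_equal(nrow(new3), 0)
})

test_that("population VCF parsing enforces the AF field", {
  p <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "c1\t100\trs9\tA\tG\t.\tPASS\tAF=0.03",
               "c1\t200\trs10\tC\tT\t.\tPASS\tDP=10"), p)
  expect_error(read_population_vcf(p), "rs10")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "c1\t100\trs9\tA\tG\t.\tPASS\tAF=0.03"), p)
  v <- read_population_vcf(p)
  expect_equal(v$pos, 99L)
  expect_equal(v$af, 0.03)
})
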