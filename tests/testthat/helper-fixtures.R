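# shared fixtures and independent oracles

demo_guide <- function() guide_spec("GACCTGCGGAAGATCGAGAC", name = "demo")

# small genome with one gene for fast end-to-end tests
tiny_genome <- function(len = 20000L, seed = 11L, tracts = NULL) {
  span <- as.integer(len)
  genes <- data.frame(name = "GENE_A", contig = "contig_1",
                      tx_start = as.integer(0.2 * span),
                      tx_end = as.integer(0.5 * span),
                      strand = "+", stringsAsFactors = FALSE)
  w <- genes$tx_end - genes$tx_start
  genes$exon_starts <- list(genes$tx_start +
                              as.integer(round(w * c(0, 0.4, 0.8))))
  genes$exon_ends <- list(genes$tx_start +
                            as.integer(round(w * c(0.1, 0.5, 1.0))))
  cfg <- synth_genome_config(n_contigs = 1L, contig_length = span,
                             gc_fraction = 0.45,
                             homopolymer_tracts = tracts,
                             gene_models = genes, seed = seed)
  make_reference(cfg)
}

# independent glocal oracle: minimum full-string edit distance over every
# window substring, both strands
brute_force_glocal <- function(spacer, window) {
  best <- nchar(spacer)            # align everything to gaps
  for (w in c(window, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(window))))) {
    m <- nchar(w)
    ij <- expand.grid(i = seq_len(m), j = seq_len(m))
    ij <- ij[ij$j >= ij$i, ]
    subs <- substring(w, ij$i, ij$j)
    best <- min(best, min(adist(spacer, subs)))
  }
  best
}

# exhaustive hypergeometric upper tail from binomial coefficients only
hyper_enum <- function(k_treat, N_treat, k_ctrl, N_ctrl) {
  K <- k_treat + k_ctrl
  N <- N_treat + N_ctrl
  js <- k_treat:min(K, N_treat)
  js <- js[N_treat - js <= N - K]
  sum(choose(K, js) * choose(N - K, N_treat - js)) / choose(N, N_treat)
}

# Benjamini-Hochberg step-up by the hand formula
bh_hand <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# brute-force oracle: per end position, the minimum full-string edit
# distance over substrings of length n-d .. n+d ending there, PAM-gated,
# then the same 3-bp same-strand collapse as the search contract
brute_force_search <- function(genome, guide, max_d) {
  seqs <- otsentry:::genome_seqs(genome)
  n <- nchar(guide$spacer)
  hits <- data.frame()
  for (ctg in names(seqs)) {
    fwd <- seqs[[ctg]]
    L <- nchar(fwd)
    for (strand in c("+", "-")) {
      txt <- if (strand == "+") fwd else
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(fwd)))
      dmin <- rep(Inf, L)
      for (len in max(1, n - max_d):(n + max_d)) {
        if (len > L) next
        subs <- substring(txt, seq_len(L - len + 1), len:L)
        d <- drop(adist(guide$spacer, subs))
        ends <- len:L
        dmin[ends] <- pmin(dmin[ends], d)
      }
      pam_ok <- vapply(seq_len(L), function(e) {
        p <- substr(txt, e + 1, e + 3)
        nchar(p) == 3 && grepl("^.GG$", p)
      }, logical(1))
      cand <- which(dmin <= max_d & pam_ok)
      if (length(cand)) {
        df <- data.frame(contig = ctg, strand = strand, end_txt = cand,
                         dist = dmin[cand])
        # collapse ends within 3 bp to best distance
        df <- df[order(df$end_txt), ]
        brk <- c(0, cumsum(diff(df$end_txt) > 3))
        df <- do.call(rbind, lapply(split(df, brk), function(g)
          g[order(g$dist), ][1, ]))
        df$end <- if (strand == "+") df$end_txt else L - df$end_txt + n
        hits <- rbind(hits, df)
      }
    }
  }
  hits
}

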