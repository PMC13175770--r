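#' Design amplicon assays over panel sites
#'
#' Extracts an amplicon reference around each site's cut position and flags
#' amplicons whose quantification neighborhood overlaps a declared
#' homopolymer tract (elevated background indel error).
#'
#' @param genome A `synth_genome`.
#' @param sites Data frame with `site_id`, `contig`, and `cut` (0-based).
#' @param halfwidth Amplicon half-width around the cut, in bases.
#' @return Data frame with `site_id`, `seq`, `cut` (cut position within the
#'   amplicon), and `tract_overlap`.
#' @export
design_amplicons <- function(genome, sites, halfwidth = 120L) {
  seqs <- genome_seqs(genome)
  tracts <- if (inherits(genome, "synth_genome")) genome$tracts else NULL
  out <- lapply(seq_len(nrow(sites)), function(i) {
    ctg <- seqs[[sites$contig[i]]]
    cut <- sites$cut[i]
    a <- max(0L, cut - halfwidth)
    b <- min(nchar(ctg), cut + halfwidth)
    overlap <- FALSE
    if (!is.null(tracts) && nrow(tracts)) {
      tct <- tracts[names(seqs)[tracts$contig] == sites$contig[i], ,
                    drop = FALSE]
      if (nrow(tct))
        overlap <- any(tct$start < b & tct$start + tct$length > a)
    }
    data.frame(site_id = sites$site_id[i],
               seq = substr(ctg, a + 1L, b), cut = cut - a,
               tract_overlap = overlap, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate an amplicon deep-sequencing assay
#'
#' Counts mode draws per-site, per-sample indel counts from a binomial whose
#' success probability is the true editing fraction plus the background
#' indel error (multiplied over homopolymer tracts). Reads mode emits
#' full-length amplicon reads: edited reads carry a planted 1-3 bp indel at
#' the cut site; all reads carry substitution noise and may acquire a
#' spurious 1-bp indel at the background rate.
#'
#' @param assays Data frame from [design_amplicons()] (counts mode only needs
#'   `site_id` and `tract_overlap`).
#' @param fractions Numeric matrix of true editing fractions,
#'   sites x samples (dimnames used for ids).
#' @param depths Read depth: scalar or matrix shaped like `fractions`.
#' @param em An [error_model()].
#' @param mode `"counts"` or `"reads"`.
#' @param seed Integer seed.
#' @return Counts mode: data frame `site_id`, `sample`, `total`, `indel`.
#'   Reads mode: nested list `[[site]][[sample]]` of `list(seq, qual)`.
#' @export
simulate_amplicon_assay <- function(assays, fractions, depths,
                                    em = error_model(),
                                    mode = c("counts", "reads"), seed = 1L) {
  mode <- match.arg(mode)
  if (!is.matrix(fractions)) fractions <- as.matrix(fractions)
  if (any(fractions < 0 | fractions > 1))
    stop("editing fractions must lie in [0, 1]", call. = FALSE)
  if (any(depths <= 0)) stop("depths must be positive", call. = FALSE)
  if (is.null(rownames(fractions))) rownames(fractions) <- assays$site_id
  if (is.null(colnames(fractions)))
    colnames(fractions) <- sprintf("sample_%d", seq_len(ncol(fractions)))
  D <- if (is.matrix(depths)) depths else
    matrix(depths, nrow(fractions), ncol(fractions))
  bg <- background_indel_rate(em, assays$tract_overlap)

  with_seed(seed, {
    if (mode == "counts") {
      rows <- expand.grid(site = seq_len(nrow(fractions)),
                          samp = seq_len(ncol(fractions)))
      p <- pmin(1, fractions[cbind(rows$site, rows$samp)] + bg[rows$site])
      tot <- D[cbind(rows$site, rows$samp)]
      data.frame(site_id = rownames(fractions)[rows$site],
                 sample = colnames(fractions)[rows$samp],
                 total = as.integer(tot),
                 indel = rbinom(nrow(rows), tot, p),
                 stringsAsFactors = FALSE)
    } else {
      out <- list()
      for (i in seq_len(nrow(assays))) {
        a <- assays[i, ]
        out[[a$site_id]] <- list()
        for (j in seq_len(ncol(fractions))) {
          n <- D[i, j]
          edited <- runif(n) < fractions[i, j]
          reads <- rep(a$seq, n)
          reads[edited] <- vapply(which(edited), function(k)
            plant_indel(a$seq, a$cut), character(1))
          spurious <- !edited & runif(n) < bg[i]
          reads[spurious] <- vapply(which(spurious), function(k)
            plant_indel(reads[k], sample(nchar(reads[k]) - 2L, 1),
                        size = 1L), character(1))
          reads <- apply_substitutions(reads, em$substitution_rate)
          out[[a$site_id]][[colnames(fractions)[j]]] <-
            list(seq = reads, qual = draw_quality_strings(nchar(reads), em))
        }
      }
      out
    }
  })
}

#' Simulate a full confirmation study at count level
#'
#' Emulates the confirmation experiment: a panel of `n_sites` amplicon
#' assays sequenced to `depth` in `n_donors` treatment donors and
#' `n_controls` controls. Each site carries its own background indel rate
#' drawn from a log-normal whose median is 0.12% (the variable background
#' the assay exhibits); the first `length(signal_fractions)` sites carry
#' true treatment editing at the given raw frequencies over their own
#' (low) backgrounds, mirroring the four confirmed off-target signals
#' (approximately 0.40%, 0.44%, 0.025%, and 0.055%); all other sites are
#' null (treatment = control background).
#'
#' @param n_sites Panel size.
#' @param depth Reads per site per sample.
#' @param n_donors,n_controls Treatment and control sample counts.
#' @param signal_fractions Raw treatment indel frequencies of the true
#'   signal sites.
#' @param signal_backgrounds Site-specific control backgrounds of the
#'   signal sites.
#' @param bg_meanlog,bg_sdlog Log-normal parameters of the null-site
#'   background distribution.
#' @param seed Integer seed.
#' @return Long quant table (`site_id`, `sample`, `role`, `total`,
#'   `indel`, `frequency`) ready for [test_confirmation()], with the truth
#'   attached as attribute `"truth_sites"`.
#' @export
simulate_confirmation_study <- function(n_sites = 255L, depth = 200000L,
                                        n_donors = 3L, n_controls = 3L,
                                        signal_fractions =
                                          c(0.0040, 0.0044, 0.00025,
                                            0.00055),
                                        signal_backgrounds =
                                          c(0.0010, 0.0012, 0.00005,
                                            0.0001),
                                        bg_meanlog = log(0.0012),
                                        bg_sdlog = 1.0, seed = 1L) {
  stopifnot(length(signal_fractions) == length(signal_backgrounds),
            n_sites > length(signal_fractions))
  with_seed(seed, {
    k <- length(signal_fractions)
    bg <- stats::rlnorm(n_sites, bg_meanlog, bg_sdlog)
    bg <- pmin(bg, 0.05)
    bg[seq_len(k)] <- signal_backgrounds
    treat_f <- bg
    treat_f[seq_len(k)] <- signal_fractions
    ids <- sprintf("site_%03d", seq_len(n_sites))
    samples <- c(sprintf("donor_%d", seq_len(n_donors)),
                 sprintf("ctrl_%d", seq_len(n_controls)))
    roles <- rep(c("treatment", "control"), c(n_donors, n_controls))
    rows <- expand.grid(site = seq_len(n_sites), samp = seq_along(samples))
    p <- ifelse(roles[rows$samp] == "treatment", treat_f[rows$site],
                bg[rows$site])
    indel <- rbinom(nrow(rows), depth, p)
    out <- data.frame(site_id = ids[rows$site],
                      sample = samples[rows$samp],
                      role = roles[rows$samp],
                      total = as.integer(depth), indel = indel,
                      frequency = indel / depth, stringsAsFactors = FALSE)
    attr(out, "truth_sites") <- data.frame(
      site_id = ids, background = bg, treatment_fraction = treat_f,
      true_signal = seq_len(n_sites) <= k, stringsAsFactors = FALSE)
    out
  })
}

# Plant a deletion (70%) or insertion (30%) of `size` (default 1-3) bases at
# 0-based position `at` of `seq`.
plant_indel <- function(seq, at, size = NULL) {
  if (is.null(size)) size <- sample(3L, 1)
  if (runif(1) < 0.7 && at + size <= nchar(seq)) {
    paste0(substr(seq, 1L, at), substr(seq, at + size + 1L, nchar(seq)))
  } else {
    paste0(substr(seq, 1L, at), random_dna(size, 0.5),
           substr(seq, at + 1L, nchar(seq)))
  }
}
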