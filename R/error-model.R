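#' Sequencing error model
#'
#' Per-base substitution noise, a per-read probability of a spurious 1-bp
#' indel (the dominant amplicon background artifact), and a multiplier
#' applied to that indel rate when the assayed window overlaps a homopolymer
#' tract of at least `min_tract_length` bases -- homopolymers are a known
#' motif for elevated indel error on short-read sequencers. The default
#' base indel error rate of 0.0012 reproduces a background indel frequency
#' with median near 0.12%.
#'
#' @param substitution_rate Per-base substitution probability.
#' @param base_indel_error_rate Per-read probability of a spurious 1-bp indel.
#' @param homopolymer_multiplier Factor (>= 1) applied to the indel error
#'   rate over homopolymer tracts.
#' @param min_tract_length Minimum homopolymer length that triggers the
#'   multiplier, in bases.
#' @param quality_mean,quality_sd Phred base-quality profile.
#' @return An object of class `error_model`.
#' @export
error_model <- function(substitution_rate = 0.001,
                        base_indel_error_rate = 0.0012,
                        homopolymer_multiplier = 5,
                        min_tract_length = 6L,
                        quality_mean = 36, quality_sd = 3) {
  rates <- c(substitution_rate, base_indel_error_rate)
  if (any(rates < 0 | rates > 1))
    stop("error rates must lie in [0, 1]", call. = FALSE)
  if (homopolymer_multiplier < 1)
    stop("homopolymer_multiplier must be >= 1", call. = FALSE)
  structure(list(substitution_rate = substitution_rate,
                 base_indel_error_rate = base_indel_error_rate,
                 homopolymer_multiplier = homopolymer_multiplier,
                 min_tract_length = as.integer(min_tract_length),
                 quality_mean = quality_mean, quality_sd = quality_sd),
            class = "error_model")
}

# background indel rate for a site, given tract overlap
background_indel_rate <- function(em, tract_overlap) {
  em$base_indel_error_rate *
    ifelse(tract_overlap, em$homopolymer_multiplier, 1)
}

# Apply iid substitution noise to a character vector of reads.
apply_substitutions <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  lens <- nchar(seqs)
  nerr <- rbinom(length(seqs), lens, rate)
  idx <- which(nerr > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample(lens[i], nerr[i])
    v <- strsplit(seqs[i], "")[[1]]
    for (p in pos) v[p] <- sample(setdiff(bases, v[p]), 1)
    seqs[i] <- paste(v, collapse = "")
  }
  seqs
}

# Draw one quality string per read.
draw_quality_strings <- function(lens, em) {
  vapply(lens, function(L) {
    q <- pmin(pmax(as.integer(round(rnorm(L, em$quality_mean,
                                          em$quality_sd))), 2L), 41L)
    rawToChar(as.raw(q + 33L))
  }, character(1))
}
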