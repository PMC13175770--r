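#' Build the flanked search window around a junction
#'
#' @param junction 0-based junction position.
#' @param genome A `synth_genome` or named character vector.
#' @param contig Contig name.
#' @param flank Flank half-width in bases (window is `[junction - flank,
#'   junction + flank)`, clipped to the contig).
#' @return List: `contig`, `start`, `end` (0-based half-open), `seq`.
#' @export
build_search_window <- function(junction, genome, contig, flank = 40L) {
  seqs <- genome_seqs(genome)
  if (!contig %in% names(seqs))
    stop("unknown contig: ", contig, call. = FALSE)
  L <- nchar(seqs[[contig]])
  if (junction < 0 || junction > L)
    stop("junction ", junction, " outside contig ", contig, call. = FALSE)
  s <- max(0L, junction - flank)
  e <- min(L, junction + flank)
  list(contig = contig, start = s, end = e,
       seq = substr(seqs[[contig]], s + 1L, e))
}

#' One-sided hypergeometric enrichment test
#'
#' Upper-tail probability of observing at least `k_treat` site-assigned
#' reads in a treatment sample of `N_treat` reads, given the pooled 2x2
#' margins against `k_ctrl` of `N_ctrl` pooled control reads (equivalently
#' a one-sided Fisher exact test). Vectorized over the treatment arm.
#'
#' @param k_treat,N_treat Site reads and total reads in the treatment
#'   sample.
#' @param k_ctrl,N_ctrl Site reads and total reads pooled across controls.
#' @return One-sided p value(s).
#' @export
enrichment_test <- function(k_treat, N_treat, k_ctrl, N_ctrl) {
  if (any(c(k_treat, N_treat, k_ctrl, N_ctrl) < 0))
    stop("counts must be nonnegative", call. = FALSE)
  if (any(k_treat > N_treat) || any(k_ctrl > N_ctrl))
    stop("site reads cannot exceed sample totals", call. = FALSE)
  K <- k_treat + k_ctrl
  phyper(k_treat - 1, K, N_treat + N_ctrl - K, N_treat, lower.tail = FALSE)
}

#' Apply the nomination criteria
#'
#' Takes per-(site, treatment-sample) test rows, applies Benjamini-Hochberg
#' across the whole run, and evaluates the three nomination criteria per
#' site: (1) bidirectional junction evidence in at least one sample,
#' (2) post-alignment Levenshtein distance below `max_lev`, (3) significant
#' adjusted p value against the pooled controls. Replicate support counts
#' the treatment samples that individually satisfy all three.
#'
#' @param records Data frame with one row per (site, treatment sample):
#'   `site_id`, `sample`, `p_value`, `levenshtein`, `bidirectional`
#'   (evidence on both sides in that sample).
#' @param fdr BH false-discovery-rate threshold.
#' @param max_lev Levenshtein cutoff (nominated requires distance
#'   `< max_lev`).
#' @return Per-site data frame: `site_id`, `p_value` (minimum across
#'   samples), `p_adj` (minimum adjusted), criteria flags
#'   (`crit_bidirectional`, `crit_levenshtein`, `crit_significant`),
#'   `nominated`, `replicate_support`.
#' @export
nominate_sites <- function(records, fdr = 0.05, max_lev = 7L) {
  if (!nrow(records))
    return(data.frame(site_id = character(0), p_value = numeric(0),
                      p_adj = numeric(0), crit_bidirectional = logical(0),
                      crit_levenshtein = logical(0),
                      crit_significant = logical(0), nominated = logical(0),
                      replicate_support = integer(0)))
  stopifnot(all(c("site_id", "sample", "p_value", "levenshtein",
                  "bidirectional") %in% names(records)))
  records$p_adj <- p.adjust(records$p_value, method = "BH")
  records$sample_pass <- records$p_adj < fdr & records$bidirectional &
    records$levenshtein < max_lev
  agg <- lapply(split(records, records$site_id), function(r) {
    data.frame(site_id = r$site_id[1],
               p_value = min(r$p_value),
               p_adj = min(r$p_adj),
               levenshtein = r$levenshtein[1],
               crit_bidirectional = any(r$bidirectional),
               crit_levenshtein = r$levenshtein[1] < max_lev,
               crit_significant = min(r$p_adj) < fdr,
               replicate_support = sum(r$sample_pass),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out$nominated <- out$crit_bidirectional & out$crit_levenshtein &
    out$crit_significant
  rownames(out) <- NULL
  out[order(out$site_id), ]
}

#' Default tier ruleset
#'
#' The study's tier definitions live in supplementary material; this
#' package ships a documented, fully configurable stand-in evaluated in
#' order (first match wins) over nominated records:
#' tier 1 -- exonic, or supported by every treatment replicate;
#' tier 2 -- intronic/flanking with support in >= 2 replicates;
#' tier 3 -- support in >= 2 replicates, or Levenshtein distance <= 3;
#' tier 4 -- every other nominated record.
#'
#' @param n_replicates Number of treatment replicates in the run.
#' @return Named list of predicate functions `record -> logical`.
#' @export
default_tier_rules <- function(n_replicates = 3L) {
  list(
    tier1 = function(r) r$annotation == "exonic" |
      r$replicate_support == n_replicates,
    tier2 = function(r) r$annotation %in% c("intronic", "flanking_5prime",
                                            "flanking_3prime") &
      r$replicate_support >= 2,
    tier3 = function(r) r$replicate_support >= 2 | r$levenshtein <= 3,
    tier4 = function(r) rep(TRUE, nrow(r)))
}

#' Assign tiers to nominated records
#'
#' @param records Per-site nomination data frame with `nominated`,
#'   `annotation`, `replicate_support`, `levenshtein`.
#' @param rules Ordered named list of predicates (see
#'   [default_tier_rules()]); names become tier labels 1..k.
#' @return `records` with an integer `tier` column (NA for records that are
#'   not nominated).
#' @export
assign_tiers <- function(records, rules = default_tier_rules()) {
  if (!"annotation" %in% names(records) || anyNA(records$annotation))
    stop("records must be annotated before tier assignment", call. = FALSE)
  tier <- rep(NA_integer_, nrow(records))
  pending <- records$nominated
  for (k in seq_along(rules)) {
    hit <- pending & rules[[k]](records)
    tier[hit] <- k
    pending <- pending & !hit
  }
  records$tier <- tier
  records
}

#' Nominate off-target sites from integration clusters
#'
#' End-to-end nomination: builds the flanked search window for every
#' cluster, aligns the guide glocally on both strands, tests per-treatment-
#' sample enrichment against pooled controls, applies BH and the three
#' criteria.
#'
#' @param clusters Cluster table from [call_integration_clusters()].
#' @param genome Reference.
#' @param guide A [guide_spec()].
#' @param sample_roles Named character vector sample -> "treatment"/
#'   "control".
#' @param sample_totals Named integer vector of per-sample total consensus
#'   reads (the representation denominator).
#' @param flank Search-window half-width, in bases.
#' @param fdr,max_lev Nomination thresholds.
#' @param pam_mode Passed to [glocal_align()].
#' @return Per-site nomination table with site coordinates (cut position,
#'   strand), the best alignment fields, counts, p values, criteria flags,
#'   `nominated` and `replicate_support`.
#' @export
nominate_from_clusters <- function(clusters, genome, guide, sample_roles,
                                   sample_totals, flank = 40L, fdr = 0.05,
                                   max_lev = 7L,
                                   pam_mode = "strict") {
  if (!nrow(clusters)) return(nominate_sites(data.frame()))
  treat <- names(sample_roles)[sample_roles == "treatment"]
  ctrl <- names(sample_roles)[sample_roles == "control"]
  N_ctrl <- sum(sample_totals[ctrl])

  site_rows <- list(); test_rows <- list()
  for (i in seq_len(nrow(clusters))) {
    cl <- clusters[i, ]
    win <- build_search_window(cl$junction, genome, cl$contig, flank)
    aln <- glocal_align(guide, win$seq, pam_mode = pam_mode)
    counts <- cl$counts[[1]]
    k_ctrl <- sum(counts$n_right[counts$sample %in% ctrl] +
                    counts$n_left[counts$sample %in% ctrl])
    if (is.infinite(aln$distance)) {
      lev <- Inf; cut <- cl$junction; strand <- NA
      proto_start <- NA; proto_end <- NA
    } else {
      lev <- aln$distance
      proto_start <- win$start + aln$start
      proto_end <- win$start + aln$end
      strand <- aln$strand
      cut <- cut_position(proto_start, proto_end, strand, guide)
    }
    for (s in treat) {
      row <- counts[counts$sample == s, , drop = FALSE]
      k <- if (nrow(row)) row$n_right + row$n_left else 0L
      bidir <- nrow(row) > 0 && row$n_right > 0 && row$n_left > 0
      test_rows[[length(test_rows) + 1]] <- data.frame(
        site_id = cl$cluster_id, sample = s,
        k_treat = k, N_treat = unname(sample_totals[s]),
        k_ctrl = k_ctrl, N_ctrl = N_ctrl,
        p_value = enrichment_test(k, sample_totals[[s]], k_ctrl, N_ctrl),
        levenshtein = lev, bidirectional = bidir,
        stringsAsFactors = FALSE)
    }
    site_rows[[length(site_rows) + 1]] <- data.frame(
      site_id = cl$cluster_id, contig = cl$contig, cut = cut,
      strand = if (is.na(strand)) NA_character_ else strand,
      proto_start = proto_start, proto_end = proto_end,
      levenshtein = lev,
      mismatches = aln$mismatches, insertions = aln$insertions,
      deletions = aln$deletions, pam_found = aln$pam_found,
      k_ctrl = k_ctrl, stringsAsFactors = FALSE)
  }
  tests <- do.call(rbind, test_rows)
  sites <- do.call(rbind, site_rows)
  nom <- nominate_sites(tests, fdr = fdr, max_lev = max_lev)
  out <- merge(sites, nom[, setdiff(names(nom), "levenshtein")],
               by = "site_id")
  out[order(out$contig, out$cut), ]
}
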