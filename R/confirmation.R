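#' Quantify amplicon indels for one site and sample
#'
#' Reads mode: every read is aligned to the amplicon reference (banded
#' global edit-distance alignment; reads are expected to span the
#' amplicon) and counts as edited iff the alignment contains at least one
#' insertion or deletion overlapping the quantification window
#' `[cut - w, cut + w]`. Substitutions never count, indels are counted
#' once per read, and an indel touching the window with any base counts.
#' Counts mode passes the provided totals through.
#'
#' @param x Reads-mode: character vector of read sequences (or a list with
#'   `$seq`). Counts-mode: list or one-row data frame with `total` and
#'   `indel`.
#' @param assay One-row assay data frame (`site_id`, `seq`, `cut`).
#' @param window_halfwidth Quantification half-width `w`, in bases.
#' @param sample,role Labels carried into the output.
#' @param band Alignment band half-width.
#' @return One-row data frame: `site_id`, `sample`, `role`, `total`,
#'   `indel`, `frequency` (NA with `flagged = TRUE` when no reads).
#' @export
quantify_amplicon_indels <- function(x, assay, window_halfwidth = 2L,
                                     sample = "sample", role = "treatment",
                                     band = 25L) {
  if (is.list(x) && !is.null(x$total)) {
    total <- as.integer(x$total); indel <- as.integer(x$indel)
  } else {
    reads <- if (is.list(x)) x$seq else x
    total <- length(reads)
    if (total == 0L) indel <- 0L
    else {
      ops <- .align_amplicon_cpp(assay$seq, reads, band)
      w0 <- assay$cut - window_halfwidth
      w1 <- assay$cut + window_halfwidth
      in_win <- vapply(seq_len(nrow(ops)), function(k) {
        rng <- indel_ambiguity_range(assay$seq, ops$type[k], ops$ref_pos[k],
                                     ops$length[k], ops$seq[k])
        rng[1] <= w1 && rng[2] >= w0
      }, logical(1))
      indel <- length(unique(ops$read[in_win]))
    }
  }
  freq <- if (total > 0) indel / total else NA_real_
  data.frame(site_id = assay$site_id, sample = sample, role = role,
             total = total, indel = indel, frequency = freq,
             flagged = total == 0L, stringsAsFactors = FALSE)
}

# Placement-ambiguity interval of an indel: the union of reference
# positions every equivalent alignment of the op can occupy (an indel in a
# repeat run can be left- or right-aligned without changing the read).
# Deletions occupy [pos, pos+len); insertions sit at the gap before `pos`
# and are treated as covering [pos-1, pos]. Returns c(start, end)
# inclusive, 0-based.
indel_ambiguity_range <- function(ref, type, pos, len, opseq,
                                  max_shift = 50L) {
  n <- nchar(ref)
  ch <- function(i) substr(ref, i + 1L, i + 1L)    # 0-based accessor
  if (type == "D") {
    lo <- pos
    k <- 0L
    while (lo > 0 && k < max_shift && ch(lo - 1L) == ch(lo + len - 1L)) {
      lo <- lo - 1L; k <- k + 1L
    }
    hi <- pos
    k <- 0L
    while (hi + len < n && k < max_shift && ch(hi) == ch(hi + len)) {
      hi <- hi + 1L; k <- k + 1L
    }
    c(lo, hi + len - 1L)
  } else {
    t <- strsplit(opseq, "")[[1]]
    lo <- pos; tl <- t
    k <- 0L
    while (lo > 0 && k < max_shift && tl[len] == ch(lo - 1L)) {
      tl <- c(tl[len], tl[-len]); lo <- lo - 1L; k <- k + 1L
    }
    hi <- pos; tr <- t
    k <- 0L
    while (hi < n && k < max_shift && tr[1] == ch(hi)) {
      tr <- c(tr[-1], tr[1]); hi <- hi + 1L; k <- k + 1L
    }
    c(lo - 1L, hi)
  }
}

#' Coverage classification and panel coverage fractions
#'
#' Classifies each site by its minimum depth across samples against the
#' coverage thresholds and reports the fraction of the panel exceeding
#' each threshold. Sites below `min_coverage` are excluded from the
#' confirmation test.
#'
#' @param quants Long quant table (`site_id`, `sample`, `total`).
#' @param thresholds Coverage thresholds, in reads.
#' @param min_coverage Minimum per-sample depth required for testing.
#' @return List: `per_site` (`site_id`, `min_depth`, `class`, `tested`)
#'   and `fractions` (threshold, fraction of sites exceeding it).
#' @export
summarize_coverage <- function(quants, thresholds = c(100, 1000, 10000),
                               min_coverage = 1000) {
  stopifnot(nrow(quants) > 0)
  md <- tapply(quants$total, quants$site_id, min)
  thresholds <- sort(thresholds)
  cls <- vapply(md, function(d) {
    over <- thresholds[d > thresholds]
    if (!length(over)) paste0("<=", thresholds[1])
    else paste0(">", max(over))
  }, character(1))
  per_site <- data.frame(site_id = names(md), min_depth = as.vector(md),
                         class = cls, tested = as.vector(md) >= min_coverage,
                         stringsAsFactors = FALSE)
  fractions <- data.frame(
    threshold = thresholds,
    fraction = vapply(thresholds, function(t) mean(md > t), numeric(1)))
  list(per_site = per_site, fractions = fractions)
}

#' Background indel-rate characterization
#'
#' Summarizes per-site control indel frequencies (median and quartiles)
#' and flags sites overlapping declared homopolymer tracts, which carry
#' elevated background error.
#'
#' @param control_quants Control-sample quant table (`site_id`,
#'   `frequency`).
#' @param tract_overlap Optional named logical vector (site -> overlaps a
#'   tract).
#' @return List: `median`, `q1`, `q3`, `iqr`, and `per_site` table with
#'   `homopolymer` flags.
#' @export
background_stats <- function(control_quants, tract_overlap = NULL) {
  stopifnot(nrow(control_quants) >= 1)
  per_site <- tapply(control_quants$frequency, control_quants$site_id, mean)
  per_site <- data.frame(site_id = names(per_site),
                         control_frequency = as.vector(per_site),
                         stringsAsFactors = FALSE)
  per_site$homopolymer <- if (is.null(tract_overlap)) FALSE
    else unname(tract_overlap[per_site$site_id])
  q <- quantile(per_site$control_frequency, c(0.25, 0.5, 0.75),
                na.rm = TRUE, names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3], iqr = q[3] - q[1],
       per_site = per_site)
}

#' Treatment-versus-control confirmation test
#'
#' Per site, a one-sided exact (hypergeometric) test of the pooled
#' treatment indel counts against the pooled control counts -- the same
#' kernel as the nomination enrichment test -- with BH correction across
#' all tested sites. A site is significant iff its adjusted p value falls
#' below `fdr` AND every treatment donor's frequency exceeds the pooled
#' control frequency (the donor-independence guard). Sites failing the
#' coverage filter are reported untested and can never be significant.
#'
#' @param quants Long quant table with `site_id`, `sample`, `role`
#'   (`treatment`/`control`), `total`, `indel`.
#' @param fdr BH threshold.
#' @param min_coverage Coverage filter (minimum per-sample depth).
#' @param per_donor If `TRUE`, tests each donor separately against the
#'   pooled controls and takes the minimum BH-adjusted p instead of
#'   pooling donors.
#' @return Per-site data frame: donor frequencies, pooled control
#'   frequency, `p_value`, `p_adj`, `significant`, `coverage_class`,
#'   `tested`.
#' @export
test_confirmation <- function(quants, fdr = 0.05, min_coverage = 1000,
                              per_donor = FALSE) {
  cov <- summarize_coverage(quants, min_coverage = min_coverage)
  sites <- unique(quants$site_id)
  rows <- lapply(sites, function(s) {
    q <- quants[quants$site_id == s, , drop = FALSE]
    tr <- q[q$role == "treatment", , drop = FALSE]
    ct <- q[q$role == "control", , drop = FALSE]
    if (!nrow(ct)) stop("site ", s, " has no control data", call. = FALSE)
    if (!nrow(tr)) stop("site ", s, " has no treatment data", call. = FALSE)
    ctrl_freq <- sum(ct$indel) / sum(ct$total)
    tested <- cov$per_site$tested[cov$per_site$site_id == s]
    if (per_donor) {
      p <- min(enrichment_test(tr$indel, tr$total, sum(ct$indel),
                               sum(ct$total)))
    } else {
      p <- enrichment_test(sum(tr$indel), sum(tr$total), sum(ct$indel),
                           sum(ct$total))
    }
    data.frame(site_id = s,
               n_donors = nrow(tr),
               mean_treatment_frequency = mean(tr$frequency),
               min_donor_frequency = min(tr$frequency),
               pooled_control_frequency = ctrl_freq,
               donor_guard = all(tr$frequency > ctrl_freq),
               p_value = if (tested) p else NA_real_,
               coverage_class =
                 cov$per_site$class[cov$per_site$site_id == s],
               tested = tested, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  out$p_adj[out$tested] <- p.adjust(out$p_value[out$tested], method = "BH")
  out$significant <- !is.na(out$p_adj) & out$p_adj < fdr & out$donor_guard
  rownames(out) <- NULL
  out
}
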