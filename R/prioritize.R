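#' Ingest method nominations
#'
#' Reads per-method nomination tables (TSV, BED-like columns plus
#' method-specific metadata) and normalizes them into one long table of
#' method nominations with 0-based cut positions. The CAST-seq ingest rule
#' is applied here: records with p >= 0.005 (the published OMT cut-off)
#' are dropped.
#'
#' @param files Named character vector or list: method label -> file path.
#'   Labels must come from `uncoverseq`, `castseq`, `cosmid`, `abnoba`,
#'   `insilico`.
#' @param castseq_p CAST-seq OMT p-value cut-off.
#' @return Data frame: `method`, `site_id`, `contig`, `cut`, `strand`, and
#'   metadata columns `tier`, `p`, `levenshtein`, `annotation`,
#'   `replicate_support` (NA where a method does not provide them),
#'   `source_file`.
#' @export
ingest_nominations <- function(files, castseq_p = 0.005) {
  methods_ok <- c("uncoverseq", "castseq", "cosmid", "abnoba", "insilico")
  bad <- setdiff(names(files), methods_ok)
  if (length(bad) || is.null(names(files)))
    stop("unknown method label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  out <- list()
  for (m in names(files)) {
    df <- read_tsv(files[[m]])
    need <- c("contig", "start", "end")
    if (!all(need %in% names(df)))
      stop(files[[m]], ": missing required columns ",
           paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
    badrow <- which(df$end < df$start)
    if (length(badrow))
      stop(files[[m]], ": end < start at row ", badrow[1], call. = FALSE)
    if (m == "castseq") {
      if (!"p" %in% names(df))
        stop(files[[m]], ": CAST-seq input requires a p column",
             call. = FALSE)
      df <- df[df$p < castseq_p, , drop = FALSE]
    }
    n <- nrow(df)
    out[[m]] <- data.frame(
      method = rep(m, n),
      site_id = if ("site_id" %in% names(df)) df$site_id else
        sprintf("%s_%03d", m, seq_len(n)),
      contig = df$contig,
      cut = if ("cut" %in% names(df)) as.integer(df$cut) else
        as.integer(floor((df$start + df$end) / 2)),
      strand = if ("strand" %in% names(df)) df$strand else ".",
      tier = if ("tier" %in% names(df)) as.integer(df$tier) else NA_integer_,
      p = if ("p" %in% names(df)) df$p else NA_real_,
      levenshtein = if ("levenshtein" %in% names(df))
        as.integer(df$levenshtein) else NA_integer_,
      annotation = if ("annotation" %in% names(df)) df$annotation else
        NA_character_,
      replicate_support = if ("replicate_support" %in% names(df))
        as.integer(df$replicate_support) else NA_integer_,
      source_file = as.character(files[[m]]), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Apply the five prioritization rules
#'
#' A nomination enters the confirmation panel if it satisfies at least one
#' of: (1) a tier 1-3 tag-integration (UNCOVERseq) nomination; (2) any
#' Abnoba-seq nomination; (3) a CAST-seq nomination reproduced in >= 2
#' replicates; (4) an in silico site with Levenshtein distance < 3 from
#' the spacer; (5) an in silico site in an annotated exonic region. A
#' configurable pass-through for COSMID nominations (rule "cosmid") is on
#' by default.
#'
#' @param noms Nomination table from [ingest_nominations()].
#' @param cosmid_passthrough Keep COSMID nominations unconditionally.
#' @return The prioritized subset with a `rules` column (comma-joined rule
#'   tags).
#' @export
prioritize_sites <- function(noms, cosmid_passthrough = TRUE) {
  if (!nrow(noms)) { noms$rules <- character(0); return(noms) }
  miss_tier <- noms$method == "uncoverseq" & is.na(noms$tier)
  if (any(miss_tier))
    stop("uncoverseq nomination without tier: ",
         noms$site_id[miss_tier][1], call. = FALSE)
  r1 <- noms$method == "uncoverseq" & !is.na(noms$tier) &
    noms$tier >= 1 & noms$tier <= 3
  r2 <- noms$method == "abnoba"
  r3 <- noms$method == "castseq" & !is.na(noms$replicate_support) &
    noms$replicate_support >= 2
  r4 <- noms$method == "insilico" & !is.na(noms$levenshtein) &
    noms$levenshtein < 3
  r5 <- noms$method == "insilico" & !is.na(noms$annotation) &
    noms$annotation == "exonic"
  r6 <- cosmid_passthrough & noms$method == "cosmid"
  m <- cbind(tier1to3 = r1, abnoba = r2, castseq_reproducible = r3,
             insilico_lev_lt3 = r4, insilico_exonic = r5, cosmid = r6)
  keep <- rowSums(m) > 0
  rules <- apply(m, 1, function(x) paste(colnames(m)[x], collapse = ","))
  out <- noms[keep, , drop = FALSE]
  out$rules <- rules[keep]
  rownames(out) <- NULL
  out
}

#' Deduplicate prioritized nominations into the confirmation panel
#'
#' Single-linkage merge of cut positions within `merge_distance` bases on
#' the same contig (strand-agnostic). Contributing methods are unioned and
#' the representative cut is the evidence-weighted median (one vote per
#' contributing nomination).
#'
#' @param prio Prioritized nominations from [prioritize_sites()].
#' @param merge_distance Merge window in bases.
#' @return Panel data frame: `panel_id`, `contig`, `cut`, `start`, `end`
#'   (merged interval), `methods` (comma-joined set), `n_nominations`,
#'   `rules` (union), `best_levenshtein`, `member_ids`.
#' @export
merge_panel <- function(prio, merge_distance = 10L) {
  if (!nrow(prio))
    return(data.frame(panel_id = character(0), contig = character(0),
                      cut = integer(0), start = integer(0), end = integer(0),
                      methods = character(0), n_nominations = integer(0),
                      rules = character(0), best_levenshtein = integer(0),
                      member_ids = character(0), stringsAsFactors = FALSE))
  if (is.null(prio$rules)) prio$rules <- ""
  out <- list()
  for (ctg in unique(prio$contig)) {
    p <- prio[prio$contig == ctg, , drop = FALSE]
    p <- p[order(p$cut), , drop = FALSE]
    brk <- c(0L, cumsum(diff(p$cut) > merge_distance))
    for (b in unique(brk)) {
      g <- p[brk == b, , drop = FALSE]
      # accept either raw nominations or an already-merged panel (so the
      # merge is idempotent)
      meth <- if ("method" %in% names(g)) g$method else
        unlist(strsplit(g$methods, ","))
      ids <- if ("site_id" %in% names(g)) g$site_id else
        unlist(strsplit(g$member_ids, ","))
      lev <- if ("levenshtein" %in% names(g)) g$levenshtein else
        g$best_levenshtein
      nvote <- if ("n_nominations" %in% names(g)) g$n_nominations else
        rep(1L, nrow(g))
      rep_cut <- weighted_median(g$cut, nvote)
      out[[length(out) + 1]] <- data.frame(
        contig = ctg, cut = rep_cut,
        start = min(g$start %||% g$cut, g$cut), end = max(g$end %||%
          (g$cut + 1L), g$cut + 1L),
        methods = paste(sort(unique(meth)), collapse = ","),
        n_nominations = sum(nvote),
        rules = paste(sort(unique(unlist(strsplit(g$rules, ",")))),
                      collapse = ","),
        best_levenshtein = if (all(is.na(lev))) NA_integer_
          else as.integer(min(lev, na.rm = TRUE)),
        member_ids = paste(sort(unique(ids)), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$cut), , drop = FALSE]
  res$panel_id <- sprintf("panel_%03d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res[, c("panel_id", "contig", "cut", "start", "end", "methods",
          "n_nominations", "rules", "best_levenshtein", "member_ids")]
}
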