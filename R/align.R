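#' Levenshtein distance
#'
#' Minimum number of substitutions, insertions, and deletions between two
#' strings (full-string dynamic programming).
#' @param a,b Character scalars.
#' @return Integer distance.
#' @export
levenshtein <- function(a, b) {
  as.integer(glocal_distance_full(a, b))
}

glocal_distance_full <- function(a, b) {
  # plain global edit distance via the same DP kernel family
  drop(adist(a, b))
}

#' Glocal (semi-global) guide alignment against a window
#'
#' Aligns the spacer end-to-end against a genomic window whose end gaps are
#' free, on both strands, and reports the placement minimizing the edit
#' distance (the post-alignment Levenshtein distance of the nomination
#' rule), with the Needleman-Wunsch score (match +1, mismatch −1, gap −2)
#' of that alignment. The PAM is checked immediately 3' of the aligned
#' protospacer. Ties break toward lower distance, then the leftmost window
#' offset, then the + strand.
#'
#' @param guide A [guide_spec()].
#' @param window Window sequence (character scalar), + strand of the genome.
#' @param pam_mode `"strict"` (the guide's PAM), `"relaxed"` (NGG or NAG),
#'   or `"none"` (skip the check).
#' @param min_window_frac If the window is shorter than this fraction of the
#'   spacer, a no-alignment sentinel (`distance = Inf`) is returned.
#' @return List of class `guide_alignment`: `distance`, `strand`, `start`,
#'   `end` (0-based half-open, window + strand coordinates), `mismatches`,
#'   `insertions`, `deletions`, `score`, `pam_found`, `aligned_spacer`,
#'   `aligned_window`.
#' @export
glocal_align <- function(guide, window, pam_mode = c("strict", "relaxed",
                                                     "none"),
                         min_window_frac = 0.5) {
  pam_mode <- match.arg(pam_mode)
  window <- toupper(window)
  if (nchar(window) < min_window_frac * nchar(guide$spacer)) {
    return(structure(list(distance = Inf, strand = NA, start = NA,
                          end = NA, mismatches = NA, insertions = NA,
                          deletions = NA, score = NA, pam_found = FALSE,
                          aligned_spacer = NA, aligned_window = NA),
                     class = "guide_alignment"))
  }
  pams <- switch(pam_mode, strict = guide$pam, relaxed = c("NGG", "NAG"),
                 none = character(0))
  best <- NULL
  for (strand in c("+", "-")) {
    w <- if (strand == "+") window else revcomp(window)
    a <- .glocal_align_cpp(guide$spacer, w)
    a$strand <- strand
    # PAM sits 3' of the aligned protospacer in the searched orientation
    pam_seq <- substr(w, a$end + 1L, a$end + nchar(guide$pam))
    a$pam_found <- length(pams) > 0 &&
      any(vapply(pams, function(p) pam_matches(pam_seq, p), logical(1)))
    if (pam_mode == "none") a$pam_found <- NA
    if (strand == "-") {   # convert to + strand window coordinates
      L <- nchar(window)
      s <- L - a$end; e <- L - a$start
      a$start <- s; a$end <- e
    }
    if (is.null(best) || a$distance < best$distance) best <- a
  }
  class(best) <- "guide_alignment"
  best
}

#' @export
print.guide_alignment <- function(x, ...) {
  if (is.infinite(x$distance)) {
    cat("guide_alignment: no alignment (window too short)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "guide_alignment: distance %d (%d mm, %d ins, %d del), strand %s, [%d,%d), score %d, PAM %s\n",
    x$distance, x$mismatches, x$insertions, x$deletions, x$strand,
    x$start, x$end, x$score,
    if (is.na(x$pam_found)) "unchecked" else if (x$pam_found) "found"
    else "absent"))
  cat(" ", x$aligned_spacer, "\n ", x$aligned_window, "\n")
  invisible(x)
}
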