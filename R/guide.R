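#' Define a CRISPR guide
#'
#' Bundles the programmable spacer sequence, the PAM rule and the cut-site
#' offset that every alignment and search operation consumes. Defaults match
#' SpCas9 practice: a 20-nt spacer, an NGG PAM 3' of the protospacer, and a
#' blunt cut 3 bp 5' of the PAM.
#'
#' @param spacer Uppercase ACGT spacer sequence (typically 20 nt).
#' @param name Guide name used in reports.
#' @param pam IUPAC PAM pattern required 3' of the protospacer.
#' @param cut_offset Signed offset, in bases, of the cut from the
#'   PAM-proximal end of the protospacer (default -3: between spacer
#'   positions 17 and 18 of a 20-mer).
#' @return An object of class `guide_spec`.
#' @examples
#' g <- guide_spec("GACCTGCGGAAGATCGAGAC", name = "demo")
#' g$cut_offset
#' @export
guide_spec <- function(spacer, name = "guide", pam = "NGG", cut_offset = -3L) {
  spacer <- toupper(spacer)
  if (!grepl("^[ACGT]+$", spacer))
    stop("spacer must be an uppercase ACGT string", call. = FALSE)
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  if (!all(strsplit(toupper(pam), "")[[1]] %in% iupac))
    stop("pam must be a valid IUPAC pattern", call. = FALSE)
  cut_offset <- as.integer(cut_offset)
  # cut must fall inside the protospacer
  if (cut_offset >= 0L || -cut_offset >= nchar(spacer))
    stop("cut_offset must place the cut inside the protospacer", call. = FALSE)
  structure(
    list(name = name, spacer = spacer, pam = toupper(pam),
         cut_offset = cut_offset),
    class = "guide_spec")
}

#' @export
print.guide_spec <- function(x, ...) {
  cat(sprintf("guide_spec '%s': %s + %s (cut offset %d)\n",
              x$name, x$spacer, x$pam, x$cut_offset))
  invisible(x)
}

#' Cut position implied by a protospacer placement
#'
#' @param proto_start,proto_end 0-based half-open protospacer interval.
#' @param strand "+" or "-" (PAM side follows strand).
#' @param guide A [guide_spec()].
#' @return 0-based cut position (the bond 5' of the returned coordinate).
#' @export
cut_position <- function(proto_start, proto_end, strand, guide) {
  ifelse(strand == "+", proto_end + guide$cut_offset,
         proto_start - guide$cut_offset)
}

pam_regex <- function(pam) {
  map <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(pam, "")[[1]]
  paste0(vapply(chars, function(c) {
    e <- map[[c]]
    if (nchar(e) == 1) e else paste0("[", e, "]")
  }, character(1)), collapse = "")
}

pam_matches <- function(seq, pam) {
  nchar(seq) == nchar(pam) & grepl(paste0("^", pam_regex(pam), "$"), seq)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# n random sequences of length `len` (uniform base composition), vectorised
random_dna_vec <- function(n, len) {
  if (n == 0) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}
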