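#' Simulate a ddPCR plate
#'
#' Dual-probe knockout assay: the reference probe detects all alleles, the
#' wild-type probe spans the cut site and detects only unedited alleles.
#' Template copies partition into droplets with Poisson occupancy, so a
#' droplet is probe-positive when it received at least one detectable copy:
#' P(positive) = 1 - exp(-lambda) with lambda the per-droplet mean copies of
#' the probe's detectable template (the WT channel sees
#' `(1 - true_ko_fraction)` of the total).
#'
#' @param true_ko_fraction True knockout fraction(s) in `[0, 1]`; one well
#'   per element (recycled against `nominal_ko` if given).
#' @param droplets_per_well Droplets generated per well.
#' @param copies_per_droplet_mean Mean template copies per droplet (total
#'   alleles, reference channel).
#' @param n_wells Wells per `true_ko_fraction` value.
#' @param nominal_ko Optional nominal KO labels for control wells.
#' @param seed Integer seed.
#' @return Data frame with `well`, `true_ko`, `nominal_ko`, `wt_positive`,
#'   `ref_positive`, `total_droplets`.
#' @export
simulate_ddpcr_plate <- function(true_ko_fraction, droplets_per_well = 20000L,
                                 copies_per_droplet_mean = 0.8,
                                 n_wells = 1L, nominal_ko = NA,
                                 seed = 1L) {
  if (any(true_ko_fraction < 0 | true_ko_fraction > 1))
    stop("true_ko_fraction must lie in [0, 1]", call. = FALSE)
  if (droplets_per_well <= 0)
    stop("droplets_per_well must be positive", call. = FALSE)
  ko <- rep(true_ko_fraction, each = n_wells)
  nom <- rep(nominal_ko, length.out = length(true_ko_fraction))
  nom <- rep(nom, each = n_wells)
  with_seed(seed, {
    n <- length(ko)
    lam_ref <- copies_per_droplet_mean
    ref_pos <- rbinom(n, droplets_per_well, 1 - exp(-lam_ref))
    wt_pos <- rbinom(n, droplets_per_well, 1 - exp(-lam_ref * (1 - ko)))
    data.frame(well = sprintf("W%03d", seq_len(n)), true_ko = ko,
               nominal_ko = nom, wt_positive = wt_pos,
               ref_positive = ref_pos,
               total_droplets = as.integer(droplets_per_well),
               stringsAsFactors = FALSE)
  })
}

#' ddPCR assay oligo fixtures
#'
#' The wild-type (FAM) and reference (HEX) probe sequences and the primer
#' pair of the knockout-efficiency assay, as plain sequences (modification
#' tags stripped).
#' @return Named character vector.
#' @export
ddpcr_assay_oligos <- function() {
  c(probe_wt_fam = "AGCCGCCGCGCGCCACTACT",
    probe_ref_hex = "CACCTTCCCCAAGCGCGG",
    primer_fwd = "ATGGGAGTGCAGGTGGAAACCATC",
    primer_rev = "CGCTGGGCCCCCGACTCA")
}
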