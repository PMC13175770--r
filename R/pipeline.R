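#' Default run configuration
#'
#' All analysis thresholds with their documented defaults (search flank 40
#' bp; nomination Levenshtein < 7; FDR 0.05; CAST-seq ingest p < 0.005;
#' variant allele frequency > 0.01; coverage thresholds 100/1,000/10,000
#' with testing above 1,000; panel merge distance 10 bp; quantification
#' window ±2 bp; ddPCR tolerance ±10 percentage points), the default
#' synthetic scale (one 1-Mb contig, 3 treatment + 3 control samples,
#' 50,000 read pairs per sample), and the simulated study conditions.
#'
#' @param seed Integer seed governing every stage.
#' @return Nested configuration list.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    genome = list(n_contigs = 1L, contig_length = 1000000L,
                  gc_fraction = 0.41,
                  tracts = list(list(contig = 1L, start = 600200L,
                                     base = "A", length = 12L))),
    guide = list(name = "synthetic_guide",
                 spacer = "GACCTGCGGAAGATCGAGAC",
                 pam = "NGG", cut_offset = -3L),
    sites = list(
      list(distance = 2L, region_class = "intronic",
           integration_rate = 0.004, editing_fraction = 0.004),
      list(distance = 4L, region_class = "intergenic",
           integration_rate = 0.002, editing_fraction = 0.002),
      list(distance = 6L, region_class = "exonic",
           integration_rate = 0.001, editing_fraction = 0.0005)),
    on_target = list(integration_rate = 0.02, editing_fraction = 0.98),
    samples = list(n_treatment = 3L, n_control = 3L, depth = 50000L),
    reads = list(umi_length = 8L, read_length = 150L,
                 tag_sequence = default_tag(), mispriming_rate = 0),
    error_model = list(substitution_rate = 0.001,
                       base_indel_error_rate = 0.0012,
                       homopolymer_multiplier = 5,
                       min_tract_length = 6L,
                       quality_mean = 36, quality_sd = 3),
    thresholds = list(flank = 40L, max_lev = 7L, insilico_max_distance = 5L,
                      insilico_priority_lev = 3L, fdr = 0.05,
                      castseq_p = 0.005, af = 0.01,
                      coverage = c(100L, 1000L, 10000L),
                      min_coverage = 1000L, merge_distance = 10L,
                      window_halfwidth = 2L, cluster_window = 5L,
                      flanking_width = 2000L, ddpcr_tolerance = 10),
    confirmation = list(depth = 200000L),
    ddpcr = list(droplets_per_well = 20000L, copies_per_droplet_mean = 0.8,
                 control_levels = c(50, 75, 100), sample_true_ko = 90),
    stages = list(simulate = TRUE, preprocess = TRUE, nominate = TRUE,
                  insilico = TRUE, prioritize = TRUE, confirm = TRUE,
                  ddpcr = TRUE))
}

validate_run_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!ok) stop("config error at ", field, ": ", why, call. = FALSE)
  }
  th <- cfg$thresholds
  chk(is.numeric(th$fdr) && th$fdr > 0 && th$fdr <= 1, "thresholds.fdr",
      "must lie in (0, 1]")
  chk(th$max_lev >= 1, "thresholds.max_lev", "must be >= 1")
  chk(th$flank >= 1, "thresholds.flank", "must be >= 1")
  chk(th$af >= 0 && th$af <= 1, "thresholds.af", "must lie in [0, 1]")
  chk(th$castseq_p > 0 && th$castseq_p < 1, "thresholds.castseq_p",
      "must lie in (0, 1)")
  chk(all(th$coverage > 0), "thresholds.coverage", "must be positive")
  chk(th$merge_distance >= 0, "thresholds.merge_distance",
      "must be nonnegative")
  chk(cfg$samples$n_treatment >= 1 && cfg$samples$n_control >= 1,
      "samples", "need >= 1 treatment and >= 1 control")
  chk(cfg$samples$depth > 0, "samples.depth", "must be positive")
  chk(grepl("^[ACGT]+$", cfg$guide$spacer), "guide.spacer",
      "must be uppercase ACGT")
  invisible(TRUE)
}

config_error_model <- function(cfg) {
  do.call(error_model, cfg$error_model)
}

#' Run the full synthetic pipeline
#'
#' Executes the stages in dependency order -- simulate, preprocess +
#' cluster, nominate, in silico search, prioritize, confirm, ddPCR,
#' report -- writing plain-text stage outputs, a config snapshot, and a
#' provenance file with per-output checksums. Reruns with an identical
#' config and seed reproduce identical outputs.
#'
#' @param config A config list from [default_run_config()], a YAML path,
#'   or `NULL` for the defaults.
#' @param outdir Run directory (created).
#' @param seed Overrides `config$seed` when given.
#' @return Invisibly, a list of in-memory stage results (`truth`,
#'   `clusters`, `nomination`, `insilico`, `panel`, `confirmation`,
#'   `ddpcr`, `summary`).
#' @export
run_pipeline <- function(config = NULL, outdir, seed = NULL) {
  if (is.null(config)) config <- default_run_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  validate_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed0 <- config$seed
  th <- config$thresholds
  em <- config_error_model(config)
  log_msg <- function(...) message("[otsentry] ", ...)

  ## stage: simulate -------------------------------------------------------
  tracts <- if (length(config$genome$tracts))
    do.call(rbind, lapply(config$genome$tracts, as.data.frame)) else NULL
  gcfg <- synth_genome_config(
    n_contigs = config$genome$n_contigs,
    contig_length = config$genome$contig_length,
    gc_fraction = config$genome$gc_fraction,
    homopolymer_tracts = tracts, seed = seed0)
  genome <- make_reference(gcfg, outdir = file.path(outdir, "reference"))
  guide <- guide_spec(config$guide$spacer, name = config$guide$name,
                      pam = config$guide$pam,
                      cut_offset = config$guide$cut_offset)
  # on-target: distance 0, intergenic by default
  req <- rbind(
    data.frame(distance = 0L, region_class = "intergenic",
               integration_rate = config$on_target$integration_rate,
               editing_fraction = config$on_target$editing_fraction),
    do.call(rbind, lapply(config$sites, as.data.frame)))
  planted <- plant_offtarget_sites(genome, guide, req, seed = seed0 + 1L)
  genome <- planted$genome
  write_fasta_genome(genome$seqs,
                     file.path(outdir, "reference", "reference.fa"))
  truth <- truth_table(planted$truth[1, ], planted$truth[-1, ],
                       n_treatment = config$samples$n_treatment,
                       n_control = config$samples$n_control,
                       depth = config$samples$depth)
  run <- simulate_tagseq_run(
    genome, truth, guide, em,
    tag_sequence = config$reads$tag_sequence,
    umi_length = config$reads$umi_length,
    read_length = config$reads$read_length,
    mispriming_rate = config$reads$mispriming_rate,
    seed = seed0 + 2L, outdir = file.path(outdir, "fastq"))
  log_msg("simulate: ", nrow(truth$sample_plan), " samples, ",
          nrow(planted$truth), " planted sites")

  st <- config$stages
  on_ <- function(x) !isFALSE(st[[x]])
  results <- list(config = config, truth = truth)

  ## stage: preprocess + cluster -------------------------------------------
  if (!on_("preprocess")) return(invisible(results))
  cons_all <- list(); totals <- integer(0)
  for (s in names(run$samples)) {
    x <- run$samples[[s]]
    ann <- preprocess_tagseq_reads(
      data.frame(id = x$id, seq = x$r1, qual = x$q1,
                 stringsAsFactors = FALSE),
      read_structure = paste0(config$reads$umi_length, "M+T"),
      tag_sequence = config$reads$tag_sequence)
    aln <- map_reads(ann$genomic, genome)
    df <- cbind(sample = s, ann,
                aln[, c("contig", "pos", "strand", "nm", "status")])
    cons <- umi_consensus(df[df$status == "mapped", , drop = FALSE])
    totals[s] <- nrow(cons)
    cons_all[[s]] <- cons
  }
  cons_all <- do.call(rbind, cons_all)
  clusters <- call_integration_clusters(cons_all,
                                        cluster_window = th$cluster_window)
  flat <- clusters[, c("cluster_id", "contig", "junction", "n_reads",
                       "bidirectional")]
  write_tsv(flat, file.path(outdir, "clusters.tsv"))
  log_msg("cluster: ", nrow(clusters), " integration clusters")

  ## stage: nominate --------------------------------------------------------
  results$clusters <- clusters
  if (!on_("nominate")) return(invisible(results))
  roles <- stats::setNames(truth$sample_plan$role, truth$sample_plan$sample)
  nom <- nominate_from_clusters(clusters, genome, guide, roles, totals,
                                flank = th$flank, fdr = th$fdr,
                                max_lev = th$max_lev)
  nom <- annotate_sites(nom, genome$genes,
                        flanking_width = th$flanking_width)
  nom <- assign_tiers(nom, default_tier_rules(config$samples$n_treatment))
  write_tsv(nom, file.path(outdir, "nomination.tsv"))
  nominated <- nom[nom$nominated, , drop = FALSE]
  if (nrow(nominated))
    write_bed6(data.frame(contig = nominated$contig,
                          start = nominated$cut,
                          end = nominated$cut + 1L,
                          name = nominated$site_id,
                          score = 0, strand = nominated$strand),
               file.path(outdir, "nominated_cut_sites.bed"))
  log_msg("nominate: ", sum(nom$nominated), " of ", nrow(nom),
          " candidates nominated")

  results$nomination <- nom

  ## stage: in silico -------------------------------------------------------
  if (!on_("insilico")) return(invisible(results))
  hits <- search_genome(genome, guide,
                        max_distance = th$insilico_max_distance)
  hits <- annotate_sites(
    transform(hits, cut = cut_position(start, end, strand, guide)),
    genome$genes, flanking_width = th$flanking_width)
  write_tsv(hits, file.path(outdir, "insilico.tsv"))
  log_msg("insilico: ", nrow(hits), " hits at distance <= ",
          th$insilico_max_distance)

  results$insilico <- hits

  ## stage: prioritize ------------------------------------------------------
  if (!on_("prioritize")) return(invisible(results))
  unc_path <- file.path(outdir, "uncoverseq_nominations.tsv")
  ins_path <- file.path(outdir, "insilico_nominations.tsv")
  write_tsv(data.frame(site_id = nominated$site_id,
                       contig = nominated$contig,
                       start = nominated$cut, end = nominated$cut + 1L,
                       cut = nominated$cut, strand = nominated$strand,
                       tier = nominated$tier,
                       levenshtein = nominated$levenshtein,
                       annotation = nominated$annotation,
                       replicate_support = nominated$replicate_support),
            unc_path)
  write_tsv(data.frame(site_id = sprintf("is_%03d", seq_len(nrow(hits))),
                       contig = hits$contig, start = hits$start,
                       end = hits$end, cut = hits$cut,
                       strand = hits$strand,
                       levenshtein = hits$levenshtein,
                       annotation = hits$annotation),
            ins_path)
  noms <- ingest_nominations(c(uncoverseq = unc_path, insilico = ins_path),
                             castseq_p = th$castseq_p)
  prio <- prioritize_sites(noms)
  panel <- merge_panel(prio, merge_distance = th$merge_distance)
  write_tsv(panel, file.path(outdir, "panel.tsv"))
  log_msg("prioritize: ", nrow(panel), " panel sites from ",
          nrow(prio), " prioritized nominations")

  results$panel <- panel

  ## stage: confirm (counts-mode amplicon assay at panel sites) -------------
  confirmation <- NULL
  if (on_("confirm") && nrow(panel)) {
    sites_truth <- all_truth_sites(truth)
    sites_truth$cut <- cut_position(sites_truth$start, sites_truth$end,
                                    sites_truth$strand, guide)
    assays <- design_amplicons(genome,
                               data.frame(site_id = panel$panel_id,
                                          contig = panel$contig,
                                          cut = panel$cut))
    truth_frac <- vapply(seq_len(nrow(panel)), function(i) {
      near <- sites_truth$contig == panel$contig[i] &
        abs(sites_truth$cut - panel$cut[i]) <= 10
      if (any(near)) sites_truth$editing_fraction[near][1] else 0
    }, numeric(1))
    samp <- c(sprintf("donor_%d", seq_len(config$samples$n_treatment)),
              sprintf("ctrl_%d", seq_len(config$samples$n_control)))
    role <- rep(c("treatment", "control"),
                c(config$samples$n_treatment, config$samples$n_control))
    fr <- outer(truth_frac, as.numeric(role == "treatment"))
    dimnames(fr) <- list(panel$panel_id, samp)
    counts <- simulate_amplicon_assay(assays, fr,
                                      depths = config$confirmation$depth,
                                      em = em, mode = "counts",
                                      seed = seed0 + 3L)
    counts$role <- role[match(counts$sample, samp)]
    counts$frequency <- counts$indel / counts$total
    confirmation <- test_confirmation(counts, fdr = th$fdr,
                                      min_coverage = th$min_coverage)
    write_tsv(counts, file.path(outdir, "amplicon_counts.tsv"))
    write_tsv(confirmation, file.path(outdir, "confirmation.tsv"))
    # scatter analogue: mean control vs mean treatment frequency per site
    write_tsv(confirmation[, c("site_id", "pooled_control_frequency",
                               "mean_treatment_frequency", "significant")],
              file.path(outdir, "confirmation_scatter.tsv"))
    log_msg("confirm: ", sum(confirmation$significant), " of ",
            nrow(confirmation), " sites significant")
  }

  results$confirmation <- confirmation
  if (!on_("ddpcr")) {
    results$summary <- write_reports(outdir, results)
    return(invisible(results))
  }

  ## stage: ddPCR ------------------------------------------------------------
  dd <- config$ddpcr
  ctrl_wells <- simulate_ddpcr_plate(dd$control_levels / 100,
                                     dd$droplets_per_well,
                                     dd$copies_per_droplet_mean,
                                     nominal_ko = dd$control_levels,
                                     seed = seed0 + 4L)
  cal <- fit_ko_curve(ctrl_wells, tolerance = th$ddpcr_tolerance)
  samp_well <- simulate_ddpcr_plate(dd$sample_true_ko / 100,
                                    dd$droplets_per_well,
                                    dd$copies_per_droplet_mean,
                                    seed = seed0 + 5L)
  ko <- estimate_ko(samp_well, cal)
  ddpcr_tab <- data.frame(true_ko = dd$sample_true_ko,
                          raw_ko = ko$raw_ko, calibrated_ko = ko$ko,
                          calibration_accepted = cal$accepted)
  write_tsv(ddpcr_tab, file.path(outdir, "ddpcr.tsv"))
  log_msg(sprintf("ddpcr: true %.1f%%, calibrated %.1f%%",
                  dd$sample_true_ko, ko$ko))

  results$ddpcr <- ddpcr_tab
  results$summary <- write_reports(outdir, results)
  invisible(results)
}

#' Write run reports with cross-checked counts
#'
#' Builds the machine-readable run summary (nomination counts by tier,
#' annotation fractions, coverage fractions, confirmed-site table, config
#' snapshot, and per-output checksums). Every count is re-derived from the
#' stage TSVs on disk and compared with the in-memory results; any
#' inconsistency is a hard error, never silently corrected.
#'
#' @param outdir Run directory holding the stage TSVs.
#' @param results In-memory stage results from [run_pipeline()].
#' @return The summary list, invisibly (written to `summary.json` and
#'   `provenance.json`).
#' @export
write_reports <- function(outdir, results) {
  nom_disk <- read_tsv(file.path(outdir, "nomination.tsv"))
  if (nrow(nom_disk) != nrow(results$nomination) ||
      sum(nom_disk$nominated) != sum(results$nomination$nominated))
    stop("consistency error: nomination.tsv does not match computed ",
         "results", call. = FALSE)
  tier_counts <- table(factor(nom_disk$tier[nom_disk$nominated],
                              levels = 1:4))
  ann <- annotation_summary(nom_disk[nom_disk$nominated, , drop = FALSE])
  confirmed <- NULL
  coverage <- NULL
  if (!is.null(results$confirmation)) {
    conf_disk <- read_tsv(file.path(outdir, "confirmation.tsv"))
    if (nrow(conf_disk) != nrow(results$confirmation) ||
        sum(conf_disk$significant) != sum(results$confirmation$significant))
      stop("consistency error: confirmation.tsv does not match computed ",
           "results", call. = FALSE)
    counts_disk <- read_tsv(file.path(outdir, "amplicon_counts.tsv"))
    cov <- summarize_coverage(counts_disk,
                              results$config$thresholds$coverage,
                              results$config$thresholds$min_coverage)
    coverage <- cov$fractions
    confirmed <- conf_disk[conf_disk$significant, , drop = FALSE]
  }
  summary <- list(
    n_candidates = nrow(nom_disk),
    n_nominated = sum(nom_disk$nominated),
    tier_counts = as.list(stats::setNames(as.integer(tier_counts),
                                          paste0("tier", 1:4))),
    annotation_fractions = ann,
    coverage_fractions = coverage,
    confirmed_sites = confirmed,
    ddpcr = results$ddpcr,
    config = results$config)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE)
  outs <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  outs <- outs[!basename(outs) %in% c("provenance.json")]
  prov <- data.frame(file = sub(paste0("^", outdir, "/?"), "", outs),
                     md5 = unname(tools::md5sum(outs)),
                     stringsAsFactors = FALSE)
  jsonlite::write_json(list(outputs = prov, seed = results$config$seed),
                       file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(summary)
}
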