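#' Default run configuration
#'
#' All thresholds default to the stated analysis conventions: 64-read gene
#' cutoff, 4-fold dual-control enrichment, p < 1e-5 region significance,
#' the default offset table, top 5\% spike-in genes for rescaling, first-8 /
#' last-5 / last-4 codon exclusions, and 100-count conversion coverage.
#'
#' @param ... overrides of the defaults.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(...) {
  cfg <- list(min_reads = 64L, fold = 4, p_max = 1e-5,
              offsets = default_offset_table(), top_fraction = 0.05,
              exclude_first_codons = 8L, exclude_last_codons_body = 5L,
              exclude_last_codons_occupancy = 4L, min_coverage = 100L,
              pause_lengths = LONG_FOOTPRINTS, seed = 1L)
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

fill_counts <- function(counts, gene_ids) {
  # complete a count table over the annotated gene universe (zeros included)
  out <- data.table(gene_id = gene_ids)
  out[, count := counts$count[match(gene_id, counts$gene_id)]]
  out[is.na(count), count := 0L]
  out[]
}

report_row <- function(stage, library, n_in, n_out) {
  data.table(stage = stage, library = library, n_in = n_in, n_out = n_out,
             n_removed = n_in - n_out)
}

#' Run the two-condition translatome comparison
#'
#' Sequences footprint ingestion, spike-in normalization, and the
#' positional statistics over a simulated (or equivalently structured)
#' dual-species experiment: per-library ORF assignment and framing, bulk
#' translation ratios, RPKM rescaling against a fixed normalizing library,
#' start/body tables with the condition fold change, and merged-replicate
#' pause tables.
#'
#' @param sim a \code{footprint_sim} (libraries + annotations + genome), or
#'   a compatible list.
#' @param config a \code{\link{run_config}}.
#' @param normalizer library id fixed as the rescaling reference (default:
#'   first replicate of the last condition, mirroring normalization to a
#'   perturbed-condition replicate).
#' @return list of class \code{run_result} with elements \code{report},
#'   \code{bulk_ratios}, \code{scaling}, \code{rescaled_totals},
#'   \code{start_body}, \code{start_body_change}, \code{metagene} and
#'   \code{pause} (per condition), plus \code{gene_counts}.
#' @export
run_translatome_comparison <- function(sim, config = run_config(),
                                       normalizer = NULL) {
  libs <- sim$libraries
  if (any(vapply(libs, function(l) all(is.na(l$species)), logical(1))))
    stop("config error: libraries must carry species tags")
  conds <- sub("_rep.*$", "", names(libs))
  if (is.null(normalizer))
    normalizer <- names(libs)[conds == conds[length(conds)]][1]
  report <- list()
  framed <- list(); counts <- list(); spike_counts <- list()
  bulk <- numeric()
  for (nm in names(libs)) {
    al <- libs[[nm]]
    an <- al[al$species == "analysis"]
    spk <- al[al$species == "spikein"]
    asg <- assign_to_orf(an, sim$annotations)
    fr <- apply_offsets(asg, config$offsets)
    framed[[nm]] <- fr
    report[[length(report) + 1L]] <-
      report_row("assign_analysis", nm, attr(asg, "n_input"),
                 attr(asg, "n_input") - attr(asg, "n_unassigned"))
    report[[length(report) + 1L]] <-
      report_row("frame_analysis", nm, nrow(asg), attr(fr, "n_kept"))
    sasg <- assign_to_orf(spk, sim$spike_annotations)
    counts[[nm]] <- fill_counts(gene_counts(asg, config$exclude_first_codons),
                                sim$annotations$gene_id)
    spike_counts[[nm]] <- fill_counts(
      gene_counts(sasg, config$exclude_first_codons),
      sim$spike_annotations$gene_id)
    bulk[nm] <- bulk_translation_ratio(counts[[nm]], spike_counts[[nm]])
  }
  glen <- spliced_length(sim$annotations)
  slen <- spliced_length(sim$spike_annotations)
  rpkms <- lapply(names(libs), function(nm) {
    libsize <- sum(counts[[nm]]$count) + sum(spike_counts[[nm]]$count)
    list(analysis = rpkm(counts[[nm]], glen, libsize),
         spike = rpkm(spike_counts[[nm]], slen, libsize))
  })
  names(rpkms) <- names(libs)
  scaling <- lapply(names(libs), function(nm)
    fit_spikein_scaling(rpkms[[nm]]$spike, rpkms[[normalizer]]$spike,
                        config$top_fraction))
  names(scaling) <- names(libs)
  rescaled_totals <- vapply(names(libs), function(nm)
    sum(apply_scaling(rpkms[[nm]]$analysis, scaling[[nm]])), numeric(1))
  # condition-level positional statistics on pooled replicates
  ucond <- unique(conds)
  pooled <- lapply(ucond, function(cc)
    rbindlist(framed[conds == cc]))
  names(pooled) <- ucond
  mg <- lapply(pooled, function(fr)
    metagene(fr, sim$annotations, "start", c(-30L, 60L),
             min_reads = config$min_reads))
  sb <- lapply(names(libs), function(nm)
    start_body_ratios(framed[[nm]], sim$annotations,
                      min_reads = config$min_reads))
  names(sb) <- names(libs)
  sb_change <- NULL
  if (length(ucond) == 2L) {
    # replicate-averaged per-gene ratios, then the condition fold change
    avg_ratio <- function(cc) {
      tabs <- sb[conds == cc]
      m <- rbindlist(tabs)[, .(ratio = mean(ratio)), by = gene_id]
      stats::setNames(m$ratio, m$gene_id)
    }
    r1 <- avg_ratio(ucond[1]); r2 <- avg_ratio(ucond[2])
    shared <- intersect(names(r1), names(r2))
    shared <- shared[r1[shared] > 0]
    sb_change <- r2[shared] / r1[shared]
  }
  pause <- lapply(pooled, function(fr)
    pause_scores(fr, sim$annotations, sim$genome, codon_position = 2L,
                 site = "A", lengths = config$pause_lengths))
  structure(list(report = rbindlist(report), bulk_ratios = bulk,
                 scaling = scaling, rescaled_totals = rescaled_totals,
                 gene_counts = counts, spike_counts = spike_counts,
                 rpkms = rpkms, start_body = sb,
                 start_body_change = sb_change,
                 metagene = mg, pause = pause, normalizer = normalizer),
            class = "run_result")
}

#' Run the CLIP quantification stage
#'
#' Computes per-library tRNA densities, dual-control enrichment calls, and
#' T-to-C conversion profiles for the IP libraries.
#'
#' @param sim a \code{clip_sim} (or list with a \code{libraries} element of
#'   \code{clip_library} objects).
#' @param reference the \code{collapsed_reference} the libraries map to.
#' @param config a \code{\link{run_config}}.
#' @return list of class \code{clip_result}: \code{report},
#'   \code{densities}, \code{enrichment}, \code{conversion} (per IP
#'   replicate).
#' @export
run_clip_analysis <- function(sim, reference, config = run_config()) {
  libs <- sim$libraries
  roles <- vapply(libs, `[[`, character(1), "role")
  if (!any(roles == "SMI") || !any(roles == "untagged"))
    stop("config error: SMI and untagged control libraries are required")
  if (!any(roles == "IP")) stop("config error: no IP library declared")
  ann <- reference$artificial_annotations
  dens <- lapply(libs, trna_density, annotations = ann,
                 cutoff = config$min_reads)
  report <- rbindlist(lapply(names(libs), function(nm)
    report_row("density_cutoff", nm, nrow(dens[[nm]]),
               sum(dens[[nm]]$meets_cutoff))))
  enr <- trna_enrichment(dens[roles == "IP"],
                         dens[[which(roles == "SMI")[1]]],
                         dens[[which(roles == "untagged")[1]]],
                         fold = config$fold)
  conv <- lapply(libs[roles == "IP"], conversion_profile,
                 target_chrom = "artificial",
                 min_coverage = config$min_coverage)
  structure(list(report = report, densities = dens, enrichment = enr,
                 conversion = conv),
            class = "clip_result")
}

#' Gene-set overrepresentation by Fisher's exact test
#'
#' Tests whether hits are overrepresented in a gene set relative to a
#' universe containing it. The primary 2x2 table subtracts the set from the
#' universe so the margins are disjoint; the literal set-vs-whole-universe
#' construction is also computed and reported.
#'
#' @param hits_in_set,set_size,hits_in_universe,universe_size counts; the
#'   universe contains the set.
#' @return list: \code{odds_ratio}, \code{p_value} (one-sided, greater),
#'   \code{p_two_sided}, \code{table} (disjoint margins), and
#'   \code{p_literal} for the non-disjoint convention.
#' @export
overrepresentation_test <- function(hits_in_set, set_size,
                                    hits_in_universe, universe_size) {
  if (hits_in_set > set_size || hits_in_universe > universe_size ||
      hits_in_set > hits_in_universe || set_size > universe_size)
    stop("inconsistent counts: the set must be contained in the universe")
  a <- hits_in_set
  b <- set_size - hits_in_set
  c_ <- hits_in_universe - hits_in_set
  d <- (universe_size - set_size) - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("in_set", "out_set"), c("hit", "not_hit")))
  ft_g <- stats::fisher.test(tab, alternative = "greater")
  ft_2 <- stats::fisher.test(tab)
  tab_lit <- matrix(c(a, b, hits_in_universe, universe_size - hits_in_universe),
                    nrow = 2, byrow = TRUE)
  ft_lit <- stats::fisher.test(tab_lit, alternative = "greater")
  list(odds_ratio = unname(ft_2$estimate), p_value = ft_g$p.value,
       p_two_sided = ft_2$p.value, table = tab, p_literal = ft_lit$p.value)
}
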