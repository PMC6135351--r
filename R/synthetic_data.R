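STOP_CODONS <- c("TAA", "TAG", "TGA")

default_length_distribution <- function() {
  c(`15` = 0.01, `16` = 0.01, `17` = 0.01, `18` = 0.01, `19` = 0.01,
    `20` = 0.04, `21` = 0.05, `22` = 0.04,
    `25` = 0.04, `26` = 0.05, `27` = 0.03,
    `28` = 0.32, `29` = 0.18, `30` = 0.12, `31` = 0.05,
    `32` = 0.02, `33` = 0.005, `34` = 0.005)
}

#' Configuration for footprint library simulation
#'
#' Defaults model a desk-scale recovery-from-starvation experiment: a few
#' hundred genes with lognormal expression, a footprint length law
#' dominated by 28-30 mers with minor short (20-22) and boundary classes,
#' high but imperfect reading-frame fidelity, and a spike-in species whose
#' per-gene abundances are fixed across conditions.
#'
#' @param n_genes number of analysis-species genes (default 200).
#' @param gene_length_range codon range, inclusive (default 100-300).
#' @param expression_meanlog,expression_sdlog lognormal expression law
#'   (defaults 0 and 1.5; expression spanning a few decades, as in real
#'   mRNA abundance distributions, keeps the spike-in regression well
#'   conditioned).
#' @param length_distribution named probability vector over lengths 15-34;
#'   must sum to 1 within 1e-9.
#' @param frame_fidelity probability a 5' end lands in the canonical frame
#'   for its length class (default 0.95).
#' @param start_pause_multiplier scalar or per-gene named vector of
#'   occupancy multipliers at the start-codon position (P site = codon 1).
#' @param codon_pause_multipliers named vector codon -> A-site dwell
#'   multiplier (applied wherever that codon is decoded in the A site).
#'   Pause multipliers model the perturbed state and are applied to the
#'   last condition only (the first condition is the unperturbed baseline);
#'   with a single condition they apply to it directly.
#' @param global_translation_factor scaling of analysis-species totals in
#'   condition 2 relative to condition 1 (spike-in totals are unchanged).
#' @param spikein_fraction fraction of condition-1 reads from the spike-in
#'   species (default 0.1).
#' @param n_spike_genes spike-in gene count (default 400, so the top-5
#'   percent regression uses at least 20 genes).
#' @param reads_per_library expected condition-1 library size (default
#'   2e4).
#' @param second_codons optional codon panel cycled through gene position 2
#'   (gives every panel codon a sizeable gene cohort for +2 pause
#'   analyses); NULL draws codon 2 at random.
#' @param seed integer RNG seed.
#' @return validated list of class \code{footprint_sim_config}.
#' @export
footprint_sim_config <- function(n_genes = 200L,
                                 gene_length_range = c(100L, 300L),
                                 expression_meanlog = 0,
                                 expression_sdlog = 1.5,
                                 length_distribution = default_length_distribution(),
                                 frame_fidelity = 0.95,
                                 start_pause_multiplier = 1,
                                 codon_pause_multipliers = numeric(),
                                 global_translation_factor = 1,
                                 spikein_fraction = 0.1,
                                 n_spike_genes = 400L,
                                 reads_per_library = 2e4,
                                 second_codons = NULL,
                                 seed = 1L) {
  stopifnot(abs(sum(length_distribution) - 1) < 1e-9,
            all(as.integer(names(length_distribution)) %in% 15:34),
            all(length_distribution >= 0),
            frame_fidelity >= 0, frame_fidelity <= 1,
            all(start_pause_multiplier > 0),
            all(codon_pause_multipliers > 0),
            global_translation_factor > 0,
            spikein_fraction > 0, spikein_fraction < 1)
  structure(as.list(environment()), class = "footprint_sim_config")
}

random_cds <- function(n_codons, second_codon = NULL) {
  pool <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                    c("A","C","G","T")), 1, paste, collapse = ""),
                  STOP_CODONS)
  body <- sample(pool, n_codons - 2L, replace = TRUE)
  if (!is.null(second_codon)) body[1] <- second_codon
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

build_sim_gene_set <- function(n_genes, len_range, chrom, pad = 60L,
                               minus_fraction = 0.2, prefix = "g",
                               second_codons = NULL) {
  n_cod <- len_range[1] +
    sample.int(len_range[2] - len_range[1] + 1L, n_genes, replace = TRUE) - 1L
  strands <- ifelse(runif(n_genes) < minus_fraction, "-", "+")
  sc <- if (is.null(second_codons)) rep(list(NULL), n_genes) else
    as.list(rep_len(second_codons, n_genes))
  seqs <- vapply(seq_len(n_genes), function(i)
    random_cds(n_cod[i], sc[[i]]), character(1))
  pieces <- character(n_genes)
  starts <- integer(n_genes)
  pos <- 0L
  for (i in seq_len(n_genes)) {
    placed <- if (strands[i] == "+") seqs[i] else revcomp(seqs[i])
    pieces[i] <- paste0(strrep("N", 0), paste0(
      paste(sample(c("A","C","G","T"), pad, replace = TRUE), collapse = ""),
      placed,
      paste(sample(c("A","C","G","T"), pad, replace = TRUE), collapse = "")))
    starts[i] <- pos + pad
    pos <- pos + nchar(pieces[i])
  }
  ann <- orf_annotation(sprintf("%s%03d", prefix, seq_len(n_genes)),
                        chrom, strands, starts, starts + 3L * n_cod)
  list(sequence = paste(pieces, collapse = ""), annotations = ann,
       n_codons = n_cod)
}

sample_gene_reads <- function(ann_row, n_cod, n_reads, cfg, start_mult,
                              codon_mult, cds_seq) {
  # P-site codon weights over 1..(n_cod - 5)
  p_max <- n_cod - 5L
  w <- rep(1, p_max)
  w[1] <- w[1] * start_mult
  if (length(codon_mult)) {
    a_codons <- substring(cds_seq, 3L * seq_len(p_max) + 1L, 3L * seq_len(p_max) + 3L)
    m <- codon_mult[a_codons]
    m[is.na(m)] <- 1
    w <- w * m
  }
  p <- sample.int(p_max, n_reads, replace = TRUE, prob = w)
  ld <- cfg$length_distribution
  len <- integer(n_reads)
  at_start <- p == 1L
  if (any(at_start)) {
    long <- ld[names(ld) %in% as.character(25:31)]
    len[at_start] <- as.integer(sample(names(long), sum(at_start),
                                       replace = TRUE, prob = long / sum(long)))
  }
  if (any(!at_start))
    len[!at_start] <- as.integer(sample(names(ld), sum(!at_start),
                                        replace = TRUE, prob = ld))
  off <- default_offset_table()[as.character(len)]
  off[is.na(off)] <- 0L
  rel5 <- 3L * (p - 1L) - 12L - as.integer(off)
  jitter <- runif(n_reads) >= cfg$frame_fidelity
  rel5[jitter] <- rel5[jitter] + sample(c(-1L, 1L), sum(jitter), replace = TRUE)
  five_prime <- if (ann_row$strand == "+") ann_row$cds_start + rel5
                else ann_row$cds_end - 1L - rel5
  data.table(chrom = ann_row$chrom, strand = ann_row$strand,
             five_prime = as.integer(five_prime), length = len)
}

#' Simulate dual-species footprint libraries with known ground truth
#'
#' Generates an analysis-species gene set and a spike-in gene set on
#' separate chromosomes, then per condition and replicate draws reads whose
#' P-site codon positions honor the configured pause multipliers and whose
#' 5' ends honor the canonical offset geometry (a 28-mer paused with the
#' start codon in the P site has its 5' end 12 nt upstream of the A of
#' AUG), perturbed by the frame-fidelity parameter. Spike-in per-gene
#' abundances are identical across conditions up to Poisson sampling;
#' analysis-species totals differ by the global translation factor.
#'
#' @param config a \code{\link{footprint_sim_config}}.
#' @param n_conditions 1 or 2.
#' @param n_replicates replicates per condition (default 2).
#' @return list of class \code{footprint_sim}: \code{libraries} (named list
#'   of \code{alignments}, e.g. \code{cond1_rep1}), \code{annotations}
#'   (analysis genes), \code{spike_annotations}, \code{genome}, and
#'   \code{truth} (realized expression, injected multipliers and factor).
#' @export
simulate_footprint_libraries <- function(config, n_conditions = 2L,
                                         n_replicates = 2L) {
  stopifnot(n_conditions %in% 1:2, n_replicates >= 1L)
  cfg <- config
  set.seed(cfg$seed)
  gs <- build_sim_gene_set(cfg$n_genes, cfg$gene_length_range, "chrSim",
                           second_codons = cfg$second_codons)
  sp <- build_sim_gene_set(cfg$n_spike_genes, c(80L, 200L), "chrSpike",
                           minus_fraction = 0, prefix = "spike")
  gen <- genome(c(chrSim = gs$sequence, chrSpike = sp$sequence))
  expr <- rlnorm(cfg$n_genes, cfg$expression_meanlog, cfg$expression_sdlog)
  names(expr) <- gs$annotations$gene_id
  if (all(expr == 0)) stop("degenerate config: zero expression for all genes")
  sexpr <- rlnorm(cfg$n_spike_genes, cfg$expression_meanlog, cfg$expression_sdlog)
  names(sexpr) <- sp$annotations$gene_id
  smult <- if (length(cfg$start_pause_multiplier) == 1L)
    stats::setNames(rep(cfg$start_pause_multiplier, cfg$n_genes), names(expr))
  else cfg$start_pause_multiplier[names(expr)]
  gene_w <- expr * gs$n_codons
  spike_w <- sexpr * sp$n_codons
  cds_seqs <- vapply(seq_len(cfg$n_genes), function(i)
    feature_seq(gs$annotations[i], gen), character(1))
  spike_seqs <- vapply(seq_len(cfg$n_spike_genes), function(i)
    feature_seq(sp$annotations[i], gen), character(1))

  libs <- list()
  for (cond in seq_len(n_conditions)) {
    f <- if (cond == 1L) 1 else cfg$global_translation_factor
    perturbed <- cond == n_conditions
    for (rep_i in seq_len(n_replicates)) {
      n_analysis <- rpois(1, (1 - cfg$spikein_fraction) * cfg$reads_per_library * f)
      n_spike <- rpois(1, cfg$spikein_fraction * cfg$reads_per_library)
      per_gene <- as.vector(stats::rmultinom(1, n_analysis, gene_w))
      per_spike <- as.vector(stats::rmultinom(1, n_spike, spike_w))
      parts <- vector("list", 0L)
      for (i in seq_len(cfg$n_genes)) {
        if (per_gene[i] == 0L) next
        parts[[length(parts) + 1L]] <-
          sample_gene_reads(gs$annotations[i], gs$n_codons[i], per_gene[i],
                            cfg, if (perturbed) smult[[i]] else 1,
                            if (perturbed) cfg$codon_pause_multipliers
                            else numeric(), cds_seqs[i])
      }
      for (i in seq_len(cfg$n_spike_genes)) {
        if (per_spike[i] == 0L) next
        parts[[length(parts) + 1L]] <-
          sample_gene_reads(sp$annotations[i], sp$n_codons[i], per_spike[i],
                            cfg, 1, numeric(), spike_seqs[i])
      }
      rd <- rbindlist(parts)
      species <- c(rep("analysis", sum(per_gene)), rep("spikein", sum(per_spike)))
      lib_id <- sprintf("cond%d_rep%d", cond, rep_i)
      libs[[lib_id]] <- alignments(
        read_id = sprintf("%s_r%07d", lib_id, seq_len(nrow(rd))),
        chrom = rd$chrom, strand = rd$strand, five_prime = rd$five_prime,
        length = rd$length, species = species)
    }
  }
  truth <- list(expression = expr, spike_expression = sexpr,
                start_pause_multiplier = smult,
                codon_pause_multipliers = cfg$codon_pause_multipliers,
                global_translation_factor = cfg$global_translation_factor,
                seed = cfg$seed)
  structure(list(libraries = libs, annotations = gs$annotations,
                 spike_annotations = sp$annotations, genome = gen,
                 truth = truth),
            class = "footprint_sim")
}

#' Configuration for CLIP library simulation
#'
#' @param mean_reads expected primary reads per family per library
#'   (default 300, enough that the 64-count cutoff passes for unenriched
#'   families).
#' @param multimap_mix named probabilities over classes 0, 1, 3, 255.
#' @param conversion_rate T-to-C probability at designated crosslink sites
#'   in IP libraries (default 0.5).
#' @param background_conversion global T-to-C error rate (default 0.01).
#' @param enriched_families character vector of family ids over-sampled in
#'   IP libraries.
#' @param enrichment_multiplier IP over-sampling factor for enriched
#'   families (default 8).
#' @param ip_replicates number of IP replicates (default 2).
#' @param read_length_range CLIP read length range (default 20-35).
#' @param seed integer RNG seed.
#' @return validated list of class \code{clip_sim_config}.
#' @export
clip_sim_config <- function(mean_reads = 300,
                            multimap_mix = c(`255` = 0.55, `3` = 0.25,
                                             `1` = 0.12, `0` = 0.08),
                            conversion_rate = 0.5,
                            background_conversion = 0.01,
                            enriched_families = character(),
                            enrichment_multiplier = 8,
                            ip_replicates = 2L,
                            read_length_range = c(20L, 35L),
                            seed = 1L) {
  stopifnot(abs(sum(multimap_mix) - 1) < 1e-9,
            all(names(multimap_mix) %in% c("0", "1", "3", "255")),
            conversion_rate >= 0, conversion_rate <= 1,
            background_conversion >= 0, background_conversion <= 1,
            enrichment_multiplier > 0, ip_replicates >= 1L)
  structure(as.list(environment()), class = "clip_sim_config")
}

extra_placements <- c(`255` = 0L, `3` = 1L, `1` = 2L, `0` = 4L)

#' Simulate CLIP libraries over a collapsed reference
#'
#' IP libraries over-sample the designated enriched families relative to
#' the SMI and untagged controls; one crosslink site per family (the first
#' T at or after position 10) carries elevated T-to-C conversions in IP
#' reads; every read records its multimap class and all its placements,
#' with non-primary placements falling within the same consolidated family
#' locus (multimapping between copies collapses onto one representative).
#'
#' @param config a \code{\link{clip_sim_config}}.
#' @param reference a \code{collapsed_reference} with at least one
#'   artificial-chromosome family.
#' @return list of class \code{clip_sim}: \code{libraries} (named list of
#'   \code{clip_library}: \code{IP_rep1}, ..., \code{SMI_rep1},
#'   \code{untagged_rep1}) and \code{truth} (enriched set, crosslink sites,
#'   rates).
#' @export
simulate_clip_libraries <- function(config, reference) {
  cfg <- config
  ann <- reference$artificial_annotations
  if (nrow(ann) == 0L) stop("reference has no artificial-chromosome families")
  set.seed(cfg$seed)
  gen <- collapsed_genome(reference)
  art <- gen[["artificial"]]
  fams <- ann$gene_id
  stopifnot(all(cfg$enriched_families %in% fams))
  # crosslink site per family: first T at offset >= 10 within the locus
  sites <- stats::setNames(rep(NA_integer_, length(fams)), fams)
  t_pos <- gregexpr("T", art, fixed = TRUE)[[1]]
  for (i in seq_along(fams)) {
    cand <- t_pos[t_pos - 1L >= ann$cds_start[i] + 10L &
                    t_pos - 1L < ann$cds_end[i]] - 1L
    if (length(cand)) sites[i] <- cand[1]
  }
  if (anyNA(sites)) stop("config error: a family has no T available as a ",
                         "crosslink site on the read-bearing strand")
  roles <- c(rep("IP", cfg$ip_replicates), "SMI", "untagged")
  reps <- c(seq_len(cfg$ip_replicates), 1L, 1L)
  libs <- list()
  for (li in seq_along(roles)) {
    role <- roles[li]
    parts <- vector("list", 0L)
    mms <- vector("list", 0L)
    read_n <- 0L
    for (i in seq_along(fams)) {
      lam <- cfg$mean_reads *
        if (role == "IP" && fams[i] %in% cfg$enriched_families)
          cfg$enrichment_multiplier else 1
      n <- rpois(1, lam)
      if (n == 0L) next
      len <- sample(seq(cfg$read_length_range[1], cfg$read_length_range[2]),
                    n, replace = TRUE)
      lo <- ann$cds_start[i]
      hi <- pmax(lo, ann$cds_end[i] - len)
      start <- lo + floor(runif(n) * (hi - lo + 1L))
      cls <- as.integer(sample(names(cfg$multimap_mix), n, replace = TRUE,
                               prob = cfg$multimap_mix))
      ids <- sprintf("%s_rep%d_f%02d_r%05d", role, reps[li], i, seq_len(n))
      prim <- data.table(read_id = ids, chrom = "artificial", strand = "+",
                         five_prime = as.integer(start), length = len,
                         multimap_class = cls, is_primary = TRUE)
      parts[[length(parts) + 1L]] <- prim
      # secondary placements: residual multimapping on a collapsed
      # reference falls within the same consolidated family locus
      n_extra <- extra_placements[as.character(cls)]
      if (any(n_extra > 0L)) {
        idx <- rep(seq_len(n), n_extra)
        es <- lo + floor(runif(length(idx)) * (hi[idx] - lo + 1L))
        parts[[length(parts) + 1L]] <-
          data.table(read_id = ids[idx], chrom = "artificial", strand = "+",
                     five_prime = as.integer(es), length = len[idx],
                     multimap_class = cls[idx], is_primary = FALSE)
      }
      # T->C conversions on primary placements
      covers <- start <= sites[i] & start + len > sites[i]
      rate <- if (role == "IP") cfg$conversion_rate else cfg$background_conversion
      hit <- covers & runif(n) < rate
      if (any(hit))
        mms[[length(mms) + 1L]] <-
          data.table(read_id = ids[hit], chrom = "artificial",
                     pos = sites[[i]], ref_base = "T", read_base = "C")
      if (cfg$background_conversion > 0) {
        ts_in <- t_pos[t_pos - 1L >= ann$cds_start[i] &
                         t_pos - 1L < ann$cds_end[i]] - 1L
        ts_in <- setdiff(ts_in, sites[i])
        for (tp in ts_in) {
          cv <- which(start <= tp & start + len > tp)
          bg <- cv[runif(length(cv)) < cfg$background_conversion]
          if (length(bg))
            mms[[length(mms) + 1L]] <-
              data.table(read_id = ids[bg], chrom = "artificial",
                         pos = tp, ref_base = "T", read_base = "C")
        }
      }
    }
    al <- rbindlist(parts)
    lib_al <- alignments(al$read_id, al$chrom, al$strand, al$five_prime,
                         al$length, al$multimap_class, al$is_primary)
    libs[[sprintf("%s_rep%d", role, reps[li])]] <-
      clip_library(lib_al, role = role, replicate = reps[li],
                   mismatches = rbindlist(mms))
  }
  truth <- list(enriched_families = cfg$enriched_families,
                enrichment_multiplier = cfg$enrichment_multiplier,
                crosslink_sites = sites,
                conversion_rate = cfg$conversion_rate,
                background_conversion = cfg$background_conversion,
                mean_reads = cfg$mean_reads, seed = cfg$seed)
  structure(list(libraries = libs, truth = truth), class = "clip_sim")
}

#' Simulate a gradient absorbance trace from triangular peaks
#'
#' The trace is a baseline plus a sum of triangular peaks sampled at
#' uniformly spaced positions; each peak's analytic area is height x
#' half-width, retrievable from the \code{peak_areas} attribute for
#' closed-form validation of Riemann quantification.
#'
#' @param peaks \code{data.frame(center, width, height)}; width is the
#'   half-width (the triangle spans center +/- width).
#' @param baseline constant baseline absorbance.
#' @param n_points number of sample points (>= 10).
#' @param range positions range, default \code{c(0, 1)}.
#' @return a \code{gradient_trace} with attributes \code{peak_areas} and
#'   \code{peaks}.
#' @export
simulate_gradient_trace <- function(peaks, baseline = 0, n_points = 1e4L,
                                    range = c(0, 1)) {
  pk <- as.data.table(peaks)
  stopifnot(n_points >= 10L, all(pk$width > 0))
  x <- seq(range[1], range[2], length.out = n_points)
  y <- rep(baseline, n_points)
  for (i in seq_len(nrow(pk)))
    y <- y + pmax(0, pk$height[i] * (1 - abs(x - pk$center[i]) / pk$width[i]))
  tr <- gradient_trace(x, y)
  setattr(tr, "peak_areas", pk$height * pk$width)
  setattr(tr, "peaks", pk)
  tr
}
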