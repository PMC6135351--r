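LONG_FOOTPRINTS <- c(25L, 26L, 28L, 29L, 30L, 31L)
SHORT_FOOTPRINTS <- 20:22

# P-site codon index of a framed in-frame 5' end (rel5 = -12 => codon 1)
p_site_codon <- function(rel5) (rel5 + 12L) %/% 3L + 1L

#' Metagene occupancy profile
#'
#' Per gene, read counts at each position are divided by the gene's average
#' read count per nucleotide (its expression level); the normalized values
#' are then averaged across qualifying genes at each position relative to
#' the anchor. With framed reads and a start anchor, the start-codon
#' occupancy is the value at position -12.
#'
#' @param framed output of \code{\link{apply_offsets}} (or raw assignment).
#' @param annotations an \code{orf_annotation} table.
#' @param anchor \code{"start"} (positions relative to the A of AUG) or
#'   \code{"stop"} (relative to the first nt of the stop codon).
#' @param window integer vector \code{c(lo, hi)} of anchor-relative
#'   positions.
#' @param min_reads per-gene read cutoff (default 64).
#' @param min_gene_length minimum spliced CDS length in nt (default 0).
#' @return \code{data.table(position, occupancy)} with attributes
#'   \code{n_genes} and, for a start anchor, \code{start_occupancy}.
#' @export
metagene <- function(framed, annotations, anchor = c("start", "stop"),
                     window = c(-40L, 60L), min_reads = 64L,
                     min_gene_length = 0L) {
  anchor <- match.arg(anchor)
  a <- as.data.table(framed)
  lens <- spliced_length(annotations)
  gtot <- a[, .N, by = gene_id]
  keep <- gtot[N >= min_reads & lens[gene_id] >= min_gene_length, gene_id]
  if (length(keep) == 0L) stop("no genes pass the read/length filters")
  pos <- seq.int(window[1], window[2])
  acc <- numeric(length(pos))
  for (g in keep) {
    sub <- a[gene_id == g]
    L <- lens[[g]]
    expr <- nrow(sub) / L
    rel <- if (anchor == "start") sub$rel5 else sub$rel5 - (L - 3L)
    cnt <- tabulate(rel - window[1] + 1L, nbins = length(pos))
    acc <- acc + cnt / expr
  }
  out <- data.table(position = pos, occupancy = acc / length(keep))
  setattr(out, "n_genes", length(keep))
  if (anchor == "start")
    setattr(out, "start_occupancy", out[position == -12L, occupancy])
  out[]
}

#' Start-codon to ORF-body read ratios
#'
#' Start reads are framed 5' ends exactly 12 nt upstream of the A of AUG
#' (P site = codon 1). Body reads are the remaining in-frame reads,
#' excluding the start position and the last 5 codons. Genes with fewer than
#' \code{min_reads} reads or zero body reads are excluded (reported in the
#' \code{excluded} attribute).
#'
#' @param framed output of \code{\link{apply_offsets}}.
#' @param annotations an \code{orf_annotation} table.
#' @param lengths footprint lengths used (default 25, 26, 28-31 mers).
#' @param min_reads per-gene cutoff, default 64.
#' @return \code{data.table(gene_id, start_count, body_count, ratio)}.
#' @export
start_body_ratios <- function(framed, annotations,
                              lengths = LONG_FOOTPRINTS, min_reads = 64L) {
  a <- as.data.table(framed)[length %in% lengths]
  lens <- spliced_length(annotations)
  per <- a[, {
    n_cod <- lens[[.BY$gene_id]] %/% 3L
    inframe <- rel5 %% 3L == 0L
    p <- p_site_codon(rel5)
    list(n_reads = .N,
         start_count = sum(rel5 == -12L),
         body_count = sum(inframe & p >= 2L & p <= n_cod - 5L))
  }, by = gene_id]
  excluded <- per[n_reads < min_reads | body_count == 0L, gene_id]
  out <- per[n_reads >= min_reads & body_count > 0L]
  out[, ratio := start_count / body_count]
  out[, n_reads := NULL]
  setorder(out, gene_id)
  setattr(out, "excluded", excluded)
  setattr(out, "lengths", lengths)
  out[]
}

#' Per-gene fold change of start/body ratios between two conditions
#'
#' @param table_a,table_b \code{start_body_ratios} outputs for the baseline
#'   and perturbed condition; genes must have nonzero body counts in both
#'   (others are dropped).
#' @return named numeric vector of \code{ratio_b / ratio_a} per shared gene.
#' @export
start_body_change <- function(table_a, table_b) {
  m <- merge(as.data.table(table_a), as.data.table(table_b),
             by = "gene_id", suffixes = c("_a", "_b"))
  m <- m[ratio_a > 0]
  stats::setNames(m$ratio_b / m$ratio_a, m$gene_id)
}

#' Nucleotide sequence context around each start codon
#'
#' Extracts the 29-nt window covering positions -13..+16, where +1..+3 are
#' the start codon and -1/+4 flank it. The 13 upstream nucleotides follow
#' the genome linearly; the 16 CDS nucleotides are spliced.
#'
#' @param annotations an \code{orf_annotation} table.
#' @param genome a \code{genome} object.
#' @return named character vector of 29-nt strings.
#' @export
start_contexts <- function(annotations, genome) {
  out <- character(nrow(annotations))
  for (i in seq_len(nrow(annotations))) {
    g <- annotations[i]
    cs <- genome[[g$chrom]]
    if (g$strand == "+") {
      if (g$cds_start < 13L) stop(g$gene_id, ": not enough upstream sequence")
      up <- substring(cs, g$cds_start - 12L, g$cds_start)
    } else {
      if (g$cds_end + 13L > nchar(cs)) stop(g$gene_id, ": not enough upstream sequence")
      up <- revcomp(substring(cs, g$cds_end + 1L, g$cds_end + 13L))
    }
    out[i] <- paste0(up, substring(feature_seq(g, genome), 1L, 16L))
  }
  stats::setNames(out, annotations$gene_id)
}

#' Nucleotide-usage bias in the top quartile of ranked genes
#'
#' Genes are ranked (decreasing) by a per-gene statistic, typically the
#' between-condition change in start/body ratio. At each of the 26 variable
#' positions around the start codon (-13..-1 and +4..+16; the invariant AUG
#' at +1..+3 is excluded), the usage of each nucleotide in the top quartile
#' is compared to expected counts derived from the all-gene frequencies via
#' the log-likelihood ratio statistic G = 2 * sum(O * ln(O/E)), referred to
#' chi-squared with 3 degrees of freedom and Bonferroni-adjusted for the 26
#' simultaneous positions. O = 0 terms contribute 0; an E = 0, O > 0 cell
#' renders the position's G undefined (NA) rather than infinite.
#'
#' @param gene_ranking named numeric vector of the ranking statistic.
#' @param contexts named 29-nt strings from \code{\link{start_contexts}}.
#' @param quartile top fraction used (default 0.25); the boundary takes the
#'   first \code{ceiling(n * quartile)} genes with stable id tie-breaking.
#' @return list of class \code{nucleotide_bias}: \code{positions} (a
#'   \code{data.table(position, G, p_raw, p_bonferroni)}) and
#'   \code{per_nucleotide} (long table with O, E and the per-nucleotide bias
#'   term at every position).
#' @export
nucleotide_bias <- function(gene_ranking, contexts, quartile = 0.25) {
  genes <- intersect(names(gene_ranking), names(contexts))
  if (length(genes) < 8L) stop("too few genes with both ranking and context")
  ranked <- genes[order(-gene_ranking[genes], genes)]
  top <- ranked[seq_len(ceiling(length(genes) * quartile))]
  pos_labels <- c(-13:-1, 4:16)
  str_idx <- c(1:13, 17:29)
  nts <- c("A", "C", "G", "T")
  all_mat <- do.call(rbind, strsplit(contexts[genes], "", fixed = TRUE))
  top_mat <- all_mat[match(top, genes), , drop = FALSE]
  rows <- vector("list", length(pos_labels))
  for (k in seq_along(pos_labels)) {
    allc <- table(factor(all_mat[, str_idx[k]], levels = nts))
    obs <- table(factor(top_mat[, str_idx[k]], levels = nts))
    E <- as.numeric(allc) / length(genes) * length(top)
    O <- as.numeric(obs)
    bias <- ifelse(O == 0, 0,
                   ifelse(E == 0, NA_real_, 2 * O * log(O / E)))
    rows[[k]] <- data.table(position = pos_labels[k], nucleotide = nts,
                            O = O, E = E, bias = bias)
  }
  long <- rbindlist(rows)
  summ <- long[, .(G = sum(bias)), by = position]
  summ[, p_raw := pchisq(G, df = 3, lower.tail = FALSE)]
  summ[, p_bonferroni := pmin(1, p_raw * 26)]
  structure(list(positions = summ[], per_nucleotide = long[],
                 n_top = length(top), n_all = length(genes)),
            class = "nucleotide_bias")
}

#' Single-codon pause scores
#'
#' For a codon position and ribosomal site, the score of gene j is the
#' framed 5'-end count at the position placing that codon in the site,
#' divided by the gene's in-frame read density (total in-frame reads over
#' the number of codons with in-frame reads, reads in the last 5 codons
#' excluded from the denominator tally). A gene with perfectly uniform
#' in-frame coverage scores 1 everywhere; genes with no in-frame reads are
#' excluded.
#'
#' @param framed output of \code{\link{apply_offsets}}.
#' @param annotations an \code{orf_annotation} table.
#' @param genome optional \code{genome}; when given, the codon identity at
#'   each scored position is reported.
#' @param codon_position integer vector of 1-based codon indices (default 2,
#'   the first codon decoded in the A site after initiation).
#' @param site ribosomal site holding the codon: \code{"A"}, \code{"P"} or
#'   \code{"E"}.
#' @param lengths footprint lengths used (default long footprints).
#' @return \code{data.table(gene_id, codon_position, codon, score)}.
#' @export
pause_scores <- function(framed, annotations, genome = NULL,
                         codon_position = 2L, site = c("A", "P", "E"),
                         lengths = LONG_FOOTPRINTS) {
  site <- match.arg(site)
  shift <- switch(site, A = -1L, P = 0L, E = 1L)  # P-site codon = position + shift
  a <- as.data.table(framed)[length %in% lengths]
  lens <- spliced_length(annotations)
  pieces <- vector("list", 0L)
  for (g in unique(a$gene_id)) {
    sub <- a[gene_id == g]
    n_cod <- lens[[g]] %/% 3L
    inf <- sub$rel5[sub$rel5 %% 3L == 0L]
    if (length(inf) == 0L) next
    p <- p_site_codon(inf)
    p_den <- p[p <= n_cod - 5L]
    if (length(p_den) == 0L) next
    density <- length(p_den) / length(unique(p_den))
    targets <- codon_position + shift
    cnt <- vapply(targets, function(tc) sum(p == tc), numeric(1))
    cod <- if (is.null(genome)) NA_character_ else
      codon_at(annotations[annotations$gene_id == g], genome, codon_position)
    pieces[[length(pieces) + 1L]] <-
      data.table(gene_id = g, codon_position = codon_position,
                 codon = cod, score = cnt / density)
  }
  out <- rbindlist(pieces)
  if (nrow(out) == 0L)
    out <- data.table(gene_id = character(), codon_position = integer(),
                      codon = character(), score = numeric())
  setattr(out, "site", site)
  out[]
}

#' Merge pause-score tables from biological replicates
#' @param ... pause-score tables.
#' @return pooled \code{data.table} (distributions concatenated).
#' @export
merge_pause_scores <- function(...) {
  rbindlist(list(...))
}

#' Median shift and K-S comparison of pause-score distributions
#'
#' For every (codon identity, codon position) present in both tables, the
#' ratio of condition medians and the two-sample Kolmogorov-Smirnov p-value
#' of the empirical score distributions. Codons with fewer than
#' \code{min_genes} genes in either condition are skipped.
#'
#' @param scores_a,scores_b \code{\link{pause_scores}} tables (baseline,
#'   perturbed), typically replicate-merged.
#' @param min_genes minimum genes per codon and condition (default 10).
#' @return \code{data.table(codon, codon_position, n_a, n_b, median_shift,
#'   ks_p)} where \code{median_shift = median_b / median_a}.
#' @export
pause_shift_by_codon <- function(scores_a, scores_b, min_genes = 10L) {
  a <- as.data.table(scores_a)
  b <- as.data.table(scores_b)
  keys <- merge(unique(a[, .(codon, codon_position)]),
                unique(b[, .(codon, codon_position)]),
                by = c("codon", "codon_position"))
  rows <- vector("list", 0L)
  for (i in seq_len(nrow(keys))) {
    va <- a[codon == keys$codon[i] & codon_position == keys$codon_position[i], score]
    vb <- b[codon == keys$codon[i] & codon_position == keys$codon_position[i], score]
    if (length(va) < min_genes || length(vb) < min_genes) next
    ks <- suppressWarnings(ks.test(va, vb))
    med_a <- median(va)
    rows[[length(rows) + 1L]] <-
      data.table(codon = keys$codon[i], codon_position = keys$codon_position[i],
                 n_a = length(va), n_b = length(vb),
                 median_shift = if (med_a > 0) median(vb) / med_a else NA_real_,
                 ks_p = ks$p.value)
  }
  out <- rbindlist(rows)
  if (nrow(out) == 0L)
    out <- data.table(codon = character(), codon_position = integer(),
                      n_a = integer(), n_b = integer(),
                      median_shift = numeric(), ks_p = numeric())
  out[]
}

#' Metacodon occupancy at the E, P, and A sites
#'
#' All genomic instances of each codon are aligned on the ribosome: a framed
#' in-frame 5' end with P-site codon p contributes to relative offsets
#' r = c - (p + 1) for every codon instance c (A site r = 0, P site r = -1,
#' E site r = -2, flanks r in {-4, -3, +1, +2}). Site occupancies summed
#' over the genome are normalized by the mean of the four flanking
#' occupancies. The first 8 and last 4 codons of each ORF are excluded, as
#' are genes with mean coverage below 1 in-frame read per codon.
#'
#' @param framed output of \code{\link{apply_offsets}}.
#' @param annotations an \code{orf_annotation} table.
#' @param genome a \code{genome} object (codon identities).
#' @param length_class \code{"long"} (25, 26, 28-31 mers) or \code{"short"}
#'   (20-22 mers).
#' @param min_coverage minimum mean in-frame reads per codon (default 1).
#' @return \code{data.table(codon, E, P, A, flank_mean)} with E/P/A already
#'   flank-normalized; codons never observed after filtering are absent.
#' @export
metacodon_occupancy <- function(framed, annotations, genome,
                                length_class = c("long", "short"),
                                min_coverage = 1) {
  length_class <- match.arg(length_class)
  lengths <- if (length_class == "long") LONG_FOOTPRINTS else SHORT_FOOTPRINTS
  a <- as.data.table(framed)[length %in% lengths]
  lens <- spliced_length(annotations)
  offsets <- c(-4L, -3L, -2L, -1L, 0L, 1L, 2L)
  pieces <- vector("list", 0L)
  for (g in unique(a$gene_id)) {
    sub <- a[gene_id == g]
    n_cod <- lens[[g]] %/% 3L
    inf <- sub$rel5[sub$rel5 %% 3L == 0L]
    if (length(inf) / n_cod < min_coverage) next
    p <- p_site_codon(inf)
    cnt <- tabulate(p[p >= 1L & p <= n_cod], nbins = n_cod)
    cseq <- feature_seq(annotations[annotations$gene_id == g], genome)
    codons <- substring(cseq, 3L * (seq_len(n_cod) - 1L) + 1L, 3L * seq_len(n_cod))
    use <- seq.int(9L, n_cod - 4L)
    if (length(use) == 0L) next
    for (r in offsets) {
      src <- use - r - 1L  # P-site codon index whose reads see instance at offset r
      ok <- src >= 1L & src <= n_cod
      pieces[[length(pieces) + 1L]] <-
        data.table(codon = codons[use[ok]], r = r, count = cnt[src[ok]])
    }
  }
  long <- rbindlist(pieces)
  if (nrow(long) == 0L) stop("no genes pass the coverage filter")
  agg <- long[, .(total = sum(count)), by = .(codon, r)]
  wide <- dcast(agg, codon ~ r, value.var = "total", fill = 0)
  setnames(wide, as.character(offsets),
           c("fm2", "fm1", "E_raw", "P_raw", "A_raw", "fp1", "fp2"))
  wide[, flank_mean := (fm2 + fm1 + fp1 + fp2) / 4]
  out <- wide[flank_mean > 0,
              .(codon, E = E_raw / flank_mean, P = P_raw / flank_mean,
                A = A_raw / flank_mean, flank_mean)]
  setorder(out, codon)
  out[]
}
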