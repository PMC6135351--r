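#' Bulk translation ratio from a dual-species library
#'
#' The total analysis-species CDS count divided by the total spike-in
#' species CDS count; the ratio of this quantity between two conditions
#' measures the global change in mRNA-bound ribosomes.
#'
#' @param analysis_counts,spikein_counts \code{gene_counts} tables (or any
#'   data.frame with a \code{count} column) for the two species of one
#'   library.
#' @return a single number, analysis total / spike-in total.
#' @export
bulk_translation_ratio <- function(analysis_counts, spikein_counts) {
  tot_s <- sum(spikein_counts$count)
  if (tot_s <= 0) stop("degenerate library: zero spike-in reads")
  sum(analysis_counts$count) / tot_s
}

#' Reads per kilobase per million mapped reads
#'
#' @param counts a \code{gene_counts} table.
#' @param gene_lengths named vector of gene lengths in nt (spliced CDS for
#'   the analysis species; summed isoform exon lengths for the spike-in).
#' @param library_size total mapped reads of the library.
#' @return named numeric vector of RPKM values; genes lacking a length are
#'   skipped with a warning.
#' @export
rpkm <- function(counts, gene_lengths, library_size) {
  stopifnot(library_size > 0)
  len <- gene_lengths[counts$gene_id]
  miss <- is.na(len)
  if (any(miss)) {
    warning("skipping ", sum(miss), " gene(s) with no annotated length")
    counts <- counts[!miss]
    len <- len[!miss]
  }
  stopifnot(all(len > 0))
  stats::setNames(counts$count / (len / 1e3) / (library_size / 1e6),
                  counts$gene_id)
}

#' Fit the spike-in rescaling factor between two libraries
#'
#' Least squares of the normalizing library's spike-in RPKMs (y) against
#' the library-to-normalize's spike-in RPKMs (x), restricted to the top
#' fraction of spike-in genes ranked by the normalizer's RPKM. The applied
#' slope is fit through the origin: spike-in RPKMs of two libraries are
#' proportional by construction (zero expression maps to zero), and with
#' top-fraction selection a free intercept soaks up the selection's
#' regression-to-the-mean offset and systematically understates the slope
#' at moderate coverage. A free-intercept fit is still computed and its
#' intercept and r-squared reported for QC. The slope is the global
#' scaling factor applied multiplicatively to the analysis-species RPKMs
#' of the library being normalized.
#'
#' @param target_rpkms named spike-in RPKM vector of the library to
#'   normalize.
#' @param normalizer_rpkms named spike-in RPKM vector of the normalizing
#'   library.
#' @param top_fraction fraction of genes (by normalizer RPKM) used, default
#'   0.05.
#' @return list of class \code{scaling_fit}: \code{slope}, \code{intercept},
#'   \code{fit_r2}, \code{n_genes_used}.
#' @export
fit_spikein_scaling <- function(target_rpkms, normalizer_rpkms,
                                top_fraction = 0.05) {
  shared <- intersect(names(target_rpkms), names(normalizer_rpkms))
  n_top <- ceiling(length(shared) * top_fraction)
  if (n_top < 20L)
    stop("insufficient data: fewer than 20 genes in the top fraction")
  top <- shared[order(-normalizer_rpkms[shared], shared)][seq_len(n_top)]
  x <- target_rpkms[top]
  y <- normalizer_rpkms[top]
  fit <- lm(y ~ x + 0)
  slope <- unname(coef(fit)[1])
  if (!is.finite(slope) || slope <= 0)
    stop("invalid fit: non-positive slope")
  qc <- lm(y ~ x)  # free-intercept fit, reported only
  r2 <- suppressWarnings(summary(qc)$r.squared)  # exact fits are legitimate
  structure(list(slope = slope, intercept = unname(coef(qc)[1]),
                 fit_r2 = r2, n_genes_used = n_top),
            class = "scaling_fit")
}

#' Rescale analysis-species RPKMs by a fitted scaling factor
#' @param analysis_rpkms named RPKM vector.
#' @param fit a \code{scaling_fit}.
#' @return rescaled RPKM vector (\code{rpkm * slope}).
#' @export
apply_scaling <- function(analysis_rpkms, fit) {
  analysis_rpkms * fit$slope
}
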