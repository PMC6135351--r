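#' @import data.table
#' @importFrom stats median lm coef pchisq phyper ks.test rpois rlnorm runif
#' @importFrom utils head tail
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Construct a genome object
#'
#' A genome is a named set of chromosome sequences over the DNA alphabet
#' \code{A,C,G,T,N}. Internally all coordinates in the package are 0-based
#' half-open; reported tables use the field's 1-based inclusive convention.
#'
#' @param sequences named character vector, one DNA string per chromosome.
#' @return an object of class \code{genome} (named character vector).
#' @export
genome <- function(sequences) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("chromosome names must be non-empty")
  if (anyDuplicated(names(sequences)))
    stop("chromosome names must be unique")
  sequences <- toupper(unlist(sequences))
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("sequence of ", paste(names(sequences)[bad], collapse = ", "),
         " contains characters outside {A,C,G,T,N}")
  structure(sequences, class = "genome")
}

#' Reverse complement of DNA strings
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                   collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Build an ORF/feature annotation table
#'
#' Each row models one gene with strand-aware CDS coordinates and exon
#' blocks. For \code{mRNA} biotype the spliced CDS length must be a positive
#' multiple of 3 (start codon through stop codon).
#'
#' @param gene_id,chrom,strand,cds_start,cds_end vectors of equal length;
#'   coordinates 0-based half-open on the genome.
#' @param exon_blocks optional list of two-column matrices (start, end),
#'   0-based half-open, sorted, non-overlapping, within the CDS span.
#'   Defaults to a single block spanning the CDS.
#' @param biotype one of \code{mRNA}, \code{tRNA}, \code{rRNA}, \code{other}.
#' @return a \code{data.table} with class \code{orf_annotation}.
#' @export
orf_annotation <- function(gene_id, chrom, strand, cds_start, cds_end,
                           exon_blocks = NULL, biotype = "mRNA") {
  n <- length(gene_id)
  stopifnot(all(strand %in% c("+", "-")))
  if (is.null(exon_blocks))
    exon_blocks <- Map(function(s, e) matrix(c(s, e), ncol = 2), cds_start, cds_end)
  biotype <- rep_len(biotype, n)
  stopifnot(all(biotype %in% c("mRNA", "tRNA", "rRNA", "other")))
  ann <- data.table(gene_id = as.character(gene_id), chrom = as.character(chrom),
                    strand = strand,
                    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
                    biotype = biotype, exon_blocks = exon_blocks)
  for (i in seq_len(n)) {
    bl <- ann$exon_blocks[[i]]
    if (!is.matrix(bl) || ncol(bl) != 2) stop("exon_blocks must be n x 2 matrices")
    if (is.unsorted(bl[, 1]) || any(bl[, 2] <= bl[, 1]))
      stop(gene_id[i], ": exon blocks must be sorted with end > start")
    if (nrow(bl) > 1 && any(bl[-1, 1] < bl[-nrow(bl), 2]))
      stop(gene_id[i], ": exon blocks overlap")
    if (bl[1, 1] < ann$cds_start[i] || bl[nrow(bl), 2] > ann$cds_end[i])
      stop(gene_id[i], ": exon blocks outside CDS span")
    if (biotype[i] == "mRNA") {
      L <- sum(bl[, 2] - bl[, 1])
      if (L <= 0 || L %% 3 != 0)
        stop(gene_id[i], ": mRNA spliced CDS length must be a positive multiple of 3")
    }
  }
  setattr(ann, "class", c("orf_annotation", class(ann)))
  ann[]
}

#' Spliced CDS length (nt) per gene
#' @param annotations an \code{orf_annotation} table.
#' @return named integer vector of spliced lengths.
#' @export
spliced_length <- function(annotations) {
  out <- vapply(annotations$exon_blocks, function(b) sum(b[, 2] - b[, 1]), numeric(1))
  stats::setNames(as.integer(out), annotations$gene_id)
}

#' Strand-corrected spliced sequence of a feature
#' @param annotation a one-row \code{orf_annotation}.
#' @param genome a \code{genome} object.
#' @param spliced if \code{FALSE}, return the full genomic span including
#'   introns (used for family identity of intron-containing tRNAs).
#' @return a DNA string in the sense orientation of the feature.
#' @export
feature_seq <- function(annotation, genome, spliced = TRUE) {
  chrom <- annotation$chrom
  if (!chrom %in% names(genome)) stop("chromosome ", chrom, " not in genome")
  cs <- genome[[chrom]]
  if (annotation$cds_start < 0 || annotation$cds_end > nchar(cs))
    stop(annotation$gene_id, ": coordinates outside chromosome bounds")
  if (spliced) {
    bl <- annotation$exon_blocks[[1]]
    s <- paste(substring(cs, bl[, 1] + 1L, bl[, 2]), collapse = "")
  } else {
    s <- substring(cs, annotation$cds_start + 1L, annotation$cds_end)
  }
  if (annotation$strand == "-") s <- revcomp(s) else s
}

#' Codon at a 1-based codon index of an ORF
#'
#' Codon 1 is the start codon; indexing runs over the spliced,
#' strand-corrected CDS.
#'
#' @param annotation a one-row \code{orf_annotation}.
#' @param genome a \code{genome} object.
#' @param codon_index 1-based codon index.
#' @return three-letter codon string.
#' @export
codon_at <- function(annotation, genome, codon_index) {
  s <- feature_seq(annotation, genome)
  n_cod <- nchar(s) %/% 3L
  if (any(codon_index < 1L) || any(codon_index > n_cod))
    stop("codon_index out of range [1, ", n_cod, "]")
  substring(s, 3L * (codon_index - 1L) + 1L, 3L * codon_index)
}

count_occurrences <- function(pattern, subject) {
  # non-overlapping scan is wrong for multimap counting; use overlapping count
  n <- 0L
  start <- 1L
  repeat {
    hit <- regexpr(pattern, substring(subject, start), fixed = TRUE)
    if (hit == -1L) break
    n <- n + 1L
    start <- start + hit
  }
  n
}

genome_kmer_hits <- function(genome, kmer) {
  # occurrences of kmer on either strand of the genome (overlapping allowed)
  rc <- revcomp(kmer)
  tot <- 0L
  for (cs in unclass(genome)) {
    tot <- tot + count_occurrences(kmer, cs)
    if (rc != kmer) tot <- tot + count_occurrences(rc, cs)
  }
  tot
}

#' Build a collapsed multicopy reference
#'
#' Masks every tRNA/rRNA feature that contains a window-length substring
#' occurring elsewhere in the genome (either strand) and places one
#' representative of each distinct masked-family sequence on an artificial
#' chromosome, loci separated by 25 N spacers. Family identity is exact
#' sequence identity of the feature's genomic span (introns included).
#' Never-masked single-copy features remain endogenous only.
#'
#' @param genome a \code{genome} object.
#' @param features an \code{orf_annotation} table restricted to tRNA/rRNA
#'   biotypes.
#' @param window multimap window length in nt (default 40).
#' @return a list of class \code{collapsed_reference} with elements
#'   \code{masked_genome}, \code{artificial_chrom}, \code{artificial_annotations},
#'   \code{family_map}, \code{masked_ids}, \code{spacer} (= 25).
#' @export
build_collapsed_reference <- function(genome, features, window = 40L) {
  stopifnot(window >= 1L)
  if (nrow(features) > 0 && !all(features$biotype %in% c("tRNA", "rRNA")))
    stop("features must be restricted to tRNA/rRNA biotypes")
  spacer <- 25L
  if (nrow(features) == 0L) {
    return(structure(list(masked_genome = genome, artificial_chrom = "",
                          artificial_annotations = orf_annotation(
                            character(), character(), character(),
                            integer(), integer(), list()),
                          family_map = stats::setNames(character(), character()),
                          masked_ids = character(), spacer = spacer),
                     class = "collapsed_reference"))
  }
  seqs <- vapply(seq_len(nrow(features)), function(i)
    feature_seq(features[i], genome, spliced = FALSE), character(1))
  masked <- logical(nrow(features))
  for (i in seq_len(nrow(features))) {
    s <- seqs[i]
    if (nchar(s) < window) next
    for (p in seq_len(nchar(s) - window + 1L)) {
      if (genome_kmer_hits(genome, substring(s, p, p + window - 1L)) >= 2L) {
        masked[i] <- TRUE
        break
      }
    }
  }
  seqs_masked <- seqs[masked]
  ids_masked <- features$gene_id[masked]
  # representative of each distinct masked-family sequence: lexicographically
  # first member id, placed in representative-id order for determinism
  fam <- split(ids_masked, seqs_masked)
  reps <- vapply(fam, function(ids) sort(ids)[1], character(1))
  ord <- order(reps)
  reps <- reps[ord]
  fam_seqs <- names(fam)[ord]
  family_map <- stats::setNames(rep(reps, lengths(fam)[ord]), unlist(fam[ord]))

  # mask the genome
  mg <- unclass(genome)
  for (i in which(masked)) {
    ch <- features$chrom[i]
    s0 <- features$cds_start[i]; e0 <- features$cds_end[i]
    mg[[ch]] <- paste0(substring(mg[[ch]], 1L, s0),
                       strrep("N", e0 - s0),
                       substring(mg[[ch]], e0 + 1L))
  }

  art <- paste(fam_seqs, collapse = strrep("N", spacer))
  widths <- nchar(fam_seqs)
  starts <- if (length(widths)) cumsum(c(0L, head(widths + spacer, -1L))) else integer()
  bio <- features$biotype[match(reps, features$gene_id)]
  art_ann <- orf_annotation(reps, rep("artificial", length(reps)), "+",
                            starts, starts + widths, biotype = bio)
  structure(list(masked_genome = genome(mg), artificial_chrom = art,
                 artificial_annotations = art_ann,
                 family_map = family_map, masked_ids = ids_masked,
                 spacer = spacer),
            class = "collapsed_reference")
}

#' Full genome view of a collapsed reference
#'
#' Masked endogenous chromosomes plus the artificial chromosome, for use as
#' an alignment target or by downstream quantification.
#' @param ref a \code{collapsed_reference}.
#' @return a \code{genome} object including chromosome \code{"artificial"}.
#' @export
collapsed_genome <- function(ref) {
  g <- unclass(ref$masked_genome)
  if (nzchar(ref$artificial_chrom)) g[["artificial"]] <- ref$artificial_chrom
  genome(g)
}
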