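#' Construct an alignment table
#'
#' The atomic input of both the profiling and the CLIP stages: one row per
#' aligned placement with the biological 5' end, read length, and multimap
#' class. Mismatch events, when present, live in a separate table keyed by
#' \code{read_id} (see \code{\link{conversion_profile}}).
#'
#' @param read_id,chrom,strand,five_prime,length equal-length vectors;
#'   \code{five_prime} is the 0-based genomic position of the read 5' end
#'   (for minus-strand reads, the rightmost aligned base).
#' @param multimap_class one of 0, 1, 3, 255 (STAR MAPQ convention:
#'   255 unique, 3 two placements, 1 three to four, 0 five or more).
#' @param is_primary logical flag, one placement per read.
#' @param species optional species tag (analysis vs spike-in).
#' @return a \code{data.table} of class \code{alignments}.
#' @export
alignments <- function(read_id, chrom, strand, five_prime, length,
                       multimap_class = 255L, is_primary = TRUE,
                       species = NA_character_) {
  stopifnot(all(strand %in% c("+", "-")))
  if (any(length < 15L))
    stop("alignments shorter than 15 nt are not retained")
  if (!all(multimap_class %in% c(0L, 1L, 3L, 255L)))
    stop("multimap_class must be one of 0, 1, 3, 255")
  al <- data.table(read_id = as.character(read_id), chrom = as.character(chrom),
                   strand = strand, five_prime = as.integer(five_prime),
                   length = as.integer(length),
                   multimap_class = as.integer(multimap_class),
                   is_primary = is_primary, species = species)
  setattr(al, "class", c("alignments", class(al)))
  al[]
}

# map genomic positions to transcript coordinates relative to the A of AUG
# (0 = first nt of start codon); positions upstream/downstream of the spliced
# CDS extend linearly along the genome; intronic positions return NA
transcript_pos <- function(blocks, strand, gpos) {
  starts <- blocks[, 1]; ends <- blocks[, 2]
  w <- ends - starts
  L <- sum(w)
  n <- length(w)
  out <- rep(NA_integer_, length(gpos))
  if (strand == "+") {
    cum <- c(0L, cumsum(w))
    idx <- findInterval(gpos, starts)
    up <- idx == 0L
    out[up] <- gpos[up] - starts[1]
    inb <- idx >= 1L & gpos < ends[pmax(idx, 1L)]
    out[inb] <- cum[idx[inb]] + gpos[inb] - starts[idx[inb]]
    down <- idx == n & gpos >= ends[n]
    out[down] <- L + gpos[down] - ends[n]
  } else {
    cum_after <- rev(c(0L, cumsum(rev(w))))[-1]  # spliced nt downstream of exon j
    idx <- findInterval(gpos, starts)
    up <- gpos >= ends[n]
    out[up] <- ends[n] - 1L - gpos[up]
    inb <- idx >= 1L & gpos < ends[pmax(idx, 1L)] & !up
    out[inb] <- cum_after[idx[inb]] + ends[idx[inb]] - 1L - gpos[inb]
    down <- idx == 0L
    out[down] <- L + starts[1] - 1L - gpos[down]
  }
  out
}

#' Assign reads to ORFs by the 5'-end window rule
#'
#' A read is assigned to a gene iff its strand matches and its 5' end lies
#' between 12 nt upstream of the A of AUG and 15 nt upstream of the first nt
#' of the stop codon, inclusive, in transcript coordinates. Reads satisfying
#' several overlapping gene windows are assigned to each (with a warning).
#'
#' @param alignments an \code{alignments} table.
#' @param annotations an \code{orf_annotation} table (mRNA biotype).
#' @return \code{data.table} with columns \code{gene_id, read_id, rel5,
#'   length, multimap_class, species}, where \code{rel5} is the in-gene 5'
#'   offset (0 = A of AUG). Attributes: \code{n_input}, \code{n_assigned}
#'   (rows), \code{n_unassigned} (reads in no window).
#' @export
assign_to_orf <- function(alignments, annotations) {
  al <- as.data.table(alignments)
  al[, .row := .I]
  lens <- spliced_length(annotations)
  # candidate prefilter: reads within the padded genomic span of each gene
  # (exact transcript-coordinate window test follows per gene)
  spans <- data.table(gidx = seq_len(nrow(annotations)),
                      chrom = annotations$chrom, strand = annotations$strand,
                      start = annotations$cds_start - 13L,
                      end = annotations$cds_end + 13L)
  pts <- al[, .(chrom, strand, start = five_prime, end = five_prime, .row)]
  setkey(spans, chrom, strand, start, end)
  hits <- foverlaps(pts, spans, type = "within", nomatch = NULL)
  pieces <- vector("list", 0L)
  for (i in unique(hits$gidx)) {
    g <- annotations[i]
    sub <- al[hits[gidx == i, .row]]
    rel5 <- transcript_pos(g$exon_blocks[[1]], g$strand, sub$five_prime)
    keep <- !is.na(rel5) & rel5 >= -12L & rel5 <= lens[[g$gene_id]] - 3L - 15L
    if (!any(keep)) next
    pieces[[length(pieces) + 1L]] <-
      data.table(gene_id = g$gene_id, read_id = sub$read_id[keep],
                 rel5 = rel5[keep], length = sub$length[keep],
                 multimap_class = sub$multimap_class[keep],
                 species = sub$species[keep], .row = sub$.row[keep])
  }
  out <- rbindlist(pieces)
  if (nrow(out) == 0L)
    out <- data.table(gene_id = character(), read_id = character(),
                      rel5 = integer(), length = integer(),
                      multimap_class = integer(), species = character(),
                      .row = integer())
  if (anyDuplicated(out$.row))
    warning("some reads fall in the windows of multiple overlapping genes; ",
            "they contribute to each")
  n_assigned_reads <- length(unique(out$.row))
  out[, .row := NULL]
  al[, .row := NULL]
  setattr(out, "n_input", nrow(al))
  setattr(out, "n_assigned", nrow(out))
  setattr(out, "n_unassigned", nrow(al) - n_assigned_reads)
  out[]
}

#' Default footprint length offset table
#'
#' Offsets (nt, applied in the 5'->3' transcript direction) that put each
#' well-phased footprint length class in frame with 28-mers, whose 5' ends
#' sit 12 nt upstream of the P-site codon. 27-mers are deliberately absent
#' (not well phased).
#' @return named integer vector, names are footprint lengths.
#' @export
default_offset_table <- function() {
  c(`20` = 0L, `21` = 0L, `22` = 1L, `25` = 0L, `26` = 0L,
    `28` = 0L, `29` = 1L, `30` = 1L, `31` = 1L)
}

#' Apply length-specific frame offsets to assigned reads
#'
#' Shifts each read's transcript 5' coordinate by its length-class offset;
#' reads of lengths absent from the table are dropped and counted.
#'
#' @param assigned output of \code{\link{assign_to_orf}}.
#' @param offsets named integer vector (length -> offset); defaults to
#'   \code{\link{default_offset_table}}.
#' @return the framed table (same columns, shifted \code{rel5}) with
#'   attributes \code{n_kept} and \code{n_dropped}.
#' @export
apply_offsets <- function(assigned, offsets = default_offset_table()) {
  a <- as.data.table(assigned)
  off <- offsets[as.character(a$length)]
  keep <- !is.na(off)
  out <- a[keep]
  out[, rel5 := rel5 + as.integer(off[keep])]
  setattr(out, "n_kept", nrow(out))
  setattr(out, "n_dropped", nrow(a) - nrow(out))
  out[]
}

#' Reading-frame composition of raw 5' ends
#'
#' Fractions of (un-offset) read 5' ends in each frame modulo 3 relative to
#' the first nucleotide of the start codon; frame 0 means a multiple of 3.
#'
#' @param assigned output of \code{\link{assign_to_orf}} (raw, not framed).
#' @param lengths footprint lengths to include (default 20-22 mers).
#' @return numeric vector of fractions named "0", "1", "2".
#' @export
frame_composition <- function(assigned, lengths = 20:22) {
  a <- as.data.table(assigned)[length %in% lengths]
  if (nrow(a) == 0L) stop("no reads after length filter")
  f <- factor(((a$rel5 %% 3L) + 3L) %% 3L, levels = 0:2)
  tab <- table(f)
  stats::setNames(as.numeric(tab) / sum(tab), c("0", "1", "2"))
}

#' Footprint length histogram over CDS-assigned alignments
#'
#' @param alignments an \code{alignments} table.
#' @param annotations an \code{orf_annotation} table.
#' @return named integer vector: length -> count of assigned alignments
#'   (each alignment counted once even if in several gene windows).
#' @export
length_histogram <- function(alignments, annotations) {
  al <- as.data.table(alignments)
  al[, .row := .I]
  asg <- suppressWarnings(assign_to_orf(al, annotations))
  # count each input alignment once: re-derive rows via read_id+length match
  asg_u <- unique(asg, by = c("read_id", "length"))
  tab <- table(asg_u$length)
  stats::setNames(as.integer(tab), names(tab))
}

#' Per-gene read counts with early-codon exclusion
#'
#' Counts assigned reads per gene after omitting reads whose inferred P-site
#' codon (under the canonical 12-nt offset geometry) lies within the first
#' \code{exclude_first_codons} codons.
#'
#' @param assigned output of \code{\link{assign_to_orf}} or
#'   \code{\link{apply_offsets}}.
#' @param exclude_first_codons integer, default 8.
#' @param lengths optional footprint length filter (default: all lengths).
#' @return \code{data.table(gene_id, count)} with metadata attributes
#'   \code{exclude_first_codons} and \code{lengths}.
#' @export
gene_counts <- function(assigned, exclude_first_codons = 8L, lengths = NULL) {
  a <- as.data.table(assigned)
  if (!is.null(lengths)) a <- a[length %in% lengths]
  p_codon <- (a$rel5 + 12L) %/% 3L + 1L
  a <- a[p_codon > exclude_first_codons]
  out <- a[, .(count = .N), by = gene_id][order(gene_id)]
  setattr(out, "exclude_first_codons", as.integer(exclude_first_codons))
  setattr(out, "lengths", lengths)
  out[]
}
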