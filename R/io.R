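#' Write/read alignments in the simplified tabular format
#'
#' Plain TSV with columns read_id, chrom, strand, five_prime, length,
#' multimap_class, is_primary, species; lossless round-trip.
#' @param al an \code{alignments} table.
#' @param path file path.
#' @export
write_alignments_tsv <- function(al, path) {
  fwrite(as.data.table(al), path, sep = "\t")
}

#' @rdname write_alignments_tsv
#' @return \code{read_alignments_tsv}: an \code{alignments} table.
#' @export
read_alignments_tsv <- function(path) {
  d <- fread(path, sep = "\t", colClasses = list(character = "read_id"))
  alignments(d$read_id, d$chrom, d$strand, d$five_prime, d$length,
             d$multimap_class, d$is_primary, d$species)
}

#' Write alignments as minimal SAM
#'
#' Unmapped-sequence records (SEQ/QUAL "*") with a legal header; FLAG 16
#' encodes minus-strand placements, MAPQ carries the multimap class, POS is
#' the 1-based leftmost coordinate.
#' @param al an \code{alignments} table.
#' @param chrom_lengths named integer vector of reference lengths.
#' @param path file path.
#' @export
write_sam <- function(al, chrom_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  a <- as.data.table(al)
  left <- ifelse(a$strand == "+", a$five_prime, a$five_prime - a$length + 1L)
  flag <- ifelse(a$strand == "+", 0L, 16L) +
    ifelse(a$is_primary, 0L, 256L)
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*",
                 a$read_id, flag, a$chrom, left + 1L, a$multimap_class,
                 a$length)
  writeLines(c(hdr, rec), path)
}

#' Read/write FASTA
#'
#' Uses Biostrings when installed, otherwise a plain-text fallback.
#' @param path file path.
#' @return \code{read_fasta}: a \code{genome} object.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readDNAStringSet(path)
    return(genome(stats::setNames(as.character(x),
                                  sub("\\s.*$", "", names(x)))))
  }
  lines <- readLines(path)
  idx <- grep("^>", lines)
  nm <- sub("^>", "", sub("\\s.*$", "", lines[idx]))
  ends <- c(idx[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(idx), function(i)
    paste(lines[(idx[i] + 1L):ends[i]], collapse = ""), character(1))
  genome(stats::setNames(seqs, nm))
}

#' @rdname read_fasta
#' @param g a \code{genome} object.
#' @param width line wrap width.
#' @export
write_fasta <- function(g, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(g)) {
    writeLines(paste0(">", nm), con)
    s <- g[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write a collapsed reference to disk
#'
#' Emits the masked genome plus artificial chromosome as FASTA, a BED of
#' artificial-chromosome loci, and a two-column TSV family map.
#' @param ref a \code{collapsed_reference}.
#' @param prefix output path prefix (creates \code{<prefix>.fa},
#'   \code{<prefix>.bed}, \code{<prefix>.family_map.tsv}).
#' @export
write_collapsed_reference <- function(ref, prefix) {
  write_fasta(collapsed_genome(ref), paste0(prefix, ".fa"))
  ann <- ref$artificial_annotations
  fwrite(data.table(chrom = ann$chrom, start = ann$cds_start,
                    end = ann$cds_end, name = ann$gene_id),
         paste0(prefix, ".bed"), sep = "\t", col.names = FALSE)
  fwrite(data.table(gene_id = names(ref$family_map),
                    representative = unname(ref$family_map)),
         paste0(prefix, ".family_map.tsv"), sep = "\t")
  invisible(prefix)
}

#' Write simulation truth as JSON
#' @param truth a truth list from a simulator.
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
}

#' Write a position/value table as bedGraph
#' @param dt \code{data.frame(chrom, start, end, value)}.
#' @param path file path.
#' @export
write_bedgraph <- function(dt, path) {
  fwrite(as.data.table(dt)[, .(chrom, start, end, value)], path,
         sep = "\t", col.names = FALSE)
}
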