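library(data.table)

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# toy genome with nfam tRNA families, each present in `copies` identical
# loci, so every family collapses onto the artificial chromosome
make_trna_ref <- function(nfam = 16L, flen = 75L, copies = 2L, seed = 42L,
                          window = 40L) {
  set.seed(seed)
  fam_seqs <- replicate(nfam, rand_dna(flen))
  chrom <- ""
  rows <- list()
  for (i in seq_len(nfam)) for (cp in seq_len(copies)) {
    chrom <- paste0(chrom, rand_dna(100L))
    st <- nchar(chrom)
    chrom <- paste0(chrom, fam_seqs[i])
    rows[[length(rows) + 1L]] <-
      data.frame(id = sprintf("tRNA%02d_%d", i, cp), start = st,
                 end = st + flen)
  }
  chrom <- paste0(chrom, rand_dna(100L))
  rows <- do.call(rbind, rows)
  g <- genome(c(chr1 = chrom))
  ann <- orf_annotation(rows$id, "chr1", "+", rows$start, rows$end,
                        biotype = "tRNA")
  list(genome = g, annotations = ann,
       reference = build_collapsed_reference(g, ann, window))
}

# toy mRNA gene set: two plus-strand and one minus-strand gene with
# generous flanks, for assignment and positional unit tests
make_toy_genes <- function(seed = 7L, n_codons = c(20L, 30L, 25L)) {
  set.seed(seed)
  make_cds <- function(nc) paste0(
    "ATG", paste(sample(setdiff(
      apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                        c("A","C","G","T")), 1, paste, collapse = ""),
      c("TAA", "TAG", "TGA")), nc - 2L, replace = TRUE), collapse = ""), "TAA")
  strands <- c("+", "+", "-")
  chrom <- ""
  starts <- integer(3)
  for (i in 1:3) {
    chrom <- paste0(chrom, rand_dna(50L))
    starts[i] <- nchar(chrom)
    cds <- make_cds(n_codons[i])
    chrom <- paste0(chrom, if (strands[i] == "+") cds else revcomp(cds))
  }
  chrom <- paste0(chrom, rand_dna(50L))
  g <- genome(c(chrT = chrom))
  ann <- orf_annotation(c("tA", "tB", "tC"), "chrT", strands, starts,
                        starts + 3L * n_codons)
  list(genome = g, annotations = ann)
}

# framed-read table with exactly `per_pos` reads at every in-frame position
# (P-site codons 1..n_cod): the fixed point of every normalization
uniform_framed <- function(annotations, per_pos = 1L, length = 28L) {
  lens <- spliced_length(annotations)
  parts <- lapply(annotations$gene_id, function(g) {
    n_cod <- lens[[g]] %/% 3L
    rel5 <- rep(3L * (seq_len(n_cod) - 1L) - 12L, each = per_pos)
    data.table(gene_id = g,
               read_id = sprintf("%s_u%05d", g, seq_along(rel5)),
               rel5 = rel5, length = length, multimap_class = 255L,
               species = "analysis")
  })
  rbindlist(parts)
}

# analysis-species framed reads of one simulated library
framed_of <- function(sim, nm, offsets = default_offset_table()) {
  al <- sim$libraries[[nm]]
  apply_offsets(assign_to_orf(al[al$species == "analysis"], sim$annotations),
                offsets)
}
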