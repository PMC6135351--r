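toy <- make_toy_genes()

test_that("metagene is the identity on uniform per-nucleotide coverage", {
  lens <- spliced_length(toy$annotations)
  fr <- data.table::rbindlist(lapply(toy$annotations$gene_id, function(g) {
    rel5 <- rep(seq.int(0L, lens[[g]] - 1L), 2L)
    data.table::data.table(gene_id = g, read_id = seq_along(rel5),
                           rel5 = rel5, length = 28L)
  }))
  mg <- metagene(fr, toy$annotations, "start", c(0L, 30L), min_reads = 1L)
  expect_equal(mg$occupancy, rep(1, nrow(mg)), tolerance = 1e-12)
  expect_identical(attr(mg, "n_genes"), 3L)
})

test_that("delta input: one position carries occupancy = gene length", {
  ann <- toy$annotations[2]  # 30 codons, L = 90
  fr <- data.table::data.table(gene_id = "tB", read_id = sprintf("r%d", 1:20),
                               rel5 = 0L, length = 28L)
  mg <- metagene(fr, toy$annotations, "start", c(-10L, 10L), min_reads = 1L)
  expect_equal(mg[position == 0, occupancy], 90, tolerance = 1e-12)
  expect_equal(mg[position != 0, sum(occupancy)], 0)
})

test_that("metagene matches a direct two-loop tally oracle", {
  set.seed(17)
  lens <- spliced_length(toy$annotations)
  fr <- data.table::rbindlist(lapply(toy$annotations$gene_id, function(g) {
    n <- 80L
    data.table::data.table(gene_id = g, read_id = sprintf("%s_%d", g, 1:n),
                           rel5 = sample(-12:(lens[[g]] - 18L), n, TRUE),
                           length = 28L)
  }))
  win <- c(-12L, 20L)
  mg <- metagene(fr, toy$annotations, "start", win, min_reads = 1L)
  oracle <- numeric(diff(win) + 1L)
  for (g in toy$annotations$gene_id) {
    sub <- fr[gene_id == g]
    expr <- nrow(sub) / lens[[g]]
    for (k in seq_along(oracle)) {
      pos <- win[1] + k - 1L
      oracle[k] <- oracle[k] + sum(sub$rel5 == pos) / expr
    }
  }
  expect_equal(mg$occupancy, oracle / 3, tolerance = 1e-12)
})

test_that("stop-anchored metagene aligns on the first stop nucleotide", {
  ann <- toy$annotations[1]  # 20 codons, L = 60, stop starts at 57
  fr <- data.table::data.table(gene_id = "tA", read_id = 1:70,
                               rel5 = c(rep(57L - 12L, 20L),
                                        sample(-12:40, 50L, TRUE)),
                               length = 28L)
  mg <- metagene(fr, toy$annotations, "stop", c(-20L, 2L), min_reads = 1L)
  expect_gt(mg[position == -12L, occupancy], mg[position == -11L, occupancy])
})

test_that("start/body ratios follow the constructed tallies", {
  # gene tB (30 codons): 10 start reads, 100 body reads spread in frame
  body_p <- rep(seq(2L, 25L), length.out = 100L)
  fr <- data.table::data.table(
    gene_id = "tB", read_id = seq_len(110L),
    rel5 = c(rep(-12L, 10L), 3L * (body_p - 1L) - 12L),
    length = 28L)
  sb <- start_body_ratios(fr, toy$annotations, min_reads = 1L)
  expect_equal(sb$ratio, 0.1)
  expect_identical(sb$start_count, 10L)
  expect_identical(sb$body_count, 100L)
  # all reads in the last 5 codons: excluded with body 0
  fr2 <- data.table::data.table(gene_id = "tB", read_id = 1:70,
                                rel5 = 3L * (27L - 1L) - 12L, length = 28L)
  sb2 <- start_body_ratios(fr2, toy$annotations, min_reads = 1L)
  expect_identical(nrow(sb2), 0L)
  expect_identical(attr(sb2, "excluded"), "tB")
})

test_that("G-statistic: zero deviation gives G = 0 and p = 1", {
  set.seed(23)
  nts <- c("A", "C", "G", "T")
  ctx <- stats::setNames(replicate(64, paste(
    c(sample(nts, 13, TRUE), "ATG", sample(nts, 13, TRUE)), collapse = "")),
    sprintf("g%02d", 1:64))
  # degenerate ranking: every gene equal; quartile = stable first 16 by id.
  # With contexts cloned from the quartile, O = E at every position.
  ids <- names(ctx)
  top_ids <- sort(ids)[1:16]
  # craft contexts so each position's top-quartile composition equals the
  # all-gene composition exactly: all genes share one context string
  ctx[] <- ctx[[1]]
  nb <- nucleotide_bias(stats::setNames(rep(1, 64), ids), ctx)
  expect_equal(nb$positions$G, rep(0, 26), tolerance = 1e-12)
  expect_equal(nb$positions$p_raw, rep(1, 26))
  expect_equal(nb$positions$p_bonferroni, rep(1, 26))
  expect_identical(nb$positions$position, c(-13:-1, 4:16))
})

test_that("G equals the independent summation oracle on printed-style counts", {
  O <- c(30, 20, 25, 25)
  E <- c(25, 25, 25, 25)
  # oracle: term-by-term accumulation in rational-friendly order
  oracle <- 0
  for (k in 4:1) oracle <- oracle + 2 * O[k] * log(O[k] / E[k])
  g_terms <- ifelse(O == 0, 0, 2 * O * log(O / E))
  expect_equal(sum(g_terms), oracle, tolerance = 1e-12)
  expect_equal(oracle, 2 * (30 * log(30 / 25) + 20 * log(20 / 25)),
               tolerance = 1e-12)
})

test_that("nucleotide_bias matches a direct tally oracle on random input", {
  set.seed(61)
  nts <- c("A", "C", "G", "T")
  n <- 120L
  ids <- sprintf("g%03d", seq_len(n))
  ctx <- stats::setNames(vapply(ids, function(i) paste(
    c(sample(nts, 13, TRUE), "ATG", sample(nts, 13, TRUE)), collapse = ""),
    character(1)), ids)
  ranking <- stats::setNames(rnorm(n), ids)
  nb <- nucleotide_bias(ranking, ctx)
  # oracle: explicit top-quartile selection and per-position tallies
  top <- ids[order(-ranking, ids)][1:ceiling(n / 4)]
  str_idx <- c(1:13, 17:29)
  for (k in c(1L, 7L, 20L, 26L)) {
    allc <- table(factor(substring(ctx, str_idx[k], str_idx[k]),
                         levels = nts))
    topc <- table(factor(substring(ctx[top], str_idx[k], str_idx[k]),
                         levels = nts))
    E <- as.numeric(allc) / n * length(top)
    O <- as.numeric(topc)
    G <- sum(ifelse(O == 0, 0, 2 * O * log(O / E)))
    expect_equal(nb$positions$G[k], G, tolerance = 1e-9)
    expect_equal(nb$positions$p_raw[k], pchisq(G, 3, lower.tail = FALSE))
  }
  # G additivity: position G equals the sum of its four nucleotide terms
  sums <- nb$per_nucleotide[, .(s = sum(bias)), by = position]
  expect_equal(nb$positions$G, sums$s, tolerance = 1e-9)
})

test_that("G additivity and p monotonicity hold on random tables", {
  set.seed(31)
  for (i in 1:20) {
    O <- as.numeric(stats::rmultinom(1, 200, runif(4, 0.5, 1)))
    E <- rep(50, 4)
    terms <- ifelse(O == 0, 0, 2 * O * log(O / E))
    G <- sum(terms)
    expect_gte(G, -1e-9)
    expect_equal(G, sum(terms), tolerance = 1e-9)
  }
  gs <- c(0.5, 1, 2, 4, 8, 16)
  ps <- pchisq(gs, 3, lower.tail = FALSE)
  expect_true(all(diff(ps) < 0))
})

test_that("pause scores: uniform gene scores 1 everywhere", {
  fr <- uniform_framed(toy$annotations, per_pos = 3L)
  ps <- pause_scores(fr, toy$annotations, toy$genome,
                     codon_position = c(2L, 5L), site = "A")
  expect_equal(ps$score, rep(1, nrow(ps)), tolerance = 1e-12)
  # codon identity is read from the genome
  expect_identical(ps[gene_id == "tA" & codon_position == 2L, codon],
                   codon_at(toy$annotations[1], toy$genome, 2L))
})

test_that("pause score hand example: 25 reads at +2, density 100/10", {
  # 10 codons with reads, 100 in-frame reads total, 25 at codon 2 P-site...
  # A-site indexing: +2 in the A site means P-site codon 1 (5' end at -12)
  p_codons <- c(rep(1L, 25L), rep(c(3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L),
                                  length.out = 75L))
  fr <- data.table::data.table(gene_id = "tB", read_id = seq_along(p_codons),
                               rel5 = 3L * (p_codons - 1L) - 12L,
                               length = 28L)
  ps <- pause_scores(fr, toy$annotations, codon_position = 2L, site = "A")
  expect_equal(ps$score, 25 / (100 / 10))
})

test_that("within-gene mean pause score is 1 when the tail is empty", {
  set.seed(41)
  ann <- toy$annotations[2]  # 30 codons
  p <- sample(1:24, 400L, replace = TRUE)  # last 5 codons of tail empty
  fr <- data.table::data.table(gene_id = "tB", read_id = seq_along(p),
                               rel5 = 3L * (p - 1L) - 12L, length = 28L)
  covered <- sort(unique(p))
  ps <- pause_scores(fr, toy$annotations, codon_position = covered + 1L,
                     site = "A")
  expect_equal(mean(ps$score), 1, tolerance = 1e-9)
})

test_that("K-S statistic agrees with a brute-force ECDF gap scan", {
  set.seed(43)
  a <- rlnorm(20); b <- rlnorm(20, 0.4)
  ks <- suppressWarnings(stats::ks.test(a, b))
  grid <- sort(c(a, b))
  gaps <- vapply(grid, function(x) abs(mean(a <= x) - mean(b <= x)),
                 numeric(1))
  expect_equal(unname(ks$statistic), max(gaps), tolerance = 1e-12)
})

test_that("pause shift: self-comparison is flat, exact factor 2 is recovered", {
  set.seed(47)
  tab <- data.table::data.table(gene_id = sprintf("g%02d", 1:30),
                                codon_position = 2L, codon = "TCT",
                                score = rlnorm(30))
  self <- pause_shift_by_codon(tab, tab)
  expect_equal(self$median_shift, 1)
  expect_equal(self$ks_p, 1, tolerance = 1e-9)
  tab2 <- data.table::copy(tab)[, score := score * 2]
  sh <- pause_shift_by_codon(tab, tab2)
  expect_equal(sh$median_shift, 2)
  # under-populated codons are skipped
  small <- tab[1:5]
  expect_identical(nrow(pause_shift_by_codon(small, small)), 0L)
})

test_that("metacodon occupancy is 1 under uniform coverage and filters genes", {
  fr <- uniform_framed(toy$annotations, per_pos = 2L)
  occ <- metacodon_occupancy(fr, toy$annotations, toy$genome, "long")
  expect_equal(occ$E, rep(1, nrow(occ)), tolerance = 1e-12)
  expect_equal(occ$P, rep(1, nrow(occ)), tolerance = 1e-12)
  expect_equal(occ$A, rep(1, nrow(occ)), tolerance = 1e-12)
  # a gene with mean coverage < 1 read per codon is excluded entirely
  thin <- uniform_framed(toy$annotations[1], per_pos = 1L)[seq_len(10L)]
  expect_error(metacodon_occupancy(thin, toy$annotations[1], toy$genome,
                                   "long"), "coverage")
})

test_that("doubled A-site weight on one codon shows up at ~2 in its A occupancy", {
  cfg <- footprint_sim_config(n_genes = 40L, gene_length_range = c(60L, 120L),
                              expression_sdlog = 0.3,
                              codon_pause_multipliers = c(CCA = 2),
                              reads_per_library = 6e4, frame_fidelity = 1,
                              seed = 53L)
  sim <- simulate_footprint_libraries(cfg, 1L, 1L)
  fr <- framed_of(sim, "cond1_rep1")
  occ <- metacodon_occupancy(fr, sim$annotations, sim$genome, "long")
  expect_equal(occ[codon == "CCA", A], 2, tolerance = 0.15)
  others <- occ[codon != "CCA" & !codon %in% c("TAA", "TAG", "TGA"), A]
  expect_equal(median(others), 1, tolerance = 0.1)
})
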