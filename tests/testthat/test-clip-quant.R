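test_that("multimap weights are the fixed published factors", {
  expect_equal(multimap_weight(c(0L, 1L, 3L, 255L)), c(0.2, 0.286, 0.5, 1))
  expect_error(multimap_weight(7L), "unknown multimap class")
  expect_error(alignments("r", "c", "+", 1L, 20L, multimap_class = 2L),
               "multimap_class")
})

test_that("single unique read: per-position 1/len coverage, density 1", {
  ann <- orf_annotation("t1", "artificial", "+", 100L, 175L, biotype = "tRNA")
  al <- alignments("r1", "artificial", "+", 110L, 30L)
  lib <- clip_library(al, "IP")
  dt <- trna_density(lib, ann, cutoff = 1)
  expect_equal(dt$density, 1)       # 30 x (1/30) / 1 primary
  expect_equal(dt$end5_count, 1)
  expect_true(dt$meets_cutoff)
})

test_that("class-3 two-locus placement conserves one read-equivalent", {
  ann <- orf_annotation(c("t1", "t2"), "artificial", "+", c(0L, 200L),
                        c(80L, 280L), biotype = "tRNA")
  al <- alignments(c("r1", "r1"), "artificial", "+", c(10L, 210L), 30L,
                   multimap_class = 3L, is_primary = c(TRUE, FALSE))
  dt <- trna_density(clip_library(al, "IP"), ann, cutoff = 1)
  # each placement deposits 0.5 spread over its length: total 1.0
  expect_equal(sum(dt$density) * attr(dt, "n_primary"), 1.0)
  expect_equal(sum(dt$end5_count), 1.0)
})

test_that("densities match a brute-force per-position accumulation oracle", {
  set.seed(71)
  ann <- orf_annotation(c("t1", "t2", "t3"), "artificial", "+",
                        c(0L, 150L, 320L), c(90L, 260L, 400L),
                        biotype = "tRNA")
  n <- 50L
  cls <- sample(c(0L, 1L, 3L, 255L), n, replace = TRUE)
  al <- alignments(sprintf("r%02d", 1:n), "artificial", "+",
                   sample.int(380L, n, replace = TRUE),
                   sample(20:32, n, replace = TRUE), cls)
  lib <- clip_library(al, "SMI")
  dt <- trna_density(lib, ann, cutoff = 1)
  # oracle: accumulate weight/len into an explicit coverage vector
  cov <- numeric(500L)
  w <- c(`0` = 0.2, `1` = 0.286, `3` = 0.5, `255` = 1)
  for (k in seq_len(n)) {
    idx <- (al$five_prime[k] + 1L):(al$five_prime[k] + al$length[k])
    cov[idx] <- cov[idx] + w[[as.character(al$multimap_class[k])]] / al$length[k]
  }
  for (i in 1:3) {
    g <- ann[i]
    expect_equal(dt$density[i],
                 sum(cov[(g$cds_start + 1L):g$cds_end]) / n,
                 tolerance = 1e-12)
  }
})

test_that("density is invariant under read duplication", {
  ann <- orf_annotation("t1", "artificial", "+", 0L, 100L, biotype = "tRNA")
  al <- alignments(sprintf("r%d", 1:20), "artificial", "+",
                   rep(c(5L, 40L), 10L), 25L)
  d1 <- trna_density(clip_library(al, "IP"), ann, cutoff = 1)
  al2 <- rbind(al, data.table::copy(al)[, read_id := paste0(read_id, "b")])
  d2 <- trna_density(clip_library(al2, "IP"), ann, cutoff = 1)
  expect_equal(d1$density, d2$density, tolerance = 1e-12)
})

test_that("tRNA enrichment: boundary inclusion, null case, cutoff gating", {
  mk <- function(dens, cut = TRUE) data.table::data.table(
    gene_id = c("t1", "t2"), end5_count = 100, density = dens,
    meets_cutoff = cut)
  # IP exactly 4x both controls: called (>= rule)
  enr <- trna_enrichment(list(mk(c(4, 1))), mk(c(1, 1)), mk(c(1, 1)))
  expect_identical(enr[gene_id == "t1", enriched], TRUE)
  expect_identical(enr[gene_id == "t2", enriched], FALSE)
  # identical IP and controls: nothing called
  enr0 <- trna_enrichment(list(mk(c(2, 3)), mk(c(2, 3))), mk(c(2, 3)),
                          mk(c(2, 3)))
  expect_false(any(enr0$enriched))
  # cutoff failure anywhere blocks the call
  enr2 <- trna_enrichment(list(mk(c(8, 8))), mk(c(1, 1), cut = FALSE),
                          mk(c(1, 1)))
  expect_false(any(enr2$enriched))
  expect_false(any(enr2$testable))
})

test_that("region enrichment: self-comparison gives fold 1 and no calls", {
  set.seed(73)
  al <- alignments(sprintf("r%03d", 1:200), "artificial", "+",
                   sample.int(900L, 200L, replace = TRUE), 30L)
  ip <- clip_library(al, "IP")
  ctrl <- clip_library(data.table::copy(al), "SMI")
  iv <- data.frame(chrom = "artificial", start = c(100L, 500L),
                   end = c(200L, 640L))
  re <- region_enrichment(list(ip1 = ip, ip2 = ip), list(smi = ctrl), iv)
  expect_equal(re$tests$fold, rep(1, 4), tolerance = 1e-12)
  expect_false(any(re$regions$reproducible))
  # the 1-based inclusive interval [1188, 1282] spans 95 nt
  iv95 <- data.frame(chrom = "artificial", start = 1188L - 1L, end = 1282L)
  re95 <- region_enrichment(list(ip1 = ip), list(smi = ctrl), iv95)
  expect_identical(re95$regions$width, 95L)
})

test_that("Fisher p matches an exhaustive hypergeometric tail enumeration", {
  cases <- list(c(5, 15, 1, 19), c(12, 88, 3, 97), c(0, 10, 5, 5),
                c(30, 70, 10, 90))
  for (cs in cases) {
    a <- cs[1]; b <- cs[2]; c_ <- cs[3]; d <- cs[4]
    p_pkg <- riboclip:::fisher_exact_greater(a, b, c_, d)
    # oracle: sum the point hypergeometric masses of every table with
    # first cell >= a at fixed margins
    m <- a + b; nn <- c_ + d; k <- a + c_
    xs <- max(0, k - nn):min(k, m)
    mass <- choose(m, xs) * choose(nn, k - xs) / choose(m + nn, k)
    expect_equal(p_pkg, sum(mass[xs >= a]), tolerance = 1e-12)
    expect_equal(p_pkg,
                 stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                                    alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("enrichment fold symmetry: swapping IP and control inverts folds", {
  set.seed(79)
  al1 <- alignments(sprintf("a%03d", 1:150), "artificial", "+",
                    sample.int(500L, 150L, replace = TRUE), 25L)
  al2 <- alignments(sprintf("b%03d", 1:150), "artificial", "+",
                    sample.int(500L, 150L, replace = TRUE), 25L)
  l1 <- clip_library(al1, "IP"); l2 <- clip_library(al2, "SMI")
  iv <- data.frame(chrom = "artificial", start = 50L, end = 250L)
  f12 <- region_enrichment(list(a = l1), list(b = l2), iv)$tests$fold
  f21 <- region_enrichment(list(b = l2), list(a = l1), iv)$tests$fold
  expect_equal(f12, 1 / f21, tolerance = 1e-12)
})

test_that("conversion profile tallies and masks correctly", {
  al <- alignments(sprintf("r%02d", 1:10), "artificial", "+", 0L, 30L)
  mm <- data.table::data.table(read_id = sprintf("r%02d", 1:3),
                               chrom = "artificial", pos = 12L,
                               ref_base = "T", read_base = "C")
  lib <- clip_library(al, "IP", mismatches = mm)
  cp <- conversion_profile(lib, "artificial", min_coverage = 5L)
  expect_equal(cp[pos == 12L, tc_count], 3L)
  expect_equal(cp[pos == 12L, frequency], 0.3)
  expect_equal(cp[pos == 13L, frequency], 0)
  # masked under min_coverage; masking is monotone in the threshold
  cp100 <- conversion_profile(lib, "artificial", min_coverage = 100L)
  expect_true(all(is.na(cp100$frequency)))
  expect_true(all(is.na(cp$frequency) | cp$frequency >= 0 & cp$frequency <= 1))
  # clean input: no mismatch events anywhere
  lib0 <- clip_library(al, "IP")
  cp0 <- conversion_profile(lib0, "artificial", min_coverage = 5L)
  expect_true(all(cp0$frequency == 0))
})

test_that("simulated crosslink site recovers rate; background stays low", {
  fx <- make_trna_ref(nfam = 6L)
  csim <- simulate_clip_libraries(
    clip_sim_config(mean_reads = 600, background_conversion = 0.01,
                    seed = 83L), fx$reference)
  cp <- conversion_profile(csim$libraries$IP_rep1, "artificial",
                           min_coverage = 50L)
  sites <- csim$truth$crosslink_sites
  at_sites <- cp[pos %in% sites & !is.na(frequency), frequency]
  away <- cp[!pos %in% sites & !is.na(frequency), frequency]
  expect_gt(min(at_sites), 0.35)
  expect_lt(max(away), 0.1)
  # zero-background config: signal only at the sites
  csim0 <- simulate_clip_libraries(
    clip_sim_config(mean_reads = 600, background_conversion = 0,
                    seed = 83L), fx$reference)
  cp0 <- conversion_profile(csim0$libraries$IP_rep1, "artificial",
                            min_coverage = 50L)
  expect_true(all(cp0[!pos %in% sites & !is.na(frequency), frequency] == 0))
})
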