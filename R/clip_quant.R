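MULTIMAP_WEIGHTS <- c(`0` = 0.2, `1` = 0.286, `3` = 0.5, `255` = 1)

#' Fractional assignment weight for a multimap class
#'
#' Fixed per-class scaling factors applied to every placement of a
#' multimapping read (MAPQ convention: 255 unique, 3 two placements,
#' 1 three-four, 0 five or more). The printed factors are applied exactly
#' as stated and never renormalized, so classes 0 and 1 deposit slightly
#' less or more than one read-equivalent by construction.
#'
#' @param multimap_class integer vector with values in \{0, 1, 3, 255\}.
#' @return numeric vector of weights.
#' @export
multimap_weight <- function(multimap_class) {
  w <- MULTIMAP_WEIGHTS[as.character(multimap_class)]
  if (anyNA(w))
    stop("unknown multimap class: ",
         paste(unique(multimap_class[is.na(w)]), collapse = ", "))
  unname(w)
}

#' Construct a CLIP library
#'
#' @param alignments an \code{alignments} table holding every placement of
#'   every read (one primary placement per read).
#' @param role library role: \code{"IP"}, \code{"SMI"} (size-matched input)
#'   or \code{"untagged"}.
#' @param replicate integer replicate index.
#' @param library_id identifier string.
#' @param mismatches optional \code{data.table(read_id, chrom, pos,
#'   ref_base, read_base)} of mismatch events (0-based positions).
#' @return list of class \code{clip_library}.
#' @export
clip_library <- function(alignments, role = c("IP", "SMI", "untagged"),
                         replicate = 1L, library_id = NULL,
                         mismatches = NULL) {
  role <- match.arg(role)
  if (is.null(mismatches))
    mismatches <- data.table(read_id = character(), chrom = character(),
                             pos = integer(), ref_base = character(),
                             read_base = character())
  if (is.null(library_id)) library_id <- paste0(role, "_rep", replicate)
  if (!any(alignments$is_primary)) stop("library has no primary alignments")
  structure(list(library_id = library_id, role = role,
                 replicate = as.integer(replicate),
                 alignments = as.data.table(alignments),
                 mismatches = as.data.table(mismatches)),
            class = "clip_library")
}

placement_span <- function(al) {
  # genomic [start, end) covered by each placement
  start <- ifelse(al$strand == "+", al$five_prime, al$five_prime - al$length + 1L)
  data.table(start = as.integer(start), end = as.integer(start + al$length))
}

#' Length-normalized tRNA read densities with fractional multimap weights
#'
#' Every placement deposits weight/read-length at each covered position;
#' a gene's density is the summed coverage across its span divided by the
#' library's total primary alignments. Weighted 5'-end counts (same
#' fractional weights) drive the 64-count inclusion cutoff.
#'
#' @param library a \code{clip_library}.
#' @param annotations an \code{orf_annotation} table on the collapsed
#'   reference (e.g. \code{ref$artificial_annotations}).
#' @param cutoff minimum weighted 5'-end count (default 64).
#' @return \code{data.table(gene_id, end5_count, density, meets_cutoff)}
#'   with attribute \code{n_primary}.
#' @export
trna_density <- function(library, annotations, cutoff = 64) {
  al <- library$alignments
  n_primary <- sum(al$is_primary)
  if (n_primary == 0L) stop("degenerate library: zero primary alignments")
  w <- multimap_weight(al$multimap_class)
  span <- placement_span(al)
  rows <- vector("list", nrow(annotations))
  for (i in seq_len(nrow(annotations))) {
    g <- annotations[i]
    onchrom <- al$chrom == g$chrom
    ov <- pmin(span$end, g$cds_end) - pmax(span$start, g$cds_start)
    ov[!onchrom] <- 0L
    ov <- pmax(ov, 0L)
    cov_sum <- sum(w * ov / al$length)
    e5 <- sum(w[onchrom & al$five_prime >= g$cds_start &
                  al$five_prime < g$cds_end])
    rows[[i]] <- data.table(gene_id = g$gene_id, end5_count = e5,
                            density = cov_sum / n_primary)
  }
  out <- rbindlist(rows)
  out[, meets_cutoff := end5_count >= cutoff]
  setattr(out, "n_primary", n_primary)
  out[]
}

#' Dual-control tRNA enrichment calls
#'
#' A gene is called enriched iff it meets the count cutoff in every library
#' and its density is at least \code{fold}-fold that of both the SMI and
#' the untagged control in every IP replicate. Median-centered log10
#' densities are attached for replicate-correlation QC.
#'
#' @param ip_tables list of \code{\link{trna_density}} tables, one per IP
#'   replicate.
#' @param smi_table,untagged_table control density tables.
#' @param fold enrichment threshold (default 4; the rule is inclusive).
#' @return \code{data.table} with per-library densities, \code{testable}
#'   (cutoff met everywhere) and \code{enriched} flags; attribute
#'   \code{log10_centered} holds the QC matrix.
#' @export
trna_enrichment <- function(ip_tables, smi_table, untagged_table, fold = 4) {
  if (!is.list(ip_tables) || length(ip_tables) < 1L)
    stop("supply a list of at least one IP density table")
  tabs <- c(stats::setNames(ip_tables,
                            paste0("IP", seq_along(ip_tables))),
            list(SMI = smi_table, untagged = untagged_table))
  genes <- Reduce(intersect, lapply(tabs, `[[`, "gene_id"))
  out <- data.table(gene_id = genes)
  for (nm in names(tabs)) {
    t <- as.data.table(tabs[[nm]])
    out[, paste0("density_", nm) := t$density[match(genes, t$gene_id)]]
    out[, paste0("cutoff_", nm) := t$meets_cutoff[match(genes, t$gene_id)]]
  }
  cutcols <- grep("^cutoff_", names(out), value = TRUE)
  out[, testable := Reduce(`&`, .SD), .SDcols = cutcols]
  ipcols <- paste0("density_", paste0("IP", seq_along(ip_tables)))
  enr <- out$testable
  for (ic in ipcols)
    enr <- enr & out[[ic]] >= fold * out$density_SMI &
      out[[ic]] >= fold * out$density_untagged
  out[, enriched := enr]
  qc <- sapply(c(ipcols, "density_SMI", "density_untagged"), function(cn) {
    v <- log10(out[[cn]][out$testable])
    v - median(v)
  })
  setattr(out, "log10_centered", qc)
  out[]
}

region_counts <- function(library, intervals) {
  al <- library$alignments[library$alignments$is_primary == TRUE]
  span <- placement_span(al)
  vapply(seq_len(nrow(intervals)), function(i) {
    sum(al$chrom == intervals$chrom[i] &
          span$end > intervals$start[i] & span$start < intervals$end[i])
  }, numeric(1))
}

#' Candidate-region enrichment versus control libraries
#'
#' For each candidate interval, the in-region read fraction of every IP
#' library is compared to that of every control: fold = (in/total)_IP /
#' (in/total)_control, with one pseudo-read added to both in-region counts
#' only when the control count is zero, and a one-sided Fisher exact p-value
#' on the raw 2x2 counts (in-region vs rest, IP vs control). An interval is
#' reproducible iff fold > \code{fold} and p < \code{p_max} against every
#' control in every IP replicate.
#'
#' @param ip_libraries named list of \code{clip_library} (>= 1; >= 2 for a
#'   meaningful reproducibility flag).
#' @param control_libraries named list of \code{clip_library}.
#' @param candidate_intervals \code{data.frame(chrom, start, end)} with
#'   0-based half-open coordinates (caller-supplied peak candidates).
#' @param fold,p_max reproducibility thresholds (defaults 4 and 1e-5;
#'   fold is exclusive per the > 4.0 rule).
#' @return list with \code{tests} (long table: interval x IP x control with
#'   fold and p) and \code{regions} (per interval: width and
#'   \code{reproducible} flag).
#' @export
region_enrichment <- function(ip_libraries, control_libraries,
                              candidate_intervals, fold = 4, p_max = 1e-5) {
  iv <- as.data.table(candidate_intervals)
  iv[, interval := paste0(chrom, ":", start, "-", end)]
  ipc <- lapply(ip_libraries, region_counts, intervals = iv)
  ctc <- lapply(control_libraries, region_counts, intervals = iv)
  ipt <- vapply(ip_libraries, function(l) sum(l$alignments$is_primary), numeric(1))
  ctt <- vapply(control_libraries, function(l) sum(l$alignments$is_primary), numeric(1))
  rows <- vector("list", 0L)
  for (i in seq_along(ip_libraries)) for (j in seq_along(control_libraries)) {
    a <- ipc[[i]]; b <- ctc[[j]]
    a_f <- a; b_f <- b
    zero <- b == 0
    a_f[zero] <- a[zero] + 1
    b_f[zero] <- b[zero] + 1
    fc <- (a_f / ipt[i]) / (b_f / ctt[j])
    p <- vapply(seq_len(nrow(iv)), function(k)
      fisher_exact_greater(a[k], ipt[i] - a[k], b[k], ctt[j] - b[k]),
      numeric(1))
    rows[[length(rows) + 1L]] <-
      data.table(interval = iv$interval, ip = names(ip_libraries)[i],
                 control = names(control_libraries)[j],
                 ip_count = a, control_count = b, fold = fc, p = p)
  }
  tests <- rbindlist(rows)
  fold_thr <- fold
  verdict <- tests[, .(pass = all(fold > fold_thr & p < p_max)), by = interval]
  regions <- iv[, .(interval, chrom, start, end, width = end - start)]
  regions[, reproducible := verdict$pass[match(interval, verdict$interval)]]
  list(tests = tests[], regions = regions[])
}

# one-sided (greater) Fisher exact p for table rbind(c(a, b), c(c, d)):
# hypergeometric upper tail of a
fisher_exact_greater <- function(a, b, c, d) {
  phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

#' Per-position T-to-C conversion profile
#'
#' Frequency of reference-T to read-C transitions among reads covering each
#' position of a chromosome; positions with coverage below
#' \code{min_coverage} are masked (frequency NA) but still reported.
#'
#' @param library a \code{clip_library} whose \code{mismatches} table holds
#'   the per-read mismatch events.
#' @param target_chrom chromosome to profile.
#' @param min_coverage coverage mask threshold (default 100).
#' @return \code{data.table(pos, coverage, tc_count, frequency)} over all
#'   covered positions (0-based).
#' @export
conversion_profile <- function(library, target_chrom, min_coverage = 100L) {
  al <- library$alignments[library$alignments$chrom == target_chrom &
                             library$alignments$is_primary == TRUE]
  if (nrow(al) == 0L)
    return(data.table(pos = integer(), coverage = integer(),
                      tc_count = integer(), frequency = numeric()))
  span <- placement_span(al)
  lo <- min(span$start); hi <- max(span$end)
  cov <- integer(hi - lo)
  for (i in seq_len(nrow(al))) {
    idx <- (span$start[i] - lo + 1L):(span$end[i] - lo)
    cov[idx] <- cov[idx] + 1L
  }
  mm <- library$mismatches[chrom == target_chrom & ref_base == "T" &
                             read_base == "C"]
  tc <- integer(hi - lo)
  if (nrow(mm) > 0L) {
    tabs <- mm[, .N, by = pos]
    tc[tabs$pos - lo + 1L] <- tabs$N
  }
  out <- data.table(pos = seq.int(lo, hi - 1L), coverage = cov, tc_count = tc)
  out[, frequency := ifelse(coverage >= min_coverage, tc_count / coverage,
                            NA_real_)]
  out[]
}
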