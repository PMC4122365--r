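#' Quality thresholds defining evaluable loci
#'
#' A locus is evaluable when, in every one of the three pools, its read depth,
#' consensus base quality and best read mapping quality meet these thresholds.
#' Defaults: depth >= 10, base quality >= 20, best read quality >= 40.
#'
#' @param min_depth,min_baseq,min_bestq non-negative integers.
#' @export
quality_thresholds <- function(min_depth = 10L, min_baseq = 20L,
                               min_bestq = 40L) {
  if (min_depth < 0 || min_baseq < 0 || min_bestq < 0)
    stop("thresholds must be >= 0")
  structure(list(min_depth = as.integer(min_depth),
                 min_baseq = as.integer(min_baseq),
                 min_bestq = as.integer(min_bestq)),
            class = "quality_thresholds")
}

#' Fixed-difference caller configuration
#'
#' A SNP is called at an evaluable site when each selected pool carries a base
#' different from both the reference and the control consensus at frequency
#' >= `fix_threshold` (default 0.90) and that base's control frequency is
#' <= `rare_threshold` (default 0.10). Identity of the H1 and H2 alleles is
#' recorded but only required when `require_h_identity = TRUE`, mirroring the
#' design where identity held empirically without being imposed.
#'
#' @param fix_threshold,rare_threshold frequency thresholds,
#'   `rare_threshold < fix_threshold`.
#' @param require_h_identity require the H1 and H2 alleles to match.
#' @param control_absence_max_reads for indels: maximum control reads
#'   supporting the event for it to count as "not identified" in the control.
#' @param freq_denominator `"base"` (sum of A/C/G/T counts; gapped or N reads
#'   do not dilute frequencies) or `"depth"` (raw read depth).
#' @export
caller_config <- function(fix_threshold = 0.90, rare_threshold = 0.10,
                          require_h_identity = FALSE,
                          control_absence_max_reads = 0L,
                          freq_denominator = c("base", "depth")) {
  if (!(rare_threshold < fix_threshold))
    stop("rare_threshold must be < fix_threshold")
  if (fix_threshold <= 0.5)
    stop("fix_threshold must exceed 0.5 so the fixed allele is unique")
  structure(list(fix_threshold = fix_threshold,
                 rare_threshold = rare_threshold,
                 require_h_identity = isTRUE(require_h_identity),
                 control_absence_max_reads = as.integer(control_absence_max_reads),
                 freq_denominator = match.arg(freq_denominator)),
            class = "caller_config")
}

#' Compute the evaluable-locus mask
#'
#' @param table a [pool_site_table()].
#' @param thresholds a [quality_thresholds()].
#' @return An `evaluable_mask`: list with `evaluable` (logical per table row)
#'   and `by_arm` (data.frame of per-arm site counts and evaluable fractions).
#' @export
evaluable_mask <- function(table, thresholds = quality_thresholds()) {
  stopifnot(inherits(table, "pool_site_table"),
            inherits(thresholds, "quality_thresholds"))
  ok <- rep(TRUE, nrow(table))
  for (p in .POOLS) {
    ok <- ok &
      table[[.pool_col("depth", p)]] >= thresholds$min_depth &
      table[[.pool_col("baseq", p)]] >= thresholds$min_baseq &
      table[[.pool_col("bestq", p)]] >= thresholds$min_bestq
  }
  arms <- unique(table$arm)
  by_arm <- data.frame(
    arm = arms,
    n_sites = as.integer(tapply(ok, factor(table$arm, arms), length)),
    n_evaluable = as.integer(tapply(ok, factor(table$arm, arms), sum)),
    stringsAsFactors = FALSE)
  by_arm$fraction <- ifelse(by_arm$n_sites > 0,
                            by_arm$n_evaluable / by_arm$n_sites, NA_real_)
  structure(list(evaluable = ok, by_arm = by_arm), class = "evaluable_mask")
}

.mask_vector <- function(mask, n) {
  if (inherits(mask, "evaluable_mask")) mask <- mask$evaluable
  stopifnot(is.logical(mask), length(mask) == n)
  mask
}

# per-pool base-count matrix, frequency denominator, majority base and its
# frequency; ties in the majority are broken toward the reference base
.pool_base_stats <- function(table, pool, cfg) {
  cnt <- cbind(A = table[[.pool_col("A", pool)]],
               C = table[[.pool_col("C", pool)]],
               G = table[[.pool_col("G", pool)]],
               T = table[[.pool_col("T", pool)]])
  denom <- if (cfg$freq_denominator == "base") rowSums(cnt)
           else table[[.pool_col("depth", pool)]]
  ref_i <- match(table$ref, .BASES)
  n <- nrow(cnt)
  # stable argmax with tie -> reference: bump the ref count by epsilon
  bump <- matrix(0, n, 4)
  bump[cbind(seq_len(n), ref_i)] <- 0.25
  maj_i <- max.col(cnt + bump, ties.method = "first")
  maj <- .BASES[maj_i]
  maj_count <- cnt[cbind(seq_len(n), maj_i)]
  list(counts = cnt, denom = denom, major = maj,
       major_freq = ifelse(denom > 0, maj_count / denom, NA_real_))
}

.base_freq <- function(stats, base) {
  i <- match(base, .BASES)
  cnt <- stats$counts[cbind(seq_along(i), i)]
  ifelse(stats$denom > 0, cnt / stats$denom, NA_real_)
}

#' Call fixed-difference SNPs
#'
#' At each evaluable site, the candidate allele of each selected pool is its
#' majority base. A call is emitted when, for both H1 and H2, the candidate
#' differs from the reference base and from the control consensus base
#' (majority base of C1, ties broken toward the reference), reaches frequency
#' >= `fix_threshold` in its own pool, and has frequency <= `rare_threshold`
#' in the control. With `require_h_identity = FALSE` (default) a site where
#' H1 and H2 fix different bases is still emitted, with `h_identity = FALSE`
#' and the H2 allele in `h_allele_H2`.
#'
#' @param table a [pool_site_table()].
#' @param mask an `evaluable_mask` (or logical vector) computed from the same
#'   table; non-evaluable sites are never called.
#' @param cfg a [caller_config()].
#' @return An `snp_calls` data.frame (see [call_io]).
#' @export
call_snps <- function(table, mask, cfg = caller_config()) {
  stopifnot(inherits(table, "pool_site_table"), inherits(cfg, "caller_config"))
  keep <- .mask_vector(mask, nrow(table))
  tab <- table[keep, , drop = FALSE]
  n <- nrow(tab)
  if (n == 0) return(.as_call_class(.empty_snp_df(), "snp"))
  c1 <- .pool_base_stats(tab, "C1", cfg)
  h1 <- .pool_base_stats(tab, "H1", cfg)
  h2 <- .pool_base_stats(tab, "H2", cfg)
  c_cons <- c1$major
  ok_pool <- function(h) {
    h$major != tab$ref & h$major != c_cons &
      !is.na(h$major_freq) & h$major_freq >= cfg$fix_threshold &
      !is.na(.base_freq(c1, h$major)) &
      .base_freq(c1, h$major) <= cfg$rare_threshold
  }
  ok <- ok_pool(h1) & ok_pool(h2)
  identical_h <- h1$major == h2$major
  if (cfg$require_h_identity) ok <- ok & identical_h
  ok[is.na(ok)] <- FALSE
  calls <- data.frame(
    arm = tab$arm[ok], pos = tab$pos[ok], ref = tab$ref[ok],
    h_allele = h1$major[ok], h_allele_H2 = h2$major[ok],
    c_consensus = c_cons[ok],
    freq_H1 = h1$major_freq[ok], freq_H2 = h2$major_freq[ok],
    freq_C1 = .base_freq(c1, h1$major)[ok],
    h_identity = identical_h[ok],
    stringsAsFactors = FALSE)
  .as_call_class(calls, "snp")
}

.empty_snp_df <- function() {
  data.frame(arm = character(0), pos = integer(0), ref = character(0),
             h_allele = character(0), h_allele_H2 = character(0),
             c_consensus = character(0), freq_H1 = numeric(0),
             freq_H2 = numeric(0), freq_C1 = numeric(0),
             h_identity = logical(0), stringsAsFactors = FALSE)
}

#' Call fixed-difference small indels
#'
#' An indel (insertion or deletion event at a site) is called when all of the
#' following hold at an evaluable site: the strand support pattern in each
#' selected pool is either two-strand ("*": at least one supporting read on
#' each strand) or same-strand ("+": at least 2 reads on one strand); both
#' selected pools have depth >= `min_depth`; the event is carried by >= 90%
#' (the caller's `fix_threshold`) of reads in both selected pools; and the
#' control shows at most `control_absence_max_reads` supporting reads. The
#' call's `maq_type` is `"*"` when both selected pools have two-strand
#' support, `"+"` otherwise. Support fractions use read depth as denominator.
#'
#' @inheritParams call_snps
#' @param thresholds a [quality_thresholds()]; its `min_depth` is the explicit
#'   selected-pool coverage criterion.
#' @return An `indel_calls` data.frame (`homopolymer_flag` is `NA` until
#'   [flag_homopolymer()] is applied).
#' @export
call_indels <- function(table, mask, cfg = caller_config(),
                        thresholds = quality_thresholds()) {
  stopifnot(inherits(table, "pool_site_table"), inherits(cfg, "caller_config"))
  keep <- .mask_vector(mask, nrow(table))
  tab <- table[keep, , drop = FALSE]
  out <- list()
  for (sign in c("ins", "del")) {
    f <- function(field, p) tab[[.pool_col(paste0(sign, field), p)]]
    strand_type <- function(p) {
      fwd <- f("_fwd", p); rev <- f("_rev", p)
      ifelse(fwd >= 1 & rev >= 1, "*",
             ifelse(fwd >= 2 | rev >= 2, "+", NA_character_))
    }
    t1 <- strand_type("H1"); t2 <- strand_type("H2")
    d1 <- tab[[.pool_col("depth", "H1")]]
    d2 <- tab[[.pool_col("depth", "H2")]]
    s1 <- ifelse(d1 > 0, f("", "H1") / d1, 0)
    s2 <- ifelse(d2 > 0, f("", "H2") / d2, 0)
    c_sup <- f("", "C1")
    ok <- !is.na(t1) & !is.na(t2) &
      d1 >= thresholds$min_depth & d2 >= thresholds$min_depth &
      s1 >= cfg$fix_threshold & s2 >= cfg$fix_threshold &
      c_sup <= cfg$control_absence_max_reads
    if (!any(ok)) next
    out[[sign]] <- data.frame(
      arm = tab$arm[ok], pos = tab$pos[ok], ref = tab$ref[ok],
      indel_seq = tab$ref[ok],           # single-base events at the site
      sign = sign,
      maq_type = ifelse(t1[ok] == "*" & t2[ok] == "*", "*", "+"),
      support_H1 = s1[ok], support_H2 = s2[ok],
      control_support_reads = c_sup[ok],
      homopolymer_flag = NA,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    calls <- data.frame(arm = character(0), pos = integer(0),
                        ref = character(0), indel_seq = character(0),
                        sign = character(0), maq_type = character(0),
                        support_H1 = numeric(0), support_H2 = numeric(0),
                        control_support_reads = integer(0),
                        homopolymer_flag = logical(0), stringsAsFactors = FALSE)
  } else {
    calls <- do.call(rbind, out)
    calls <- calls[order(calls$arm, calls$pos, method = "radix"), , drop = FALSE]
    rownames(calls) <- NULL
  }
  .as_call_class(calls, "indel")
}

#' Estimate the false-discovery rate by reciprocal replicate comparison
#'
#' True selection signals must be concordant between the two selected
#' replicates, which differ from each other only by drift and sampling. The
#' discovery criterion is therefore applied between H1 and H2: a locus counts
#' as a reciprocal false positive when one selected pool's majority base
#' differs from the reference at frequency >= `fix_threshold` while that base
#' is at frequency <= `rare_threshold` in the other selected pool. Both
#' directions are scanned and a locus is counted once. The FDR is the
#' reciprocal count divided by the number of called SNPs (default) or by the
#' number of evaluable loci.
#'
#' @inheritParams call_snps
#' @param called_snps number of SNP calls in the main scan.
#' @param denominator `"called"` or `"evaluable"`.
#' @return An `fdr_estimate`: list with `reciprocal_false_loci`,
#'   `called_snps`, `evaluable_loci`, `denominator`, `fdr`.
#' @export
estimate_fdr_reciprocal <- function(table, mask, cfg = caller_config(),
                                    called_snps,
                                    denominator = c("called", "evaluable")) {
  stopifnot(inherits(table, "pool_site_table"), inherits(cfg, "caller_config"))
  denominator <- match.arg(denominator)
  keep <- .mask_vector(mask, nrow(table))
  tab <- table[keep, , drop = FALSE]
  n_eval <- nrow(tab)
  count <- 0L
  if (n_eval > 0) {
    h1 <- .pool_base_stats(tab, "H1", cfg)
    h2 <- .pool_base_stats(tab, "H2", cfg)
    dir_hit <- function(a, b) {
      # a's majority base fixed and non-reference, rare in b
      a$major != tab$ref &
        !is.na(a$major_freq) & a$major_freq >= cfg$fix_threshold &
        !is.na(.base_freq(b, a$major)) &
        .base_freq(b, a$major) <= cfg$rare_threshold
    }
    hit <- dir_hit(h1, h2) | dir_hit(h2, h1)
    hit[is.na(hit)] <- FALSE
    count <- sum(hit)
  }
  denom_value <- if (denominator == "called") called_snps else n_eval
  if (denom_value == 0) {
    if (count > 0) stop("undefined FDR: reciprocal loci found but denominator is 0")
    fdr <- 0
  } else {
    fdr <- count / denom_value
  }
  structure(list(reciprocal_false_loci = as.integer(count),
                 called_snps = as.integer(called_snps),
                 evaluable_loci = as.integer(n_eval),
                 denominator = denominator, fdr = fdr),
            class = "fdr_estimate")
}

#' @export
print.fdr_estimate <- function(x, ...) {
  cat(sprintf("reciprocal false loci: %d\ndenominator (%s): %d\nFDR: %.3g\n",
              x$reciprocal_false_loci, x$denominator,
              if (x$denominator == "called") x$called_snps else x$evaluable_loci,
              x$fdr))
  invisible(x)
}

#' Flag indel calls adjacent to homopolymer tracts
#'
#' Single-base indels inside homopolymer runs are the classic short-read
#' alignment artifact. A call is flagged when its inserted/deleted sequence is
#' a single repeated base and a reference run of that base with length >=
#' `min_run` contains or abuts (within 1 bp of) the call position. Calls are
#' flagged, never removed.
#'
#' @param indel_calls an `indel_calls` table.
#' @param reference `DNAStringSet` of arm sequences.
#' @param min_run minimum homopolymer run length (default 5).
#' @return The calls with `homopolymer_flag` filled in.
#' @export
flag_homopolymer <- function(indel_calls, reference, min_run = 5L) {
  stopifnot(inherits(indel_calls, "indel_calls"))
  n <- nrow(indel_calls)
  if (n == 0) {
    indel_calls$homopolymer_flag <- logical(0)
    return(indel_calls)
  }
  flags <- logical(n)
  for (i in seq_len(n)) {
    arm <- indel_calls$arm[i]
    pos <- indel_calls$pos[i]
    if (!arm %in% names(reference)) stop("unknown arm: ", arm)
    arm_seq <- reference[[arm]]
    if (pos < 1 || pos > length(arm_seq))
      stop("position outside reference: ", arm, ":", pos)
    seqs <- strsplit(indel_calls$indel_seq[i], "")[[1]]
    if (length(unique(seqs)) != 1L) next   # not a single repeated base
    b <- seqs[1]
    lo <- max(1L, pos - min_run - 1L)
    hi <- min(length(arm_seq), pos + min_run + 1L)
    win <- strsplit(as.character(Biostrings::subseq(arm_seq, lo, hi)), "")[[1]]
    r <- rle(win)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values == b & r$lengths >= min_run)
    # run (in window coords) must contain or abut window position of the call
    wpos <- pos - lo + 1L
    flags[i] <- any(starts[runs] <= wpos + 1L & ends[runs] >= wpos - 1L)
  }
  indel_calls$homopolymer_flag <- flags
  indel_calls
}
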