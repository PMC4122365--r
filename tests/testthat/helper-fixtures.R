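# fixture builders shared across test files

# one pool-table row; each pool is list(counts=c(A=,C=,G=,T=), depth=, del=c(fwd,rev),
# ins=c(fwd,rev), baseq=, bestq=); unspecified fields default to clean values
site_row <- function(arm = "2L", pos = 1L, ref = "A",
                     C1 = list(), H1 = list(), H2 = list()) {
  row <- data.frame(arm = arm, pos = as.integer(pos), ref = ref,
                    stringsAsFactors = FALSE)
  pools <- list(C1 = C1, H1 = H1, H2 = H2)
  for (p in names(pools)) {
    spec <- pools[[p]]
    counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
    if (!is.null(spec$counts)) counts[names(spec$counts)] <- spec$counts
    del <- if (is.null(spec$del)) c(0L, 0L) else spec$del
    ins <- if (is.null(spec$ins)) c(0L, 0L) else spec$ins
    depth <- if (is.null(spec$depth)) sum(counts) + sum(del) else spec$depth
    row[[paste0("depth_", p)]] <- as.integer(depth)
    for (b in c("A", "C", "G", "T")) row[[paste0(b, "_", p)]] <- counts[[b]]
    row[[paste0("del_", p)]] <- sum(del)
    row[[paste0("ins_", p)]] <- sum(ins)
    row[[paste0("del_fwd_", p)]] <- del[1]
    row[[paste0("del_rev_", p)]] <- del[2]
    row[[paste0("ins_fwd_", p)]] <- ins[1]
    row[[paste0("ins_rev_", p)]] <- ins[2]
    row[[paste0("baseq_", p)]] <- if (is.null(spec$baseq)) 35L else spec$baseq
    row[[paste0("bestq_", p)]] <- if (is.null(spec$bestq)) 50L else spec$bestq
  }
  row
}

make_table <- function(...) pool_site_table(do.call(rbind, list(...)))

# a random pool table (valid but arbitrary counts/qualities)
random_table <- function(n, arms = c("X", "2L")) {
  pos <- sort(sample.int(10 * n, n))
  rows <- lapply(seq_len(n), function(i) {
    mk <- function() {
      depth <- rpois(1, 12)
      counts <- as.vector(rmultinom(1, depth, c(0.4, 0.2, 0.2, 0.2)))
      names(counts) <- c("A", "C", "G", "T")
      list(counts = counts, depth = depth,
           baseq = sample(10:45, 1), bestq = sample(20:70, 1))
    }
    site_row(arm = sample(arms, 1), pos = pos[i],
             ref = sample(c("A", "C", "G", "T"), 1),
             C1 = mk(), H1 = mk(), H2 = mk())
  })
  # distinct (arm,pos): regenerate arms to avoid collisions
  df <- do.call(rbind, rows)
  df <- df[!duplicated(paste(df$arm, df$pos)), , drop = FALSE]
  pool_site_table(df)
}

# a tiny deterministic gene model set used by annotation tests:
# one + strand gene and its mirrored - strand twin on another arm
toy_models <- function() {
  genes <- data.frame(
    gene_id = c("gplus", "gminus"),
    arm = c("2L", "2R"),
    strand = c("+", "-"),
    start = c(10001L, 10001L), end = c(15000L, 15000L),
    stringsAsFactors = FALSE)
  # exon1 10001-11500 (UTR 10001-10800, CDS from 10801), intron, exon2
  exons <- data.frame(
    gene_id = c("gplus", "gplus", "gminus", "gminus"),
    start = c(10001L, 12001L, 10001L, 12001L),
    end = c(11500L, 15000L, 11500L, 15000L),
    stringsAsFactors = FALSE)
  cds <- data.frame(
    gene_id = c("gplus", "gplus", "gminus", "gminus"),
    start = c(10801L, 12001L, 10801L, 12001L),
    end = c(11500L, 13300L, 11500L, 13300L),   # 700 + 1300 = 2000... not %3
    stringsAsFactors = FALSE)
  # adjust so CDS totals are divisible by 3: 700 + 1301 = 2001
  cds$end[cds$gene_id == "gplus" & cds$start == 12001L] <- 13301L
  cds$end[cds$gene_id == "gminus" & cds$start == 12001L] <- 13301L
  structure(list(genes = genes, exons = exons, cds = cds,
                 arm_lengths = c("2L" = 30000L, "2R" = 30000L)),
            class = "gene_models")
}

# reference matching toy_models with clean ORFs patched in
toy_reference <- function(seed = 99) {
  withr::with_seed(seed, {
    ref <- Biostrings::DNAStringSet(c(
      "2L" = paste(sample(c("A", "C", "G", "T"), 30000, TRUE), collapse = ""),
      "2R" = paste(sample(c("A", "C", "G", "T"), 30000, TRUE), collapse = "")))
    poolscan:::.patch_orfs(ref, toy_models())
  })
}

# independent transcription of the published SNP criteria, used as the
# brute-force oracle against call_snps(); deliberately written from the
# criteria text, not from the implementation
snp_criteria_oracle <- function(ref, c1, h1, h2, fix = 0.9, rare = 0.1) {
  bases <- c("A", "C", "G", "T")
  modal <- function(v) {
    # majority base, tie toward the reference
    mx <- max(v)
    cand <- bases[v == mx]
    if (ref %in% cand) ref else cand[1]
  }
  freq <- function(v, b) if (sum(v) == 0) NA_real_ else v[[b]] / sum(v)
  c_base <- modal(c1)
  b1 <- modal(h1); b2 <- modal(h2)
  ok <- function(b, hv) {
    !is.na(freq(hv, b)) && b != ref && b != c_base &&
      freq(hv, b) >= fix &&
      !is.na(freq(c1, b)) && freq(c1, b) <= rare
  }
  ok(b1, h1) && ok(b2, h2)
}
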