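# evaluable mask, fixed-difference SNP/indel calling, reciprocal FDR,
# homopolymer flagging

test_that("the evaluable mask requires all thresholds in all three pools", {
  q <- function(d, bq, bsq) list(counts = c(A = d), baseq = bq, bestq = bsq)
  tab <- make_table(
    site_row(pos = 1, C1 = q(12, 25, 41), H1 = q(15, 30, 45), H2 = q(11, 22, 50)),
    site_row(pos = 2, C1 = q(9, 25, 41), H1 = q(15, 30, 45), H2 = q(11, 22, 50)),
    site_row(pos = 3, C1 = q(12, 19, 41), H1 = q(15, 30, 45), H2 = q(11, 22, 50)),
    site_row(pos = 4, C1 = q(12, 25, 39), H1 = q(15, 30, 45), H2 = q(11, 22, 50)))
  m <- evaluable_mask(tab)
  expect_identical(m$evaluable, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(m$by_arm$fraction, 0.25)
})

test_that("the mask equals an independent per-site recomputation", {
  withr::with_seed(30, tab <- random_table(10000))
  m <- evaluable_mask(tab)$evaluable
  redo <- vapply(seq_len(nrow(tab)), function(i) {
    all(vapply(c("C1", "H1", "H2"), function(p) {
      tab[[paste0("depth_", p)]][i] >= 10 &&
        tab[[paste0("baseq_", p)]][i] >= 20 &&
        tab[[paste0("bestq_", p)]][i] >= 40
    }, logical(1)))
  }, logical(1))
  expect_identical(m, redo)
})

test_that("a textbook fixed difference is called with the right frequencies", {
  # ref A; C1 A:28 T:2; H1 T:19 A:1; H2 T:10
  tab <- make_table(site_row(
    pos = 100, ref = "A",
    C1 = list(counts = c(A = 28, T = 2)),
    H1 = list(counts = c(T = 19, A = 1)),
    H2 = list(counts = c(T = 10))))
  calls <- call_snps(tab, evaluable_mask(tab))
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$h_allele, "T")
  expect_identical(calls$c_consensus, "A")
  expect_equal(calls$freq_H1, 0.95)
  expect_equal(calls$freq_H2, 1)
  expect_equal(calls$freq_C1, 2 / 30, tolerance = 1e-12)
  expect_true(calls$h_identity)

  # H1 at 17/20 = 0.85 is below the fixation threshold: no call
  tab2 <- make_table(site_row(
    pos = 100, ref = "A",
    C1 = list(counts = c(A = 28, T = 2)),
    H1 = list(counts = c(T = 17, A = 3)),
    H2 = list(counts = c(T = 10))))
  expect_identical(nrow(call_snps(tab2, evaluable_mask(tab2))), 0L)

  # masked sites are never called even if counts qualify
  m <- evaluable_mask(tab)
  m$evaluable[] <- FALSE
  expect_identical(nrow(call_snps(tab, m)), 0L)
})

test_that("caller matches the criteria oracle on sampled count configurations", {
  # random three-pool two-allele configurations at depth 10..12 per pool
  withr::with_seed(31, {
    n <- 4000
    d <- matrix(sample(10:12, 3 * n, TRUE), n, 3)
    alt <- matrix(0L, n, 3)
    for (j in 1:3) alt[, j] <- vapply(d[, j], function(x) sample(0:x, 1), 1L)
  })
  rows <- lapply(seq_len(n), function(i) {
    site_row(pos = i, ref = "A",
             C1 = list(counts = c(A = d[i, 1] - alt[i, 1], T = alt[i, 1])),
             H1 = list(counts = c(A = d[i, 2] - alt[i, 2], T = alt[i, 2])),
             H2 = list(counts = c(A = d[i, 3] - alt[i, 3], T = alt[i, 3])))
  })
  tab <- pool_site_table(do.call(rbind, rows))
  calls <- call_snps(tab, evaluable_mask(tab))
  called <- tab$pos %in% calls$pos
  want <- vapply(seq_len(nrow(tab)), function(i) {
    cnt <- function(p) setNames(c(tab[[paste0("A_", p)]][i], tab[[paste0("C_", p)]][i],
                                  tab[[paste0("G_", p)]][i], tab[[paste0("T_", p)]][i]),
                                c("A", "C", "G", "T"))
    snp_criteria_oracle("A", cnt("C1"), cnt("H1"), cnt("H2"))
  }, logical(1))
  expect_identical(called, want)
})

test_that("tri-allelic discordant sites respect the identity switch", {
  # H1 fixes T, H2 fixes G, both absent from C1
  tab <- make_table(site_row(
    pos = 5, ref = "A",
    C1 = list(counts = c(A = 20)),
    H1 = list(counts = c(T = 19, A = 1)),
    H2 = list(counts = c(G = 18))))
  loose <- call_snps(tab, evaluable_mask(tab), caller_config())
  expect_identical(nrow(loose), 1L)
  expect_false(loose$h_identity)
  expect_identical(loose$h_allele, "T")
  expect_identical(loose$h_allele_H2, "G")
  strict <- call_snps(tab, evaluable_mask(tab),
                      caller_config(require_h_identity = TRUE))
  expect_identical(nrow(strict), 0L)
})

test_that("indel calls follow the strand-support typing rules", {
  mk <- function(del_c1, del_h1, del_h2, depth = 12) {
    site_row(pos = 50, ref = "A",
             C1 = list(counts = c(A = depth - sum(del_c1)), del = del_c1),
             H1 = list(counts = c(A = depth - sum(del_h1)), del = del_h1),
             H2 = list(counts = c(A = depth - sum(del_h2)), del = del_h2))
  }
  # both strands in both H pools: type "*"
  tab <- make_table(mk(c(0, 0), c(6, 5), c(6, 6)))
  calls <- call_indels(tab, evaluable_mask(tab))
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$maq_type, "*")
  expect_identical(calls$sign, "del")
  expect_gte(calls$support_H1, 0.9)

  # same-strand support >= 2: type "+"
  tab2 <- make_table(mk(c(0, 0), c(11, 0), c(12, 0)))
  calls2 <- call_indels(tab2, evaluable_mask(tab2))
  expect_identical(calls2$maq_type, "+")

  # a single supporting read on one strand types neither "*" nor "+"
  tab3 <- make_table(site_row(
    pos = 50, ref = "A",
    C1 = list(counts = c(A = 12)),
    H1 = list(counts = c(A = 1), del = c(11, 0)),
    H2 = list(counts = c(A = 11), del = c(1, 0))))
  expect_identical(nrow(call_indels(tab3, evaluable_mask(tab3))), 0L)

  # depth below 10 in an H pool fails the explicit coverage criterion even
  # when the mask itself is looser
  tab4 <- make_table(site_row(
    pos = 50, ref = "A",
    C1 = list(counts = c(A = 12)),
    H1 = list(counts = c(A = 0), del = c(5, 4)),
    H2 = list(counts = c(A = 0), del = c(6, 6))))
  expect_identical(tab4$depth_H1, 9L)
  loose_mask <- evaluable_mask(tab4, quality_thresholds(min_depth = 5))
  expect_true(loose_mask$evaluable)
  expect_identical(nrow(call_indels(tab4, loose_mask,
                                    thresholds = quality_thresholds())), 0L)

  # support below 90% of reads fails
  tab5 <- make_table(mk(c(0, 0), c(5, 5), c(6, 6)))  # H1 10/12 = 0.83
  expect_identical(nrow(call_indels(tab5, evaluable_mask(tab5))), 0L)
})

test_that("control absence for indels is a configurable read-count bound", {
  mk <- function(c1_del) {
    make_table(site_row(
      pos = 7, ref = "G",
      C1 = list(counts = c(G = 12 - sum(c1_del)), del = c1_del),
      H1 = list(counts = c(G = 1), del = c(6, 5)),
      H2 = list(counts = c(G = 0), del = c(6, 6))))
  }
  with1 <- mk(c(1, 0))
  expect_identical(nrow(call_indels(with1, evaluable_mask(with1))), 0L)
  relaxed <- caller_config(control_absence_max_reads = 1)
  expect_identical(nrow(call_indels(with1, evaluable_mask(with1), relaxed)), 1L)
  clean <- mk(c(0, 0))
  expect_identical(nrow(call_indels(clean, evaluable_mask(clean))), 1L)
})

test_that("the FDR worked example reproduces the published arithmetic", {
  # one reciprocal locus among 2514 called SNPs
  tab <- make_table(site_row(
    pos = 9, ref = "A",
    C1 = list(counts = c(A = 20)),
    H1 = list(counts = c(T = 19, A = 1)),   # T fixed in H1
    H2 = list(counts = c(A = 19, T = 1))))  # T rare in H2
  fdr <- estimate_fdr_reciprocal(tab, evaluable_mask(tab), caller_config(),
                                 called_snps = 2514L)
  expect_identical(fdr$reciprocal_false_loci, 1L)
  expect_equal(fdr$fdr, 1 / 2514)
  expect_equal(signif(fdr$fdr, 2), 4.0e-4)

  # zero reciprocal loci: FDR 0
  tab0 <- make_table(site_row(
    pos = 9, ref = "A", C1 = list(counts = c(A = 20)),
    H1 = list(counts = c(T = 19, A = 1)),
    H2 = list(counts = c(T = 18))))
  fdr0 <- estimate_fdr_reciprocal(tab0, evaluable_mask(tab0), caller_config(),
                                  called_snps = 10L)
  expect_identical(fdr0$reciprocal_false_loci, 0L)
  expect_identical(fdr0$fdr, 0)

  # reciprocal loci with a zero denominator is undefined
  expect_error(estimate_fdr_reciprocal(tab, evaluable_mask(tab),
                                       caller_config(), called_snps = 0L),
               "undefined FDR")
})

test_that("a reciprocal locus is counted once even when both directions fire", {
  # H1 fixes T (rare in H2) and H2 fixes G (rare in H1) at one site
  tab <- make_table(site_row(
    pos = 3, ref = "A",
    C1 = list(counts = c(A = 20)),
    H1 = list(counts = c(T = 19, G = 1)),
    H2 = list(counts = c(G = 19, T = 1))))
  fdr <- estimate_fdr_reciprocal(tab, evaluable_mask(tab), caller_config(),
                                 called_snps = 100L)
  expect_identical(fdr$reciprocal_false_loci, 1L)
})

test_that("homopolymer flags match a run-length oracle on random contexts", {
  withr::with_seed(32, {
    arm_seq <- paste(sample(c("A", "C", "G", "T"), 20000, TRUE,
                            prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
  })
  ref <- Biostrings::DNAStringSet(c("2L" = arm_seq))
  withr::with_seed(33, pos <- sort(sample(10:19990, 2000)))
  chars <- strsplit(arm_seq, "")[[1]]
  calls <- structure(data.frame(
    arm = "2L", pos = pos, ref = chars[pos], indel_seq = chars[pos],
    sign = "del", maq_type = "*", support_H1 = 1, support_H2 = 1,
    control_support_reads = 0L, homopolymer_flag = NA,
    stringsAsFactors = FALSE), class = c("indel_calls", "data.frame"))
  flagged <- flag_homopolymer(calls, ref, min_run = 5)
  # oracle: locate runs >= 5 with a regex, flag positions touching them
  oracle <- vapply(seq_along(pos), function(i) {
    b <- chars[pos[i]]
    runs <- gregexpr(paste0(b, "{5,}"), arm_seq)[[1]]
    if (runs[1] == -1) return(FALSE)
    ends <- runs + attr(runs, "match.length") - 1
    any(runs <= pos[i] + 1 & ends >= pos[i] - 1)
  }, logical(1))
  expect_identical(flagged$homopolymer_flag, oracle)
  expect_gt(sum(oracle), 0)

  # boundary examples: run of 6 flags, run of 2 does not
  ref2 <- Biostrings::DNAStringSet(c("2L" = "GGCAAAAAACGGTTAACG"))
  two <- structure(data.frame(
    arm = "2L", pos = c(4L, 15L), ref = c("A", "A"),
    indel_seq = c("A", "A"), sign = "del", maq_type = "*",
    support_H1 = 1, support_H2 = 1, control_support_reads = 0L,
    homopolymer_flag = NA, stringsAsFactors = FALSE),
    class = c("indel_calls", "data.frame"))
  out <- flag_homopolymer(two, ref2, min_run = 5)
  expect_identical(out$homopolymer_flag, c(TRUE, FALSE))
  bad <- two
  bad$pos[1] <- 1000L
  expect_error(flag_homopolymer(bad, ref2), "outside reference")
})

test_that("identical table and config produce byte-identical call files", {
  withr::with_seed(34, {
    cfg <- sim_config(genome_length = 3e4, n_arms = 1, pop_size = 200,
                      generations = 60, pool_males = 50, pool_females = 50,
                      selection_targets = data.frame(s = rep(0.3, 4)))
    sim <- simulate_experiment(cfg, seq_config(mean_depth = 20),
                               polymorphic_site_density = 3)
  })
  mask <- evaluable_mask(sim$table)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_calls(call_snps(sim$table, mask), f1)
  write_calls(call_snps(sim$table, mask), f2)
  expect_identical(readLines(f1), readLines(f2))
})
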