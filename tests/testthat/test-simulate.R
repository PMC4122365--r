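# synthetic-data generator: founder panel, Wright-Fisher dynamics, pool
# sampling, sequencing emulation

test_that("founder panel handles empty, counting, and determinism cases", {
  cfg <- sim_config(genome_length = 10000, n_arms = 1, pop_size = 100,
                    generations = 0, pool_males = 10, pool_females = 10)
  # density 0: no polymorphic sites, reference still produced
  withr::with_seed(1, p0 <- generate_founders(cfg, 0))
  expect_identical(nrow(p0$sites), 0L)
  expect_identical(names(p0$reference), "X")
  expect_identical(Biostrings::width(p0$reference), 10000L)

  # a site carried by k founders starts at p0 = k / 27
  withr::with_seed(2, pan <- generate_founders(cfg, 5))
  expect_identical(nrow(pan$sites), 50L)
  expect_equal(pan$sites$p0, pan$sites$k_founders / 27)
  expect_equal(unname(colSums(pan$haplotypes)), pan$sites$k_founders)
  one <- pan$sites$k_founders == 1
  expect_equal(pan$sites$p0[one], rep(1 / 27, sum(one)))
  # every site keeps at least one reference-carrying founder
  expect_true(all(pan$sites$k_founders < cfg$n_founders))
  # positions strictly increasing within the arm
  expect_true(all(diff(pan$sites$pos) > 0))

  # identical seed, identical panel
  withr::with_seed(2, pan2 <- generate_founders(cfg, 5))
  expect_identical(pan, pan2)

  expect_error(sim_config(genome_length = 0), "empty genome")
  expect_error(sim_config(pop_size = 100, pool_males = 80, pool_females = 80),
               "pool size")
  expect_error(sim_config(selection_targets = data.frame(s = -1.5)), "> -1")
})

test_that("zero generations leave frequencies exactly at p0", {
  cfg <- sim_config(genome_length = 20000, n_arms = 1, pop_size = 50,
                    generations = 0, pool_males = 10, pool_females = 10)
  withr::with_seed(3, {
    pan <- generate_founders(cfg, 2)
    evo <- evolve_replicates(pan, cfg)
  })
  for (p in c("C1", "H1", "H2"))
    expect_identical(unname(evo$freq[, p]), pan$sites$p0)
})

test_that("neutral drift conserves the mean allele frequency", {
  # 1000 independent neutral sites all starting at p0 = 0.25 stand in for
  # 1000 replicate runs (sites evolve independently)
  cfg <- sim_config(genome_length = 1e5, n_arms = 1, pop_size = 100,
                    generations = 40, pool_males = 10, pool_females = 10)
  withr::with_seed(4, {
    pan <- generate_founders(cfg, 10, indel_fraction = 0)
    pan$sites$p0 <- 0.25
    evo <- evolve_replicates(pan, cfg)
  })
  p_final <- evo$freq[, "C1"]
  se <- sd(p_final) / sqrt(length(p_final))
  expect_lt(abs(mean(p_final) - 0.25), 3 * se)
})

test_that("selection follows the deterministic recursion in large populations", {
  recursion <- function(p, s, g) {
    for (i in seq_len(g)) p <- p * (1 + s) / (1 + p * s)
    p
  }
  cfg <- sim_config(genome_length = 10000, n_arms = 1, pop_size = 10000,
                    generations = 100,
                    selection_targets = data.frame(s = rep(0.2, 10)))
  withr::with_seed(5, {
    pan <- generate_founders(cfg, 1, indel_fraction = 0)
    pan$sites$p0[pan$sites$selected] <- 0.05
    evo <- evolve_replicates(pan, cfg)
  })
  want <- recursion(0.05, 0.2, 100)
  got <- evo$freq[pan$sites$selected, c("H1", "H2")]
  expect_true(all(abs(got - want) < 0.02))
  # control stays neutral: no systematic push toward fixation
  ctrl <- evo$freq[pan$sites$selected, "C1"]
  expect_true(all(abs(ctrl - 0.05) < 0.05))
})

test_that("expected heterozygosity decays by 1 - 1/(2N) per generation", {
  cfg <- sim_config(genome_length = 1e5, n_arms = 1, pop_size = 25,
                    generations = 30, pool_males = 5, pool_females = 5)
  withr::with_seed(6, {
    pan <- generate_founders(cfg, 20, indel_fraction = 0)
    pan$sites$p0 <- 0.5
    evo <- evolve_replicates(pan, cfg)
  })
  p <- evo$freq[, "C1"]
  het <- 2 * p * (1 - p)
  want <- 2 * 0.5 * 0.5 * (1 - 1 / (2 * 25))^30
  se <- sd(het) / sqrt(length(het))
  expect_lt(abs(mean(het) - want), 3 * se)
})

test_that("neutral fixation probability approximates p0", {
  cfg <- sim_config(genome_length = 1e5, n_arms = 1, pop_size = 20,
                    generations = 400, pool_males = 5, pool_females = 5)
  withr::with_seed(7, {
    pan <- generate_founders(cfg, 10, indel_fraction = 0)
    pan$sites$p0 <- 0.2
    evo <- evolve_replicates(pan, cfg)
  })
  p <- evo$freq[, "H1"]
  absorbed <- p %in% c(0, 1)
  expect_gt(mean(absorbed), 0.99)   # 400 generations at 2N=40 absorbs
  fix <- mean(p == 1)
  se <- sqrt(0.2 * 0.8 / length(p))
  expect_lt(abs(fix - 0.2), 3 * se)
})

test_that("the three populations are exchangeable under neutrality", {
  cfg <- sim_config(genome_length = 1e5, n_arms = 1, pop_size = 100,
                    generations = 50, pool_males = 10, pool_females = 10)
  withr::with_seed(8, {
    pan <- generate_founders(cfg, 10, indel_fraction = 0)
    evo <- evolve_replicates(pan, cfg)
  })
  ks <- suppressWarnings(stats::ks.test(evo$freq[, "H1"], evo$freq[, "C1"]))
  expect_gt(ks$p.value, 0.01)
  ks2 <- suppressWarnings(stats::ks.test(evo$freq[, "H2"], evo$freq[, "H1"]))
  expect_gt(ks2$p.value, 0.01)
})

test_that("expected-callable flags match a direct re-evaluation of the definition", {
  cfg <- sim_config(genome_length = 1e5, n_arms = 2, pop_size = 50,
                    generations = 100, pool_males = 10, pool_females = 10,
                    selection_targets = data.frame(s = rep(0.3, 5)))
  withr::with_seed(9, {
    pan <- generate_founders(cfg, 3)
    evo <- evolve_replicates(pan, cfg, fix_threshold = 0.9,
                             rare_threshold = 0.1)
  })
  tr <- evo$truth
  redo <- ifelse(tr$site_type == "snp",
                 tr$freq_H1 >= 0.9 & tr$freq_H2 >= 0.9 & tr$freq_C1 <= 0.1,
                 tr$freq_H1 >= 0.9 & tr$freq_H2 >= 0.9 & tr$freq_C1 == 0)
  expect_identical(tr$expected_callable, redo)
  expect_true(all(tr$selected == (tr$s > 0)))
  expect_error(evolve_replicates(local({p <- pan; p$sites$s[1] <- Inf; p}), cfg),
               "non-finite")
})

test_that("pool sampling draws the right chromosome copy numbers", {
  cfg <- sim_config(genome_length = 1000, n_arms = 1, pop_size = 500,
                    generations = 0, pool_males = 100, pool_females = 100)
  # X arm: 2*100 + 100 = 300 copies; autosome: 400
  sx <- sample_pool(c(0.5, 1), cfg, arm_is_X = TRUE)
  sa <- sample_pool(c(0.5, 1), cfg, arm_is_X = FALSE)
  expect_identical(unique(sx$copies), 300L)
  expect_identical(unique(sa$copies), 400L)
  # a fixed site stays fixed under any sampling
  expect_identical(sx$freq[2], 1)
  expect_identical(sa$freq[2], 1)
  small <- cfg
  small$pop_size <- 150L   # sneak past the constructor to hit the guard
  expect_error(sample_pool(0.5, small), "exceeds")
})

test_that("sequencing without error reproduces a fixed pool exactly", {
  sites <- data.frame(arm = "2L", pos = c(10L, 20L), ref = c("A", "G"),
                      alt = c("T", "C"), site_type = "snp",
                      stringsAsFactors = FALSE)
  scfg <- seq_config(mean_depth = 20, base_error = 0)
  withr::with_seed(10, {
    tab <- sequence_pool(matrix(1, 2, 3, dimnames = list(NULL, c("C1", "H1", "H2"))),
                         sites, scfg)
  })
  # pool fixed for the alternate: all base reads carry it
  expect_identical(tab$T_H1[tab$pos == 10], tab$depth_H1[tab$pos == 10])
  expect_identical(tab$A_H1[tab$pos == 10], 0L)
  expect_identical(tab$C_C1[tab$pos == 20], tab$depth_C1[tab$pos == 20])
})

test_that("sequencing depth and allele fractions match their sampling models", {
  n <- 10000
  sites <- data.frame(arm = "2L", pos = seq_len(n), ref = "A", alt = "T",
                      site_type = "snp", stringsAsFactors = FALSE)
  pf <- matrix(0.5, n, 3, dimnames = list(NULL, c("C1", "H1", "H2")))
  withr::with_seed(11, {
    tab <- sequence_pool(pf, sites, seq_config(mean_depth = 15, base_error = 0))
  })
  # depth ~ Poisson(15)
  se_d <- sd(tab$depth_H1) / sqrt(n)
  expect_lt(abs(mean(tab$depth_H1) - 15), 3 * se_d)
  # alternate fraction ~ Binomial(depth, 0.5)
  frac <- tab$T_H1 / pmax(tab$depth_H1, 1)
  se_f <- sd(frac) / sqrt(n)
  expect_lt(abs(mean(frac[tab$depth_H1 > 0]) - 0.5), 3 * se_f)
})

test_that("base-calling errors scatter uniformly over the other bases", {
  n <- 30000
  sites <- data.frame(arm = "2L", pos = seq_len(n), ref = "A", alt = "T",
                      site_type = "snp", stringsAsFactors = FALSE)
  pf <- matrix(0, n, 3, dimnames = list(NULL, c("C1", "H1", "H2")))
  withr::with_seed(12, {
    tab <- sequence_pool(pf, sites, seq_config(mean_depth = 10, base_error = 0.1))
  })
  err <- colSums(cbind(tab$C_H1, tab$G_H1, tab$T_H1))
  total_err <- sum(err)
  expect_gt(total_err, 0)
  chisq <- sum((err - total_err / 3)^2 / (total_err / 3))
  expect_lt(chisq, qchisq(0.999, df = 2))
  # overall error rate close to 0.1
  expect_lt(abs(total_err / sum(tab$depth_H1) - 0.1), 0.01)
})

test_that("indel reads are strand-split and excluded from deletion base counts", {
  n <- 2000
  sites <- data.frame(arm = "2L", pos = seq_len(n), ref = "A", alt = "A",
                      site_type = rep(c("del", "ins"), n / 2),
                      stringsAsFactors = FALSE)
  pf <- matrix(0.5, n, 3, dimnames = list(NULL, c("C1", "H1", "H2")))
  withr::with_seed(13, {
    tab <- sequence_pool(pf, sites, seq_config(mean_depth = 20, base_error = 0))
  })
  del <- sites$site_type == "del"
  base_sum <- tab$A_H1 + tab$C_H1 + tab$G_H1 + tab$T_H1
  expect_identical(base_sum[del] + tab$del_H1[del], tab$depth_H1[del])
  expect_identical(base_sum[!del], tab$depth_H1[!del])
  expect_identical(tab$del_fwd_H1 + tab$del_rev_H1, tab$del_H1)
  # both strands represented overall
  expect_gt(sum(tab$del_fwd_H1), 0)
  expect_gt(sum(tab$del_rev_H1), 0)
})

test_that("the full simulated experiment is reproducible under a fixed seed", {
  cfg <- sim_config(genome_length = 2e4, n_arms = 2, pop_size = 100,
                    generations = 30, pool_males = 20, pool_females = 20,
                    selection_targets = data.frame(s = rep(0.2, 3)))
  s1 <- simulate_experiment(cfg, seq_config(), polymorphic_site_density = 2,
                            seed = 14)
  s2 <- simulate_experiment(cfg, seq_config(), polymorphic_site_density = 2,
                            seed = 14)
  expect_identical(s1$table, s2$table)
  expect_identical(s1$truth, s2$truth)
  # selected sites start from a single carrier founder
  expect_true(all(s1$panel$sites$k_founders[s1$panel$sites$selected] == 1L))
})
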