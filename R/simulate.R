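#' Simulation design configuration
#'
#' Describes the evolve-and-resequence design being emulated: a panel of
#' isogenic founder lines seeds one control and two replicate selected
#' populations, which evolve independently for a number of generations; a
#' sex-balanced pool of adults is then drawn from each population for
#' sequencing. Defaults follow the emulated study design: 27 founder lines,
#' 180 generations of selection, pools of 100 males and 100 females.
#'
#' @param n_founders number of isogenic founder lines.
#' @param genome_length bases per chromosome arm.
#' @param n_arms number of chromosome arms; arms are named `X, 2L, 2R, 3L, 3R,
#'   ...` in that order, so the first arm is hemizygous in males.
#' @param pop_size diploid individuals per population (effective size of each
#'   selection chamber; the study does not report one, so it is a free
#'   parameter).
#' @param generations generations of evolution.
#' @param selection_targets `NULL` for a fully neutral simulation, or a
#'   data.frame with column `s` (per-generation selection coefficient of the
#'   derived allele, `s > -1`) and optionally `arm`/`pos`; rows without
#'   coordinates are planted at random loci by [generate_founders()].
#' @param pool_males,pool_females adults of each sex in the sequencing pool.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_founders = 27L, genome_length = 1e5, n_arms = 2L,
                       pop_size = 500L, generations = 180L,
                       selection_targets = NULL,
                       pool_males = 100L, pool_females = 100L) {
  if (genome_length < 1) stop("empty genome")
  if (n_founders < 2) stop("need at least 2 founder lines")
  if (pop_size < 2) stop("pop_size must be >= 2")
  if (generations < 0) stop("generations must be >= 0")
  if (pool_males + pool_females > pop_size)
    stop("pool size exceeds population size")
  if (!is.null(selection_targets)) {
    if (!is.data.frame(selection_targets) || !"s" %in% names(selection_targets))
      stop("selection_targets must be a data.frame with column 's'")
    if (any(!is.finite(selection_targets$s)))
      stop("non-finite selection coefficient")
    if (any(selection_targets$s <= -1))
      stop("selection coefficient must be > -1")
  }
  structure(list(n_founders = as.integer(n_founders),
                 genome_length = as.integer(genome_length),
                 n_arms = as.integer(n_arms),
                 pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 selection_targets = selection_targets,
                 pool_males = as.integer(pool_males),
                 pool_females = as.integer(pool_females)),
            class = "sim_config")
}

#' Sequencing-emulation configuration
#'
#' Per-site pooled short-read sequencing is emulated with Poisson depth,
#' symmetric per-read base-calling error, and alignment-style quality fields:
#' a consensus base quality and a best-read mapping quality per site per pool,
#' drawn from clamped-and-rounded normal distributions. The quality defaults
#' (base quality ~ N(35, 5), best read quality ~ N(50, 10)) produce realistic
#' mixtures of passing and failing sites around the 20/40 masking thresholds.
#'
#' @param mean_depth Poisson mean read depth per site per pool.
#' @param base_error per-read probability that the reported base is flipped to
#'   a uniformly chosen other base; must be in `[0, 0.5)`.
#' @param baseq_mean,baseq_sd,bestq_mean,bestq_sd emission parameters.
#' @return A `seq_config` list.
#' @export
seq_config <- function(mean_depth = 15, base_error = 0.005,
                       baseq_mean = 35, baseq_sd = 5,
                       bestq_mean = 50, bestq_sd = 10) {
  if (mean_depth <= 0) stop("mean_depth must be positive")
  if (base_error < 0 || base_error >= 0.5) stop("base_error must be in [0, 0.5)")
  if (baseq_sd < 0 || bestq_sd < 0) stop("quality sd must be >= 0")
  structure(list(mean_depth = mean_depth, base_error = base_error,
                 baseq_mean = baseq_mean, baseq_sd = baseq_sd,
                 bestq_mean = bestq_mean, bestq_sd = bestq_sd),
            class = "seq_config")
}

.arm_names <- function(n) {
  base <- c("X", "2L", "2R", "3L", "3R")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, paste0("arm", seq_len(n - length(base))))
}

.random_reference <- function(arms, genome_length) {
  seqs <- vapply(arms, function(a) {
    paste(sample(.BASES, genome_length, replace = TRUE), collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(setNames(seqs, arms))
}

#' Generate a founder panel of isogenic lines
#'
#' Polymorphic sites are scattered uniformly over the genome at the requested
#' density. Each neutral site carries its derived (minor) allele in `k`
#' founder lines with `k` uniform on 1..13, spanning the frequency spectrum
#' attainable with 27 isogenic lines; the founder-pool starting frequency is
#' `p0 = k / n_founders`. Sites named in `selection_targets` carry the derived
#' allele in a single founder line (`p0 = 1/n_founders`): the fixed-vs-rare
#' contrast between selected and control populations that the scan looks for
#' only arises for adaptive variants that start rare, since a mid-frequency
#' variant stays at mid frequency in the unselected control.
#'
#' A configurable fraction of sites are single-base indels: a duplication or
#' deletion of the reference base at the site, so the event sequence is always
#' derivable from the reference.
#'
#' @param cfg a [sim_config()].
#' @param polymorphic_site_density polymorphic sites per kb (may be 0).
#' @param reference optional `DNAStringSet` of arm sequences; generated
#'   randomly when `NULL`.
#' @param indel_fraction fraction of polymorphic sites that are indels
#'   (split evenly between insertions and deletions).
#' @return A `founder_panel`: list with `sites` (data.frame `arm, pos, ref,
#'   alt, site_type, k_founders, p0, s, selected`), `haplotypes` (founders x
#'   sites 0/1 derived-allele matrix) and `reference`.
#' @export
generate_founders <- function(cfg, polymorphic_site_density,
                              reference = NULL, indel_fraction = 0.05) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$genome_length < 1) stop("empty genome")
  if (polymorphic_site_density < 0) stop("density must be >= 0")
  arms <- .arm_names(cfg$n_arms)
  if (is.null(reference)) {
    reference <- .random_reference(arms, cfg$genome_length)
  } else {
    stopifnot(all(arms %in% names(reference)))
    reference <- reference[arms]
  }
  n_per_arm <- round(polymorphic_site_density * cfg$genome_length / 1000)
  sites_list <- lapply(arms, function(a) {
    if (n_per_arm == 0) return(NULL)
    pos <- sort(sample.int(cfg$genome_length, n_per_arm))
    data.frame(arm = a, pos = pos, stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, sites_list)
  if (is.null(sites) || nrow(sites) == 0) {
    sites <- data.frame(arm = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        site_type = character(0), k_founders = integer(0),
                        p0 = numeric(0), s = numeric(0), selected = logical(0),
                        stringsAsFactors = FALSE)
    return(structure(list(sites = sites,
                          haplotypes = matrix(0L, cfg$n_founders, 0),
                          reference = reference),
                     class = "founder_panel"))
  }
  n <- nrow(sites)
  ref_base <- vapply(seq_len(n), function(i) {
    as.character(Biostrings::subseq(reference[[sites$arm[i]]],
                                    sites$pos[i], sites$pos[i]))
  }, character(1))
  sites$ref <- ref_base
  is_indel <- runif(n) < indel_fraction
  ind_sign <- ifelse(runif(n) < 0.5, "ins", "del")
  sites$site_type <- ifelse(is_indel, ind_sign, "snp")
  sites$alt <- ifelse(is_indel, sites$ref,
                      vapply(sites$ref, function(b)
                        sample(setdiff(.BASES, b), 1), character(1)))
  k_max <- min(13L, cfg$n_founders - 1L)
  sites$k_founders <- sample.int(k_max, n, replace = TRUE)
  sites$s <- 0
  sites$selected <- FALSE
  tg <- cfg$selection_targets
  if (!is.null(tg) && nrow(tg) > 0) {
    if (nrow(tg) > n) stop("more selection targets than polymorphic sites")
    has_coord <- all(c("arm", "pos") %in% names(tg)) &&
      !anyNA(tg$arm) && !anyNA(tg$pos)
    if (has_coord) {
      idx <- match(paste(tg$arm, tg$pos), paste(sites$arm, sites$pos))
      if (anyNA(idx)) stop("selection target at a non-polymorphic locus")
    } else {
      idx <- sample.int(n, nrow(tg))
    }
    sites$s[idx] <- tg$s
    sites$selected[idx] <- TRUE
    sites$k_founders[idx] <- 1L   # adaptive variants start rare
  }
  sites$p0 <- sites$k_founders / cfg$n_founders
  hap <- matrix(0L, cfg$n_founders, n)
  for (i in seq_len(n))
    hap[sample.int(cfg$n_founders, sites$k_founders[i]), i] <- 1L
  rownames(sites) <- NULL
  structure(list(sites = sites, haplotypes = hap, reference = reference),
            class = "founder_panel")
}

#' Evolve the three replicate populations by Wright-Fisher sampling
#'
#' Each population starts at the founder-pool frequencies `p0` and evolves
#' independently for `generations` generations. Sites segregate independently
#' (free recombination). Per generation, the expected derived-allele frequency
#' under selection is `p' = p (1 + s) / (1 + p s)` and the next generation is
#' formed by binomial sampling of `2 * pop_size` gametes. The control
#' population has `s = 0` everywhere; the two selected replicates share the
#' panel's selection coefficients.
#'
#' @param panel a `founder_panel`.
#' @param cfg the [sim_config()] used to build it.
#' @param fix_threshold,rare_threshold thresholds used for the truth table's
#'   `expected_callable` flag (the fixed-difference definition applied to the
#'   true final frequencies).
#' @param keep_trajectories if `TRUE`, also return the full
#'   `generations x sites` frequency paths per population.
#' @return list with `freq` (sites x 3 matrix of final derived-allele
#'   frequencies, columns C1/H1/H2), `truth` (truth table data.frame) and
#'   optionally `trajectories`.
#' @export
evolve_replicates <- function(panel, cfg,
                              fix_threshold = 0.9, rare_threshold = 0.1,
                              keep_trajectories = FALSE) {
  stopifnot(inherits(panel, "founder_panel"), inherits(cfg, "sim_config"))
  if (cfg$pop_size < 2) stop("pop_size must be >= 2")
  s_sel <- panel$sites$s
  if (any(!is.finite(s_sel))) stop("non-finite selection coefficient")
  n <- nrow(panel$sites)
  two_n <- 2L * cfg$pop_size
  pops <- .POOLS
  freq <- matrix(NA_real_, n, 3, dimnames = list(NULL, pops))
  traj <- if (keep_trajectories)
    setNames(vector("list", 3), pops) else NULL
  for (j in seq_along(pops)) {
    s <- if (pops[j] == "C1") rep(0, n) else s_sel
    p <- panel$sites$p0
    if (keep_trajectories)
      traj[[j]] <- matrix(NA_real_, cfg$generations, n)
    if (cfg$generations > 0) {
      for (g in seq_len(cfg$generations)) {
        p_exp <- p * (1 + s) / (1 + p * s)
        p <- rbinom(n, two_n, p_exp) / two_n
        if (keep_trajectories) traj[[j]][g, ] <- p
      }
    }
    freq[, j] <- p
  }
  truth <- cbind(panel$sites[, c("arm", "pos", "ref", "alt", "site_type",
                                 "k_founders", "p0", "s", "selected")],
                 data.frame(freq_C1 = freq[, "C1"], freq_H1 = freq[, "H1"],
                            freq_H2 = freq[, "H2"]))
  # each variant type's own control criterion: SNPs may be rare in the
  # control, indels must be absent from it
  control_ok <- ifelse(truth$site_type == "snp",
                       truth$freq_C1 <= rare_threshold,
                       truth$freq_C1 == 0)
  truth$expected_callable <- truth$freq_H1 >= fix_threshold &
    truth$freq_H2 >= fix_threshold & control_ok
  rownames(truth) <- NULL
  out <- list(freq = freq, truth = truth)
  if (keep_trajectories) out$trajectories <- traj
  out
}

#' Draw a sex-balanced sequencing pool from a population
#'
#' Individuals are sampled without replacement, so pooled allele counts are
#' hypergeometric draws from the population's `2 * pop_size` chromosome
#' copies. Autosomal arms contribute 2 copies per pooled individual; on the X
#' males are hemizygous, so the pool carries `2 * females + males` copies.
#'
#' @param freqs vector of population derived-allele frequencies (multiples of
#'   `1 / (2 pop_size)`, as produced by [evolve_replicates()]).
#' @param cfg the [sim_config()].
#' @param arm_is_X logical (recycled): whether each site lies on the X arm.
#' @return list with `freq` (pooled frequencies) and `copies` (chromosome
#'   copies sampled per site).
#' @export
sample_pool <- function(freqs, cfg, arm_is_X = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$pool_males + cfg$pool_females > cfg$pop_size)
    stop("pool size exceeds population size")
  n <- length(freqs)
  arm_is_X <- rep_len(arm_is_X, n)
  two_n <- 2L * cfg$pop_size
  k_alt <- as.integer(round(freqs * two_n))
  copies <- ifelse(arm_is_X,
                   2L * cfg$pool_females + cfg$pool_males,
                   2L * (cfg$pool_males + cfg$pool_females))
  drawn <- rhyper(n, m = k_alt, n = two_n - k_alt, k = copies)
  list(freq = drawn / copies, copies = copies)
}

# distribute n_flips error reads of each site uniformly over the 3 non-`from`
# bases; `counts` is a sites x 4 matrix (A,C,G,T)
.scatter_errors <- function(counts, from_base, n_flips) {
  idx <- which(n_flips > 0)
  for (i in idx) {
    others <- setdiff(.BASES, from_base[i])
    add <- as.vector(rmultinom(1, n_flips[i], rep(1 / 3, 3)))
    counts[i, others] <- counts[i, others] + add
  }
  counts
}

#' Emulate pooled short-read sequencing of the three pools
#'
#' Per site and pool: read depth is Poisson; each read samples its allele from
#' the pooled frequencies; base-calling error flips a read's reported base to
#' a uniformly chosen other base with probability `base_error`. Reads carrying
#' a deletion report no base (base counts sum to depth minus deletion
#' support); insertion-carrying reads report the reference base. Indel
#' support is split between strands by fair coin. Quality fields are emitted
#' per site and pool from the configured distributions.
#'
#' @param pool_freq sites x 3 matrix of pooled derived-allele frequencies
#'   (columns C1, H1, H2).
#' @param sites the `sites` data.frame of a `founder_panel`.
#' @param scfg a [seq_config()].
#' @return A [pool_site_table()].
#' @export
sequence_pool <- function(pool_freq, sites, scfg) {
  stopifnot(inherits(scfg, "seq_config"))
  n <- nrow(sites)
  stopifnot(nrow(pool_freq) == n)
  out <- sites[, c("arm", "pos", "ref")]
  is_snp <- sites$site_type == "snp"
  is_del <- sites$site_type == "del"
  is_ins <- sites$site_type == "ins"
  for (p in .POOLS) {
    pf <- pool_freq[, p]
    depth <- rpois(n, scfg$mean_depth)
    counts <- matrix(0L, n, 4, dimnames = list(NULL, .BASES))
    del_f <- del_r <- ins_f <- ins_r <- integer(n)

    alt_reads <- integer(n)
    alt_reads[is_snp] <- rbinom(sum(is_snp), depth[is_snp], pf[is_snp])
    ref_reads <- depth - alt_reads
    event_reads <- integer(n)
    ind <- is_del | is_ins
    event_reads[ind] <- rbinom(sum(ind), depth[ind], pf[ind])
    # deletion-carrying reads report no base; insertion reads report ref
    ref_reads[is_del] <- depth[is_del] - event_reads[is_del]
    fwd <- rbinom(n, event_reads, 0.5)
    del_f[is_del] <- fwd[is_del]
    del_r[is_del] <- event_reads[is_del] - fwd[is_del]
    ins_f[is_ins] <- fwd[is_ins]
    ins_r[is_ins] <- event_reads[is_ins] - fwd[is_ins]

    e <- scfg$base_error
    flips_ref <- rbinom(n, ref_reads, e)
    ridx <- cbind(seq_len(n), match(sites$ref, .BASES))
    counts[ridx] <- counts[ridx] + ref_reads - flips_ref
    counts <- .scatter_errors(counts, sites$ref, flips_ref)
    if (any(is_snp)) {
      flips_alt <- integer(n)
      flips_alt[is_snp] <- rbinom(sum(is_snp), alt_reads[is_snp], e)
      aidx <- cbind(seq_len(n), match(sites$alt, .BASES))
      ai <- aidx[is_snp, , drop = FALSE]
      counts[ai] <- counts[ai] + alt_reads[is_snp] - flips_alt[is_snp]
      counts <- .scatter_errors(counts, sites$alt, flips_alt)
    }
    out[[.pool_col("depth", p)]] <- depth
    for (b in .BASES) out[[.pool_col(b, p)]] <- counts[, b]
    out[[.pool_col("del", p)]] <- del_f + del_r
    out[[.pool_col("ins", p)]] <- ins_f + ins_r
    out[[.pool_col("del_fwd", p)]] <- del_f
    out[[.pool_col("del_rev", p)]] <- del_r
    out[[.pool_col("ins_fwd", p)]] <- ins_f
    out[[.pool_col("ins_rev", p)]] <- ins_r
    out[[.pool_col("baseq", p)]] <-
      pmax(0L, as.integer(round(rnorm(n, scfg$baseq_mean, scfg$baseq_sd))))
    out[[.pool_col("bestq", p)]] <-
      pmax(0L, as.integer(round(rnorm(n, scfg$bestq_mean, scfg$bestq_sd))))
  }
  pool_site_table(out)
}

#' Run the full synthetic evolve-and-resequence experiment
#'
#' Convenience wrapper: founder panel, Wright-Fisher evolution of the three
#' populations, sex-balanced pool sampling, and sequencing emulation.
#'
#' @inheritParams generate_founders
#' @param scfg a [seq_config()].
#' @param seed optional integer seed set once at the start.
#' @param fix_threshold,rare_threshold passed to [evolve_replicates()] for the
#'   truth table.
#' @return list with `table` (a [pool_site_table()]), `truth`, `panel` and
#'   `pool_freq` (pooled frequencies actually sequenced).
#' @export
simulate_experiment <- function(cfg, scfg, polymorphic_site_density = 2,
                                reference = NULL, indel_fraction = 0.05,
                                fix_threshold = 0.9, rare_threshold = 0.1,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  panel <- generate_founders(cfg, polymorphic_site_density,
                             reference = reference,
                             indel_fraction = indel_fraction)
  evo <- evolve_replicates(panel, cfg, fix_threshold = fix_threshold,
                           rare_threshold = rare_threshold)
  is_x <- panel$sites$arm == "X"
  pool_freq <- sapply(.POOLS, function(p)
    sample_pool(evo$freq[, p], cfg, arm_is_X = is_x)$freq)
  if (nrow(panel$sites) == 1)
    pool_freq <- matrix(pool_freq, 1, 3, dimnames = list(NULL, .POOLS))
  if (nrow(panel$sites) == 0)
    pool_freq <- matrix(numeric(0), 0, 3, dimnames = list(NULL, .POOLS))
  tab <- sequence_pool(pool_freq, panel$sites, scfg)
  list(table = tab, truth = evo$truth, panel = panel, pool_freq = pool_freq)
}
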