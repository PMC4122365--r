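#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` items without
#' replacement from a population of `N` containing `K` successes. Computed by
#' summing the probability mass in log space (log-binomials via [lchoose()],
#' incremental log-sum-exp), so small tail probabilities keep full relative
#' precision. All arguments are recycled; `k <= 0` returns exactly 1.
#'
#' @param N population size.
#' @param K successes in the population (`K <= N`).
#' @param n draws (`n <= N`).
#' @param k observed successes (`k <= min(K, n)`).
#' @return numeric vector of upper-tail probabilities.
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  m <- max(length(N), length(K), length(n), length(k))
  N <- rep_len(as.numeric(N), m); K <- rep_len(as.numeric(K), m)
  n <- rep_len(as.numeric(n), m); k <- rep_len(as.numeric(k), m)
  if (any(K > N)) stop("K must be <= N")
  if (any(n > N)) stop("n must be <= N")
  if (any(k > pmin(K, n))) stop("k must be <= min(K, n)")
  if (any(c(N, K, n) < 0)) stop("N, K, n must be non-negative")
  k <- pmax(k, 0)
  top <- pmin(K, n)
  lse <- rep(-Inf, m)
  denom <- lchoose(N, n)
  max_terms <- max(top - k, 0) + 1
  for (j in seq_len(max_terms) - 1) {
    i <- k + j
    active <- i <= top
    if (!any(active)) break
    lt <- ifelse(active, lchoose(K, i) + lchoose(N - K, n - i) - denom, -Inf)
    hi <- pmax(lse, lt)
    lo <- pmin(lse, lt)
    lse <- ifelse(is.infinite(hi) & hi < 0, -Inf, hi + log1p(exp(lo - hi)))
  }
  p <- exp(lse)
  p[k <= 0] <- 1
  pmin(p, 1)
}

#' Genome-wide and per-gene polymorphism density
#'
#' Computes the expected (mean) polymorphism frequency across all extended
#' genes, `mu` = total polymorphisms mapped to extended genes divided by
#' total extended-gene length in kb, and per-gene densities and
#' multiples-of-mu. A call overlapping several extended genes contributes one
#' polymorphism to each (the per-gene tallies are independent), and by the
#' same convention the default `mu` denominator is the sum of per-gene
#' extended lengths with overlaps double-counted; `nonredundant = TRUE`
#' switches the denominator to the length of the union of extended spans.
#'
#' @param assignments output of [assign_regions()] (possibly concatenated over
#'   SNPs and indels).
#' @param index an [build_extended_index()] result.
#' @param nonredundant use the non-redundant union length as mu denominator.
#' @return A `density_stats`: list with `mu` (polymorphisms per kb),
#'   `total_polymorphisms`, `total_kb` and `genes` (data.frame `gene_id,
#'   n_polymorphisms, ext_kb, density, multiple`).
#' @export
compute_density_stats <- function(assignments, index, nonredundant = FALSE) {
  stopifnot(inherits(index, "extended_gene_index"))
  g <- index$genes
  if (nrow(g) == 0 || sum(g$ext_length) == 0)
    stop("zero total extended-gene length")
  mapped <- assignments[!is.na(assignments$gene_id), , drop = FALSE]
  cnt <- table(factor(mapped$gene_id, levels = g$gene_id))
  genes <- data.frame(gene_id = g$gene_id,
                      n_polymorphisms = as.integer(cnt),
                      ext_kb = g$ext_length / 1000,
                      stringsAsFactors = FALSE)
  total_kb <- if (nonredundant) {
    gr <- GenomicRanges::GRanges(g$arm, IRanges::IRanges(g$ext_start, g$ext_end))
    sum(IRanges::width(GenomicRanges::reduce(gr, ignore.strand = TRUE))) / 1000
  } else sum(genes$ext_kb)
  mu <- sum(genes$n_polymorphisms) / total_kb
  genes$density <- genes$n_polymorphisms / genes$ext_kb
  genes$multiple <- if (mu > 0) genes$density / mu else NA_real_
  structure(list(mu = mu, total_polymorphisms = sum(genes$n_polymorphisms),
                 total_kb = total_kb, genes = genes,
                 nonredundant = nonredundant),
            class = "density_stats")
}

#' Filter genes by polymorphism-density multiple or absolute density
#'
#' @param stats a [compute_density_stats()] result.
#' @param min_multiple keep genes with density >= `min_multiple * mu`.
#' @param min_density keep genes with density >= `min_density` (per kb).
#' @return the filtered `genes` data.frame.
#' @export
density_filter <- function(stats, min_multiple = NULL, min_density = NULL) {
  stopifnot(inherits(stats, "density_stats"))
  g <- stats$genes
  keep <- rep(TRUE, nrow(g))
  if (!is.null(min_multiple)) keep <- keep & g$multiple >= min_multiple
  if (!is.null(min_density)) keep <- keep & g$density >= min_density
  g[keep, , drop = FALSE]
}

.enrichment_result <- function(N, K, n, k, mode) {
  if (K > N || n > N) stop("K and n must be <= N")
  if (k > min(K, n)) stop("k must be <= min(K, n)")
  structure(list(N = as.numeric(N), K = as.numeric(K), n = as.numeric(n),
                 k = as.numeric(k),
                 p_upper = hypergeom_upper_tail(N, K, n, k), mode = mode),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("%s-level enrichment: N=%g K=%g n=%g k=%g  p(upper)=%.3g\n",
              x$mode, x$N, x$K, x$n, x$k, x$p_upper))
  invisible(x)
}

# distinct positions of `calls` falling inside the union of extended spans of
# `gene_ids`; `positions` optionally restricts the universe of positions
.positions_in_genes <- function(index, gene_ids, positions = NULL) {
  g <- index$genes[index$genes$gene_id %in% gene_ids, , drop = FALSE]
  gr <- GenomicRanges::reduce(
    GenomicRanges::GRanges(g$arm, IRanges::IRanges(g$ext_start, g$ext_end)),
    ignore.strand = TRUE)
  if (is.null(positions)) return(sum(IRanges::width(gr)))
  q <- GenomicRanges::GRanges(positions$arm,
                              IRanges::IRanges(positions$pos, positions$pos))
  sum(IRanges::overlapsAny(q, gr, ignore.strand = TRUE))
}

#' Locus-level hypergeometric enrichment of polymorphisms in a gene set
#'
#' Tests whether the polymorphic loci concentrate in the target set's
#' extended genes: of `N` total positions in the universe's extended genes,
#' `K` lie in the target set's extended genes; `n` distinct positions are
#' polymorphic, `k` of them in the target set. Positions shared by several
#' genes of a set count once (the unit is the genomic position). With
#' `table`/`mask` supplied, the universe of positions is restricted to
#' evaluable loci.
#'
#' @param calls SNP and/or indel calls (any data.frame with `arm`, `pos`).
#' @param index an [build_extended_index()] result.
#' @param target_genes character vector of gene IDs (non-empty, a subset of
#'   `universe_genes`).
#' @param universe_genes character vector of gene IDs (default: all genes in
#'   the index).
#' @param table,mask optional [pool_site_table()] and [evaluable_mask()]
#'   restricting countable positions to evaluable loci.
#' @return An `enrichment_result` with `mode = "locus"`.
#' @export
locus_enrichment <- function(calls, index, target_genes,
                             universe_genes = NULL, table = NULL, mask = NULL) {
  stopifnot(inherits(index, "extended_gene_index"))
  if (is.null(universe_genes)) universe_genes <- index$genes$gene_id
  if (length(target_genes) == 0) stop("empty target set")
  if (!all(target_genes %in% universe_genes))
    stop("target set must be a subset of the universe")
  restrict <- NULL
  if (!is.null(table)) {
    keep <- .mask_vector(mask, nrow(table))
    restrict <- data.frame(arm = table$arm[keep], pos = table$pos[keep],
                           stringsAsFactors = FALSE)
  }
  if (is.null(restrict)) {
    N <- .positions_in_genes(index, universe_genes)
    K <- .positions_in_genes(index, target_genes)
  } else {
    N <- .positions_in_genes(index, universe_genes, restrict)
    K <- .positions_in_genes(index, target_genes, restrict)
  }
  loci <- unique(calls[, c("arm", "pos")])
  n <- .positions_in_genes(index, universe_genes, loci)
  k <- .positions_in_genes(index, target_genes, loci)
  .enrichment_result(N, K, n, k, mode = "locus")
}

#' Gene-level overlap enrichment between two gene sets
#'
#' Classic gene-set overlap test: from a universe of `N` genes, `K` belong to
#' the target set and `n` are polymorphic; `k` genes are in both.
#'
#' @param polymorphic_genes character vector of polymorphic gene IDs.
#' @param target_genes character vector of target-set gene IDs.
#' @param universe either the universe gene count or a character vector of
#'   universe gene IDs (then both sets must be subsets).
#' @return An `enrichment_result` with `mode = "gene"`.
#' @export
gene_overlap_enrichment <- function(polymorphic_genes, target_genes, universe) {
  polymorphic_genes <- unique(polymorphic_genes)
  target_genes <- unique(target_genes)
  if (is.character(universe)) {
    universe <- unique(universe)
    if (!all(polymorphic_genes %in% universe) ||
        !all(target_genes %in% universe))
      stop("sets must be subsets of the universe")
    N <- length(universe)
  } else {
    N <- as.numeric(universe)
    if (length(polymorphic_genes) > N || length(target_genes) > N)
      stop("sets must be subsets of the universe")
  }
  K <- length(target_genes)
  n <- length(polymorphic_genes)
  k <- length(intersect(polymorphic_genes, target_genes))
  .enrichment_result(N, K, n, k, mode = "gene")
}

#' Locus-level enrichment across many pathway sets
#'
#' Runs [locus_enrichment()] for every set and reports raw upper-tail p-values
#' (the primary output) together with Benjamini-Hochberg adjusted q-values.
#'
#' @inheritParams locus_enrichment
#' @param pathway_sets named list of gene-ID vectors.
#' @return data.frame with `set, N, K, n, k, p, q`.
#' @export
enrich_pathways <- function(calls, index, pathway_sets,
                            universe_genes = NULL, table = NULL, mask = NULL) {
  if (is.null(universe_genes))
    universe_genes <- unique(unlist(pathway_sets))
  rows <- lapply(names(pathway_sets), function(nm) {
    r <- locus_enrichment(calls, index, pathway_sets[[nm]],
                          universe_genes = universe_genes,
                          table = table, mask = mask)
    data.frame(set = nm, N = r$N, K = r$K, n = r$n, k = r$k, p = r$p_upper,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out
}

# uniform distinct positions within a reduced GRanges
.sample_positions <- function(gr, k) {
  w <- IRanges::width(gr)
  total <- sum(w)
  if (k > total) stop("more positions requested than available")
  off <- sample.int(total, k)
  cw <- cumsum(w)
  block <- findInterval(off - 1L, c(0L, cw), rightmost.closed = FALSE)
  within <- off - c(0L, cw)[block] - 1L
  data.frame(arm = as.character(GenomicRanges::seqnames(gr))[block],
             pos = IRanges::start(gr)[block] + within,
             stringsAsFactors = FALSE)
}

#' Plant polymorphic loci preferentially in a target gene set
#'
#' Power-simulation utility: draws `n` distinct positions from the union of
#' the universe's extended-gene spans, with the target set receiving
#' `fold`-times preferential weight. The split between target and non-target
#' strata is binomial with odds `fold * K : (N - K)` (K target positions of N
#' total); positions are uniform without replacement within each stratum.
#'
#' @param index an [build_extended_index()] result.
#' @param target_genes gene IDs of the preferred set.
#' @param n number of polymorphic positions to plant.
#' @param fold preference factor (`fold = 1` is the uniform null).
#' @param universe_genes universe gene IDs (default: all genes in the index).
#' @return data.frame with `arm`, `pos` (distinct positions).
#' @export
plant_polymorphisms <- function(index, target_genes, n, fold = 1,
                                universe_genes = NULL) {
  stopifnot(inherits(index, "extended_gene_index"), fold > 0)
  if (is.null(universe_genes)) universe_genes <- index$genes$gene_id
  g <- index$genes
  span_of <- function(ids) {
    gg <- g[g$gene_id %in% ids, , drop = FALSE]
    GenomicRanges::reduce(
      GenomicRanges::GRanges(gg$arm, IRanges::IRanges(gg$ext_start, gg$ext_end)),
      ignore.strand = TRUE)
  }
  tspan <- span_of(target_genes)
  uspan <- span_of(universe_genes)
  rest <- GenomicRanges::setdiff(uspan, tspan, ignore.strand = TRUE)
  K <- sum(IRanges::width(tspan))
  M <- sum(IRanges::width(rest))
  k_t <- rbinom(1, n, fold * K / (fold * K + M))
  k_t <- min(k_t, K)
  out <- rbind(.sample_positions(tspan, k_t),
               .sample_positions(rest, n - k_t))
  out[order(out$arm, out$pos, method = "radix"), , drop = FALSE]
}
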