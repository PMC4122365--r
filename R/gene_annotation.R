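#' Build an extended-gene index with a six-way region partition
#'
#' Each gene span is widened by `flank` bases on each side (clipped to the
#' arm) to form the "extended gene", capturing proximal regulatory sequence.
#' Within each extended span a strand-aware partition is constructed:
#' upstream flank, 5' UTR, CDS exon, intron, 3' UTR, downstream flank. UTRs
#' are inferred as exon-minus-CDS when the models carry no explicit UTR
#' features; 5' vs 3' follows the gene's strand. The partition tiles the
#' extended span exactly once per gene; overlapping genes are indexed
#' independently (no merging).
#'
#' @param models a `gene_models` object ([read_gene_models()]).
#' @param flank flank width in bp (default 2000).
#' @return An `extended_gene_index`: list with `genes` (adds
#'   `ext_start`, `ext_end`, `ext_length`, `cds_length`), `partition` (a
#'   `GRanges` with `gene_id` and `region`), and `cds` (per-gene CDS segments
#'   in genomic order).
#' @export
build_extended_index <- function(models, flank = 2000L) {
  stopifnot(inherits(models, "gene_models"), flank >= 0)
  g <- models$genes
  arm_len <- models$arm_lengths
  g$ext_start <- pmax(1L, g$start - as.integer(flank))
  g$ext_end <- pmin(as.integer(arm_len[g$arm]), g$end + as.integer(flank))
  g$ext_length <- g$ext_end - g$ext_start + 1L
  parts <- vector("list", nrow(g))
  g$cds_length <- integer(nrow(g))
  for (i in seq_len(nrow(g))) {
    id <- g$gene_id[i]
    ex <- models$exons[models$exons$gene_id == id, , drop = FALSE]
    cd <- models$cds[models$cds$gene_id == id, , drop = FALSE]
    exr <- IRanges::reduce(IRanges::IRanges(ex$start, ex$end))
    cdr <- IRanges::reduce(IRanges::IRanges(cd$start, cd$end))
    cds_len <- sum(IRanges::width(cdr))
    if (cds_len %% 3 != 0)
      stop("CDS length of gene ", id, " is not divisible by 3")
    g$cds_length[i] <- cds_len
    gene_r <- IRanges::IRanges(g$start[i], g$end[i])
    utr <- IRanges::setdiff(exr, cdr)
    intron <- IRanges::setdiff(gene_r, exr)
    plus <- g$strand[i] == "+"
    up <- if (g$ext_start[i] <= g$start[i] - 1L)
      IRanges::IRanges(g$ext_start[i], g$start[i] - 1L) else IRanges::IRanges()
    down <- if (g$end[i] + 1L <= g$ext_end[i])
      IRanges::IRanges(g$end[i] + 1L, g$ext_end[i]) else IRanges::IRanges()
    if (!plus) { tmp <- up; up <- down; down <- tmp }
    # UTR blocks genomically before the CDS are 5' on +, 3' on -
    if (length(cdr) > 0 && length(utr) > 0) {
      before <- IRanges::end(utr) < min(IRanges::start(cdr))
      utr5 <- utr[if (plus) before else !before]
      utr3 <- utr[if (plus) !before else before]
    } else {
      utr5 <- utr
      utr3 <- IRanges::IRanges()
    }
    blocks <- list(upstream = up, five_prime_UTR = utr5, CDS = cdr,
                   intron = intron, three_prime_UTR = utr3, downstream = down)
    parts[[i]] <- do.call(rbind, lapply(names(blocks), function(nm) {
      b <- blocks[[nm]]
      if (length(b) == 0) return(NULL)
      data.frame(arm = g$arm[i], start = IRanges::start(b),
                 end = IRanges::end(b), strand = g$strand[i],
                 gene_id = id, region = nm, stringsAsFactors = FALSE)
    }))
    if (sum(parts[[i]]$end - parts[[i]]$start + 1L) != g$ext_length[i])
      stop("region partition does not tile the extended span of gene ", id)
  }
  pdf <- do.call(rbind, parts)
  partition <- if (!is.null(pdf) && nrow(pdf) > 0)
    GenomicRanges::GRanges(pdf$arm, IRanges::IRanges(pdf$start, pdf$end),
                           strand = pdf$strand, gene_id = pdf$gene_id,
                           region = pdf$region)
  else GenomicRanges::GRanges()
  cds <- models$cds[order(match(models$cds$gene_id, g$gene_id),
                          models$cds$start), , drop = FALSE]
  rownames(cds) <- NULL
  structure(list(genes = g, partition = partition, cds = cds,
                 arm_lengths = arm_len, flank = as.integer(flank),
                 strand = setNames(g$strand, g$gene_id)),
            class = "extended_gene_index")
}

#' Assign variant calls to extended genes and gene regions
#'
#' A call is assigned to every gene whose extended span contains its position;
#' the region label comes from the containing partition block. Calls outside
#' every extended gene receive a single row with `gene_id = NA` and region
#' `"intergenic"`, so assigned plus intergenic rows conserve the call count.
#'
#' @param calls any data.frame with `arm` and `pos` columns (e.g. `snp_calls`
#'   or `indel_calls`).
#' @param index an [build_extended_index()] result.
#' @return data.frame with `arm, pos, gene_id, region, multi_gene`.
#' @export
assign_regions <- function(calls, index) {
  stopifnot(inherits(index, "extended_gene_index"))
  n <- nrow(calls)
  if (n == 0)
    return(data.frame(arm = character(0), pos = integer(0),
                      gene_id = character(0), region = character(0),
                      multi_gene = logical(0), stringsAsFactors = FALSE))
  q <- GenomicRanges::GRanges(calls$arm, IRanges::IRanges(calls$pos, calls$pos))
  ov <- GenomicRanges::findOverlaps(q, index$partition, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  md <- S4Vectors::mcols(index$partition)
  hits <- data.frame(arm = calls$arm[qi], pos = calls$pos[qi],
                     gene_id = md$gene_id[si],
                     region = md$region[si], stringsAsFactors = FALSE)
  genes_per_call <- tabulate(qi, nbins = n)
  hits$multi_gene <- genes_per_call[qi] > 1
  missed <- which(genes_per_call == 0)
  if (length(missed) > 0) {
    hits <- rbind(hits, data.frame(arm = calls$arm[missed],
                                   pos = calls$pos[missed],
                                   gene_id = NA_character_,
                                   region = "intergenic",
                                   multi_gene = FALSE,
                                   stringsAsFactors = FALSE))
  }
  hits <- hits[order(hits$arm, hits$pos, hits$gene_id, method = "radix"), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# spliced CDS sequence of one gene (transcript orientation)
.spliced_cds <- function(index, gene_id, reference) {
  segs <- index$cds[index$cds$gene_id == gene_id, , drop = FALSE]
  arm <- index$genes$arm[index$genes$gene_id == gene_id]
  s <- paste(vapply(seq_len(nrow(segs)), function(k)
    as.character(Biostrings::subseq(reference[[arm]],
                                    segs$start[k], segs$end[k])),
    character(1)), collapse = "")
  if (index$strand[gene_id] == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Classify the coding effect of SNP calls
#'
#' For each call falling in a CDS block of a gene, the affected codon is
#' reconstructed from the spliced CDS (strand-aware, frame from the CDS
#' segment order), the alternate base substituted (complemented on the minus
#' strand), and both codons translated with the standard genetic code.
#' Effects: `synonymous`, `nonsynonymous`, `nonsense` (gained stop),
#' `lost-stop`; calls in no CDS are reported once as `non-coding`.
#'
#' @param calls an `snp_calls` table (uses `h_allele` as the alternate base).
#' @param index an [build_extended_index()] result.
#' @param reference `DNAStringSet` of arm sequences.
#' @return data.frame with `arm, pos, gene_id, codon_index, ref_codon,
#'   alt_codon, ref_aa, alt_aa, effect`.
#' @export
classify_coding <- function(calls, index, reference) {
  stopifnot(inherits(index, "extended_gene_index"))
  empty <- data.frame(arm = character(0), pos = integer(0),
                      gene_id = character(0), codon_index = integer(0),
                      ref_codon = character(0), alt_codon = character(0),
                      ref_aa = character(0), alt_aa = character(0),
                      effect = character(0), stringsAsFactors = FALSE)
  if (nrow(calls) == 0) return(empty)
  asn <- assign_regions(calls, index)
  cds_hits <- asn[asn$region == "CDS", , drop = FALSE]
  out <- list()
  key_all <- paste(calls$arm, calls$pos)
  key_cds <- unique(paste(cds_hits$arm, cds_hits$pos))
  for (j in seq_len(nrow(cds_hits))) {
    arm <- cds_hits$arm[j]; pos <- cds_hits$pos[j]
    id <- cds_hits$gene_id[j]
    i <- match(paste(arm, pos), key_all)
    ref_base <- as.character(Biostrings::subseq(reference[[arm]], pos, pos))
    if (ref_base != calls$ref[i])
      stop("reference inconsistency at ", arm, ":", pos,
           " (call ref ", calls$ref[i], ", sequence ", ref_base, ")")
    segs <- index$cds[index$cds$gene_id == id, , drop = FALSE]
    k <- which(segs$start <= pos & segs$end >= pos)[1]
    plus <- index$strand[id] == "+"
    if (plus) {
      off <- sum(segs$end[seq_len(k - 1)] - segs$start[seq_len(k - 1)] + 1L) +
        (pos - segs$start[k] + 1L)
    } else {
      after <- seq_len(nrow(segs)) > k
      off <- sum(segs$end[after] - segs$start[after] + 1L) +
        (segs$end[k] - pos + 1L)
    }
    ci <- (off - 1L) %/% 3L + 1L
    cds_seq <- .spliced_cds(index, id, reference)
    ref_codon <- substr(cds_seq, 3L * ci - 2L, 3L * ci)
    alt_base <- calls$h_allele[i]
    if (!plus) alt_base <- unname(.COMPLEMENT[alt_base])
    pos_in_codon <- off - 3L * (ci - 1L)
    alt_codon <- ref_codon
    substr(alt_codon, pos_in_codon, pos_in_codon) <- alt_base
    ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon])
    alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
    effect <- if (ref_aa == alt_aa) "synonymous"
      else if (alt_aa == "*") "nonsense"
      else if (ref_aa == "*") "lost-stop"
      else "nonsynonymous"
    out[[length(out) + 1L]] <- data.frame(
      arm = arm, pos = pos, gene_id = id, codon_index = ci,
      ref_codon = ref_codon, alt_codon = alt_codon,
      ref_aa = ref_aa, alt_aa = alt_aa, effect = effect,
      stringsAsFactors = FALSE)
  }
  nc <- !(key_all %in% key_cds)
  if (any(nc)) {
    out[[length(out) + 1L]] <- data.frame(
      arm = calls$arm[nc], pos = calls$pos[nc], gene_id = NA_character_,
      codon_index = NA_integer_, ref_codon = NA_character_,
      alt_codon = NA_character_, ref_aa = NA_character_,
      alt_aa = NA_character_, effect = "non-coding", stringsAsFactors = FALSE)
  }
  res <- if (length(out) > 0) do.call(rbind, out) else empty
  res <- res[order(res$arm, res$pos, res$gene_id, method = "radix"), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Normalize counts by feature size relative to a reference class
#'
#' Computes `counts / sizes` and rescales so the reference class equals 1.
#' Used for the two standard views of call distributions: per chromosome arm
#' (counts per kb, rescaled so the X arm is the reference unit) and per gene
#' region (counts per total positions of that region class, rescaled so the
#' intron class is the reference unit).
#'
#' @param counts named numeric vector of call counts per class.
#' @param sizes named numeric vector of class sizes (same names; all > 0).
#' @param reference name of the reference class.
#' @return data.frame with `class`, `count`, `size`, `density`, `relative`.
#' @export
normalize_counts <- function(counts, sizes, reference) {
  stopifnot(!is.null(names(counts)), !is.null(names(sizes)))
  sizes <- sizes[names(counts)]
  if (anyNA(sizes)) stop("sizes missing for some classes")
  if (any(sizes <= 0)) stop("zero or negative class size: ",
                            names(sizes)[sizes <= 0][1])
  if (!reference %in% names(counts)) stop("unknown reference class: ", reference)
  density <- counts / sizes
  ref_d <- density[[reference]]
  if (ref_d == 0) stop("reference class has zero density; cannot rescale")
  data.frame(class = names(counts), count = as.numeric(counts),
             size = as.numeric(sizes), density = as.numeric(density),
             relative = as.numeric(density / ref_d),
             stringsAsFactors = FALSE, row.names = NULL)
}
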