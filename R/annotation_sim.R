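#' Generate synthetic gene models and pathway sets over a reference
#'
#' Places non-overlapping protein-coding gene models on each arm, each with a
#' 5' UTR, 1-3 CDS exons separated by introns, and a 3' UTR, on a random
#' strand. The reference sequence under every CDS is rewritten so that the
#' spliced CDS is a valid open reading frame: start codon, no internal stop
#' codons, terminal stop codon; total CDS length is a multiple of 3. Gene IDs
#' are `gene0001, ...`. Genes are partitioned round-robin into pathway sets.
#'
#' @param reference `DNAStringSet` of arm sequences (patched copy returned).
#' @param n_genes total genes to place (distributed over arms by length).
#' @param n_pathways number of pathway sets (>= 2 unless `n_genes` < 2).
#' @param utr_range,intron_range,codon_range ranges (bp / codons) the
#'   per-gene structure is drawn from.
#' @return list with `models` (a `gene_models` object: data.frames `genes`,
#'   `exons`, `cds`), `pathways` (named list of gene-ID vectors) and
#'   `reference` (the patched sequences).
#' @export
generate_annotation <- function(reference, n_genes, n_pathways = 3L,
                                utr_range = c(50L, 300L),
                                intron_range = c(60L, 200L),
                                codon_range = c(80L, 400L)) {
  arms <- names(reference)
  arm_len <- Biostrings::width(reference)
  if (n_genes == 0) {
    models <- structure(list(
      genes = data.frame(gene_id = character(0), arm = character(0),
                         strand = character(0), start = integer(0),
                         end = integer(0), stringsAsFactors = FALSE),
      exons = data.frame(gene_id = character(0), start = integer(0),
                         end = integer(0), stringsAsFactors = FALSE),
      cds = data.frame(gene_id = character(0), start = integer(0),
                       end = integer(0), stringsAsFactors = FALSE),
      arm_lengths = setNames(arm_len, arms)), class = "gene_models")
    return(list(models = models, pathways = setNames(list(), character(0)),
                reference = reference))
  }
  per_arm <- diff(round(c(0, cumsum(arm_len / sum(arm_len))) * n_genes))
  genes <- exons <- cds <- list()
  gid <- 0L
  for (a in seq_along(arms)) {
    if (per_arm[a] == 0) next
    # draw each gene's internal structure first, then check packing
    structs <- lapply(seq_len(per_arm[a]), function(i) {
      n_ex <- sample(1:3, 1)
      codons <- sample(codon_range[1]:codon_range[2], 1)
      cds_len <- 3L * codons
      # split CDS over exons
      if (n_ex > 1) {
        cuts <- sort(sample(seq_len(cds_len - 1), n_ex - 1))
        seg <- diff(c(0L, cuts, cds_len))
      } else seg <- cds_len
      introns <- if (n_ex > 1)
        sample(intron_range[1]:intron_range[2], n_ex - 1, replace = TRUE)
      else integer(0)
      utr5 <- sample(utr_range[1]:utr_range[2], 1)
      utr3 <- sample(utr_range[1]:utr_range[2], 1)
      list(seg = as.integer(seg), introns = introns,
           utr5 = utr5, utr3 = utr3,
           span = utr5 + sum(seg) + sum(introns) + utr3)
    })
    spans <- vapply(structs, `[[`, numeric(1), "span")
    gap <- 500L
    if (sum(spans) + gap * (per_arm[a] + 1) > arm_len[a])
      stop("infeasible packing: ", per_arm[a], " genes do not fit on arm ",
           arms[a])
    # place with random extra slack distributed between genes
    slack_total <- arm_len[a] - sum(spans) - gap * (per_arm[a] + 1L)
    slack <- if (per_arm[a] > 1) {
      br <- sort(sample.int(slack_total + 1L, per_arm[a] - 1L, replace = TRUE) - 1L)
      diff(c(0L, br, slack_total))
    } else slack_total
    cursor <- gap
    for (i in seq_len(per_arm[a])) {
      st <- structs[[i]]
      cursor <- cursor + slack[i]
      gid <- gid + 1L
      id <- sprintf("gene%04d", gid)
      strand <- sample(c("+", "-"), 1)
      gstart <- cursor + 1L
      gend <- cursor + st$span
      # genomic blocks laid left-to-right; strand only flips UTR identity
      ex_start <- integer(0); ex_end <- integer(0)
      cd_start <- integer(0); cd_end <- integer(0)
      left_utr <- if (strand == "+") st$utr5 else st$utr3
      right_utr <- if (strand == "+") st$utr3 else st$utr5
      seg <- if (strand == "+") st$seg else rev(st$seg)
      introns <- if (strand == "+") st$introns else rev(st$introns)
      p <- gstart
      for (k in seq_along(seg)) {
        exs <- p
        if (k == 1) {
          cs <- p + left_utr
        } else cs <- p
        ce <- cs + seg[k] - 1L
        exe <- if (k == length(seg)) ce + right_utr else ce
        ex_start <- c(ex_start, exs); ex_end <- c(ex_end, exe)
        cd_start <- c(cd_start, cs); cd_end <- c(cd_end, ce)
        p <- exe + 1L + if (k < length(seg)) introns[k] else 0L
      }
      genes[[length(genes) + 1L]] <-
        data.frame(gene_id = id, arm = arms[a], strand = strand,
                   start = gstart, end = gend, stringsAsFactors = FALSE)
      exons[[length(exons) + 1L]] <-
        data.frame(gene_id = id, start = ex_start, end = ex_end,
                   stringsAsFactors = FALSE)
      cds[[length(cds) + 1L]] <-
        data.frame(gene_id = id, start = cd_start, end = cd_end,
                   stringsAsFactors = FALSE)
      cursor <- gend + gap
    }
  }
  as_int <- function(df) {
    for (cc in intersect(c("start", "end"), names(df)))
      df[[cc]] <- as.integer(df[[cc]])
    rownames(df) <- NULL
    df
  }
  models <- structure(list(genes = as_int(do.call(rbind, genes)),
                           exons = as_int(do.call(rbind, exons)),
                           cds = as_int(do.call(rbind, cds)),
                           arm_lengths = setNames(as.integer(arm_len), arms)),
                      class = "gene_models")
  reference <- .patch_orfs(reference, models)
  ids <- models$genes$gene_id
  n_pathways <- min(n_pathways, length(ids))
  pw <- split(ids, rep_len(seq_len(n_pathways), length(ids)))
  names(pw) <- sprintf("pathway%02d", seq_len(n_pathways))
  list(models = models, pathways = pw, reference = reference)
}

# rewrite reference under each CDS with a stop-free ORF (start codon, random
# non-stop codons, terminal stop), respecting strand
.patch_orfs <- function(reference, models) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- setdiff(names(Biostrings::GENETIC_CODE), stops)
  seqs <- as.character(reference)
  for (i in seq_len(nrow(models$genes))) {
    g <- models$genes[i, ]
    segs <- models$cds[models$cds$gene_id == g$gene_id, , drop = FALSE]
    segs <- segs[order(segs$start), , drop = FALSE]
    cds_len <- sum(segs$end - segs$start + 1L)
    stopifnot(cds_len %% 3 == 0)
    n_codons <- cds_len %/% 3
    orf <- paste0("ATG",
                  paste(sample(codons, n_codons - 2L, replace = TRUE),
                        collapse = ""),
                  sample(stops, 1))
    if (g$strand == "-")
      orf <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(orf)))
    # distribute the (genome-strand) ORF over segments in ascending order
    off <- 0L
    s <- seqs[[g$arm]]
    for (k in seq_len(nrow(segs))) {
      w <- segs$end[k] - segs$start[k] + 1L
      substr(s, segs$start[k], segs$end[k]) <- substr(orf, off + 1L, off + w)
      off <- off + w
    }
    seqs[[g$arm]] <- s
  }
  Biostrings::DNAStringSet(seqs)
}

#' Write / read gene models as GFF3
#'
#' Uses the standard `gene -> mRNA -> exon/CDS` feature hierarchy with
#' `ID`/`Parent` attributes (one transcript per gene), 1-based inclusive
#' coordinates, via rtracklayer.
#'
#' @param models a `gene_models` object.
#' @param path GFF3 file path.
#' @export
write_gene_models <- function(models, path) {
  g <- models$genes
  if (nrow(g) == 0) {
    writeLines(c("##gff-version 3",
                 sprintf("##sequence-region %s 1 %d",
                         names(models$arm_lengths),
                         unname(models$arm_lengths))), path)
    return(invisible(path))
  }
  mk <- function(type, df, id, parent) {
    if (nrow(df) == 0)
      return(GenomicRanges::GRanges(
        type = character(0), ID = character(0), Parent = character(0)))
    GenomicRanges::GRanges(
      seqnames = df$arm,
      ranges = IRanges::IRanges(df$start, df$end),
      strand = df$strand, type = type, ID = id, Parent = parent)
  }
  ex <- models$exons
  ex$arm <- g$arm[match(ex$gene_id, g$gene_id)]
  ex$strand <- g$strand[match(ex$gene_id, g$gene_id)]
  cd <- models$cds
  cd$arm <- g$arm[match(cd$gene_id, g$gene_id)]
  cd$strand <- g$strand[match(cd$gene_id, g$gene_id)]
  # GFF3 phase: bases to skip to reach the first full codon of each segment,
  # accumulated in transcript order
  cd$phase <- integer(nrow(cd))
  for (id in g$gene_id) {
    rows <- which(cd$gene_id == id)
    if (g$strand[match(id, g$gene_id)] == "-") rows <- rev(rows)
    lens <- cd$end[rows] - cd$start[rows] + 1L
    cd$phase[rows] <- as.integer((3L - (cumsum(c(0L, lens[-length(lens)])) %% 3L)) %% 3L)
  }
  arm_names <- names(models$arm_lengths)
  mk2 <- function(type, df, id, parent, phase = NA_integer_) {
    gr <- mk(type, df, id, parent)
    S4Vectors::mcols(gr)$phase <- rep_len(phase, length(gr))
    GenomeInfoDb::seqlevels(gr) <- arm_names
    GenomeInfoDb::seqlengths(gr) <- unname(models$arm_lengths)
    gr
  }
  gr <- c(
    mk2("gene", g, g$gene_id, NA_character_),
    mk2("mRNA", g, paste0(g$gene_id, ".t1"), g$gene_id),
    mk2("exon", ex, NA_character_, paste0(ex$gene_id, ".t1")),
    mk2("CDS", cd, NA_character_, paste0(cd$gene_id, ".t1"), cd$phase))
  rtracklayer::export(gr, path, format = "gff3")
  # rtracklayer (<= 1.62) omits ##sequence-region directives; add them so arm
  # lengths survive a round trip
  lines <- readLines(path)
  directives <- sprintf("##sequence-region %s 1 %d", arm_names,
                        unname(models$arm_lengths))
  writeLines(append(lines, directives, after = 1L), path)
  invisible(path)
}

#' @param arm_lengths named integer vector of arm lengths; if `NULL`, taken
#'   from `##sequence-region` directives when present, else from the furthest
#'   feature end.
#' @rdname write_gene_models
#' @export
read_gene_models <- function(path, arm_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  typ <- as.character(md$type)
  arm <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  ids <- as.character(md$ID)
  parent <- vapply(as.list(md$Parent), function(x)
    if (length(x) == 0) NA_character_ else x[[1]], character(1))
  tx2gene <- setNames(parent[typ == "mRNA"], ids[typ == "mRNA"])
  gi <- typ == "gene"
  genes <- data.frame(gene_id = ids[gi], arm = arm[gi], strand = strand[gi],
                      start = IRanges::start(gr)[gi], end = IRanges::end(gr)[gi],
                      stringsAsFactors = FALSE)
  sub <- function(t) {
    k <- typ == t
    df <- data.frame(gene_id = unname(tx2gene[parent[k]]),
                     start = IRanges::start(gr)[k], end = IRanges::end(gr)[k],
                     stringsAsFactors = FALSE)
    df <- df[order(match(df$gene_id, genes$gene_id), df$start), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  if (is.null(arm_lengths)) {
    # rtracklayer (<= 1.62) ignores ##sequence-region; read the directives
    hdr <- grep("^##sequence-region", readLines(path, n = 200L), value = TRUE)
    if (length(hdr) > 0) {
      f <- strsplit(hdr, "[ \t]+")
      arm_lengths <- setNames(vapply(f, function(x) as.integer(x[4]), 1L),
                              vapply(f, `[[`, character(1), 2L))
    } else {
      arm_lengths <- tapply(IRanges::end(gr), arm, max)
      arm_lengths <- setNames(as.integer(arm_lengths), names(arm_lengths))
    }
  }
  structure(list(genes = genes, exons = sub("exon"), cds = sub("CDS"),
                 arm_lengths = arm_lengths),
            class = "gene_models")
}
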