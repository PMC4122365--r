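#' Variant-call containers and I/O
#'
#' SNP calls are data.frames of class `snp_calls` with columns
#' `arm, pos, ref, h_allele, h_allele_H2, c_consensus, freq_H1, freq_H2,
#' freq_C1, h_identity`; `freq_H1`/`freq_H2` are the frequencies of each
#' selected pool's own fixed allele and `freq_C1` the control frequency of
#' `h_allele`. Indel calls (`indel_calls`) carry
#' `arm, pos, ref, indel_seq, sign, maq_type, support_H1, support_H2,
#' control_support_reads, homopolymer_flag`.
#'
#' `write_calls()` emits either the native TSV or a minimal VCF 4.2 (1-based
#' positions in both). Indels in VCF use symbolic `<DEL>`/`<INS>` alleles with
#' the event sequence in INFO, since the table dialect does not carry flanking
#' context. Calls are sorted by (arm, pos) before writing; unsorted input is
#' sorted with a message, never an error.
#'
#' @param calls an `snp_calls` or `indel_calls` data.frame.
#' @param path output file.
#' @param format `"tsv"` or `"vcf"`.
#' @return `write_calls` returns `path` invisibly; `read_calls` returns the
#'   call table with its class restored.
#' @name call_io
NULL

.snp_call_cols <- c("arm", "pos", "ref", "h_allele", "h_allele_H2",
                    "c_consensus", "freq_H1", "freq_H2", "freq_C1", "h_identity")
.indel_call_cols <- c("arm", "pos", "ref", "indel_seq", "sign", "maq_type",
                      "support_H1", "support_H2", "control_support_reads",
                      "homopolymer_flag")

.as_call_class <- function(df, what = c("snp", "indel")) {
  what <- match.arg(what)
  cols <- if (what == "snp") .snp_call_cols else .indel_call_cols
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0)
    stop(what, " call table missing columns: ", paste(missing_cols, collapse = ", "))
  df <- df[, cols, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c(paste0(what, "_calls"), "data.frame")
  df
}

.sorted_calls <- function(calls) {
  ord <- order(calls$arm, calls$pos, method = "radix")
  if (!identical(ord, seq_len(nrow(calls)))) {
    message("calls were unsorted; sorting by (arm, pos) before write")
    calls <- calls[ord, , drop = FALSE]
    rownames(calls) <- NULL
  }
  calls
}

#' @rdname call_io
#' @export
write_calls <- function(calls, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  what <- if (inherits(calls, "snp_calls")) "snp"
          else if (inherits(calls, "indel_calls")) "indel"
          else stop("calls must be an 'snp_calls' or 'indel_calls' table")
  calls <- .sorted_calls(calls)
  if (format == "tsv") {
    write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=poolscan",
    "##INFO=<ID=FH1,Number=1,Type=Float,Description=\"Frequency of the H1 allele in pool H1\">",
    "##INFO=<ID=FH2,Number=1,Type=Float,Description=\"Frequency of the H2 allele in pool H2\">",
    "##INFO=<ID=FC1,Number=1,Type=Float,Description=\"Frequency of the H1 allele in control pool C1\">",
    "##INFO=<ID=HID,Number=0,Type=Flag,Description=\"H1 and H2 alleles identical\">",
    "##INFO=<ID=CB,Number=1,Type=String,Description=\"Control consensus base\">",
    "##INFO=<ID=AH2,Number=1,Type=String,Description=\"H2 allele when different from ALT\">",
    "##INFO=<ID=SEQ,Number=1,Type=String,Description=\"Inserted/deleted sequence\">",
    "##INFO=<ID=MAQTYPE,Number=1,Type=String,Description=\"Indel strand-support type (star or plus)\">",
    "##INFO=<ID=SH1,Number=1,Type=Float,Description=\"Fraction of H1 reads supporting the indel\">",
    "##INFO=<ID=SH2,Number=1,Type=Float,Description=\"Fraction of H2 reads supporting the indel\">",
    "##INFO=<ID=CSUP,Number=1,Type=Integer,Description=\"Control reads supporting the indel\">",
    "##INFO=<ID=HPFLAG,Number=0,Type=Flag,Description=\"Adjacent to a homopolymer run\">",
    "##ALT=<ID=DEL,Description=\"Single-base deletion of the reference base at POS\">",
    "##ALT=<ID=INS,Description=\"Single-base duplication of the reference base at POS\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  fmt_num <- function(x) formatC(x, format = "g", digits = 6)
  if (nrow(calls) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  if (what == "snp") {
    info <- paste0("FH1=", fmt_num(calls$freq_H1),
                   ";FH2=", fmt_num(calls$freq_H2),
                   ";FC1=", fmt_num(calls$freq_C1),
                   ";CB=", calls$c_consensus,
                   ifelse(calls$h_identity, ";HID",
                          paste0(";AH2=", calls$h_allele_H2)))
    body <- paste(calls$arm, calls$pos, ".", calls$ref, calls$h_allele,
                  ".", "PASS", info, sep = "\t")
  } else {
    alt <- ifelse(calls$sign == "del", "<DEL>", "<INS>")
    mtype <- ifelse(calls$maq_type == "*", "star", "plus")
    info <- paste0("SEQ=", calls$indel_seq,
                   ";MAQTYPE=", mtype,
                   ";SH1=", fmt_num(calls$support_H1),
                   ";SH2=", fmt_num(calls$support_H2),
                   ";CSUP=", calls$control_support_reads,
                   ifelse(!is.na(calls$homopolymer_flag) & calls$homopolymer_flag,
                          ";HPFLAG", ""))
    body <- paste(calls$arm, calls$pos, ".", calls$ref, alt,
                  ".", "PASS", info, sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' @param what `"snp"` or `"indel"`; which table type the file holds.
#' @rdname call_io
#' @export
read_calls <- function(path, what = c("snp", "indel"), format = c("tsv", "vcf")) {
  what <- match.arg(what)
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    if (what == "snp" && nrow(df) > 0) {
      df$h_identity <- as.logical(df$h_identity)
    }
    if (what == "indel" && nrow(df) > 0)
      df$homopolymer_flag <- as.logical(df$homopolymer_flag)
    return(.as_call_class(df, what))
  }
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  get_info <- function(info, key) {
    hit <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    out <- rep(NA_character_, length(info))
    found <- lengths(regmatches(info, gregexpr(paste0("(^|;)", key, "="), info))) > 0
    out[found] <- sub(paste0("^;?", key, "="), "", hit)
    out
  }
  if (length(body) == 0) {
    empty <- if (what == "snp") {
      data.frame(arm = character(0), pos = integer(0), ref = character(0),
                 h_allele = character(0), h_allele_H2 = character(0),
                 c_consensus = character(0), freq_H1 = numeric(0),
                 freq_H2 = numeric(0), freq_C1 = numeric(0),
                 h_identity = logical(0), stringsAsFactors = FALSE)
    } else {
      data.frame(arm = character(0), pos = integer(0), ref = character(0),
                 indel_seq = character(0), sign = character(0),
                 maq_type = character(0), support_H1 = numeric(0),
                 support_H2 = numeric(0), control_support_reads = integer(0),
                 homopolymer_flag = logical(0), stringsAsFactors = FALSE)
    }
    return(.as_call_class(empty, what))
  }
  f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  info <- f[, 8]
  if (what == "snp") {
    hid <- grepl("(^|;)HID($|;)", info)
    ah2 <- get_info(info, "AH2")
    df <- data.frame(
      arm = f[, 1], pos = as.integer(f[, 2]), ref = f[, 4],
      h_allele = f[, 5],
      h_allele_H2 = ifelse(hid, f[, 5], ah2),
      c_consensus = get_info(info, "CB"),
      freq_H1 = as.numeric(get_info(info, "FH1")),
      freq_H2 = as.numeric(get_info(info, "FH2")),
      freq_C1 = as.numeric(get_info(info, "FC1")),
      h_identity = hid, stringsAsFactors = FALSE)
  } else {
    df <- data.frame(
      arm = f[, 1], pos = as.integer(f[, 2]), ref = f[, 4],
      indel_seq = get_info(info, "SEQ"),
      sign = ifelse(f[, 5] == "<DEL>", "del", "ins"),
      maq_type = ifelse(get_info(info, "MAQTYPE") == "star", "*", "+"),
      support_H1 = as.numeric(get_info(info, "SH1")),
      support_H2 = as.numeric(get_info(info, "SH2")),
      control_support_reads = as.integer(get_info(info, "CSUP")),
      homopolymer_flag = grepl("(^|;)HPFLAG($|;)", info),
      stringsAsFactors = FALSE)
  }
  .as_call_class(df, what)
}

#' Read / write the simulation truth table
#'
#' One row per simulated polymorphic site: ancestral (reference) and derived
#' allele, site type (`snp`, `ins`, `del`), founder frequency `p0`, selection
#' coefficient, true final allele frequency in each population, the selected
#' flag, and `expected_callable` - whether the site satisfies the
#' fixed-difference definition on the true final frequencies.
#'
#' @param truth data.frame as produced by [evolve_replicates()].
#' @param path file path.
#' @export
write_truth_table <- function(truth, path) {
  write.table(truth[order(truth$arm, truth$pos, method = "radix"), ],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  df$selected <- as.logical(df$selected)
  df$expected_callable <- as.logical(df$expected_callable)
  df
}
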