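#' Construct a validated pool site table
#'
#' The pool site table is the central per-locus container: one row per genomic
#' site, with read depth, A/C/G/T counts, indel read support (with per-strand
#' breakdown), consensus base quality and best read mapping quality for each of
#' the three pools C1 (control), H1 and H2 (selected replicates).
#'
#' @param df data.frame carrying the columns `arm`, `pos`, `ref` and, for each
#'   pool `p` in `C1,H1,H2`, the columns
#'   `depth_p, A_p, C_p, G_p, T_p, del_p, ins_p, del_fwd_p, del_rev_p,
#'   ins_fwd_p, ins_rev_p, baseq_p, bestq_p`.
#' @return A `pool_site_table` (a data.frame), rows sorted by (arm, pos).
#' @details Invariants enforced: `ref` is one of A/C/G/T; all counts and
#'   qualities are non-negative; per pool the base counts sum to at most the
#'   depth (reads spanning a deletion report no base); `del = del_fwd +
#'   del_rev` and `ins = ins_fwd + ins_rev`; (arm, pos) pairs are unique.
#' @export
pool_site_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.pool_columns(), names(df))
  if (length(missing_cols) > 0)
    stop("pool table is missing columns: ", paste(missing_cols, collapse = ", "))
  df <- df[, .pool_columns()]
  df$arm <- as.character(df$arm)
  df$ref <- as.character(df$ref)
  num_cols <- setdiff(.pool_columns(), c("arm", "ref"))
  for (cc in num_cols) df[[cc]] <- as.integer(df[[cc]])
  .validate_pool_rows(df, line = NULL)
  ord <- order(df$arm, df$pos, method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  key <- paste(df$arm, df$pos)
  if (anyDuplicated(key))
    stop("duplicate (arm, pos) keys: ", paste(unique(key[duplicated(key)])[1:3], collapse = ", "))
  class(df) <- c("pool_site_table", "data.frame")
  df
}

# shared row validation; `line` maps row index -> file line for I/O errors
.validate_pool_rows <- function(df, line = NULL) {
  where <- function(i) {
    if (is.null(line)) paste0("row ", i) else paste0("line ", line[i])
  }
  bad <- which(!(df$ref %in% .BASES))
  if (length(bad) > 0)
    stop("invalid ref base at ", where(bad[1]), ": '", df$ref[bad[1]], "'")
  num_cols <- setdiff(.pool_columns(), c("arm", "ref"))
  for (cc in num_cols) {
    v <- df[[cc]]
    bad <- which(is.na(v) | v < 0)
    if (length(bad) > 0)
      stop("negative or missing value in column '", cc, "' at ", where(bad[1]))
  }
  for (p in .POOLS) {
    base_sum <- df[[.pool_col("A", p)]] + df[[.pool_col("C", p)]] +
      df[[.pool_col("G", p)]] + df[[.pool_col("T", p)]]
    bad <- which(base_sum > df[[.pool_col("depth", p)]])
    if (length(bad) > 0)
      stop("base counts exceed depth for pool ", p, " at ", where(bad[1]))
    bad <- which(df[[.pool_col("del_fwd", p)]] + df[[.pool_col("del_rev", p)]] !=
                   df[[.pool_col("del", p)]])
    if (length(bad) > 0)
      stop("del strand counts do not sum to del for pool ", p, " at ", where(bad[1]))
    bad <- which(df[[.pool_col("ins_fwd", p)]] + df[[.pool_col("ins_rev", p)]] !=
                   df[[.pool_col("ins", p)]])
    if (length(bad) > 0)
      stop("ins strand counts do not sum to ins for pool ", p, " at ", where(bad[1]))
  }
  invisible(TRUE)
}

#' Read a pool count table from its TSV dialect
#'
#' @param path path to a tab-separated file whose header names the columns of
#'   [pool_site_table()].
#' @return A `pool_site_table`. Malformed rows are rejected (never silently
#'   repaired) with the offending file line number in the error message.
#' @export
read_pool_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  missing_cols <- setdiff(.pool_columns(), names(df))
  if (length(missing_cols) > 0)
    stop("header does not match the pool-table dialect; missing: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) return(pool_site_table(df))
  line <- seq_len(nrow(df)) + 1L     # header is line 1
  df$arm <- as.character(df$arm)
  df$ref <- as.character(df$ref)
  .validate_pool_rows(df, line = line)
  key <- paste(df$arm, df$pos)
  dup <- which(duplicated(key))
  if (length(dup) > 0)
    stop("duplicate (arm, pos) at line ", line[dup[1]], ": ", key[dup[1]])
  pool_site_table(df)
}

#' Write a pool count table
#'
#' Rows are stable-sorted by (arm, pos) so repeated writes are byte-identical.
#'
#' @param x a `pool_site_table`.
#' @param path output path.
#' @export
write_pool_table <- function(x, path) {
  stopifnot(inherits(x, "pool_site_table"))
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import a PoPoolation2-style sync file
#'
#' The sync format carries per-pool `A:T:C:G:N:del` count strings and no
#' quality information. Columns are taken in the order C1, H1, H2. `N` reads
#' count toward depth but not toward any base; deletion reads are recorded
#' without strand information (assigned to the forward strand) and there is no
#' insertion channel. Missing quality fields are filled with the supplied
#' defaults and the returned table carries attribute `qualities_defaulted =
#' TRUE`.
#'
#' @param path sync file path.
#' @param default_baseq,default_bestq integers used for every site's base and
#'   best-read quality.
#' @return A `pool_site_table`.
#' @export
import_sync <- function(path, default_baseq = 30L, default_bestq = 50L) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    tab <- pool_site_table(.empty_pool_df())
    attr(tab, "qualities_defaulted") <- TRUE
    return(tab)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 6L))
    stop("sync line ", which(nf != 6L)[1],
         ": expected 6 columns (chrom pos ref + 3 pools), got ", nf[nf != 6L][1])
  m <- do.call(rbind, parts)
  out <- data.frame(arm = m[, 1], pos = as.integer(m[, 2]), ref = m[, 3],
                    stringsAsFactors = FALSE)
  for (j in seq_along(.POOLS)) {
    p <- .POOLS[j]
    cnt <- do.call(rbind, strsplit(m[, 3 + j], ":", fixed = TRUE))
    if (ncol(cnt) != 6L)
      stop("sync pool field must have 6 ':'-separated counts (A:T:C:G:N:del)")
    cnt <- matrix(as.integer(cnt), nrow = nrow(cnt))
    # sync order is A:T:C:G:N:del
    out[[.pool_col("A", p)]] <- cnt[, 1]
    out[[.pool_col("T", p)]] <- cnt[, 2]
    out[[.pool_col("C", p)]] <- cnt[, 3]
    out[[.pool_col("G", p)]] <- cnt[, 4]
    out[[.pool_col("del", p)]] <- cnt[, 6]
    out[[.pool_col("del_fwd", p)]] <- cnt[, 6]
    out[[.pool_col("del_rev", p)]] <- 0L
    out[[.pool_col("ins", p)]] <- 0L
    out[[.pool_col("ins_fwd", p)]] <- 0L
    out[[.pool_col("ins_rev", p)]] <- 0L
    out[[.pool_col("depth", p)]] <- rowSums(cnt)   # N and del kept in depth
    out[[.pool_col("baseq", p)]] <- as.integer(default_baseq)
    out[[.pool_col("bestq", p)]] <- as.integer(default_bestq)
  }
  tab <- pool_site_table(out)
  attr(tab, "qualities_defaulted") <- TRUE
  tab
}

.empty_pool_df <- function() {
  df <- data.frame(arm = character(0), pos = integer(0), ref = character(0),
                   stringsAsFactors = FALSE)
  for (p in .POOLS) for (f in .POOL_FIELDS) df[[.pool_col(f, p)]] <- integer(0)
  df
}

#' Read / write pathway gene-set files
#'
#' One set per line: `set_name TAB comma-separated gene IDs`.
#'
#' @param path file path.
#' @return `read_pathway_sets`: a named list of character vectors (unique
#'   members).
#' @export
read_pathway_sets <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(setNames(list(), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0)
    stop("pathway file line ", bad[1], ": expected 'name<TAB>id,id,...'")
  nms <- vapply(parts, `[[`, character(1), 1L)
  if (any(!nzchar(nms))) stop("pathway set with empty name")
  if (anyDuplicated(nms)) stop("duplicate pathway set name: ",
                               nms[duplicated(nms)][1])
  members <- lapply(parts, function(pp) unique(strsplit(pp[[2]], ",", fixed = TRUE)[[1]]))
  setNames(members, nms)
}

#' @param sets named list of character vectors.
#' @rdname read_pathway_sets
#' @export
write_pathway_sets <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(seq_along(sets), function(i) {
    paste0(names(sets)[i], "\t", paste(unique(sets[[i]]), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
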