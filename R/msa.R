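#' Multiple sequence alignment container
#'
#' A light container for an aligned set of protein sequences with a
#' designated master (query) row — the object the curation operations and the
#' profile-HMM builder consume. Rows are equal-length gapped strings over the
#' 20 canonical residues plus `-`.
#'
#' @param rows Character vector of aligned rows (equal nchar).
#' @param ids Row labels (default seq1..seqN).
#' @param master Index of the master row (default 1).
#' @return A `gm_msa` object.
#' @examples
#' gm_msa(c("AC-D", "ACAD"), ids = c("q", "s"))
#' @export
gm_msa <- function(rows, ids = NULL, master = 1L) {
  rows <- toupper(as.character(rows))
  if (!length(rows)) abort("An alignment needs at least one row.")
  if (length(unique(nchar(rows))) != 1) abort("Alignment rows differ in length.")
  if (is.null(ids)) ids <- sprintf("seq%d", seq_along(rows))
  if (length(ids) != length(rows)) abort("`ids` length mismatch.")
  master <- as.integer(master)
  if (master < 1 || master > length(rows)) abort("Master row out of range.")
  structure(list(rows = unname(rows), ids = as.character(ids), master = master),
            class = "gm_msa")
}

#' @export
print.gm_msa <- function(x, ...) {
  cat("<gm_msa> ", length(x$rows), " rows x ", nchar(x$rows[1]),
      " columns, master = ", x$ids[x$master], "\n", sep = "")
  invisible(x)
}

#' Number of rows / columns of an alignment
#' @param msa A [gm_msa].
#' @return Integer.
#' @export
msa_nrow <- function(msa) length(msa$rows)

#' @rdname msa_nrow
#' @export
msa_ncol <- function(msa) nchar(msa$rows[1])

# Character matrix view (rows x columns).
msa_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$rows, "", fixed = TRUE))
}

# Fractional identity between two gapped rows over columns where both are
# non-gap; 0 when no co-aligned columns exist.
aligned_identity <- function(a, b) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  both <- ca != "-" & cb != "-"
  if (!any(both)) return(0)
  mean(ca[both] == cb[both])
}

#' Greedy maximin diversity filter for an alignment
#'
#' Reduces an alignment to the master plus a maximally diverse subset of
#' rows: starting from the master, iteratively add the row with the lowest
#' maximum pairwise identity to the rows already kept, until `n_keep` rows or
#' the input is exhausted. Deterministic; ties broken by row order.
#'
#' @param msa A [gm_msa].
#' @param n_keep Number of rows to keep (default 30).
#' @return A [gm_msa] with at most `n_keep` rows, master first.
#' @export
msa_diff_filter <- function(msa, n_keep = 30L) {
  stopifnot(inherits(msa, "gm_msa"))
  n <- msa_nrow(msa)
  kept <- msa$master
  pool <- setdiff(seq_len(n), kept)
  # max identity of every pool row to the kept set, updated incrementally
  maxid <- vapply(pool, function(i) {
    aligned_identity(msa$rows[i], msa$rows[msa$master])
  }, numeric(1))
  while (length(kept) < n_keep && length(pool)) {
    pick <- which.min(maxid)   # lowest max-identity; ties -> earliest row
    chosen <- pool[pick]
    kept <- c(kept, chosen)
    pool <- pool[-pick]
    maxid <- maxid[-pick]
    if (length(pool)) {
      upd <- vapply(pool, function(i) {
        aligned_identity(msa$rows[i], msa$rows[chosen])
      }, numeric(1))
      maxid <- pmax(maxid, upd)
    }
  }
  gm_msa(msa$rows[kept], ids = msa$ids[kept], master = 1L)
}

#' Remove insert columns relative to the master row
#'
#' Deletes every column in which the master row has a gap, yielding a
#' master-slave alignment whose master row is gap-free. Row count is
#' unchanged.
#'
#' @param msa A [gm_msa].
#' @return A [gm_msa].
#' @export
remove_inserts <- function(msa) {
  stopifnot(inherits(msa, "gm_msa"))
  m <- msa_matrix(msa)
  keep <- m[msa$master, ] != "-"
  rows <- apply(m[, keep, drop = FALSE], 1, chars_seq)
  gm_msa(rows, ids = msa$ids, master = msa$master)
}

#' Drop problem rows and poorly covered columns
#'
#' Removes rows with fewer than `min_seq_residues` non-gap residues (short or
#' fragmentary sequences), then columns whose residue coverage falls below
#' `min_col_coverage` — in that fixed order. Errors when curation would leave
#' fewer than two rows or lose the master.
#'
#' @param msa A [gm_msa].
#' @param min_col_coverage Minimum fraction of non-gap residues per column
#'   (default 0.5).
#' @param min_seq_residues Minimum non-gap residues per row (default 10).
#' @return A [gm_msa].
#' @export
drop_problem_regions <- function(msa, min_col_coverage = 0.5,
                                 min_seq_residues = 10L) {
  stopifnot(inherits(msa, "gm_msa"))
  m <- msa_matrix(msa)
  res_per_row <- rowSums(m != "-")
  keep_rows <- res_per_row >= min_seq_residues
  keep_rows[msa$master] <- TRUE  # master is never curated away here
  if (sum(keep_rows) < 2) abort("curation emptied alignment")
  dropped_rows <- sum(!keep_rows)
  m <- m[keep_rows, , drop = FALSE]
  new_master <- match(msa$master, which(keep_rows))
  cov <- colMeans(m != "-")
  keep_cols <- cov >= min_col_coverage
  if (!any(keep_cols)) abort("curation emptied alignment")
  if (dropped_rows || any(!keep_cols)) {
    inform(paste0("Curation dropped ", dropped_rows, " row(s) and ",
                  sum(!keep_cols), " column(s)."))
  }
  rows <- apply(m[, keep_cols, drop = FALSE], 1, chars_seq)
  gm_msa(rows, ids = msa$ids[keep_rows], master = new_master)
}

#' Read / write Stockholm alignments
#'
#' Minimal Stockholm 1.0 support: sequence lines and `#=GF` free text;
#' wrapped alignments are concatenated by id. The first row becomes the
#' master on read.
#'
#' @param path File path.
#' @return [read_stockholm()] returns a [gm_msa].
#' @export
read_stockholm <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "# STOCKHOLM")) {
    abort("Not a Stockholm file.")
  }
  seqs <- list()
  order <- character()
  for (l in lines[-1]) {
    if (l == "" || startsWith(l, "#") || startsWith(l, "//")) next
    parts <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(parts) != 2) next
    id <- parts[1]
    if (!id %in% order) order <- c(order, id)
    seqs[[id]] <- paste0(seqs[[id]] %||% "", parts[2])
  }
  rows <- gsub("\\.", "-", toupper(unlist(seqs[order])))
  gm_msa(rows, ids = order, master = 1L)
}

#' @rdname read_stockholm
#' @param msa A [gm_msa] to write.
#' @export
write_stockholm <- function(msa, path) {
  idw <- max(nchar(msa$ids)) + 2L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# STOCKHOLM 1.0", con)
  writeLines(sprintf(paste0("%-", idw, "s%s"), msa$ids, msa$rows), con)
  writeLines("//", con)
  invisible(path)
}

#' Read / write A3M alignments
#'
#' In A3M, lowercase residues are inserts relative to the master and carry no
#' alignment column; match columns are uppercase or `-`. On read, inserts are
#' expanded into explicit gap columns (so `remove_inserts()` round-trips the
#' A3M semantics); on write, columns gapped in the master are emitted as
#' lowercase inserts of the other rows.
#'
#' @param path File path.
#' @return [read_a3m()] returns a [gm_msa] with the first sequence as master.
#' @export
read_a3m <- function(path) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  if (!length(heads)) abort("Not a FASTA/A3M file.")
  ids <- sub("^>\\s*", "", lines[heads])
  ids <- vapply(strsplit(ids, "\\s+"), `[[`, character(1), 1)
  bounds <- c(heads, length(lines) + 1L)
  raw <- vapply(seq_along(heads), function(i) {
    paste0(lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)], collapse = "")
  }, character(1))
  # per row: vector of match-state chars and inserts after each match state
  n_match <- nchar(gsub("[a-z.]", "", raw[1]))
  expand <- lapply(raw, function(s) {
    ch <- seq_chars(s)
    match_ch <- character(n_match)
    ins <- vector("list", n_match + 1L)
    mi <- 0L
    for (c0 in ch) {
      if (c0 %in% c(".")) next
      if (c0 == tolower(c0) && c0 != "-") {
        ins[[mi + 1L]] <- c(ins[[mi + 1L]], toupper(c0))
      } else {
        mi <- mi + 1L
        match_ch[mi] <- toupper(c0)
      }
    }
    if (mi != n_match) abort("A3M rows disagree on match-column count.")
    list(match = match_ch, ins = ins)
  })
  ins_w <- vapply(seq_len(n_match + 1L), function(j) {
    max(vapply(expand, function(e) length(e$ins[[j]]), integer(1)))
  }, integer(1))
  rows <- vapply(expand, function(e) {
    out <- character()
    for (j in seq_len(n_match + 1L)) {
      if (ins_w[j] > 0) {
        v <- e$ins[[j]]
        out <- c(out, v, rep("-", ins_w[j] - length(v)))
      }
      if (j <= n_match) out <- c(out, e$match[j])
    }
    chars_seq(out)
  }, character(1))
  gm_msa(rows, ids = ids, master = 1L)
}

#' @rdname read_a3m
#' @param msa A [gm_msa] to write.
#' @export
write_a3m <- function(msa, path) {
  m <- msa_matrix(msa)
  is_match <- m[msa$master, ] != "-"
  con <- file(path, "w")
  on.exit(close(con))
  ord <- c(msa$master, setdiff(seq_len(msa_nrow(msa)), msa$master))
  for (i in ord) {
    out <- ifelse(is_match, m[i, ], ifelse(m[i, ] == "-", "", tolower(m[i, ])))
    writeLines(c(paste0(">", msa$ids[i]), paste0(out, collapse = "")), con)
  }
  invisible(path)
}

#' Read / write protein FASTA
#'
#' Thin wrappers around Biostrings for plain (unaligned) protein FASTA.
#'
#' @param path File path.
#' @return [read_fasta()] returns a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- vapply(strsplit(names(x), "\\s+"), `[[`, character(1), 1)
  out
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}
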