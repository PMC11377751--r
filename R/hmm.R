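#' Profile hidden Markov model
#'
#' Position-specific match emissions over the 20 residues, insert emissions
#' equal to the background, and per-state match/insert/delete transitions.
#' The search architecture is local: begin uniformly into any match state at
#' any sequence position, and exit uniformly over the remaining match states
#' (`p_end(i) = 1/(n_match - i + 1)`), which keeps total path probability at
#' most 1 so that a background-equal profile can never score positive bits.
#'
#' Constructed by [hmm_from_msa()]; not usually called directly.
#'
#' @param match_emissions `n_match x 20` row-stochastic matrix.
#' @param transitions List of numeric vectors `tMM`, `tMI`, `tMD`, `tIM`,
#'   `tII`, `tDM`, `tDD`, each of length `n_match - 1` (transitions out of
#'   states 1..n-1).
#' @param background Background frequencies.
#' @param name Profile name.
#' @param match_map Optional integer vector mapping match states to master
#'   residue positions (for interval reporting).
#' @return A `profile_hmm` object.
#' @export
profile_hmm <- function(match_emissions, transitions,
                        background = background_frequencies(),
                        name = "profile", match_map = NULL) {
  n <- nrow(match_emissions)
  if (n < 1) abort("A profile needs at least one match state.")
  stopifnot(ncol(match_emissions) == 20)
  if (max(abs(rowSums(match_emissions) - 1)) > 1e-9) {
    abort("Match emission rows must sum to 1.")
  }
  for (nm in c("tMM", "tMI", "tMD", "tIM", "tII", "tDM", "tDD")) {
    if (length(transitions[[nm]]) != max(0L, n - 1L)) {
      abort(paste0("Transition vector ", nm, " must have length n_match - 1."))
    }
  }
  if (n > 1) {
    sums <- cbind(transitions$tMM + transitions$tMI + transitions$tMD,
                  transitions$tIM + transitions$tII,
                  transitions$tDM + transitions$tDD)
    if (max(abs(sums - 1)) > 1e-9) abort("Transition rows must sum to 1.")
  }
  colnames(match_emissions) <- AA
  structure(list(n_match = n,
                 match_emissions = match_emissions,
                 transitions = transitions,
                 background = background,
                 name = name,
                 match_map = match_map %||% seq_len(n)),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("<profile_hmm> ", x$name, ": ", x$n_match, " match states\n", sep = "")
  invisible(x)
}

#' Build a profile HMM from an alignment
#'
#' Columns whose gap fraction is below `match_gap_fraction` become match
#' states. Sequences receive Henikoff position-based weights (computed over
#' the match columns). Match emissions use background-proportional
#' pseudocounts, `e[i, a] = (weighted count + alpha * f[a]) /
#' (total weight + alpha)`; transitions come from weighted state-path counts
#' with add-one smoothing. Insert emissions are the background.
#'
#' @param msa A [gm_msa].
#' @param alpha Pseudocount weight (default 1).
#' @param match_gap_fraction Gap-fraction threshold for match columns
#'   (default 0.5).
#' @param background Background frequencies.
#' @param name Profile name (default the master id).
#' @return A [profile_hmm]. `match_map` maps match states to master-row
#'   residue positions (NA where the master is gapped in a match column).
#' @examples
#' hmm <- hmm_from_msa(gm_msa(c("ACD", "ACD")))
#' hmm$n_match
#' @export
hmm_from_msa <- function(msa, alpha = 1, match_gap_fraction = 0.5,
                         background = background_frequencies(),
                         name = NULL) {
  stopifnot(inherits(msa, "gm_msa"))
  if (msa_nrow(msa) == 1) {   # closed form; common in iterative building
    return(single_sequence_hmm(gsub("-", "", msa$rows[1]), alpha = alpha,
                               background = background,
                               name = name %||% msa$ids[1]))
  }
  m <- msa_matrix(msa)
  nseq <- nrow(m)
  gap_frac <- colMeans(m == "-")
  is_match <- gap_frac < match_gap_fraction
  if (!any(is_match)) abort("No usable (match) columns in the alignment.")
  mcols <- which(is_match)
  n <- length(mcols)

  ridx <- matrix(match(m, AA), nseq)      # NA = gap or ambiguity code
  Mi <- ridx[, mcols, drop = FALSE]
  # per-column weighted residue counts, Henikoff weights (vectorised)
  CNT <- vapply(seq_len(n), function(k) tabulate(Mi[, k], 20),
                integer(20))              # 20 x n
  r_col <- colSums(CNT > 0)
  w <- henikoff_weights_idx(Mi, CNT, r_col)

  em <- matrix(0, n, 20, dimnames = list(NULL, AA))
  for (a in seq_len(20)) {
    em[, a] <- colSums((!is.na(Mi) & Mi == a) * w, na.rm = TRUE)
  }
  tot <- colSums((!is.na(Mi)) * w)
  em <- (em + rep(alpha * background, each = n)) / (tot + alpha)

  trans <- transition_counts(m, mcols, w, n)
  # match state -> master residue coordinate (counted over ALL columns, so
  # master residues in non-match columns still advance the coordinate)
  master_full <- m[msa$master, ]
  pos_full <- cumsum(master_full != "-")
  match_map <- ifelse(master_full[mcols] == "-", NA_integer_,
                      pos_full[mcols])
  profile_hmm(em, trans, background = background,
              name = name %||% msa$ids[msa$master],
              match_map = as.integer(match_map))
}

# Henikoff position-based sequence weights from residue-index matrices.
# Gap cells contribute nothing; weights are the per-row mean contribution
# over its non-gap columns (not renormalised: two identical rows each get
# weight 1/2 so their total counts as one observation).
henikoff_weights_idx <- function(Mi, CNT, r_col) {
  nseq <- nrow(Mi)
  n <- ncol(Mi)
  colidx <- rep(seq_len(n), each = nseq)
  cell_cnt <- CNT[cbind(as.vector(Mi), colidx)]        # NA where gap
  contrib <- 1 / (r_col[colidx] * cell_cnt)
  contrib[is.na(contrib)] <- 0
  contrib <- matrix(contrib, nseq)
  n_res <- rowSums(!is.na(Mi))
  ifelse(n_res > 0, rowSums(contrib) / pmax(n_res, 1), 0)
}

#' @keywords internal
henikoff_weights <- function(m) {
  Mi <- matrix(match(m, AA), nrow(m))
  CNT <- vapply(seq_len(ncol(Mi)), function(k) tabulate(Mi[, k], 20),
                integer(20))
  henikoff_weights_idx(Mi, CNT, colSums(CNT > 0))
}

# Weighted state-path transition counts with add-one smoothing, vectorised
# over match-column junctions. Insert residues attach to the preceding match
# state; paths entering inserts from a delete contribute the insert self and
# exit counts only (delete-to-insert itself is not a model transition).
transition_counts <- function(m, mcols, w, n) {
  k1 <- max(0L, n - 1L)
  cnt <- list(tMM = rep(1, k1), tMI = rep(1, k1), tMD = rep(1, k1),
              tIM = rep(1, k1), tII = rep(1, k1),
              tDM = rep(1, k1), tDD = rep(1, k1))
  if (n > 1) {
    nseq <- nrow(m)
    # residues inside insert columns, grouped by the junction they follow
    junction <- integer(ncol(m))
    junction[mcols] <- NA_integer_
    junction[-mcols] <- findInterval(setdiff(seq_len(ncol(m)), mcols), mcols)
    ins_cols <- setdiff(seq_len(ncol(m)), mcols)
    M <- m[, mcols, drop = FALSE] != "-"       # TRUE = match, FALSE = delete
    for (s in seq_len(nseq)) {
      inscnt <- integer(n + 1L)
      if (length(ins_cols)) {
        occ <- ins_cols[m[s, ins_cols] != "-"]
        if (length(occ)) {
          tb <- tabulate(junction[occ] + 1L, n + 1L)
          inscnt <- tb
        }
      }
      prev_m <- M[s, seq_len(n - 1L)]
      next_m <- M[s, 2L:n]
      cins <- inscnt[2L:n]                     # junction i sits after col i
      ws <- w[s]
      no <- cins == 0L
      cnt$tMM <- cnt$tMM + ws * (no & prev_m & next_m)
      cnt$tMD <- cnt$tMD + ws * (no & prev_m & !next_m)
      cnt$tDM <- cnt$tDM + ws * (no & !prev_m & next_m)
      cnt$tDD <- cnt$tDD + ws * (no & !prev_m & !next_m)
      has <- cins > 0L
      cnt$tMI <- cnt$tMI + ws * (has & prev_m)
      cnt$tII <- cnt$tII + ws * pmax(cins - 1L, 0L)
      cnt$tIM <- cnt$tIM + ws * (has & next_m)
    }
  }
  list(
    tMM = cnt$tMM / (cnt$tMM + cnt$tMI + cnt$tMD),
    tMI = cnt$tMI / (cnt$tMM + cnt$tMI + cnt$tMD),
    tMD = cnt$tMD / (cnt$tMM + cnt$tMI + cnt$tMD),
    tIM = cnt$tIM / (cnt$tIM + cnt$tII),
    tII = cnt$tII / (cnt$tIM + cnt$tII),
    tDM = cnt$tDM / (cnt$tDM + cnt$tDD),
    tDD = cnt$tDD / (cnt$tDM + cnt$tDD)
  )
}

# Numeric pieces handed to the C++ kernels. Log space (Viterbi): log2-odds
# emissions, damped log2 transitions, log2 exit probabilities. Linear space
# (scaled forward): the same quantities as odds / probabilities.
hmm_numeric <- function(hmm) {
  n <- hmm$n_match
  lem <- log2(sweep(hmm$match_emissions, 2, hmm$background, "/"))
  p_end <- 1 / (n - seq_len(n) + 1)
  damp <- log2(1 - p_end[-n])       # zero-length when n == 1
  tr <- matrix(-Inf, n, 7)
  if (n > 1) {
    i <- seq_len(n - 1)
    tr[i, 1] <- log2(hmm$transitions$tMM) + damp
    tr[i, 2] <- log2(hmm$transitions$tMI) + damp
    tr[i, 3] <- log2(hmm$transitions$tMD) + damp
    tr[i, 4] <- log2(hmm$transitions$tIM)
    tr[i, 5] <- log2(hmm$transitions$tII)
    tr[i, 6] <- log2(hmm$transitions$tDM)
    tr[i, 7] <- log2(hmm$transitions$tDD)
  }
  otr <- 2^tr
  otr[!is.finite(tr)] <- 0
  list(lem = lem, trans = tr, logend = log2(p_end),
       oem = 2^lem, otrans = otr, pend = p_end)
}

# Sequence string -> 0-based residue indices; ambiguity codes -> -1
# (scored as background, logged once).
seq_indices <- function(seq) {
  res <- seq_chars(toupper(seq))
  idx <- match(res, AA) - 1L
  if (anyNA(idx)) {
    bad <- unique(res[is.na(idx)])
    inform(paste0("Non-canonical residue(s) scored as background: ",
                  paste(bad, collapse = ", ")))
    idx[is.na(idx)] <- -1L
  }
  idx
}

#' Forward log-odds score of a sequence under a profile HMM
#'
#' Log2 odds of the sequence under the local-alignment profile HMM versus the
#' i.i.d. background model, summed over all alignments in log space (finite
#' for any input). Non-canonical residues are emitted as background.
#'
#' @param hmm A [profile_hmm].
#' @param seq Amino-acid string.
#' @return Score in bits.
#' @export
forward_score <- function(hmm, seq) {
  stopifnot(inherits(hmm, "profile_hmm"))
  if (!nchar(seq)) abort("Empty sequence.")
  num <- hmm_numeric(hmm)
  cpp_forward(num$oem, seq_indices(seq), num$otrans, num$pend)
}

#' Viterbi alignment of a sequence to a profile HMM
#'
#' Best single state path and its log2-odds score; the trace maps sequence
#' positions to match states. Viterbi never exceeds the forward score.
#'
#' @inheritParams forward_score
#' @return List with `score` (bits), `qstart`/`qend` (match-state interval),
#'   `tstart`/`tend` (sequence interval, 1-based inclusive), and `trace`
#'   (two-column matrix of aligned match-state / sequence-position pairs).
#' @export
viterbi_align <- function(hmm, seq) {
  stopifnot(inherits(hmm, "profile_hmm"))
  if (!nchar(seq)) abort("Empty sequence.")
  num <- hmm_numeric(hmm)
  cpp_viterbi(num$lem, seq_indices(seq), num$trans, num$logend)
}

#' Local profile-profile alignment by column co-emission
#'
#' Aligns the match columns of two profiles with the co-emission log-odds
#' column score `S(i, j) = log2 sum_a e_q[i, a] * e_t[j, a] / f[a]` and
#' affine gap costs, Smith-Waterman style. Symmetric for symmetric gap costs.
#'
#' @param hmm_q,hmm_t Query and target [profile_hmm] objects (must share the
#'   background).
#' @param gap_open,gap_extend Affine gap costs in bits (defaults 3 and 0.3).
#' @return List with `score` (bits), `qstart`/`qend`, `tstart`/`tend`
#'   (match-column intervals), and `pairs` (aligned column pairs).
#' @export
hmm_hmm_align <- function(hmm_q, hmm_t, gap_open = 3, gap_extend = 0.3) {
  stopifnot(inherits(hmm_q, "profile_hmm"), inherits(hmm_t, "profile_hmm"))
  S <- log2(hmm_q$match_emissions %*% t(sweep(hmm_t$match_emissions, 2,
                                              hmm_q$background, "/")))
  cpp_pp_align(S, gap_open, gap_extend)
}
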