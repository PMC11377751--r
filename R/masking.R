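# Position-specific coiled-coil propensity table (stand-in, documented).
#
# Relative propensities (ratio to background usage) per heptad position for
# the 20 residues. The values are a stand-in derived from the qualitative
# residue statistics of solved coiled coils: hydrophobic residues (L/I/V/M/A/F)
# dominate core positions a and d; charged/polar residues (E/K/Q/R, then
# A/S/N/D/T) dominate the solvent-exposed b,c,e,f,g positions; proline is
# strongly excluded everywhere and glycine/tryptophan disfavoured. All
# downstream checks are property-based (relative scores), not tied to the
# original published matrix values.
cc_propensity_table <- local({
  core <- c(A = 1.6, C = 0.35, D = 0.25, E = 0.35, F = 1.1, G = 0.15,
            H = 0.4, I = 2.3, K = 0.35, L = 3.2, M = 2.0, N = 0.4, P = 0.05,
            Q = 0.5, R = 0.4, S = 0.4, T = 0.5, V = 1.6, W = 0.35, Y = 0.5)
  surf <- c(A = 1.5, C = 0.3, D = 1.3, E = 2.5, F = 0.3, G = 0.45, H = 0.7,
            I = 0.35, K = 2.2, L = 0.35, M = 0.4, N = 1.2, P = 0.05,
            Q = 2.0, R = 1.8, S = 1.0, T = 0.9, V = 0.35, W = 0.25, Y = 0.5)
  tab <- matrix(0, nrow = 20, ncol = 7, dimnames = list(AA, letters[1:7]))
  for (p in 1:7) tab[, p] <- if (p %in% c(1, 4)) core[AA] else surf[AA]
  tab
})

# Two-Gaussian score model for the coiled-coil posterior: score distributions
# of genuine heptad-repeat windows vs globular/background windows (window 21,
# weighted). Parameters estimated once from large simulated samples of each
# class; see the methods vignette.
cc_gauss <- list(cc = c(mean = 0.68, sd = 0.10),
                 gl = c(mean = -0.12, sd = 0.17),
                 prior_gl = 30)

#' Per-residue coiled-coil probability profile
#'
#' COILS-style sliding-window scoring: each residue is scored in each of the
#' 7 heptad frames by its position-specific log propensity; the window score
#' is the (optionally weighted) mean log propensity over the window,
#' maximised over frames; each residue receives the maximum score of any
#' window covering it. The score is converted to a probability with a
#' two-Gaussian posterior (coiled-coil vs globular score distributions). The
#' weighted variant up-weights core positions a and d by 2.5.
#'
#' @param seq Amino-acid string.
#' @param window Window length, one of 14, 21, 28 (default 21).
#' @param weighted Up-weight heptad positions a/d by 2.5 (default TRUE).
#' @return Numeric vector of per-residue probabilities in `[0, 1]` (length 0
#'   with a message when the sequence is shorter than the window). Attribute
#'   `score` carries the raw per-residue window scores.
#' @examples
#' p <- coiled_coil_profile(strrep("LEALEGK", 6))
#' range(p)
#' @export
coiled_coil_profile <- function(seq, window = 21L, weighted = TRUE) {
  if (!window %in% c(14L, 21L, 28L)) abort("`window` must be 14, 21 or 28.")
  res <- seq_chars(toupper(seq))
  L <- length(res)
  if (L < window) {
    inform("Sequence shorter than window; empty coiled-coil profile.")
    out <- numeric(0)
    attr(out, "score") <- numeric(0)
    return(out)
  }
  res[!res %in% AA] <- "A"  # ambiguity codes: neutral stand-in residue
  logtab <- log(cc_propensity_table)
  w_ad <- if (weighted) 2.5 else 1
  # per-residue, per-frame log propensity and weight
  lp <- matrix(0, nrow = L, ncol = 7)
  wt <- matrix(1, nrow = L, ncol = 7)
  ridx <- match(res, AA)
  for (f in 0:6) {
    pos <- ((seq_len(L) - 1L + f) %% 7L) + 1L
    lp[, f + 1L] <- logtab[cbind(ridx, pos)]
    wt[, f + 1L][pos %in% c(1L, 4L)] <- w_ad
  }
  score <- rep(-Inf, L)
  for (start in seq_len(L - window + 1L)) {
    idx <- start:(start + window - 1L)
    # weighted mean log propensity per frame, maximised over frames
    s <- max(colSums(lp[idx, , drop = FALSE] * wt[idx, , drop = FALSE]) /
               colSums(wt[idx, , drop = FALSE]))
    cover <- score[idx] < s
    score[idx][cover] <- s
  }
  g_cc <- stats::dnorm(score, cc_gauss$cc["mean"], cc_gauss$cc["sd"])
  g_gl <- stats::dnorm(score, cc_gauss$gl["mean"], cc_gauss$gl["sd"])
  prob <- g_cc / (g_cc + cc_gauss$prior_gl * g_gl)
  prob[is.na(prob)] <- 0
  attr(prob, "score") <- score
  prob
}

#' Coiled-coil mask regions at a probability cutoff
#'
#' @inheritParams coiled_coil_profile
#' @param cutoff Probability threshold masking a residue (default 0.5).
#' @return Tibble `start`, `end`, `kind = "coiled_coil"`, `score` (maximum
#'   probability inside the region); 1-based inclusive, merged.
#' @export
coiled_coil_mask <- function(seq, window = 21L, weighted = TRUE,
                             cutoff = 0.5) {
  prob <- coiled_coil_profile(seq, window, weighted)
  runs_to_regions(prob >= cutoff, prob, kind = "coiled_coil")
}

#' Low-compositional-complexity mask by windowed Shannon entropy
#'
#' A residue is masked when the minimum Shannon entropy (base 2, over residue
#' frequencies) of any length-`window` window covering it falls below
#' `entropy_threshold`. Adjacent masked residues merge into regions; the
#' region score is its minimum covering-window entropy. Sequences shorter
#' than the window are treated as a single window.
#'
#' @param seq Amino-acid string.
#' @param window Window length (default 12).
#' @param entropy_threshold Bits (default 2.2, the SEG-convention trigger).
#' @return Tibble `start`, `end`, `kind = "low_complexity"`, `score`.
#' @examples
#' low_complexity_mask(strrep("A", 12))
#' @export
low_complexity_mask <- function(seq, window = 12L,
                                entropy_threshold = 2.2) {
  res <- seq_chars(toupper(seq))
  L <- length(res)
  if (L == 0) {
    return(tibble(start = integer(), end = integer(), kind = character(),
                  score = numeric()))
  }
  win <- min(window, L)
  n_win <- L - win + 1L
  codes <- match(res, unique(res))
  nlev <- max(codes)
  went <- vapply(seq_len(n_win), function(s) {
    p <- tabulate(codes[s:(s + win - 1L)], nlev) / win
    p <- p[p > 0]
    -sum(p * log2(p))
  }, numeric(1))
  minent <- rep(Inf, L)
  for (s in seq_len(n_win)) {
    idx <- s:(s + win - 1L)
    lower <- minent[idx] > went[s]
    minent[idx][lower] <- went[s]
  }
  runs_to_regions(minent < entropy_threshold, minent,
                  kind = "low_complexity", score_fun = min)
}

shannon_entropy <- function(res) {
  p <- table(res) / length(res)
  -sum(p * log2(p))
}

# Boolean run-length encoding into 1-based inclusive regions.
runs_to_regions <- function(mask, values, kind, score_fun = max) {
  if (!length(mask) || !any(mask)) {
    return(tibble(start = integer(), end = integer(), kind = character(),
                  score = numeric()))
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  tibble(start = starts[keep], end = ends[keep], kind = kind,
         score = vapply(keep, function(k) {
           score_fun(values[starts[k]:ends[k]])
         }, numeric(1)))
}

#' Unmasked regions of a sequence
#'
#' The complement of the union of mask regions, dropping fragments shorter
#' than `min_region_length` (logged). A fully masked sequence yields an empty
#' list of intervals and the query is reported as skipped.
#'
#' @param seq Amino-acid string (only its length is used).
#' @param masks Tibble of mask regions (`start`, `end`; e.g. row-bound
#'   [coiled_coil_mask()] and [low_complexity_mask()] output).
#' @param min_region_length Shortest searchable fragment kept (default 30).
#' @return Tibble `start`, `end`, 1-based inclusive, sorted, disjoint.
#' @export
searchable_regions <- function(seq, masks, min_region_length = 30L) {
  L <- nchar(seq)
  masked <- rep(FALSE, L)
  if (nrow(masks)) {
    check_interval(masks$start, masks$end, L)
    for (i in seq_len(nrow(masks))) masked[masks$start[i]:masks$end[i]] <- TRUE
  }
  regions <- runs_to_regions(!masked, as.numeric(!masked), kind = "searchable")
  dropped <- regions$end - regions$start + 1L < min_region_length
  if (any(dropped)) {
    inform(paste0("Dropping ", sum(dropped), " searchable fragment(s) shorter than ",
                  min_region_length, " residues."))
  }
  regions <- regions[!dropped, c("start", "end")]
  if (!nrow(regions)) {
    inform("Sequence fully masked; query skipped.")
  }
  regions
}

#' Mask a query sequence for homology search
#'
#' Convenience wrapper combining the coiled-coil and low-complexity masks and
#' the searchable-region complement.
#'
#' @inheritParams coiled_coil_profile
#' @inheritParams low_complexity_mask
#' @inheritParams searchable_regions
#' @param cc_cutoff Coiled-coil probability cutoff (default 0.5).
#' @return List with `masks` (tibble `start`,`end`,`kind`,`score`) and
#'   `regions` (searchable intervals).
#' @export
mask_sequence <- function(seq, window = 21L, weighted = TRUE,
                          cc_cutoff = 0.5, lc_window = 12L,
                          entropy_threshold = 2.2, min_region_length = 30L) {
  cc <- if (nchar(seq) >= window) {
    coiled_coil_mask(seq, window, weighted, cc_cutoff)
  } else {
    tibble(start = integer(), end = integer(), kind = character(),
           score = numeric())
  }
  lc <- low_complexity_mask(seq, lc_window, entropy_threshold)
  masks <- bind_rows(cc, lc)
  list(masks = masks,
       regions = searchable_regions(seq, masks, min_region_length))
}

#' Write mask regions as BED-like TSV
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' the writer subtracts 1 from `start` and leaves `end` as is.
#'
#' @param masks Tibble with `start`, `end`, `kind`, `score`.
#' @param seq_id Sequence identifier for the first column.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_mask_bed <- function(masks, seq_id, path) {
  bed <- data.frame(seq_id = seq_id, start = masks$start - 1L,
                    end = masks$end, kind = masks$kind, score = masks$score)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
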