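#' Decoy sequence sampler for E-value calibration
#'
#' Returns a sampler closure producing i.i.d. background-composition decoy
#' sequences whose lengths are resampled from a reference length
#' distribution (typically the search target set), matching the background
#' model of the log-odds score.
#'
#' @param lengths Integer vector of reference sequence lengths.
#' @param background Background frequencies.
#' @return Function `f(n, seed)` returning `n` decoy sequences.
#' @export
decoy_sampler <- function(lengths, background = background_frequencies()) {
  lengths <- as.integer(lengths)
  stopifnot(length(lengths) >= 1, all(lengths >= 1))
  function(n, seed) {
    with_seed_(seed, {
      len <- sample(lengths, n, replace = TRUE)
      vapply(len, function(L) chars_seq(sample_background(L, background)),
             character(1))
    })
  }
}

#' Calibrate a Gumbel E-value distribution on decoys
#'
#' Scores `n_decoys` background decoys with the query profile (Viterbi bits
#' for sequence targets, profile-profile bits for profile targets, where each
#' decoy sequence is wrapped into a single-sequence profile) and fits a
#' Gumbel (extreme-value) distribution by maximum likelihood. The E-value of
#' a later score s is `E(s) = n_db * (1 - exp(-exp(-lambda * (s - mu))))`.
#' Deterministic under `seed`.
#'
#' @param hmm Query [profile_hmm].
#' @param sampler Decoy sampler from [decoy_sampler()].
#' @param n_decoys Number of decoys (>= 200).
#' @param seed Integer seed.
#' @param mode `"sequence"` (Viterbi vs decoy sequences) or `"profile"`
#'   (profile-profile vs single-sequence decoy profiles).
#' @param n_db Effective database size; `NULL` (default) defers to search
#'   time, where it becomes the target-set size.
#' @param tail_fraction Fraction of top decoy scores used for a censored
#'   tail fit (default 0.3); 1 fits the full sample.
#' @return An `evd_params` object (`lambda`, `mu`, `n_db`, `mode`).
#' @export
calibrate_evd <- function(hmm, sampler, n_decoys = 200L, seed = 1L,
                          mode = c("sequence", "profile"), n_db = NULL,
                          tail_fraction = 0.3) {
  mode <- match.arg(mode)
  if (n_decoys < 200) abort("Calibration needs at least 200 decoys.")
  decoys <- sampler(n_decoys, seed)
  scores <- score_targets(hmm, decoys, mode)
  fit <- fit_gumbel(scores, tail_fraction = tail_fraction)
  structure(list(lambda = fit$lambda, mu = fit$mu, n_db = n_db, mode = mode),
            class = "evd_params")
}

#' @export
print.evd_params <- function(x, ...) {
  cat(sprintf("<evd_params> lambda = %.3f, mu = %.3f bits, n_db = %s (%s)\n",
              x$lambda, x$mu, x$n_db %||% "deferred", x$mode))
  invisible(x)
}

# Forward (sequence mode) or profile-profile (profile mode) bit scores of
# the query profile against a character vector of target sequences. The
# forward score is the search statistic; Viterbi supplies only alignment
# traces.
score_targets <- function(hmm, seqs, mode) {
  if (mode == "sequence") {
    num <- hmm_numeric(hmm)
    vapply(seqs, function(s) {
      cpp_forward(num$oem, seq_indices(s), num$otrans, num$pend)
    }, numeric(1), USE.NAMES = FALSE)
  } else {
    vapply(seqs, function(s) {
      t_hmm <- single_sequence_hmm(s, background = hmm$background)
      hmm_hmm_align(hmm, t_hmm)$score
    }, numeric(1), USE.NAMES = FALSE)
  }
}

# Maximum-likelihood Gumbel fit (max convention). `tail_fraction < 1`
# switches to a type-I censored fit on the upper tail: scores below the
# censoring threshold contribute only P(X < tau) to the likelihood. E-values
# live in the upper tail, so fitting there is what makes the survival
# function accurate where it is used; the full-sample fit is kept for
# clean Gumbel data.
fit_gumbel <- function(x, tail_fraction = 1) {
  if (length(unique(x)) < 2) abort("Degenerate (constant) decoy scores.")
  if (tail_fraction >= 1) return(fit_gumbel_full(x))
  tau <- stats::quantile(x, 1 - tail_fraction, names = FALSE)
  xt <- x[x > tau]
  if (length(unique(xt)) < 10) return(fit_gumbel_full(x))
  n0 <- sum(x <= tau)
  start <- fit_gumbel_full(x)
  nll <- function(par) {
    lambda <- exp(par[1]); mu <- par[2]
    z <- lambda * (xt - mu)
    ztau <- lambda * (tau - mu)
    # log F(tau) = -exp(-lambda (tau - mu))
    -(n0 * (-exp(-ztau)) + sum(log(lambda) - z - exp(-z)))
  }
  fit <- stats::optim(c(log(start$lambda), start$mu), nll,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  list(lambda = exp(fit$par[1]), mu = fit$par[2])
}

fit_gumbel_full <- function(x) {
  xbar <- mean(x)
  xmin <- min(x)
  g <- function(beta) {
    w <- exp(-(x - xmin) / beta)   # in (0, 1]; no overflow for small beta
    xbar - sum(x * w) / sum(w) - beta
  }
  s <- stats::sd(x)
  lo <- s / 50
  hi <- s * 50
  # g is decreasing in beta; bracket then solve
  while (g(hi) > 0 && hi < s * 1e4) hi <- hi * 2
  beta <- uniroot(g, c(lo, hi), tol = 1e-10)$root
  mu <- -beta * (log(mean(exp(-(x - max(x)) / beta))) - max(x) / beta)
  list(lambda = 1 / beta, mu = mu)
}

#' E-value of a bit score under calibrated parameters
#'
#' `E(s) = n_db * P(S >= s)` under the fitted Gumbel null; monotone
#' non-increasing in s.
#'
#' @param evd An `evd_params` object.
#' @param score Bit score(s).
#' @param n_db Database-size override (used when calibration deferred it).
#' @return Numeric E-value(s), >= 0.
#' @export
evalue <- function(evd, score, n_db = NULL) {
  stopifnot(inherits(evd, "evd_params"))
  nd <- n_db %||% evd$n_db %||% 1
  nd * (-expm1(-exp(-evd$lambda * (score - evd$mu))))
}

# Match-state index -> master residue coordinate; where the master is gapped
# in that match column, fall back to the nearest mapped state.
map_pos <- function(map, idx) {
  if (idx < 1 || idx > length(map)) return(NA_integer_)
  v <- map[idx]
  if (!is.na(v)) return(v)
  ok <- which(!is.na(map))
  if (!length(ok)) return(NA_integer_)
  map[ok[which.min(abs(ok - idx))]]
}

# Single-sequence profile: one match state per residue. Closed form of
# hmm_from_msa() on a one-row alignment (Henikoff weight 1; add-one-smoothed
# single-path transitions), built directly for speed.
single_sequence_hmm <- function(seq, alpha = 1,
                                background = background_frequencies(),
                                name = "single") {
  res <- seq_chars(toupper(seq))
  n <- length(res)
  em <- matrix(rep(background * alpha / (1 + alpha), each = n), n, 20,
               dimnames = list(NULL, AA))
  idx <- match(res, AA)
  ok <- which(!is.na(idx))
  em[cbind(ok, idx[ok])] <- em[cbind(ok, idx[ok])] + 1 / (1 + alpha)
  if (length(ok) < n) {   # ambiguity codes emit background
    em[setdiff(seq_len(n), ok), ] <- rep(background, each = n - length(ok))
  }
  k <- max(0L, n - 1L)
  trans <- list(tMM = rep(0.5, k), tMI = rep(0.25, k), tMD = rep(0.25, k),
                tIM = rep(0.5, k), tII = rep(0.5, k),
                tDM = rep(0.5, k), tDD = rep(0.5, k))
  profile_hmm(em, trans, background = background, name = name)
}

# Shared decoy-profile set for profile-mode calibration: single-sequence
# profiles over background decoys, reusable across query profiles.
build_decoy_profiles <- function(lengths, n, seed,
                                 background = background_frequencies()) {
  seqs <- decoy_sampler(lengths, background)(n, seed)
  lapply(seqs, single_sequence_hmm, background = background)
}

# Fit an evd_params object from already-computed decoy scores.
evd_from_scores <- function(scores, mode, n_db = NULL, tail_fraction = 0.3) {
  fit <- fit_gumbel(scores, tail_fraction = tail_fraction)
  structure(list(lambda = fit$lambda, mu = fit$mu, n_db = n_db, mode = mode),
            class = "evd_params")
}

# Profile-mode calibration against a precomputed decoy-profile set.
calibrate_profile_evd <- function(hmm, decoy_profiles, tail_fraction = 0.3) {
  scores <- vapply(decoy_profiles, function(d) hmm_hmm_align(hmm, d)$score,
                   numeric(1))
  evd_from_scores(scores, mode = "profile", tail_fraction = tail_fraction)
}

#' Search a target database with a query profile
#'
#' Scores the query profile against every target — Viterbi for sequence
#' targets, profile-profile co-emission alignment for profile targets —
#' assigns E-values from the calibrated Gumbel, and returns hits with
#' `E <= e_max` sorted ascending by E-value (ties by target id). Query
#' intervals are reported in master-sequence coordinates via the profile's
#' `match_map`.
#'
#' @param query_hmm A [profile_hmm].
#' @param targets Named character vector of sequences, or named list of
#'   [profile_hmm] objects (the family-library case).
#' @param evd Calibrated `evd_params` for this query (matching mode).
#' @param e_max E-value cutoff (default 0.01).
#' @return Tibble `query`, `target`, `q_start`, `q_end`, `t_start`, `t_end`,
#'   `bits`, `evalue`, with the alignment trace as a list column.
#' @export
hmm_search <- function(query_hmm, targets, evd, e_max = 0.01) {
  stopifnot(inherits(query_hmm, "profile_hmm"), inherits(evd, "evd_params"))
  empty <- tibble(query = character(), target = character(),
                  q_start = integer(), q_end = integer(),
                  t_start = integer(), t_end = integer(),
                  bits = numeric(), evalue = numeric(), trace = list())
  if (!length(targets)) return(empty)
  is_profile <- is.list(targets) && inherits(targets[[1]], "profile_hmm")
  ids <- names(targets) %||% sprintf("target%d", seq_along(targets))
  n_db <- length(targets)
  rows <- list()
  if (is_profile) {
    for (k in seq_along(targets)) {
      al <- hmm_hmm_align(query_hmm, targets[[k]])
      if (al$qend == 0) next
      ev <- evalue(evd, al$score, n_db = n_db)
      if (ev > e_max) next
      rows[[length(rows) + 1L]] <- tibble(
        query = query_hmm$name, target = ids[k],
        q_start = map_pos(query_hmm$match_map, al$qstart),
        q_end = map_pos(query_hmm$match_map, al$qend),
        t_start = map_pos(targets[[k]]$match_map, al$tstart),
        t_end = map_pos(targets[[k]]$match_map, al$tend),
        bits = al$score, evalue = ev, trace = list(al$pairs))
    }
  } else {
    # forward score decides significance; Viterbi traces only for the hits
    num <- hmm_numeric(query_hmm)
    bits <- vapply(targets, function(s) {
      cpp_forward(num$oem, seq_indices(s), num$otrans, num$pend)
    }, numeric(1), USE.NAMES = FALSE)
    evs <- evalue(evd, bits, n_db = n_db)
    for (k in which(evs <= e_max)) {
      al <- viterbi_align(query_hmm, targets[[k]])
      rows[[length(rows) + 1L]] <- tibble(
        query = query_hmm$name, target = ids[k],
        q_start = map_pos(query_hmm$match_map, al$qstart),
        q_end = map_pos(query_hmm$match_map, al$qend),
        t_start = al$tstart, t_end = al$tend,
        bits = bits[k], evalue = evs[k], trace = list(al$trace))
    }
  }
  hits <- bind_rows(rows)
  if (!nrow(hits)) return(empty)
  hits[order(hits$evalue, hits$target), , drop = FALSE]
}
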