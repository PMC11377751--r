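#' Build the planted-domain benchmark world
#'
#' The standard evaluation scenario for the whole pipeline: a library of
#' synthetic domain families (defaults: 8 families, 100-residue domains, 30
#' members, mean member-to-ancestor identity 0.4), a sequence database of all
#' member domains (the UniProt stand-in), positive query proteins with one
#' planted member each, and pure-decoy queries.
#'
#' @param seed Integer seed.
#' @param n_families,domain_length,n_members,identity Family settings.
#' @param queries_per_family Planted members used as positive queries
#'   (default 5, giving 40 positives at the defaults).
#' @param n_decoys Decoy queries (default 200).
#' @param linker_length Linker length flanking planted domains (default 20).
#' @return List with `library` (a [family_library]), `db` (named member
#'   sequences), `queries` (named sequences) and `truth` (named family id per
#'   query, NA for decoys).
#' @export
gm_benchmark_world <- function(seed, n_families = 8L, domain_length = 100L,
                               n_members = 30L, identity = 0.4,
                               queries_per_family = 5L, n_decoys = 200L,
                               linker_length = 20L) {
  fams <- lapply(seq_len(n_families), function(i) {
    simulate_family(family_spec(sprintf("fam%02d", i), domain_length,
                                n_members, identity,
                                seed = child_seed(seed, i)))
  })
  names(fams) <- sprintf("fam%02d", seq_len(n_families))
  lib <- family_library(lapply(fams, `[[`, "msa"))
  db <- unlist(lapply(fams, `[[`, "members"))
  names(db) <- sub("^fam[0-9]+\\.", "", names(db))
  pp <- plant_proteins(lapply(fams, function(f) {
    f$members <- f$members[seq_len(queries_per_family)]
    f
  }), n_decoys = n_decoys, linker_length = linker_length,
  seed = child_seed(seed, 99L))
  queries <- setNames(pp$sequence, pp$protein_id)
  truth <- setNames(
    vapply(pp$truth, function(t) if (nrow(t)) t$family_id else NA_character_,
           character(1)),
    pp$protein_id)
  list(library = lib, db = db, queries = queries, truth = truth)
}

#' Run the end-to-end planted-domain recovery benchmark
#'
#' Executes masking, iterative MSA building, forward profile-profile search
#' and reciprocal validation on a [gm_benchmark_world()] and scores the
#' outcome against the planted truth: sensitivity is the fraction of
#' positive queries validated with their true family; the false-positive
#' rate is the fraction of decoy queries with any validated call.
#'
#' @param seed Integer seed (drives both the world and the search).
#' @param e_max Forward and reciprocal E-value cutoff (default 0.01).
#' @param ... Passed to [gm_benchmark_world()].
#' @return One-row tibble: `seed`, `sensitivity`, `fpr`, `n_validated`,
#'   `n_forward_hits`.
#' @export
gm_benchmark <- function(seed, e_max = 0.01, ...) {
  world <- gm_benchmark_world(seed, ...)
  res <- forward_search_all(world$queries, world$library,
                            sequence_db = world$db, e_max = e_max,
                            seed = seed)
  cands <- validate_all(res, e_max = e_max, seed = seed)
  val <- cands[cands$status == "validated", , drop = FALSE]
  pos <- names(world$truth)[!is.na(world$truth)]
  dec <- names(world$truth)[is.na(world$truth)]
  tp <- unique(val$protein_id[val$protein_id %in% pos &
                                val$family_id == world$truth[val$protein_id]])
  fp <- unique(val$protein_id[val$protein_id %in% dec])
  tibble(seed = seed,
         sensitivity = length(tp) / length(pos),
         fpr = length(fp) / length(dec),
         n_validated = nrow(val),
         n_forward_hits = nrow(res$hits))
}

#' Check E-value calibration on held-out decoys
#'
#' Calibrates a family profile on background decoys and measures, on an
#' independent decoy set, the empirical probability of E-values at or below
#' a grid of thresholds; under a perfect fit the empirical probability of
#' `E <= e0` is `e0 / n_db`.
#'
#' @param seed Integer seed.
#' @param n_calibration,n_heldout Decoy counts.
#' @param decoy_length Decoy sequence length (default 1000).
#' @param e_grid E-value thresholds to audit.
#' @param tail_fraction Censoring fraction for the Gumbel fit (default 0.1).
#' @return Tibble `e0`, `expected_p`, `observed` (count), `n`, plus the
#'   binomial 95% CI bounds for the expected probability.
#' @export
gm_calibration_check <- function(seed, n_calibration = 20000L,
                                 n_heldout = 10000L, decoy_length = 1000L,
                                 e_grid = c(0.001, 0.01, 0.1),
                                 tail_fraction = 0.1) {
  fam <- simulate_family(family_spec("calib_fam", 100, 30, 0.4,
                                     seed = child_seed(seed, 1L)))
  hmm <- hmm_from_msa(fam$msa)
  samp <- decoy_sampler(decoy_length)
  evd <- calibrate_evd(hmm, samp, n_decoys = n_calibration,
                       seed = child_seed(seed, 2L),
                       tail_fraction = tail_fraction)
  held <- samp(n_heldout, child_seed(seed, 3L))
  sc <- score_targets(hmm, held, "sequence")
  ev <- evalue(evd, sc, n_db = 1)
  tibble(e0 = e_grid,
         expected_p = e_grid,
         observed = vapply(e_grid, function(e) sum(ev <= e), numeric(1)),
         n = n_heldout,
         ci_lo = qbinom(0.025, n_heldout, e_grid),
         ci_hi = qbinom(0.975, n_heldout, e_grid))
}
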