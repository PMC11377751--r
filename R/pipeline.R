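#' Build a family library from alignments
#'
#' The PFAM-like role: a named collection of family alignments and the
#' profile HMMs built from them, the target set of the forward search and the
#' seed material of reciprocal searches.
#'
#' @param msas Named list of [gm_msa] objects (or a directory of Stockholm
#'   files via `path`).
#' @param path Optional directory containing `*.sto` Stockholm alignments.
#' @param alpha Pseudocount weight for [hmm_from_msa()].
#' @return A `family_library`: named list of `list(msa, hmm)`.
#' @export
family_library <- function(msas = NULL, path = NULL, alpha = 1) {
  if (is.null(msas)) {
    files <- list.files(path, pattern = "\\.sto$", full.names = TRUE)
    msas <- lapply(files, read_stockholm)
    names(msas) <- sub("\\.sto$", "", basename(files))
  }
  if (is.null(names(msas))) abort("Family alignments must be named.")
  out <- lapply(names(msas), function(nm) {
    list(msa = msas[[nm]], hmm = hmm_from_msa(msas[[nm]], alpha = alpha,
                                              name = nm))
  })
  names(out) <- names(msas)
  structure(out, class = "family_library")
}

library_hmms <- function(lib) lapply(lib, `[[`, "hmm")

#' Iteratively build an MSA for a query region
#'
#' Iteration 0 builds a single-sequence profile from the query; each
#' iteration scores the sequence database, includes hits with
#' `E <= e_include`, realigns every included sequence to the query via its
#' Viterbi trace (master-slave: one column per query residue), and rebuilds
#' the profile. Stops at `n_iter` iterations or at a fixpoint (no new
#' sequences). The master is always row 1; included rows are never removed,
#' so deeper iteration only adds rows.
#'
#' @param query Amino-acid string (a searchable region of a query protein).
#' @param sequence_db Named character vector of database sequences.
#' @param n_iter Maximum iterations (default 3).
#' @param e_include Inclusion E-value cutoff (default 0.01).
#' @param seed Integer seed (drives decoy calibration).
#' @param alpha Pseudocount weight.
#' @param n_decoys Calibration decoys per iteration (default 200).
#' @param query_id Master row label.
#' @param min_include_coverage Minimum fraction of master residues a hit's
#'   Viterbi alignment must cover to be included (default 0.3). Hits passing
#'   the E-value cutoff on the strength of a short local segment would enter
#'   the alignment as near-empty rows and dilute the profile; the coverage
#'   guard keeps only usable alignments (the role of hhblits' `-cov`).
#' @return A [gm_msa]; single-row when nothing is included.
#' @export
iterative_msa_build <- function(query, sequence_db, n_iter = 3L,
                                e_include = 0.01, seed = 1L, alpha = 1,
                                n_decoys = 200L, query_id = "query",
                                min_include_coverage = 0.3,
                                db_idx = NULL, calib_idx = NULL) {
  L <- nchar(query)
  msa <- gm_msa(query, ids = query_id)
  if (!length(sequence_db)) return(msa)
  # pre-encoded residue indices for the database and the calibration decoys
  # (shared across iterations; callers scanning many queries pass them in)
  if (is.null(db_idx)) db_idx <- lapply(sequence_db, seq_indices)
  if (is.null(calib_idx)) {
    dseq <- decoy_sampler(nchar(sequence_db))(n_decoys, child_seed(seed, 1L))
    calib_idx <- lapply(dseq, seq_indices)
  }
  included <- character()
  for (it in seq_len(n_iter)) {
    hmm <- hmm_from_msa(msa, alpha = alpha, name = query_id)
    num <- hmm_numeric(hmm)
    evd <- evd_from_scores(
      cpp_forward_batch(num$oem, calib_idx, num$otrans, num$pend),
      mode = "sequence")
    if (e_include <= 0) break
    bits <- cpp_forward_batch(num$oem, db_idx, num$otrans, num$pend)
    evs <- evalue(evd, bits, n_db = length(sequence_db))
    hit_ids <- names(sequence_db)[evs <= e_include]
    cand_ids <- setdiff(hit_ids, c(included, query_id))
    # realign candidates and all previously included rows to the master
    realign <- function(id) {
      al <- viterbi_align(hmm, sequence_db[[id]])
      row <- rep("-", L)
      map <- hmm$match_map
      tr <- al$trace
      for (k in seq_len(nrow(tr))) {
        p <- map[tr[k, 1]]
        if (!is.na(p)) row[p] <- seq_chars(sequence_db[[id]])[tr[k, 2]]
      }
      row
    }
    new_rows <- lapply(cand_ids, realign)
    ok <- vapply(new_rows, function(r) sum(r != "-") >= min_include_coverage * L,
                 logical(1))
    new_ids <- cand_ids[ok]
    if (!length(new_ids)) break
    old_rows <- vapply(included, function(id) chars_seq(realign(id)),
                       character(1))
    included <- c(included, new_ids)
    msa <- gm_msa(c(query, old_rows,
                    vapply(new_rows[ok], chars_seq, character(1))),
                  ids = c(query_id, names(old_rows), new_ids), master = 1L)
  }
  msa
}

#' Forward search of query proteins against a family library
#'
#' The pipeline's first search step: each query is masked (coiled-coil +
#' low complexity), each searchable region seeds an iteratively built MSA and
#' profile, and the profile is scored against every library family by
#' profile-profile alignment with Gumbel-calibrated E-values. Query hit
#' intervals are reported in full-protein coordinates.
#'
#' @param queries Named character vector of query protein sequences.
#' @param library A [family_library()].
#' @param sequence_db Sequence database for MSA building (default: the
#'   queries themselves).
#' @param e_max Forward E-value cutoff (default 0.01).
#' @param e_include MSA-inclusion cutoff (default 0.01).
#' @param n_iter MSA-building iterations (default 3).
#' @param seed Integer seed.
#' @param mask Apply masking (default TRUE).
#' @param min_region_length Shortest searchable region (default 30).
#' @param n_decoys Calibration decoys (default 200).
#' @return A `gm_search` object: `hits` tibble (`query`, `family`,
#'   `q_start`, `q_end`, `t_start`, `t_end`, `bits`, `evalue`) plus the
#'   per-region query profiles/MSAs needed for reciprocal validation.
#' @export
forward_search_all <- function(queries, library, sequence_db = queries,
                               e_max = 0.01, e_include = 0.01, n_iter = 3L,
                               seed = 1L, mask = TRUE,
                               min_region_length = 30L, n_decoys = 200L) {
  stopifnot(inherits(library, "family_library"))
  lib_hmms <- library_hmms(library)
  # shared pre-encoded database + sequence-mode calibration decoys
  db_idx <- lapply(sequence_db, seq_indices)
  dseq <- decoy_sampler(nchar(sequence_db))(n_decoys, child_seed(seed, 3L))
  calib_idx <- lapply(dseq, seq_indices)
  # each library family is calibrated once against decoy query-like profiles
  # (single-sequence profiles over background residues at query lengths)
  decoys <- build_decoy_profiles(nchar(queries), n_decoys,
                                 child_seed(seed, 7L))
  lib_evds <- lapply(lib_hmms, calibrate_profile_evd, decoy_profiles = decoys)
  hit_rows <- list()
  profiles <- list()
  qn <- names(queries)
  for (qi in seq_along(queries)) {
    qid <- qn[qi]
    seqq <- queries[[qi]]
    regions <- if (mask) {
      suppressMessages(mask_sequence(seqq,
                                     min_region_length = min_region_length)$regions)
    } else {
      tibble(start = 1L, end = nchar(seqq))
    }
    if (!nrow(regions)) next
    for (r in seq_len(nrow(regions))) {
      reg <- substr(seqq, regions$start[r], regions$end[r])
      rid <- sprintf("%s|%d-%d", qid, regions$start[r], regions$end[r])
      msa <- suppressMessages(iterative_msa_build(
        reg, sequence_db, n_iter = n_iter, e_include = e_include,
        seed = child_seed(seed, qi * 13L + r), query_id = rid,
        db_idx = db_idx, calib_idx = calib_idx))
      hmm <- hmm_from_msa(msa, name = rid)
      hits <- score_vs_library(hmm, lib_hmms, lib_evds, e_max)
      profiles[[rid]] <- list(query = qid, offset = regions$start[r],
                              msa = msa, hmm = hmm)
      if (nrow(hits)) {
        hit_rows[[rid]] <- tibble(
          query = qid, region = rid, family = hits$target,
          q_start = hits$q_start + regions$start[r] - 1L,
          q_end = hits$q_end + regions$start[r] - 1L,
          t_start = hits$t_start, t_end = hits$t_end,
          bits = hits$bits, evalue = hits$evalue)
      }
    }
  }
  hits <- if (length(hit_rows)) bind_rows(hit_rows) else
    tibble(query = character(), region = character(), family = character(),
           q_start = integer(), q_end = integer(), t_start = integer(),
           t_end = integer(), bits = numeric(), evalue = numeric())
  hits <- hits[order(hits$evalue, hits$query, hits$family), , drop = FALSE]
  structure(list(hits = hits, profiles = profiles, library = library,
                 lib_evds = lib_evds, seed = seed), class = "gm_search")
}

# Profile-profile scoring of one query profile against the calibrated family
# library: E-values come from each family's own decoy calibration.
score_vs_library <- function(hmm, lib_hmms, lib_evds, e_max) {
  n_db <- length(lib_hmms)
  rows <- list()
  for (k in seq_along(lib_hmms)) {
    al <- hmm_hmm_align(hmm, lib_hmms[[k]])
    if (al$qend == 0) next
    ev <- evalue(lib_evds[[k]], al$score, n_db = n_db)
    if (ev > e_max) next
    rows[[length(rows) + 1L]] <- tibble(
      target = names(lib_hmms)[k],
      q_start = map_pos(hmm$match_map, al$qstart),
      q_end = map_pos(hmm$match_map, al$qend),
      t_start = map_pos(lib_hmms[[k]]$match_map, al$tstart),
      t_end = map_pos(lib_hmms[[k]]$match_map, al$tend),
      bits = al$score, evalue = ev)
  }
  if (!length(rows)) {
    return(tibble(target = character(), q_start = integer(),
                  q_end = integer(), t_start = integer(), t_end = integer(),
                  bits = numeric(), evalue = numeric()))
  }
  out <- bind_rows(rows)
  out[order(out$evalue, out$target), , drop = FALSE]
}

#' @export
print.gm_search <- function(x, ...) {
  cat("<gm_search> ", nrow(x$hits), " forward hits over ",
      length(x$profiles), " query regions\n", sep = "")
  invisible(x)
}

#' Reciprocal validation of a forward hit
#'
#' Seeds a profile from the hit's target-family alignment region and searches
#' it back against the query-region profile collection. The candidate is
#' `validated` iff (i) the reciprocal search recovers the original query
#' region with `E <= e_max`, (ii) the reciprocal alignment covers at least
#' `min_coverage` of the forward query interval, and (iii) the query's best
#' forward family assignment is the hit family; otherwise `forward_only`.
#'
#' @param hit One row of `gm_search$hits`.
#' @param search A `gm_search` object (supplies the query profiles and the
#'   forward hit table).
#' @param e_max Reciprocal E-value cutoff (default 0.01, mirroring the
#'   MSA-inclusion cutoff).
#' @param min_coverage Minimum fraction of the forward query interval the
#'   reciprocal hit must cover (default 0.5).
#' @param seed Integer seed for reciprocal calibration.
#' @param n_decoys Calibration decoys.
#' @param decoy_profiles Optional precomputed decoy-profile list (shared
#'   across hits by [validate_all()]).
#' @return One-row tibble: `protein_id`, `start`, `end`, `family_id`,
#'   `forward_bits`, `forward_evalue`, `reciprocal_bits`,
#'   `reciprocal_evalue`, `status`.
#' @export
reciprocal_validate <- function(hit, search, e_max = 0.01,
                                min_coverage = 0.5, seed = 1L,
                                n_decoys = 200L, decoy_profiles = NULL) {
  stopifnot(inherits(search, "gm_search"))
  fam <- search$library[[hit$family]]
  seed_hmm <- family_region_hmm(fam, hit$t_start, hit$t_end, hit$family)
  query_hmms <- lapply(search$profiles, `[[`, "hmm")
  if (is.null(decoy_profiles)) {
    q_lens <- vapply(query_hmms, `[[`, integer(1), "n_match")
    decoy_profiles <- build_decoy_profiles(q_lens, n_decoys,
                                           child_seed(seed, 101L))
  }
  evd <- calibrate_profile_evd(seed_hmm, decoy_profiles)
  back <- hmm_search(seed_hmm, query_hmms, evd, e_max = e_max)
  status <- "forward_only"
  rec_bits <- NA_real_
  rec_e <- NA_real_
  mine <- back[back$target == hit$region, , drop = FALSE]
  if (nrow(mine)) {
    rec_bits <- mine$bits[1]
    rec_e <- mine$evalue[1]
    offset <- search$profiles[[hit$region]]$offset
    cov_start <- max(hit$q_start, mine$t_start[1] + offset - 1L)
    cov_end <- min(hit$q_end, mine$t_end[1] + offset - 1L)
    coverage <- max(0L, cov_end - cov_start + 1L) /
      (hit$q_end - hit$q_start + 1L)
    fwd <- search$hits[search$hits$region == hit$region, , drop = FALSE]
    best_family <- fwd$family[which.min(fwd$evalue)]
    if (coverage >= min_coverage && best_family == hit$family) {
      status <- "validated"
    }
  }
  tibble(protein_id = hit$query, start = hit$q_start, end = hit$q_end,
         family_id = hit$family, region = hit$region,
         forward_bits = hit$bits, forward_evalue = hit$evalue,
         reciprocal_bits = rec_bits, reciprocal_evalue = rec_e,
         status = status)
}

# Profile seeded from the family alignment restricted to a master-coordinate
# interval (the region matched by the forward hit).
family_region_hmm <- function(fam, t_start, t_end, name) {
  msa <- fam$msa
  m <- msa_matrix(msa)
  master_pos <- cumsum(m[msa$master, ] != "-")
  master_pos[m[msa$master, ] == "-"] <- NA
  keep <- which(!is.na(master_pos) & master_pos >= t_start &
                  master_pos <= t_end)
  if (length(keep) < 5) keep <- seq_len(ncol(m))  # degenerate hit: whole family
  rows <- apply(m[, keep, drop = FALSE], 1, chars_seq)
  hmm_from_msa(gm_msa(rows, ids = msa$ids, master = msa$master), name = name)
}

#' Validate every forward hit of a search
#'
#' Runs [reciprocal_validate()] on the best forward hit of each query region
#' and returns the candidate-domain catalog.
#'
#' @inheritParams reciprocal_validate
#' @param provenance Optional named character vector mapping query protein
#'   ids to a provenance flag (GO / PPI / co-expression).
#' @return Tibble of candidate domains (one per query region with a forward
#'   hit).
#' @export
validate_all <- function(search, e_max = 0.01, min_coverage = 0.5,
                         seed = 1L, n_decoys = 200L, provenance = NULL) {
  hits <- search$hits
  if (!nrow(hits)) {
    return(tibble(protein_id = character(), start = integer(),
                  end = integer(), family_id = character(),
                  region = character(), forward_bits = numeric(),
                  forward_evalue = numeric(), reciprocal_bits = numeric(),
                  reciprocal_evalue = numeric(), status = character(),
                  provenance = character()))
  }
  best <- hits[order(hits$evalue), , drop = FALSE]
  best <- best[!duplicated(best$region), , drop = FALSE]
  q_lens <- vapply(search$profiles, function(p) p$hmm$n_match, integer(1))
  decoys <- build_decoy_profiles(q_lens, n_decoys, child_seed(seed, 101L))
  out <- bind_rows(lapply(seq_len(nrow(best)), function(i) {
    reciprocal_validate(best[i, ], search, e_max = e_max,
                        min_coverage = min_coverage,
                        seed = child_seed(seed, i), n_decoys = n_decoys,
                        decoy_profiles = decoys)
  }))
  out$provenance <- if (is.null(provenance)) NA_character_ else
    unname(provenance[out$protein_id])
  arrange(out, .data$protein_id, .data$start)
}

#' Curate a candidate's alignment and re-evaluate it
#'
#' The deterministic three-step curation standing in for manual MSA
#' inspection: problem-region elimination (fragmentary rows, thin columns),
#' diversity filter to 30 rows, then insert removal (master-slave); the
#' profile is rebuilt and the forward and reciprocal searches re-run.
#' Fragment rows are removed before the diversity filter because maximin
#' diversity would otherwise preferentially retain them (a fragment shares
#' few aligned columns with anything, so it always looks maximally
#' divergent). On clean alignments the curated pipeline re-detects the
#' family found before curation (the recovery property). A single-row
#' alignment passes through unchanged.
#'
#' @param candidate One-row candidate tibble (from [validate_all()]).
#' @param search The originating `gm_search`.
#' @param e_max,min_coverage,seed,n_decoys As in [reciprocal_validate()].
#' @param n_keep Diversity-filter capacity (default 30).
#' @param min_col_coverage,min_seq_residues Problem-region thresholds.
#' @return Re-evaluated one-row candidate tibble (status may change;
#'   `rejected` when curation empties the alignment).
#' @export
curate_and_retry <- function(candidate, search, e_max = 0.01,
                             min_coverage = 0.5, seed = 1L, n_decoys = 200L,
                             n_keep = 30L, min_col_coverage = 0.5,
                             min_seq_residues = 10L) {
  prof <- search$profiles[[candidate$region]]
  msa <- prof$msa
  if (msa_nrow(msa) > 1) {
    msa <- tryCatch(
      suppressMessages(drop_problem_regions(msa, min_col_coverage,
                                            min_seq_residues)),
      error = function(e) NULL)
    if (!is.null(msa)) {
      msa <- msa_diff_filter(msa, n_keep = n_keep)
      msa <- remove_inserts(msa)
    }
    if (is.null(msa)) {
      out <- candidate
      out$status <- "rejected"
      return(out)
    }
  }
  hmm <- hmm_from_msa(msa, name = candidate$region)
  lib_hmms <- library_hmms(search$library)
  lib_evds <- search$lib_evds
  if (is.null(lib_evds)) {
    decoys <- build_decoy_profiles(rep(hmm$n_match, 4L), n_decoys,
                                   child_seed(seed, 11L))
    lib_evds <- lapply(lib_hmms, calibrate_profile_evd,
                       decoy_profiles = decoys)
  }
  hits <- score_vs_library(hmm, lib_hmms, lib_evds, e_max)
  if (!nrow(hits)) {
    out <- candidate
    out$status <- "forward_only"
    out$forward_bits <- NA_real_
    out$forward_evalue <- NA_real_
    return(out)
  }
  # refreshed search context for the curated profile
  search2 <- search
  search2$profiles[[candidate$region]]$msa <- msa
  search2$profiles[[candidate$region]]$hmm <- hmm
  offset <- prof$offset
  new_hits <- tibble(query = candidate$protein_id, region = candidate$region,
                     family = hits$target,
                     q_start = hits$q_start + offset - 1L,
                     q_end = hits$q_end + offset - 1L,
                     t_start = hits$t_start, t_end = hits$t_end,
                     bits = hits$bits, evalue = hits$evalue)
  search2$hits <- bind_rows(
    search$hits[search$hits$region != candidate$region, , drop = FALSE],
    new_hits)
  reciprocal_validate(new_hits[1, ], search2, e_max = e_max,
                      min_coverage = min_coverage,
                      seed = child_seed(seed, 12L), n_decoys = n_decoys)
}

#' Candidate catalog report
#'
#' Deterministically ordered summary of a candidate table: per-family and
#' per-provenance counts, the status breakdown, the per-stage attrition
#' funnel, and all candidate records. Round-trips through JSON.
#'
#' @param candidates Candidate tibble (e.g. from [validate_all()]).
#' @param attrition Optional attrition tibble (`stage`, `n_records`).
#' @return A `gm_report` list.
#' @export
catalog_report <- function(candidates, attrition = NULL) {
  candidates <- as_tibble(candidates)
  status_counts <- as.list(table(candidates$status))
  fam_counts <- as.list(table(candidates$family_id))
  prov_counts <- as.list(table(candidates$provenance))
  sort_by_name <- function(x) if (length(x)) x[order(names(x))] else list()
  structure(list(
    n_candidates = nrow(candidates),
    status_counts = if (length(status_counts)) status_counts else list(),
    family_counts = sort_by_name(fam_counts),
    provenance_counts = sort_by_name(prov_counts),
    attrition = if (is.null(attrition)) list() else
      as.list(setNames(attrition$n_records, attrition$stage)),
    candidates = candidates[order(candidates$protein_id, candidates$start), ,
                            drop = FALSE]
  ), class = "gm_report")
}

#' @export
print.gm_report <- function(x, ...) {
  cat("<gm_report> ", x$n_candidates, " candidates; status: ",
      paste(names(x$status_counts), unlist(x$status_counts),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write / read a catalog report as JSON
#' @param report A `gm_report`.
#' @param path JSON path.
#' @return [read_report()] returns the `gm_report`.
#' @export
write_report <- function(report, path) {
  out <- report
  out$candidates <- as.data.frame(out$candidates)
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$candidates <- as_tibble(x$candidates)
  x$status_counts <- as.list(x$status_counts)
  x$family_counts <- as.list(x$family_counts)
  x$provenance_counts <- as.list(x$provenance_counts)
  x$attrition <- as.list(x$attrition)
  structure(x, class = "gm_report")
}
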