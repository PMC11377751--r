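#' DDR pair-asymmetry filter for interaction records
#'
#' Keeps exactly the interaction pairs in which one side is annotated with DNA
#' repair (GO:0006281) while the other side carries neither GO:0006281 nor
#' GO:0006974, and records the DDR-naive partner as the candidate. Pairs where
#' both or neither side qualify are dropped, as are pairs whose naive side is
#' annotated with GO:0006974 only. Annotations are expected to be propagated
#' already (see [propagate_interest_terms()]).
#'
#' @param records Data frame with columns `protein_a`, `protein_b` (and any
#'   other columns, which are carried through).
#' @param annotations Propagated annotation data frame `protein_id`, `term_id`.
#' @return Tibble of surviving records with an added `candidate` column (the
#'   DDR-naive side).
#' @export
filter_ddr_asymmetry <- function(records, annotations) {
  records <- as_tibble(records)
  repair <- unique(annotations$protein_id[annotations$term_id == ddr_terms()[1]])
  ddr_any <- unique(annotations$protein_id[annotations$term_id %in% ddr_terms()])
  a_rep <- records$protein_a %in% repair
  b_rep <- records$protein_b %in% repair
  a_ddr <- records$protein_a %in% ddr_any
  b_ddr <- records$protein_b %in% ddr_any
  keep_ab <- a_rep & !b_ddr   # a is the repair side, b the candidate
  keep_ba <- b_rep & !a_ddr
  out <- records[keep_ab | keep_ba, , drop = FALSE]
  out$candidate <- ifelse(keep_ab[keep_ab | keep_ba],
                          out$protein_b, out$protein_a)
  out
}

#' Experimental-evidence filter
#'
#' Keeps records that (i) carry at least a piece of experimental evidence and
#' (ii) have at least `min_publications` associated publications containing
#' experimental evidence. The two conditions are separate predicates ANDed.
#'
#' @param records Data frame with `evidence_types` (list column of character
#'   vectors) and `n_publications_experimental`.
#' @param min_publications Publication threshold (default 2).
#' @return Tibble of surviving records.
#' @export
filter_evidence <- function(records, min_publications = 2L) {
  records <- as_tibble(records)
  has_exp <- vapply(records$evidence_types,
                    function(e) "experimental" %in% e, logical(1))
  records[has_exp & records$n_publications_experimental >= min_publications, ,
          drop = FALSE]
}

#' Housekeeping / contaminant exclusion filter
#'
#' Drops pairs whose DDR-naive candidate appears in the housekeeping list or
#' in the recurrent-contaminant list, and returns both the surviving records
#' and the deduplicated candidate list.
#'
#' @param records Data frame with a `candidate` column (from
#'   [filter_ddr_asymmetry()]).
#' @param housekeeping_ids,contaminant_ids Character vectors of excluded ids.
#' @param provenance Provenance flag for the candidate list
#'   (default `"PPI-derived"`).
#' @return List with `records` (surviving rows) and `candidates` (tibble
#'   `protein_id`, `provenance`).
#' @export
filter_lists <- function(records, housekeeping_ids = character(),
                         contaminant_ids = character(),
                         provenance = "PPI-derived") {
  records <- as_tibble(records)
  if (!"candidate" %in% names(records)) {
    abort("`records` must carry a `candidate` column; run the asymmetry filter first.")
  }
  drop <- records$candidate %in% c(housekeeping_ids, contaminant_ids)
  kept <- records[!drop, , drop = FALSE]
  list(records = kept,
       candidates = tibble(protein_id = sort(unique(kept$candidate)),
                           provenance = provenance))
}

#' Full interaction-candidate selection with per-stage attrition
#'
#' Runs the asymmetry, evidence, and list filters in that fixed order and
#' reports how many records survive each stage (the attrition funnel). The
#' final candidate set is order-invariant; the fixed order exists only for
#' reproducible reporting. Duplicate pairs are canonicalised by sorted id
#' before counting.
#'
#' @inheritParams filter_ddr_asymmetry
#' @inheritParams filter_evidence
#' @inheritParams filter_lists
#' @return List with `candidates`, `records`, and `attrition` (tibble
#'   `stage`, `n_records`).
#' @export
ppi_candidates <- function(records, annotations,
                           housekeeping_ids = character(),
                           contaminant_ids = character(),
                           min_publications = 2L) {
  records <- as_tibble(records)
  key <- ifelse(records$protein_a < records$protein_b,
                paste(records$protein_a, records$protein_b),
                paste(records$protein_b, records$protein_a))
  records <- records[!duplicated(key), , drop = FALSE]
  funnel <- tibble(stage = "input", n_records = nrow(records))
  s1 <- filter_ddr_asymmetry(records, annotations)
  funnel <- bind_rows(funnel, tibble(stage = "ddr_asymmetry", n_records = nrow(s1)))
  s2 <- filter_evidence(s1, min_publications)
  funnel <- bind_rows(funnel, tibble(stage = "evidence", n_records = nrow(s2)))
  s3 <- filter_lists(s2, housekeeping_ids, contaminant_ids)
  funnel <- bind_rows(funnel, tibble(stage = "exclusion_lists",
                                     n_records = nrow(s3$records)))
  list(candidates = s3$candidates, records = s3$records, attrition = funnel)
}
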