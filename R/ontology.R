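#' Transitive descendants of a GO term
#'
#' All terms reachable from `term` by following is_a edges downward
#' (children, grandchildren, ...), excluding the term itself.
#'
#' @param dag A [go_dag].
#' @param term Term id present in the DAG.
#' @return Character vector of descendant term ids (possibly empty).
#' @examples
#' d <- go_dag(data.frame(term_id = c("b", "c"), parent_id = c("a", "b")))
#' go_descendants(d, "a")
#' @export
go_descendants <- function(dag, term) {
  stopifnot(inherits(dag, "go_dag"))
  if (!term %in% dag$terms) abort(paste0("Unknown term: ", term))
  children <- split(dag$edges$term_id, dag$edges$parent_id)
  seen <- character()
  frontier <- term
  while (length(frontier)) {
    kids <- unique(unlist(children[frontier], use.names = FALSE))
    kids <- setdiff(kids, seen)
    seen <- c(seen, kids)
    frontier <- kids
  }
  setdiff(seen, term)
}

#' Propagate terms of interest over child annotations
#'
#' For each term of interest t, any protein directly annotated with a proper
#' descendant of t gains t itself. Nothing else changes; the operation is
#' idempotent and never removes annotations. This is the child-term
#' propagation used before the DDR pair-asymmetry filter.
#'
#' @param annotations Data frame `protein_id`, `term_id` of direct annotations.
#' @param dag A [go_dag].
#' @param terms Terms to propagate (default: all four terms of interest).
#' @return Tibble of annotations including the propagated rows (deduplicated).
#' @export
propagate_interest_terms <- function(annotations, dag,
                                     terms = terms_of_interest()) {
  annotations <- as_tibble(annotations)
  terms <- intersect(unname(terms), dag$terms)
  extra <- list()
  for (t in terms) {
    desc <- go_descendants(dag, t)
    hit <- unique(annotations$protein_id[annotations$term_id %in% desc])
    if (length(hit)) {
      extra[[t]] <- tibble(protein_id = hit, term_id = t)
    }
  }
  distinct(bind_rows(c(list(annotations), extra)))
}

#' Compile the GO-derived genome-maintenance candidate set
#'
#' Pools, across species, every protein annotated (after child-term
#' propagation) with any of the terms of interest, deduplicating by protein
#' id. Output order is by protein id, so the result is invariant to the order
#' in which species are supplied.
#'
#' @param annotation_sets Named list of per-species annotation data frames
#'   (`protein_id`, `term_id`); names are species labels.
#' @param dag A [go_dag] shared by all species.
#' @param terms Terms of interest (default [terms_of_interest()]).
#' @param propagate Apply [propagate_interest_terms()] first (default TRUE).
#' @return Tibble `protein_id`, `species` (comma-joined when a protein id
#'   occurs in several lists), `provenance = "GO-compiled"`.
#' @export
compile_gm_set <- function(annotation_sets, dag, terms = terms_of_interest(),
                           propagate = TRUE) {
  if (!length(annotation_sets)) abort("Supply at least one species.")
  if (is.null(names(annotation_sets))) {
    names(annotation_sets) <- sprintf("species_%d", seq_along(annotation_sets))
  }
  terms <- unname(terms)
  per <- lapply(names(annotation_sets), function(sp) {
    ann <- as_tibble(annotation_sets[[sp]])
    if (propagate) ann <- propagate_interest_terms(ann, dag, terms)
    hit <- unique(ann$protein_id[ann$term_id %in% terms])
    if (!length(hit)) return(NULL)
    tibble(protein_id = hit, species = sp)
  })
  out <- bind_rows(per)
  if (!nrow(out)) {
    return(tibble(protein_id = character(), species = character(),
                  provenance = character()))
  }
  out <- out[order(out$protein_id, out$species), ]
  out <- summarise(group_by(out, .data$protein_id),
                   species = paste(sort(unique(.data$species)), collapse = ","),
                   .groups = "drop")
  out$provenance <- "GO-compiled"
  out[order(out$protein_id), ]
}
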