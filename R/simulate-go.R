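#' The four genome-maintenance GO terms of interest
#'
#' The candidate universe is compiled from four pooled GO terms: DNA repair
#' (GO:0006281), cellular response to DNA damage stimulus (GO:0006974),
#' cytokinesis (GO:0000910) and mitotic cell cycle (GO:0000278). The first two
#' define the DDR annotation used by the pair-asymmetry filter.
#'
#' @param terms Optional replacement character vector (configurable set).
#' @return Named character vector of term ids.
#' @examples
#' terms_of_interest()
#' @export
terms_of_interest <- function(terms = NULL) {
  if (!is.null(terms)) return(terms)
  c(dna_repair = "GO:0006281",
    dna_damage_response = "GO:0006974",
    cytokinesis = "GO:0000910",
    mitotic_cell_cycle = "GO:0000278")
}

#' DDR terms (DNA repair + DNA damage response)
#' @return Character vector of the two DDR term ids.
#' @export
ddr_terms <- function() unname(terms_of_interest()[c("dna_repair", "dna_damage_response")])

#' Construct a GO DAG object from an edge table
#'
#' @param edges Data frame with columns `term_id`, `parent_id` (is_a edges).
#'   Terms appearing only as parents are added to the term set; a root has no
#'   parent row.
#' @param terms Optional explicit term universe.
#' @return A `go_dag` object (list with `terms` and `edges` tibble). The
#'   constructor verifies acyclicity and referential integrity.
#' @export
go_dag <- function(edges, terms = NULL) {
  edges <- as_tibble(edges)[, c("term_id", "parent_id")]
  terms <- unique(c(terms, edges$term_id, edges$parent_id))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$term_id, to = edges$parent_id),
    directed = TRUE, vertices = terms)
  if (!igraph::is_dag(g)) abort("GO edge table contains a cycle.")
  structure(list(terms = terms, edges = edges), class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat("<go_dag> ", length(x$terms), " terms, ", nrow(x$edges), " is_a edges\n",
      sep = "")
  invisible(x)
}

#' Simulate a GO DAG and per-protein annotations
#'
#' Builds a rooted DAG in which the four terms of interest hang off the root
#' and each carries a subtree of child terms down to `dag_depth` levels below
#' the root (`dag_depth = 1` leaves the terms of interest childless). An
#' occasional extra parent edge between sibling subtree levels makes the
#' structure a genuine DAG rather than a tree; edges always point from deeper
#' to shallower levels, so acyclicity holds by construction. Proteins are then
#' annotated according to `annotation_rules`.
#'
#' @param dag_depth Levels below the root (>= 1).
#' @param proteins Character vector of protein ids.
#' @param annotation_rules Data frame with columns `protein_id`, `mode`, and
#'   `term`: `mode = "direct"` annotates the protein with the term-of-interest
#'   named in `term` itself, `mode = "child"` with a random proper descendant
#'   of it (only available for `dag_depth >= 2`), `mode = "none"` with a
#'   random term outside every interest subtree.
#' @param seed Integer seed.
#' @param branching Children per term per level (default 2).
#' @return List with `dag` (a [go_dag]) and `annotations` (tibble
#'   `protein_id`, `term_id` of direct annotations).
#' @examples
#' rules <- data.frame(protein_id = "p1", mode = "child", term = "GO:0006281")
#' sim <- simulate_go(dag_depth = 2, proteins = "p1",
#'                    annotation_rules = rules, seed = 1)
#' @export
simulate_go <- function(dag_depth, proteins, annotation_rules, seed = 1L,
                        branching = 2L) {
  if (dag_depth < 1) abort("`dag_depth` must be >= 1.")
  rules <- as_tibble(annotation_rules)
  toi <- terms_of_interest()
  with_seed_(seed, {
    root <- "GO:0000001"
    edges <- tibble(term_id = unname(toi), parent_id = root)
    # free-standing background branch for "none" annotations
    bg_terms <- sprintf("GO:9%06d", seq_len(6))
    edges <- bind_rows(edges, tibble(term_id = bg_terms, parent_id = root))
    level <- list(unname(toi))
    counter <- 0L
    if (dag_depth >= 2) {
      for (d in 2:dag_depth) {
        prev <- level[[d - 1L]]
        kids <- character()
        for (p in prev) {
          ch <- sprintf("GO:%07d", 1000L + counter + seq_len(branching))
          counter <- counter + branching
          edges <- bind_rows(edges, tibble(term_id = ch, parent_id = p))
          # occasional second parent within the previous level (DAG, not tree)
          if (length(prev) > 1 && runif(1) < 0.2) {
            other <- sample(setdiff(prev, p), 1)
            edges <- bind_rows(edges,
                               tibble(term_id = ch[1], parent_id = other))
          }
          kids <- c(kids, ch)
        }
        level[[d]] <- kids
      }
    }
    dag <- go_dag(edges)
    desc <- lapply(unname(toi), function(t) go_descendants(dag, t))
    names(desc) <- unname(toi)
    ann <- list()
    for (i in seq_len(nrow(rules))) {
      r <- rules[i, ]
      term <- switch(r$mode,
        direct = r$term,
        child = {
          d <- desc[[r$term]]
          if (!length(d)) abort("`mode = \"child\"` needs `dag_depth >= 2`.")
          sample(d, 1)
        },
        none = sample(bg_terms, 1),
        abort(paste0("Unknown annotation mode: ", r$mode)))
      ann[[i]] <- tibble(protein_id = r$protein_id, term_id = term)
    }
    list(dag = dag,
         annotations = if (length(ann)) bind_rows(ann) else
           tibble(protein_id = character(), term_id = character()))
  })
}
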