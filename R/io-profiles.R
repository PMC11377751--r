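#' Write / read a profile HMM as plain text
#'
#' A simple documented text format modelled on HMMER's: a header with the
#' profile name, match-state count and background frequencies, then one
#' `MATCH` line per state with the 20 emission probabilities, one `MAP` line
#' with the master-coordinate map, and seven `TRANS` lines with the
#' per-state transition probabilities. Probabilities are written in full
#' double precision, so profiles round-trip exactly.
#'
#' @param hmm A [profile_hmm].
#' @param path Output path.
#' @return Invisibly, the path. [read_profile_hmm()] returns the
#'   [profile_hmm].
#' @export
write_profile_hmm <- function(hmm, path) {
  stopifnot(inherits(hmm, "profile_hmm"))
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) paste(formatC(x, format = "g", digits = 17),
                           collapse = " ")
  writeLines(c("GMSCOUT-HMM 1.0",
               paste("NAME", hmm$name),
               paste("NMATCH", hmm$n_match),
               paste("BACKGROUND", num(hmm$background)),
               paste("MAP", paste(hmm$match_map, collapse = " "))), con)
  for (i in seq_len(hmm$n_match)) {
    writeLines(paste("MATCH", i, num(hmm$match_emissions[i, ])), con)
  }
  for (nm in c("tMM", "tMI", "tMD", "tIM", "tII", "tDM", "tDD")) {
    writeLines(paste("TRANS", nm, num(hmm$transitions[[nm]])), con)
  }
  invisible(path)
}

#' @rdname write_profile_hmm
#' @export
read_profile_hmm <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "GMSCOUT-HMM")) {
    abort("Not a gmscout profile file.")
  }
  fields <- strsplit(lines, "\\s+")
  key <- vapply(fields, `[[`, character(1), 1)
  grab <- function(k) fields[[which(key == k)[1]]][-1]
  name <- paste(grab("NAME"), collapse = " ")
  n <- as.integer(grab("NMATCH"))
  background <- setNames(as.numeric(grab("BACKGROUND")), AA)
  map <- suppressWarnings(as.integer(grab("MAP")))
  em <- matrix(0, n, 20, dimnames = list(NULL, AA))
  for (idx in which(key == "MATCH")) {
    v <- fields[[idx]][-1]
    em[as.integer(v[1]), ] <- as.numeric(v[-1])
  }
  trans <- list()
  for (idx in which(key == "TRANS")) {
    v <- fields[[idx]][-1]
    trans[[v[1]]] <- as.numeric(v[-1])
  }
  if (n == 1) {
    trans <- lapply(setNames(nm = c("tMM", "tMI", "tMD", "tIM", "tII",
                                    "tDM", "tDD")),
                    function(nm) numeric(0))
  }
  profile_hmm(em, trans, background = background, name = name,
              match_map = map)
}

#' Write a simulated world to disk
#'
#' Serialises a simulation as plain-text files: planted proteins as FASTA,
#' true family alignments as Stockholm, truth intervals and planted features
#' as TSV (1-based inclusive), and a JSON manifest tying the pieces
#' together.
#'
#' @param proteins Tibble from [plant_proteins()].
#' @param families List of [simulate_family()] results (optional).
#' @param outdir Output directory (created if needed).
#' @param seed The seed used, recorded in the manifest.
#' @return Invisibly, the manifest path.
#' @export
write_simulation <- function(proteins, families = list(), outdir,
                             seed = NA_integer_) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(setNames(proteins$sequence, proteins$protein_id),
              file.path(outdir, "proteins.fasta"))
  truth <- bind_rows(lapply(seq_len(nrow(proteins)), function(i) {
    t <- proteins$truth[[i]]
    if (!nrow(t)) return(NULL)
    bind_cols(tibble(protein_id = proteins$protein_id[i]), t)
  }))
  if (is.null(truth) || !nrow(truth)) {
    truth <- tibble(protein_id = character(), family_id = character(),
                    start = integer(), end = integer())
  }
  write.table(truth, file.path(outdir, "truth_intervals.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  feats <- bind_rows(lapply(seq_len(nrow(proteins)), function(i) {
    f <- proteins$features[[i]]
    if (!nrow(f)) return(NULL)
    bind_cols(tibble(protein_id = proteins$protein_id[i]), f)
  }))
  if (is.null(feats) || !nrow(feats)) {
    feats <- tibble(protein_id = character(), kind = character(),
                    start = integer(), end = integer())
  }
  write.table(feats, file.path(outdir, "planted_features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  fam_files <- character()
  for (nm in names(families)) {
    f <- file.path(outdir, paste0(nm, ".sto"))
    write_stockholm(families[[nm]]$msa, f)
    fam_files <- c(fam_files, basename(f))
  }
  manifest <- list(seed = seed,
                   n_proteins = nrow(proteins),
                   proteins = "proteins.fasta",
                   truth_intervals = "truth_intervals.tsv",
                   planted_features = "planted_features.tsv",
                   family_alignments = as.list(fam_files))
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}
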