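#' Specify a synthetic protein domain family
#'
#' A family spec fixes everything needed to simulate one homologous domain
#' family: an ancestor length, the number of members, the target mean
#' member-to-ancestor identity, an indel rate, and a seed. Members are derived
#' from a random ancestor by i.i.d. per-site substitution and geometric-length
#' indels, which is sufficient to control divergence without tree-aware
#' evolution (a deliberate non-goal).
#'
#' @param family_id Character label.
#' @param domain_length Ancestor length in residues (>= 10).
#' @param n_members Number of member sequences (>= 2).
#' @param target_identity Target mean member-to-ancestor identity, in (0, 1].
#'   Each site is substituted with probability `1 - target_identity`, the
#'   replacement drawn from the background (so the realised identity is
#'   slightly above the target by the back-substitution mass
#'   `(1 - t) * f_same`).
#' @param indel_rate Expected indel events per site (>= 0).
#' @param seed Integer seed; identical specs give identical families.
#' @return A `family_spec` object (validated list).
#' @examples
#' family_spec("famA", domain_length = 100, n_members = 30,
#'             target_identity = 0.4, seed = 1)
#' @export
family_spec <- function(family_id, domain_length, n_members,
                        target_identity, indel_rate = 0, seed = 1L) {
  if (domain_length < 10) abort("`domain_length` must be >= 10.")
  if (n_members < 2) abort("`n_members` must be >= 2.")
  if (target_identity <= 0 || target_identity > 1) {
    abort("`target_identity` must lie in (0, 1]; 0 is rejected.")
  }
  if (indel_rate < 0) abort("`indel_rate` must be >= 0.")
  structure(
    list(family_id = as.character(family_id),
         domain_length = as.integer(domain_length),
         n_members = as.integer(n_members),
         target_identity = as.numeric(target_identity),
         indel_rate = as.numeric(indel_rate),
         seed = as.integer(seed)),
    class = "family_spec"
  )
}

#' Simulate a homologous domain family with its true alignment
#'
#' Draws a random ancestor from the background composition and derives each
#' member by per-site substitution (probability `1 - target_identity`,
#' replacement from the background) followed by indel events (Poisson count
#' with mean `indel_rate * domain_length`; geometric lengths with mean 2,
#' placed uniformly). The returned alignment records the homologous columns:
#' one column per ancestor position, plus non-homologous insert columns.
#'
#' @param spec A [family_spec()].
#' @param background Background frequencies, see [background_frequencies()].
#' @return A list with `ancestor` (string), `members` (named character vector),
#'   `msa` (a [gm_msa] of the members; attribute `homologous` flags the
#'   ancestor-derived columns), and `identity` (realised member-to-ancestor
#'   identities).
#' @examples
#' fam <- simulate_family(family_spec("f1", 60, 5, 0.6, seed = 7))
#' fam$members[1]
#' @export
simulate_family <- function(spec, background = background_frequencies()) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed_(spec$seed, {
    L <- spec$domain_length
    anc <- sample_background(L, background)
    members <- vector("list", spec$n_members)
    inserts <- vector("list", spec$n_members)   # per member: list of (pos, residues)
    deleted <- vector("list", spec$n_members)   # per member: logical over ancestor sites
    ident <- numeric(spec$n_members)
    for (m in seq_len(spec$n_members)) {
      res <- anc
      sub_mask <- runif(L) < (1 - spec$target_identity)
      if (any(sub_mask)) {
        res[sub_mask] <- sample_background(sum(sub_mask), background)
      }
      ident[m] <- mean(res == anc)
      del <- rep(FALSE, L)
      ins <- list()
      n_events <- rpois(1, spec$indel_rate * L)
      for (e in seq_len(n_events)) {
        len <- rgeom(1, 0.5) + 1L      # geometric, mean 2
        if (runif(1) < 0.5) {          # deletion
          at <- sample.int(L, 1)
          del[at:min(L, at + len - 1L)] <- TRUE
        } else {                       # insertion after position 0..L
          at <- sample.int(L + 1L, 1) - 1L
          ins[[length(ins) + 1L]] <- list(pos = at,
                                          res = sample_background(len, background))
        }
      }
      members[[m]] <- res
      deleted[[m]] <- del
      inserts[[m]] <- ins
    }

    # Assemble the true MSA: ancestor-position columns are homologous; insert
    # columns (max width over members per junction) are not.
    ins_width <- integer(L + 1L)  # junction j = after ancestor position j
    ins_at <- lapply(seq_len(spec$n_members), function(m) {
      v <- vector("list", L + 1L)
      for (iv in inserts[[m]]) {
        j <- iv$pos + 1L
        v[[j]] <- c(v[[j]], iv$res)
      }
      v
    })
    for (j in seq_len(L + 1L)) {
      ins_width[j] <- max(0L, vapply(ins_at, function(v) length(v[[j]]), integer(1)))
    }
    width <- L + sum(ins_width)
    rows <- matrix("-", nrow = spec$n_members, ncol = width)
    homologous <- logical(width)
    col <- 0L
    emit_insert <- function(j, col) {
      w <- ins_width[j]
      if (w > 0L) {
        for (m in seq_len(spec$n_members)) {
          r <- ins_at[[m]][[j]]
          if (length(r)) rows[m, col + seq_along(r)] <<- r
        }
        col <- col + w
      }
      col
    }
    col <- emit_insert(1L, col)
    for (i in seq_len(L)) {
      col <- col + 1L
      homologous[col] <- TRUE
      for (m in seq_len(spec$n_members)) {
        if (!deleted[[m]][i]) rows[m, col] <- members[[m]][i]
      }
      col <- emit_insert(i + 1L, col)
    }
    member_strings <- vapply(seq_len(spec$n_members), function(m) {
      chars_seq(rows[m, rows[m, ] != "-"])
    }, character(1))
    ids <- sprintf("%s_m%02d", spec$family_id, seq_len(spec$n_members))
    names(member_strings) <- ids
    msa <- gm_msa(apply(rows, 1, chars_seq), ids = ids, master = 1L)
    attr(msa, "homologous") <- homologous
    list(ancestor = chars_seq(anc),
         members = member_strings,
         msa = msa,
         identity = ident)
  })
}

#' Plant family members and sequence features inside synthetic proteins
#'
#' Embeds every member of every supplied family between background-composition
#' linkers, adds pure-decoy proteins, and optionally plants coiled-coil or
#' low-complexity tracts. Coiled-coil tracts are heptad repeats with
#' hydrophobic residues (L/I/V/M/F) forced at positions a and d and a
#' polar/charged bias at the remaining positions; low-complexity tracts are
#' runs over at most 3 residue types. Truth intervals delimit the planted
#' material exactly (1-based inclusive).
#'
#' @param families List of [simulate_family()] results (may be empty).
#' @param n_decoys Number of decoy proteins containing no planted domain.
#' @param linker_length Either a single non-negative integer (fixed linker
#'   length) or a function `f(n)` returning `n` non-negative lengths.
#' @param feature_specs Optional list of feature specs, each a list with
#'   `kind` (`"coiled_coil"` or `"low_complexity"`), `length` (residues) and
#'   `n` (how many decoy proteins receive one such tract).
#' @param seed Integer seed.
#' @param decoy_length Length of the decoy core segment (default 120).
#' @param background Background frequencies.
#' @return Tibble with columns `protein_id`, `sequence`, `truth` (list of
#'   tibbles `family_id`,`start`,`end`) and `features` (list of tibbles
#'   `kind`,`start`,`end`).
#' @examples
#' fam <- simulate_family(family_spec("f1", 50, 3, 0.8, seed = 2))
#' plant_proteins(list(fam), n_decoys = 2, linker_length = 25, seed = 3)
#' @export
plant_proteins <- function(families, n_decoys = 0L, linker_length = 25L,
                           feature_specs = list(), seed = 1L,
                           decoy_length = 120L,
                           background = background_frequencies()) {
  if (length(families) == 0 && n_decoys == 0) {
    abort("Request at least one family member or decoy protein.")
  }
  if (!is.function(linker_length) && any(linker_length < 0)) {
    abort("Linker length distribution has negative support.")
  }
  draw_linker <- function(n) {
    if (is.function(linker_length)) {
      len <- linker_length(n)
    } else {
      len <- rep(as.integer(linker_length), n)
    }
    if (any(len < 0)) abort("Linker length distribution has negative support.")
    as.integer(len)
  }
  with_seed_(seed, {
    if (is.function(linker_length) && any(linker_length(16L) < 0)) {
      abort("Linker length distribution has negative support.")
    }
    recs <- list()
    for (fam in families) {
      for (m in seq_along(fam$members)) {
        dom <- fam$members[[m]]
        len <- draw_linker(2L)
        seqv <- c(sample_background(len[1], background),
                  seq_chars(dom),
                  sample_background(len[2], background))
        fam_id <- sub("_m[0-9]+$", "", names(fam$members)[m])
        recs[[length(recs) + 1L]] <- list(
          protein_id = paste0("prot_", names(fam$members)[m]),
          sequence = chars_seq(seqv),
          truth = tibble(family_id = fam_id,
                         start = len[1] + 1L,
                         end = len[1] + nchar(dom)),
          features = tibble(kind = character(), start = integer(), end = integer())
        )
      }
    }
    # decoys, some with planted features
    feat_assign <- rep(list(NULL), n_decoys)
    slot <- 1L
    for (fs in feature_specs) {
      stopifnot(fs$kind %in% c("coiled_coil", "low_complexity"))
      for (k in seq_len(fs$n)) {
        if (slot > n_decoys) abort("More feature tracts requested than decoys.")
        feat_assign[[slot]] <- fs
        slot <- slot + 1L
      }
    }
    for (d in seq_len(n_decoys)) {
      fs <- feat_assign[[d]]
      if (is.null(fs)) {
        seqv <- sample_background(decoy_length, background)
        feats <- tibble(kind = character(), start = integer(), end = integer())
      } else {
        tract <- switch(fs$kind,
          coiled_coil = coiled_coil_tract(fs$length),
          low_complexity = low_complexity_tract(fs$length))
        len <- draw_linker(2L)
        seqv <- c(sample_background(len[1], background), tract,
                  sample_background(len[2], background))
        feats <- tibble(kind = fs$kind,
                        start = len[1] + 1L,
                        end = len[1] + length(tract))
      }
      recs[[length(recs) + 1L]] <- list(
        protein_id = sprintf("decoy_%03d", d),
        sequence = chars_seq(seqv),
        truth = tibble(family_id = character(), start = integer(), end = integer()),
        features = feats
      )
    }
    tibble(
      protein_id = vapply(recs, `[[`, character(1), "protein_id"),
      sequence = vapply(recs, `[[`, character(1), "sequence"),
      truth = lapply(recs, `[[`, "truth"),
      features = lapply(recs, `[[`, "features")
    )
  })
}

# Heptad repeat with hydrophobics forced at a/d; polar/charged bias elsewhere,
# matching the residue usage of natural coiled coils.
coiled_coil_tract <- function(len) {
  hyd <- c("L", "I", "V", "M", "F")
  polar <- c("E", "K", "Q", "R", "A", "S", "N", "D", "T")
  pos <- (seq_len(len) - 1L) %% 7L  # 0 = a, 3 = d
  out <- character(len)
  is_ad <- pos == 0L | pos == 3L
  out[is_ad] <- sample(hyd, sum(is_ad), replace = TRUE,
                       prob = c(0.45, 0.2, 0.15, 0.1, 0.1))
  out[!is_ad] <- sample(polar, sum(!is_ad), replace = TRUE)
  out
}

low_complexity_tract <- function(len) {
  k <- sample.int(3L, 1)
  letters_used <- sample(AA, k)
  sample(letters_used, len, replace = TRUE)
}
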