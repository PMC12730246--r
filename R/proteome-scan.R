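#' Read a protein FASTA file into a protein table
#'
#' @param path FASTA file of amino-acid sequences.
#' @return A tibble with columns `protein_id` (first whitespace-delimited
#'   token of the header) and `sequence`.
#' @export
read_proteome_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  tibble(protein_id = ids, sequence = as.character(set))
}

#' Write a protein table to FASTA
#'
#' @param proteins Tibble with `protein_id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(setNames(proteins$sequence,
                                          proteins$protein_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Scan a proteome for classified tandem-SH3 motif hits
#'
#' Applies [scan_motifs()] to every protein and concatenates the results.
#' The number of distinct proteins with at least one hit is attached as the
#' attribute `n_proteins_with_hits` (also available via
#' [n_hit_proteins()]).
#'
#' @param proteins Tibble with columns `protein_id` (unique) and `sequence`.
#' @param definition Optional [motif_definition()]; when supplied, raw
#'   [scan_sequence()] hits for that single definition are returned instead
#'   of the classified [scan_motifs()] table.
#' @return Hit tibble (see [scan_motifs()]).
#' @export
scan_proteome <- function(proteins, definition = NULL) {
  check_protein_table(proteins)
  scan_one <- if (is.null(definition)) {
    function(seq, id) scan_motifs(seq, protein_id = id)
  } else {
    stopifnot(inherits(definition, "motif_definition"))
    function(seq, id) scan_sequence(seq, definition, protein_id = id)
  }
  hits <- purrr::map2(proteins$sequence, proteins$protein_id, scan_one) |>
    bind_rows()
  attr(hits, "n_proteins_with_hits") <- n_distinct(hits$protein_id)
  hits
}

#' @rdname scan_proteome
#' @param hits A hit tibble.
#' @export
n_hit_proteins <- function(hits) {
  n_distinct(hits$protein_id)
}

check_protein_table <- function(proteins) {
  if (!is.data.frame(proteins) || nrow(proteins) == 0L) {
    abort("`proteins` must be a non-empty data frame.")
  }
  if (!all(c("protein_id", "sequence") %in% names(proteins))) {
    abort("`proteins` needs `protein_id` and `sequence` columns.")
  }
  dup <- proteins$protein_id[duplicated(proteins$protein_id)]
  if (length(dup)) {
    abort(sprintf("Duplicate protein_id(s): %s.",
                  paste(unique(dup), collapse = ", ")))
  }
  invisible(proteins)
}

#' Sequence-shuffle null model for motif counts
#'
#' Estimates how often a motif would be found in a protein purely because of
#' its residue composition: the sequence is randomly permuted (full uniform
#' permutation, residue multiset preserved exactly) `n_shuffles` times and
#' rescanned with identical semantics. The empirical p-value uses the
#' add-one estimator `(1 + #\{shuffled >= observed\}) / (n_shuffles + 1)`,
#' so it is never zero.
#'
#' The random stream for a protein is derived by hashing `protein_id` into
#' the master `seed`, so per-protein results do not depend on the order in
#' which a proteome is processed.
#'
#' @param sequence Amino-acid sequence (length >= 7).
#' @param definition A [motif_definition()].
#' @param protein_id Identifier (also seeds the per-protein stream).
#' @param n_shuffles Number of random permutations (default 100).
#' @param seed Master integer seed.
#' @return An object of class `shuffle_null`: a list with `protein_id`,
#'   `definition`, `observed_count`, `n_shuffles`, `shuffled_counts`,
#'   `mean_shuffled`, `sd_shuffled`, `empirical_p`, `seed`.
#' @examples
#' shuffle_null("AAAAAAAAAA", tsh3_motif("strong"), "toy", seed = 1)
#' @export
shuffle_null <- function(sequence, definition, protein_id = "query",
                         n_shuffles = 100L, seed = 1L) {
  stopifnot(inherits(definition, "motif_definition"))
  if (n_shuffles < 1L) abort("`n_shuffles` must be >= 1.")
  chars <- aa_check(sequence, sprintf("sequence of '%s'", protein_id))
  if (length(chars) < 7L) {
    abort("Sequence must be at least 7 residues for the shuffle null.")
  }
  observed <- count_matches(chars, definition)
  counts <- integer(n_shuffles)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_stream_seed(seed, protein_id))
  for (k in seq_len(n_shuffles)) {
    shuffled <- sample(chars)
    stopifnot(identical(sort(shuffled), sort(chars)))
    counts[k] <- count_matches(shuffled, definition)
  }
  structure(
    list(
      protein_id = protein_id,
      definition = definition$name,
      observed_count = observed,
      n_shuffles = as.integer(n_shuffles),
      shuffled_counts = counts,
      mean_shuffled = mean(counts),
      sd_shuffled = sd(counts),
      empirical_p = (1 + sum(counts >= observed)) / (n_shuffles + 1),
      seed = as.integer(seed)
    ),
    class = "shuffle_null"
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.shuffle_null <- function(x, ...) {
  cat(sprintf(
    "<shuffle_null> %s [%s]: observed %d, shuffled mean %.3f (sd %.3f), p = %.4f (n = %d)\n",
    x$protein_id, x$definition, x$observed_count, x$mean_shuffled,
    x$sd_shuffled, x$empirical_p, x$n_shuffles
  ))
  invisible(x)
}

#' @export
tidy.shuffle_null <- function(x, ...) {
  tibble(shuffle = seq_len(x$n_shuffles), count = x$shuffled_counts)
}

#' @export
glance.shuffle_null <- function(x, ...) {
  tibble(
    protein_id = x$protein_id, definition = x$definition,
    observed_count = x$observed_count, n_shuffles = x$n_shuffles,
    mean_shuffled = x$mean_shuffled, sd_shuffled = x$sd_shuffled,
    empirical_p = x$empirical_p
  )
}

#' Shuffle-null summary for every protein in a table
#'
#' @inheritParams shuffle_null
#' @param proteins Protein tibble (`protein_id`, `sequence`). Sequences
#'   shorter than 7 residues are skipped with a warning.
#' @return One-row-per-protein tibble (the [glance.shuffle_null()] rows).
#' @export
shuffle_null_proteome <- function(proteins, definition, n_shuffles = 100L,
                                  seed = 1L) {
  check_protein_table(proteins)
  short <- nchar(proteins$sequence) < 7L
  if (any(short)) {
    warn(sprintf("Skipping %d protein(s) shorter than 7 residues.",
                 sum(short)))
    proteins <- proteins[!short, ]
  }
  purrr::map2(
    proteins$sequence, proteins$protein_id,
    function(seq, id) {
      glance(shuffle_null(seq, definition, protein_id = id,
                          n_shuffles = n_shuffles, seed = seed))
    }
  ) |> bind_rows()
}

#' Disorder filter for motif hits
#'
#' Averages the per-residue disorder score over each hit's window and
#' compares it to a threshold (pass iff mean >= threshold). Hits on proteins
#' without disorder scores are never silently passed: they get
#' `disorder_status = "not_evaluable"` and `passes_disorder = NA`.
#'
#' @param hits Hit tibble with `protein_id`, `window_start`, `window_end`.
#' @param disorder Tibble with `protein_id`, `position`, `score` (scores in
#'   \[0, 1\]); see [read_disorder_tsv()].
#' @param threshold Mean-disorder cutoff (default 0.5).
#' @return `hits` with `mean_disorder_over_window`, `passes_disorder`,
#'   `disorder_status` columns added.
#' @export
disorder_filter <- function(hits, disorder, threshold = 0.5) {
  scores <- split(disorder, disorder$protein_id)
  res <- purrr::pmap(
    list(hits$protein_id, hits$window_start, hits$window_end),
    function(id, ws, we) {
      tab <- scores[[id]]
      if (is.null(tab)) {
        return(list(mean = NA_real_, status = "not_evaluable"))
      }
      vals <- tab$score[match(ws:we, tab$position)]
      if (anyNA(vals)) {
        return(list(mean = NA_real_, status = "not_evaluable"))
      }
      list(mean = mean(vals), status = "evaluated")
    }
  )
  hits |>
    mutate(
      mean_disorder_over_window = vapply(res, `[[`, numeric(1), "mean"),
      disorder_status = vapply(res, `[[`, character(1), "status"),
      passes_disorder = ifelse(
        .data$disorder_status == "evaluated",
        .data$mean_disorder_over_window >= threshold, NA
      )
    )
}

#' Annotate hits with broad-level localization
#'
#' Proteins flagged intracellular are kept as such; proteins without an
#' annotation are kept but flagged `"unknown"` rather than dropped (the
#' screen uses localization as a soft criterion).
#'
#' @param hits Hit tibble.
#' @param localization Tibble with `protein_id`, `intracellular` (logical);
#'   see [read_localization_tsv()].
#' @return `hits` with `intracellular` (logical, `NA` = unknown) and
#'   `localization_status` columns.
#' @export
annotate_localization <- function(hits, localization) {
  hits |>
    left_join(select(localization, "protein_id", "intracellular"),
              by = "protein_id") |>
    mutate(localization_status = dplyr::case_when(
      is.na(.data$intracellular) ~ "unknown",
      .data$intracellular ~ "intracellular",
      TRUE ~ "other"
    ))
}

#' Annotate hits with interaction-partner overlap
#'
#' Flags, for each hit protein, which members of a protein family (e.g.
#' NCF1, NOXO1, TKS4, TKS5) it is a known interaction partner of, according
#' to an unordered pair table. Hits in non-partners are retained but
#' flagged; self-interactions (a family protein paired with itself) are
#' reported with `self_interaction = TRUE` so downstream candidate lists can
#' exclude them.
#'
#' @param hits Hit tibble.
#' @param partner_pairs Tibble with columns `id_a`, `id_b` (unordered
#'   pairs); see [read_partner_tsv()] / [read_mitab()].
#' @param family_ids Character vector of family protein identifiers.
#' @return `hits` with list-column `partner_of`, integer `n_partners`, and
#'   logicals `is_partner`, `self_interaction`.
#' @export
overlap_partners <- function(hits, partner_pairs, family_ids) {
  pairs <- unique(rbind(
    data.frame(a = partner_pairs$id_a, b = partner_pairs$id_b),
    data.frame(a = partner_pairs$id_b, b = partner_pairs$id_a)
  ))
  partner_of <- lapply(hits$protein_id, function(id) {
    sort(unique(pairs$a[pairs$b == id & pairs$a %in% family_ids]))
  })
  hits |>
    mutate(
      partner_of = partner_of,
      n_partners = lengths(partner_of),
      is_partner = .data$n_partners > 0L,
      self_interaction = purrr::map2_lgl(
        partner_of, .data$protein_id, function(fams, id) id %in% fams
      )
    )
}

#' Readers for pipeline annotation tables
#'
#' `read_disorder_tsv()` reads per-residue disorder scores
#' (`protein_id`, `position`, `score`); `read_localization_tsv()` reads
#' broad localization flags (`protein_id`, `intracellular`);
#' `read_partner_tsv()` reads a two-column interaction pair table
#' (`id_a`, `id_b`); `read_mitab()` extracts interactor A/B identifiers
#' from a PSI-MITAB file (the `uniprotkb:`-style prefix of columns 1-2 is
#' stripped).
#'
#' @param path Input file path.
#' @return A tibble (see each description).
#' @name annotation_readers
NULL

#' @rdname annotation_readers
#' @export
read_disorder_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    position = readr::col_integer(),
    score = readr::col_double()
  ), progress = FALSE)
}

#' @rdname annotation_readers
#' @export
read_localization_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    intracellular = readr::col_logical()
  ), progress = FALSE)
}

#' @rdname annotation_readers
#' @export
read_partner_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    id_a = readr::col_character(),
    id_b = readr::col_character()
  ), progress = FALSE)
}

#' @rdname annotation_readers
#' @export
read_mitab <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(
    .default = readr::col_character()
  ), comment = "#", progress = FALSE)
  strip <- function(x) sub("^[^:]+:", "", x)
  tibble(id_a = strip(raw$X1), id_b = strip(raw$X2))
}
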