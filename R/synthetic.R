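# Run expr under a deterministic RNG stream derived from (seed, label),
# restoring the caller's RNG state afterwards.
with_stream_seed <- function(seed, label, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_stream_seed(seed, label))
  expr
}

# Approximate human proteome amino-acid frequencies (renormalised).
aa_frequencies_human <- c(
  A = 0.070, C = 0.023, D = 0.047, E = 0.071, F = 0.037, G = 0.066,
  H = 0.026, I = 0.043, K = 0.057, L = 0.100, M = 0.021, N = 0.036,
  P = 0.063, Q = 0.048, R = 0.056, S = 0.083, T = 0.054, V = 0.060,
  W = 0.012, Y = 0.027
)

sample_background <- function(n, composition) {
  composition <- composition / sum(composition)
  sample(names(composition), n, replace = TRUE, prob = composition)
}

#' Generate a synthetic proteome with planted motif instances
#'
#' Backgrounds are drawn residue-wise from a stated composition; planted
#' peptides overwrite the background at recorded positions, so every
#' genuine motif location is known. An optional decoy composition inflates
#' Pro/Arg frequency to stress the shuffle null with motif-like chance
#' matches.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Integer range `c(min, max)` for protein lengths
#'   (uniform).
#' @param composition Named residue-frequency vector (default: approximate
#'   human proteome composition).
#' @param planted Optional tibble with columns `protein_id`, `peptide`,
#'   `peptide_start` (1-based position of the peptide's first residue in
#'   the protein) and `core_offset` (1-based offset of the motif core
#'   within the peptide). Planted windows must not overlap.
#' @param seed Integer seed; regeneration with the same arguments and seed
#'   is bit-identical.
#' @return List with `proteins` (tibble `protein_id`, `sequence`) and
#'   `manifest` (tibble of planted instances with absolute `core_start`).
#' @examples
#' gen_proteome(3, planted = tibble::tibble(
#'   protein_id = "SYN0001", peptide = "SNPPPRPPA",
#'   peptide_start = 153L, core_offset = 3L
#' ), seed = 1)
#' @export
gen_proteome <- function(n_proteins = 50L, length_range = c(200L, 600L),
                         composition = aa_frequencies_human,
                         planted = NULL, seed = 1L) {
  with_stream_seed(seed, "gen_proteome", {
    ids <- sprintf("SYN%04d", seq_len(n_proteins))
    lens <- sample(seq(length_range[1], length_range[2]), n_proteins,
                   replace = TRUE)
    seqs <- lapply(lens, sample_background, composition = composition)
    names(seqs) <- ids
    manifest <- tibble(
      protein_id = character(), peptide = character(),
      peptide_start = integer(), core_offset = integer(),
      core_start = integer()
    )
    if (!is.null(planted) && nrow(planted)) {
      for (i in seq_len(nrow(planted))) {
        p <- planted[i, ]
        if (!p$protein_id %in% ids) {
          abort(sprintf("Planted protein_id '%s' is not in the proteome.",
                        p$protein_id))
        }
        pep <- strsplit(p$peptide, "", fixed = TRUE)[[1]]
        end <- p$peptide_start + length(pep) - 1L
        if (end > length(seqs[[p$protein_id]])) {
          # grow the protein so the planted window fits
          extra <- sample_background(end - length(seqs[[p$protein_id]]),
                                     composition)
          seqs[[p$protein_id]] <- c(seqs[[p$protein_id]], extra)
        }
        seqs[[p$protein_id]][p$peptide_start:end] <- pep
        manifest <- bind_rows(manifest, tibble(
          protein_id = p$protein_id, peptide = p$peptide,
          peptide_start = as.integer(p$peptide_start),
          core_offset = as.integer(p$core_offset),
          core_start = as.integer(p$peptide_start + p$core_offset - 1L)
        ))
      }
      overlaps <- manifest |>
        group_by(.data$protein_id) |>
        arrange(.data$peptide_start, .by_group = TRUE) |>
        summarise(bad = any(
          .data$peptide_start[-1L] <=
            (.data$peptide_start + nchar(.data$peptide) - 1L)[-n()]
        ), .groups = "drop")
      if (any(overlaps$bad)) {
        abort("Planted windows overlap within a protein.")
      }
    }
    list(
      proteins = tibble(
        protein_id = ids,
        sequence = vapply(seqs, paste, character(1), collapse = "")
      ),
      manifest = manifest
    )
  })
}

#' Generate a synthetic ortholog family alignment with known conservation
#'
#' Emulates the substrate of motif-conservation scoring: an
#' island-conserved motif in a drifting disordered background. Ortholog
#' rows are derived from the human sequence by i.i.d. substitutions and
#' indels at non-motif columns, while the motif island (position 0 through
#' 7 plus a buffer) is kept intact, except in "kill-list" species where the
#' core's required Arg (position 4) is substituted with Gly, destroying the
#' match. Because the rows are derived by tracked edits, the emitted
#' alignment is exact and no aligner is needed.
#'
#' Substitutions are drawn from residues other than Pro and Arg so the
#' background cannot spawn spurious motif cores; conservation labels are
#' therefore exact whenever the supplied human sequence contains no motif
#' match other than the one at `core_start`.
#'
#' @param human_seq Human (reference) amino-acid sequence containing a
#'   motif hit.
#' @param core_start 1-based core start of that hit in `human_seq`.
#' @param definition Definition the hit satisfies (default strong).
#' @param n_species Number of ortholog rows (default 10).
#' @param sub_rate Per-column substitution probability outside the motif
#'   island (default 0.1).
#' @param indel_rate Per-column insertion/deletion probability outside the
#'   island (default 0.02).
#' @param kill_species Character vector of species labels whose motif is
#'   destroyed.
#' @param motif_buffer Columns on each side of the 0-7 window also kept
#'   intact (default 1).
#' @param seed Integer seed.
#' @return List with `block` (an [alignment_block()], reference row
#'   `"human"`), `labels` (tibble `species`, `conserved`) and `manifest`.
#' @export
gen_ortholog_family <- function(human_seq, core_start,
                                definition = tsh3_motif("strong"),
                                n_species = 10L, sub_rate = 0.1,
                                indel_rate = 0.02,
                                kill_species = character(),
                                motif_buffer = 1L, seed = 1L) {
  if (sub_rate < 0 || sub_rate >= 1 || indel_rate < 0 || indel_rate >= 1) {
    abort("`sub_rate` and `indel_rate` must lie in [0, 1).")
  }
  chars <- aa_check(human_seq, "human sequence")
  hits <- scan_sequence(human_seq, definition, "human")
  if (!core_start %in% hits$core_start) {
    abort(sprintf("Human sequence has no '%s' hit with core start %d.",
                  definition$name, core_start))
  }
  species <- sprintf("sp%02d", seq_len(n_species))
  bad_kill <- setdiff(kill_species, species)
  if (length(bad_kill)) {
    abort(sprintf("Kill-list species not generated: %s.",
                  paste(bad_kill, collapse = ", ")))
  }
  with_stream_seed(seed, "gen_ortholog_family", {
    L <- length(chars)
    island <- max(1L, core_start - 1L - motif_buffer):
      min(L, core_start + 6L + motif_buffer)
    mutable <- setdiff(seq_len(L), island)
    sub_pool <- setdiff(AA_STANDARD, c("P", "R"))
    base <- matrix("-", nrow = n_species + 1L, ncol = L)
    base[1L, ] <- chars
    insertions <- vector("list", n_species)
    for (s in seq_len(n_species)) {
      row <- chars
      subs <- mutable[runif(length(mutable)) < sub_rate]
      row[subs] <- sample(sub_pool, length(subs), replace = TRUE)
      dels <- mutable[runif(length(mutable)) < indel_rate]
      row[dels] <- "-"
      if (species[s] %in% kill_species) {
        row[core_start + 3L] <- "G" # destroy the required position-4 Arg
      }
      base[s + 1L, ] <- row
      ins_at <- mutable[runif(length(mutable)) < indel_rate]
      insertions[[s]] <- lapply(ins_at, function(j) {
        list(after = j, residue = sample(sub_pool, 1L))
      })
    }
    # assemble: base columns in order, inserted columns (gap everywhere but
    # the owning row) spliced after their anchor column
    cols <- list()
    for (j in seq_len(L)) {
      cols[[length(cols) + 1L]] <- base[, j]
      for (s in seq_len(n_species)) {
        for (ins in insertions[[s]]) {
          if (ins$after == j) {
            col <- rep("-", n_species + 1L)
            col[s + 1L] <- ins$residue
            cols[[length(cols) + 1L]] <- col
          }
        }
      }
    }
    mat <- do.call(cbind, cols)
    rows <- tibble(
      row_id = c("human", species),
      species = c("human", species),
      aligned_seq = apply(mat, 1, paste, collapse = "")
    )
    labels <- tibble(species = species,
                     conserved = !(species %in% kill_species))
    list(
      block = alignment_block(rows, "human"),
      labels = labels,
      manifest = tibble(
        key = c("seed", "core_start", "definition", "n_species",
                "sub_rate", "indel_rate", "kill_species"),
        value = c(seed, core_start, definition$name, n_species, sub_rate,
                  indel_rate, paste(kill_species, collapse = ","))
      )
    )
  })
}

#' Generate synthetic multi-SH3 domain architectures
#'
#' Renders "SH3 domains" as 60-residue sequence mimics: a background drawn
#' from residues that cannot form any screened signature, with the
#' requested signature substrings planted at fixed offsets (`GWW` or its
#' tandem-incompetent `SWW` variant; an `EE` dimer for the C-double
#' negative; a `PAAYL`/`PAAYV` tail patch for the strict/relaxed
#' N-PxxPhiL). Linkers of the requested lengths are drawn from an acidic
#' alphabet. Expected screen tiers follow directly from the construction.
#'
#' @param specs Tibble with one row per protein: `protein_id`, and
#'   list-columns `gww` (logical per domain), `cdd` (logical per domain),
#'   `tail` (per domain: `"strict"`, `"relaxed"` or `"none"`) and
#'   `linkers` (numeric, length = domains - 1).
#' @param seed Integer seed.
#' @param max_linker Linker rule used for the expected tier-c labels
#'   (default 60).
#' @return List with `proteins`, `domains` (annotation tibble),
#'   `pair_labels` (expected `in_tier_b` / `in_tier_c` per consecutive
#'   pair) and `protein_labels` (expected tier-a membership).
#' @export
gen_domain_architectures <- function(specs, seed = 1L, max_linker = 60L) {
  domain_len <- 60L
  background_pool <- c("A", "G", "H", "K", "M", "N", "Q", "R", "S", "T")
  linker_pool <- c("D", "E", "G", "S")
  with_stream_seed(seed, "gen_domain_architectures", {
    proteins <- list(); domains <- list(); pair_labels <- list()
    for (i in seq_len(nrow(specs))) {
      sp <- specs[i, ]
      gww <- sp$gww[[1]]; cdd <- sp$cdd[[1]]; tail_kind <- sp$tail[[1]]
      linkers <- sp$linkers[[1]]
      n_dom <- length(gww)
      if (n_dom >= 2L && length(linkers) != n_dom - 1L) {
        abort("`linkers` must have one entry per consecutive domain pair.")
      }
      render_domain <- function(has_gww, has_cdd, tail) {
        d <- sample(background_pool, domain_len, replace = TRUE)
        d[8:10] <- if (has_gww) c("G", "W", "W") else c("S", "W", "W")
        if (has_cdd) d[30:31] <- c("E", "E")
        d[(domain_len - 4L):domain_len] <- switch(
          tail,
          strict = c("P", "A", "A", "Y", "L"),
          relaxed = c("P", "A", "A", "Y", "V"),
          none = c("A", "A", "A", "A", "A"),
          abort("`tail` must be 'strict', 'relaxed' or 'none'.")
        )
        d
      }
      seq <- sample(background_pool, 5L, replace = TRUE)
      dom_rows <- list()
      for (k in seq_len(n_dom)) {
        start <- length(seq) + 1L
        seq <- c(seq, render_domain(gww[k], cdd[k], tail_kind[k]))
        dom_rows[[k]] <- tibble(
          protein_id = sp$protein_id, domain_class = "SH3",
          source_id = "PF00018", start = start,
          end = length(seq)
        )
        if (k < n_dom) {
          seq <- c(seq, sample(linker_pool, linkers[k], replace = TRUE))
        }
      }
      seq <- c(seq, sample(background_pool, 5L, replace = TRUE))
      proteins[[i]] <- tibble(protein_id = sp$protein_id,
                              sequence = paste(seq, collapse = ""))
      domains[[i]] <- bind_rows(dom_rows)
      if (n_dom >= 2L) {
        pair_labels[[i]] <- tibble(
          protein_id = sp$protein_id,
          pair_index = seq_len(n_dom - 1L),
          expected_tier_b = gww[-n_dom] & gww[-1L],
          expected_tier_c = (gww[-n_dom] & gww[-1L]) &
            (linkers < max_linker)
        )
      }
    }
    proteins <- bind_rows(proteins)
    list(
      proteins = proteins,
      domains = bind_rows(domains),
      pair_labels = bind_rows(pair_labels),
      protein_labels = tibble(
        protein_id = specs$protein_id,
        expected_tier_a = vapply(specs$gww, length, integer(1)) >= 2L
      )
    )
  })
}

#' Generate a synthetic reference structure
#'
#' A deterministic alpha-carbon trace (ideal alpha-helical geometry, with
#' the second residue block offset in space) standing in for a tandem-SH3
#' reference region. Purely synthetic coordinates: no experimental
#' structure is reproduced.
#'
#' @param region A [region_spec()] giving the residue ids (default: the
#'   two tandem-SH3 reference ranges).
#' @return n x 3 matrix with residue-id rownames.
#' @export
gen_reference_structure <- function(region = region_spec()) {
  ids <- unclass(region)
  ranges <- attr(region, "ranges")
  coords <- matrix(0, nrow = length(ids), ncol = 3)
  row <- 1L
  for (r in seq_len(nrow(ranges))) {
    n <- ranges[r, 2] - ranges[r, 1] + 1L
    t <- seq_len(n)
    block <- cbind(
      2.3 * cos(t * 100 * pi / 180),
      2.3 * sin(t * 100 * pi / 180),
      1.5 * t
    )
    # offset blocks so the "domains" sit side by side
    block[, 1] <- block[, 1] + (r - 1L) * 25
    coords[row:(row + n - 1L), ] <- block
    row <- row + n
  }
  rownames(coords) <- ids
  coords
}

random_rotation_matrix <- function() {
  repeat {
    M <- matrix(rnorm(9), 3, 3)
    qr_dec <- qr(M)
    Q <- qr.Q(qr_dec)
    Q <- Q %*% diag(sign(diag(qr.R(qr_dec))))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    if (abs(det(Q) - 1) < 1e-9) return(Q)
  }
}

#' Generate a conformer ensemble with a controlled near-native fraction
#'
#' Near-native models are rigid motions of the reference plus small
#' Gaussian coordinate noise (calibrated to stay well below the 5-Angstrom
#' tandem threshold); non-native models additionally displace the second
#' residue block ("C-terminal domain") far from the reference arrangement
#' before the rigid motion, so their minimised RMSD exceeds it.
#'
#' @param reference n x 3 matrix with residue-id rownames (see
#'   [gen_reference_structure()]).
#' @param n_models Ensemble size (default 30, the ensemble size used for
#'   conformer classification).
#' @param near_native_fraction Fraction of models built near-native
#'   (rounded to a whole number of models).
#' @param noise_sd Per-coordinate Gaussian noise, Angstrom (default 0.3).
#' @param displacement Translation applied to the second block of
#'   non-native models, Angstrom (default 60, calibrated so the minimised
#'   RMSD of a displaced model always exceeds the 5-Angstrom threshold).
#' @param region [region_spec()] describing the block structure (default:
#'   the reference tandem ranges); the second and later ranges are
#'   displaced.
#' @param label Construct label.
#' @param seed Integer seed.
#' @return List with `conformers` (a [conformer_set()]) and `labels`
#'   (tibble `model`, `intended_tandem`).
#' @export
gen_conformers <- function(reference, n_models = 30L,
                           near_native_fraction = 0.2, noise_sd = 0.3,
                           displacement = 60, region = region_spec(),
                           label = "synthetic", seed = 1L) {
  if (near_native_fraction < 0 || near_native_fraction > 1) {
    abort("`near_native_fraction` must lie in [0, 1].")
  }
  ids <- rownames(reference)
  ranges <- attr(region, "ranges")
  second_block <- if (nrow(ranges) > 1L) {
    ids %in% as.character(unlist(
      apply(ranges[-1L, , drop = FALSE], 1, function(r) seq(r[1], r[2]),
            simplify = FALSE)
    ))
  } else {
    seq_along(ids) > length(ids) / 2
  }
  n_native <- round(near_native_fraction * n_models)
  with_stream_seed(seed, paste0("gen_conformers:", label), {
    models <- lapply(seq_len(n_models), function(i) {
      m <- reference
      if (i > n_native) {
        dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
        m[second_block, ] <- sweep(m[second_block, , drop = FALSE], 2,
                                   -displacement * dir)
      }
      R <- random_rotation_matrix()
      shift <- runif(3, -20, 20)
      m <- sweep(m %*% R, 2, -shift)
      if (noise_sd > 0) {
        m <- m + matrix(rnorm(length(m), sd = noise_sd), ncol = 3)
      }
      rownames(m) <- ids
      m
    })
    list(
      conformers = conformer_set(label, models),
      labels = tibble(model = seq_len(n_models),
                      intended_tandem = seq_len(n_models) <= n_native)
    )
  })
}

#' Write a conformer set as a multi-model PDB file
#'
#' Alpha-carbon-only MODEL/ENDMDL records in fixed-width PDB format,
#' readable by any standard PDB parser.
#'
#' @param conformers A [conformer_set()].
#' @param path Output path.
#' @param chain Chain identifier (default "A").
#' @return `path`, invisibly.
#' @export
write_conformers_pdb <- function(conformers, path, chain = "A") {
  stopifnot(inherits(conformers, "conformer_set"))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (i in seq_along(conformers$models)) {
    m <- conformers$models[[i]]
    writeLines(sprintf("MODEL     %4d", i), con)
    resno <- as.integer(rownames(m))
    lines <- sprintf(
      "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(nrow(m)), chain, resno, m[, 1], m[, 2], m[, 3]
    )
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write or read a flat key-value manifest
#'
#' @param manifest Tibble with `key` and `value` columns (or a named list).
#' @param path File path.
#' @return `read_manifest()` returns a tibble; `write_manifest()` returns
#'   `path` invisibly.
#' @export
write_manifest <- function(manifest, path) {
  if (!is.data.frame(manifest)) {
    manifest <- tibble(key = names(manifest),
                       value = vapply(manifest, paste, character(1),
                                      collapse = ","))
  }
  writeLines(paste(manifest$key, manifest$value, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(
    key = vapply(parts, `[[`, character(1), 1L),
    value = vapply(parts, function(p) {
      if (length(p) > 1L) p[2] else ""
    }, character(1))
  )
}
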