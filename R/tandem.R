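#' Read a domain annotation table
#'
#' Reads an InterPro-style TSV export with columns `protein_id`,
#' `domain_class`, `source_id`, `start`, `end` (extra columns are ignored).
#'
#' @param path TSV path.
#' @return Tibble of domain annotations.
#' @export
read_domain_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  need <- c("protein_id", "domain_class", "source_id", "start", "end")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    abort(sprintf("Domain table is missing column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  raw <- as_tibble(raw[, need])
  raw$start <- as.integer(raw$start)
  raw$end <- as.integer(raw$end)
  raw
}

check_domains <- function(domains) {
  if (any(domains$start > domains$end)) {
    abort("Domain annotations must satisfy start <= end.")
  }
  domains <- arrange(domains, .data$start)
  if (nrow(domains) > 1L) {
    overlap <- domains$start[-1L] <= domains$end[-nrow(domains)]
    if (any(overlap)) {
      abort(sprintf("Overlapping domain annotations on protein '%s'.",
                    domains$protein_id[1]))
    }
  }
  domains
}

#' Find tandem SH3 pairs on one protein
#'
#' Every consecutive pair of SH3-class domains (ordered by start) is
#' evaluated: the linker is the segment strictly between them, and the pair
#' is a tandem iff the linker is *shorter than* `max_linker` residues
#' (strict inequality; the family's tandems have linkers well under 60).
#' The linker net charge is `(#K + #R) - (#D + #E)`; the family's genuine
#' tandem linkers are acidic.
#'
#' @param domains Domain tibble (one protein; columns as in
#'   [read_domain_tsv()]). Non-SH3 domains are ignored for pairing.
#' @param sequence Full protein sequence (used for linker composition);
#'   optional, `NA` linker metrics if absent.
#' @param max_linker Linker-length cutoff, exclusive (default 60).
#' @return Tibble with one row per consecutive SH3 pair: domain
#'   coordinates, `linker_start`, `linker_end`, `linker_length`,
#'   `linker_net_charge`, `is_tandem`.
#' @examples
#' doms <- tibble::tibble(
#'   protein_id = "toy", domain_class = "SH3", source_id = "PF00018",
#'   start = c(10L, 130L), end = c(70L, 190L)
#' )
#' find_tandem_pairs(doms)
#' @export
find_tandem_pairs <- function(domains, sequence = NULL, max_linker = 60L) {
  if (n_distinct(domains$protein_id) > 1L) {
    abort("`domains` must describe a single protein.")
  }
  domains <- check_domains(domains)
  sh3 <- filter(domains, .data$domain_class == "SH3")
  if (nrow(sh3) < 2L) return(empty_pair_table())
  purrr::map(seq_len(nrow(sh3) - 1L), function(i) {
    n_dom <- sh3[i, ]
    c_dom <- sh3[i + 1L, ]
    linker_start <- n_dom$end + 1L
    linker_end <- c_dom$start - 1L
    linker_length <- c_dom$start - n_dom$end - 1L
    charge <- NA_integer_
    if (!is.null(sequence) && linker_length > 0L) {
      chars <- strsplit(substr(sequence, linker_start, linker_end), "",
                        fixed = TRUE)[[1]]
      charge <- sum(chars %in% c("K", "R")) - sum(chars %in% c("D", "E"))
    } else if (linker_length == 0L) {
      charge <- 0L
    }
    tibble(
      protein_id = n_dom$protein_id,
      n_start = n_dom$start, n_end = n_dom$end,
      c_start = c_dom$start, c_end = c_dom$end,
      linker_start = linker_start, linker_end = linker_end,
      linker_length = linker_length,
      linker_net_charge = as.integer(charge),
      is_tandem = linker_length < max_linker
    )
  }) |> bind_rows()
}

empty_pair_table <- function() {
  tibble(
    protein_id = character(), n_start = integer(), n_end = integer(),
    c_start = integer(), c_end = integer(), linker_start = integer(),
    linker_end = integer(), linker_length = integer(),
    linker_net_charge = integer(), is_tandem = logical()
  )
}

#' Detect tandemization and motif-binding sequence signatures
#'
#' Scans a pair of SH3 domain sequences for the signatures that distinguish
#' tandem-competent domains:
#' * `gww_n`, `gww_c` - the exact `GWW` triplet in the N- and C-terminal
#'   domain (its Gly is required sterically for tandemization; Gly-to-Ser
#'   changes here abolish it);
#' * `c_double_negative` - two adjacent acidic residues (`[DE][DE]`)
#'   anywhere in the C-domain, which salt-bridge the motif's position-4 Arg;
#' * `n_pxx_phi_l` - the hydrophobic `P x x Phi L` patch (Phi aromatic:
#'   F/W/Y) within the last `tail_window` residues of the N-domain;
#'   `n_pxx_phi_l_relaxed` additionally allows Val in the final position
#'   (the variant seen in CIN85).
#'
#' First-occurrence positions (1-based within each domain sequence) are
#' reported so callers can impose stricter locality.
#'
#' @param n_domain_seq,c_domain_seq Domain sequences (non-empty).
#' @param tail_window Length of the N-domain tail searched for the
#'   `PxxPhiL` patch (default 15).
#' @return One-row tibble of signature flags and positions.
#' @export
detect_signatures <- function(n_domain_seq, c_domain_seq,
                              tail_window = 15L) {
  if (!nzchar(n_domain_seq) || !nzchar(c_domain_seq)) {
    abort("Both domain sequences must be non-empty.")
  }
  gww_n_pos <- first_match(n_domain_seq, "GWW")
  gww_c_pos <- first_match(c_domain_seq, "GWW")
  cdd_pos <- first_match(c_domain_seq, "[DE][DE]")
  tail_start <- max(1L, nchar(n_domain_seq) - tail_window + 1L)
  tail_seq <- substr(n_domain_seq, tail_start, nchar(n_domain_seq))
  strict_pos <- first_match(tail_seq, "P..[FWY]L")
  relaxed_pos <- first_match(tail_seq, "P..[FWY][LV]")
  tibble(
    gww_n = !is.na(gww_n_pos), gww_n_pos = gww_n_pos,
    gww_c = !is.na(gww_c_pos), gww_c_pos = gww_c_pos,
    c_double_negative = !is.na(cdd_pos),
    c_double_negative_pos = cdd_pos,
    n_pxx_phi_l = !is.na(strict_pos),
    n_pxx_phi_l_relaxed = !is.na(relaxed_pos)
  )
}

first_match <- function(x, pattern) {
  m <- regexpr(pattern, x)
  if (m[1] == -1L) NA_integer_ else as.integer(m[1])
}

#' Screen a proteome for multi-SH3 and tandemization candidates
#'
#' Three nested tiers, mirroring the proteome screen for SH3 tandemization
#' candidates:
#' * tier **a** - proteins with at least two SH3 domains;
#' * tier **b** - consecutive SH3 pairs where *both* domains carry the GWW
#'   triplet;
#' * tier **c** - tier-b pairs whose linker also passes the tandem rule
#'   (`linker_length < max_linker`).
#'
#' @param proteins Protein tibble (`protein_id`, `sequence`).
#' @param domain_table Domain tibble covering (a subset of) the proteome;
#'   proteins in the table but absent from the proteome are skipped with a
#'   warning.
#' @param max_linker,tail_window See [find_tandem_pairs()] /
#'   [detect_signatures()].
#' @param extra_domains Optional supplementary domain tibble merged into
#'   `domain_table` before screening (repairs missing annotations, e.g. a
#'   domain present in UniProt but absent from an InterPro export).
#' @return List with `multi_sh3` (tier-a tibble: `protein_id`,
#'   `n_sh3_domains`) and `pairs` (per consecutive SH3 pair: linker
#'   profile, signature flags, `in_tier_b`, `in_tier_c`).
#' @export
screen_multi_sh3 <- function(proteins, domain_table, max_linker = 60L,
                             tail_window = 15L, extra_domains = NULL) {
  check_protein_table(proteins)
  if (!is.null(extra_domains)) {
    domain_table <- distinct(bind_rows(domain_table, extra_domains))
  }
  missing <- setdiff(unique(domain_table$protein_id), proteins$protein_id)
  if (length(missing)) {
    warn(sprintf("Skipping %d protein(s) in the domain table absent from the proteome: %s.",
                 length(missing), paste(missing, collapse = ", ")))
    domain_table <- filter(domain_table, !.data$protein_id %in% missing)
  }
  sh3_counts <- domain_table |>
    filter(.data$domain_class == "SH3") |>
    dplyr::count(.data$protein_id, name = "n_sh3_domains")
  multi <- filter(sh3_counts, .data$n_sh3_domains >= 2L)
  pairs <- purrr::map(multi$protein_id, function(id) {
    doms <- filter(domain_table, .data$protein_id == id)
    seq <- proteins$sequence[match(id, proteins$protein_id)]
    prs <- find_tandem_pairs(doms, sequence = seq, max_linker = max_linker)
    if (nrow(prs) == 0L) return(prs)
    sigs <- purrr::pmap(
      list(prs$n_start, prs$n_end, prs$c_start, prs$c_end),
      function(ns, ne, cs, ce) {
        detect_signatures(substr(seq, ns, ne), substr(seq, cs, ce),
                          tail_window = tail_window)
      }
    ) |> bind_rows()
    bind_cols(prs, sigs)
  }) |> bind_rows()
  if (nrow(pairs)) {
    pairs <- pairs |>
      mutate(in_tier_b = .data$gww_n & .data$gww_c,
             in_tier_c = .data$in_tier_b & .data$is_tandem)
  } else {
    pairs <- bind_cols(
      empty_pair_table(),
      detect_signatures("A", "A")[0, ],
      tibble(in_tier_b = logical(), in_tier_c = logical())
    )
  }
  list(multi_sh3 = multi, pairs = pairs)
}
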