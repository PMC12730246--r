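#' Pipeline configuration
#'
#' Collects the tunable parameters of the discovery pipeline, defaulting to
#' the study's stated analysis settings: 100 sequence shuffles, a
#' +/-50-column conservation window, ortholog identity > 20% with >= 60%
#' coverage, a 60-residue tandem linker cutoff (exclusive), a 15-residue
#' N-domain tail window for the PxxPhiL signature, and a 5-Angstrom tandem
#' RMSD threshold over the reference region ranges 160-211 and 229-283.
#'
#' @param definition Motif definition name (`"strong"`, `"weak"`,
#'   `"core"`) used by the shuffle null and conservation stages.
#' @param n_shuffles,seed Shuffle-null settings; `seed` is the single
#'   master seed for all stochastic stages (per-stage and per-protein
#'   streams are derived from it deterministically).
#' @param conservation_window,min_identity,min_coverage Conservation and
#'   ortholog-selection settings.
#' @param max_linker,tail_window,relaxed_phi Tandem-screen settings.
#' @param rmsd_threshold,region_ranges Ensemble-classification settings.
#' @param disorder_threshold,disorder_hard_filter Disorder handling: when
#'   `disorder_hard_filter` is `TRUE`, hits failing the disorder mean are
#'   dropped from the report; otherwise the column is descriptive.
#' @param paths Named list of input/output file paths consumed by the
#'   `run_*` stage functions.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(definition = "strong", n_shuffles = 100L,
                            seed = 1L, conservation_window = 50L,
                            min_identity = 20, min_coverage = 0.6,
                            max_linker = 60L, tail_window = 15L,
                            relaxed_phi = FALSE, rmsd_threshold = 5.0,
                            region_ranges = list(c(160L, 211L),
                                                 c(229L, 283L)),
                            disorder_threshold = 0.5,
                            disorder_hard_filter = FALSE,
                            paths = list()) {
  structure(
    list(
      definition = definition, n_shuffles = as.integer(n_shuffles),
      seed = as.integer(seed),
      conservation_window = as.integer(conservation_window),
      min_identity = min_identity, min_coverage = min_coverage,
      max_linker = as.integer(max_linker),
      tail_window = as.integer(tail_window),
      relaxed_phi = isTRUE(relaxed_phi),
      rmsd_threshold = rmsd_threshold, region_ranges = region_ranges,
      disorder_threshold = disorder_threshold,
      disorder_hard_filter = isTRUE(disorder_hard_filter),
      paths = paths
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline config from YAML
#'
#' Any field of [pipeline_config()] may be set; unset fields keep their
#' defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(sprintf("Unknown config field(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, raw)
}

cfg_path <- function(config, name, required = TRUE) {
  p <- config$paths[[name]]
  if (is.null(p) && required) {
    abort(sprintf("Config is missing required path '%s'.", name))
  }
  p
}

check_infile <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Input file not found: %s", path))
  }
  path
}

#' Pipeline stage runners
#'
#' Thin file-driven wrappers around the package's analysis functions; each
#' reads the inputs named in `config$paths`, runs one stage, writes its
#' output TSV(s) and returns the result invisibly. Re-running a stage with
#' identical config and inputs reproduces byte-identical outputs.
#'
#' * `run_scan()` - paths `proteome` (FASTA) and `hits_out`: classified
#'   motif scan of the proteome.
#' * `run_null()` - paths `proteome`, `null_out`: per-protein shuffle-null
#'   summary.
#' * `run_conserve()` - paths `alignment` (aligned FASTA), `conserve_out`,
#'   plus config fields `conserve_reference` (row id) and
#'   `conserve_core_start`.
#' * `run_tandem()` - paths `proteome`, `domains` (TSV), optional
#'   `extra_domains`, outputs `tandem_pairs_out` and `tandem_proteins_out`.
#' * `run_ensemble()` - paths `ensemble_a`, `ensemble_b` (multi-model
#'   PDB), `reference_pdb`, output `ensemble_out`.
#' * `run_report()` - assembles hits, shuffle p-values, disorder,
#'   localization and partner overlap into one ranked candidate table
#'   (path `report_out`; optional inputs `disorder`, `localization`,
#'   `partners`, `family_ids` config field).
#'
#' @param config A [pipeline_config()].
#' @return The stage result, invisibly.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
run_scan <- function(config) {
  proteins <- read_proteome_fasta(check_infile(cfg_path(config, "proteome")))
  hits <- scan_proteome(proteins)
  write_hits_tsv(hits, cfg_path(config, "hits_out"))
  invisible(hits)
}

#' @rdname pipeline_stages
#' @export
run_null <- function(config) {
  proteins <- read_proteome_fasta(check_infile(cfg_path(config, "proteome")))
  res <- shuffle_null_proteome(
    proteins, tsh3_motif(config$definition),
    n_shuffles = config$n_shuffles, seed = config$seed
  )
  write_tsv_dot(res, cfg_path(config, "null_out"))
  invisible(res)
}

#' @rdname pipeline_stages
#' @export
run_conserve <- function(config) {
  block <- read_alignment_fasta(
    check_infile(cfg_path(config, "alignment")),
    reference_row = config$conserve_reference %||% NULL
  )
  res <- conservation_score(
    block, tsh3_motif(config$definition),
    human_core_start = config$conserve_core_start,
    window = config$conservation_window
  )
  write_conservation_tsv(res, cfg_path(config, "conserve_out"))
  invisible(res)
}

#' @rdname pipeline_stages
#' @export
run_tandem <- function(config) {
  proteins <- read_proteome_fasta(check_infile(cfg_path(config, "proteome")))
  domains <- read_domain_tsv(check_infile(cfg_path(config, "domains")))
  extra <- cfg_path(config, "extra_domains", required = FALSE)
  extra_tbl <- if (!is.null(extra)) read_domain_tsv(check_infile(extra))
  screen <- screen_multi_sh3(
    proteins, domains, max_linker = config$max_linker,
    tail_window = config$tail_window, extra_domains = extra_tbl
  )
  write_tsv_dot(screen$pairs, cfg_path(config, "tandem_pairs_out"))
  write_tsv_dot(screen$multi_sh3, cfg_path(config, "tandem_proteins_out"))
  invisible(screen)
}

#' @rdname pipeline_stages
#' @export
run_ensemble <- function(config) {
  region <- region_spec(config$region_ranges)
  ref_set <- read_conformers_pdb(
    check_infile(cfg_path(config, "reference_pdb"))
  )
  reference <- ref_set$models[[1]]
  ens_a <- read_conformers_pdb(check_infile(cfg_path(config, "ensemble_a")))
  ens_b <- read_conformers_pdb(check_infile(cfg_path(config, "ensemble_b")))
  cmp <- compare_ensembles(
    rmsd_to_reference(ens_a, reference, region),
    rmsd_to_reference(ens_b, reference, region),
    threshold = config$rmsd_threshold,
    labels = c(ens_a$label, ens_b$label)
  )
  write_ensemble_tsv(cmp, cfg_path(config, "ensemble_out"))
  invisible(cmp)
}

#' @rdname pipeline_stages
#' @export
run_report <- function(config) {
  proteins <- read_proteome_fasta(check_infile(cfg_path(config, "proteome")))
  hits <- scan_proteome(proteins)
  nulls <- shuffle_null_proteome(
    proteins, tsh3_motif(config$definition),
    n_shuffles = config$n_shuffles, seed = config$seed
  )
  report <- hits |>
    left_join(select(nulls, "protein_id", shuffle_p = "empirical_p",
                     "observed_count", "mean_shuffled"),
              by = "protein_id")
  disorder_path <- cfg_path(config, "disorder", required = FALSE)
  if (!is.null(disorder_path)) {
    report <- disorder_filter(report,
                              read_disorder_tsv(check_infile(disorder_path)),
                              threshold = config$disorder_threshold)
    if (config$disorder_hard_filter) {
      report <- filter(report, is.na(.data$passes_disorder) |
                         .data$passes_disorder)
    }
  }
  loc_path <- cfg_path(config, "localization", required = FALSE)
  if (!is.null(loc_path)) {
    report <- annotate_localization(
      report, read_localization_tsv(check_infile(loc_path))
    )
  }
  partner_path <- cfg_path(config, "partners", required = FALSE)
  if (!is.null(partner_path)) {
    report <- overlap_partners(
      report, read_partner_tsv(check_infile(partner_path)),
      family_ids = config$family_ids %||% character()
    )
  } else {
    report <- mutate(report, partner_of = list(character()),
                     n_partners = 0L, is_partner = FALSE,
                     self_interaction = FALSE)
  }
  report <- report |>
    arrange(dplyr::desc(.data$is_partner), .data$shuffle_p,
            factor(.data$class_label,
                   levels = c("strong", "weak_only", "core_only")),
            .data$protein_id, .data$core_start)
  write_tsv_dot(report, cfg_path(config, "report_out"))
  invisible(report)
}

#' @rdname pipeline_stages
#' @param out_dir Output directory for the synthetic bundle.
#' @export
run_synth <- function(config, out_dir = cfg_path(config, "synth_dir")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  planted <- tibble(
    protein_id = c("SYN0001", "SYN0002", "SYN0003"),
    peptide = c("SNPPPRPPA", "PPVPPRRRP", "QRPPPRRDM"),
    peptide_start = c(153L, 40L, 80L),
    core_offset = c(3L, 3L, 3L)
  )
  prot <- gen_proteome(n_proteins = 10L, planted = planted, seed = seed)
  write_proteome_fasta(prot$proteins, file.path(out_dir, "proteome.fasta"))
  write_tsv_dot(prot$manifest, file.path(out_dir, "proteome_manifest.tsv"))
  # family reference on a P/R-free background so conservation labels are
  # exact by construction
  fam_base <- gen_proteome(
    1, length_range = c(300L, 300L),
    composition = c(A = 0.5, G = 0.3, S = 0.2),
    planted = tibble(protein_id = "SYN0001", peptide = "SNPPPRPPA",
                     peptide_start = 153L, core_offset = 3L),
    seed = seed + 1L
  )
  fam <- gen_ortholog_family(
    human_seq = fam_base$proteins$sequence[1], core_start = 155L,
    n_species = 10L, kill_species = c("sp01", "sp02"), seed = seed
  )
  aln <- fam$block$rows
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(setNames(aln$aligned_seq, aln$row_id)),
    file.path(out_dir, "family.afa")
  )
  write_tsv_dot(fam$labels, file.path(out_dir, "family_labels.tsv"))
  arch <- gen_domain_architectures(default_architecture_specs(), seed = seed)
  write_proteome_fasta(arch$proteins,
                       file.path(out_dir, "architectures.fasta"))
  write_tsv_dot(arch$domains, file.path(out_dir, "domains.tsv"))
  write_tsv_dot(arch$pair_labels, file.path(out_dir, "pair_labels.tsv"))
  reference <- gen_reference_structure()
  ref_set <- conformer_set("reference", list(reference))
  write_conformers_pdb(ref_set, file.path(out_dir, "reference.pdb"))
  ens_a <- gen_conformers(reference, near_native_fraction = 0.2,
                          label = "with_peptide", seed = seed)
  ens_b <- gen_conformers(reference, near_native_fraction = 0,
                          label = "without_peptide", seed = seed + 1L)
  write_conformers_pdb(ens_a$conformers,
                       file.path(out_dir, "ensemble_a.pdb"))
  write_conformers_pdb(ens_b$conformers,
                       file.path(out_dir, "ensemble_b.pdb"))
  write_tsv_dot(bind_rows(
    mutate(ens_a$labels, construct = "with_peptide"),
    mutate(ens_b$labels, construct = "without_peptide")
  ), file.path(out_dir, "ensemble_labels.tsv"))
  invisible(out_dir)
}

#' Default synthetic architecture panel
#'
#' The architecture specs exercised by the synthetic screen: a true tandem
#' with all signatures, a GWW-less pair, an SWW (tandem-incompetent)
#' variant, a long-linker pair, a three-domain protein with one short and
#' one long linker, and a single-domain negative.
#'
#' @return A spec tibble for [gen_domain_architectures()].
#' @export
default_architecture_specs <- function() {
  tibble(
    protein_id = c("ARCH_TANDEM", "ARCH_NOGWW", "ARCH_SWW",
                   "ARCH_LONGLINK", "ARCH_TRIPLE", "ARCH_SINGLE"),
    gww = list(c(TRUE, TRUE), c(FALSE, FALSE), c(FALSE, TRUE),
               c(TRUE, TRUE), c(TRUE, TRUE, TRUE), TRUE),
    cdd = list(c(FALSE, TRUE), c(FALSE, FALSE), c(FALSE, TRUE),
               c(FALSE, TRUE), c(FALSE, TRUE, TRUE), FALSE),
    tail = list(c("strict", "none"), c("none", "none"),
                c("strict", "none"), c("strict", "none"),
                c("strict", "relaxed", "none"), "none"),
    linkers = list(30, 30, 30, 100, c(30, 100), numeric())
  )
}
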