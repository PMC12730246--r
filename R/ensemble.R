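#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' two point sets in one-to-one correspondence, via singular value
#' decomposition of the cross-covariance of the centred coordinates, with
#' the usual determinant correction so reflections are never returned. No
#' outlier-rejection cycles are performed: every point contributes.
#'
#' @param mobile,reference Numeric matrices (n x 3), n >= 3, rows in
#'   correspondence.
#' @return List with `rotation` (3 x 3, det = +1), `translation` (length-3;
#'   the fitted mobile is `mobile %*% rotation + translation`), `rmsd`
#'   (in the units of the coordinates, conventionally Angstrom), and
#'   `degenerate` (`TRUE` for collinear/coincident point sets, which are
#'   still solved).
#' @examples
#' ref <- matrix(rnorm(12), ncol = 3)
#' superpose(ref, ref)$rmsd
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (ncol(mobile) != 3L || ncol(reference) != 3L) {
    abort("Point sets must be n x 3 matrices.")
  }
  if (nrow(mobile) != nrow(reference)) {
    abort(sprintf("Point count mismatch: mobile has %d, reference %d.",
                  nrow(mobile), nrow(reference)))
  }
  if (nrow(mobile) < 3L) {
    abort("At least 3 point pairs are required for superposition.")
  }
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  fitted <- P %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  # rank deficiency of the centred mobile set signals collinear/coincident
  # points; the solution is still the least-squares optimum
  degenerate <- sum(svd(P)$d > max(1e-8, 1e-8 * max(abs(P)))) < 2L
  list(
    rotation = R,
    translation = as.numeric(cr - cm %*% R),
    rmsd = rmsd,
    degenerate = degenerate
  )
}

#' Region specification for superposition
#'
#' Non-overlapping, sorted residue ranges selecting the alpha-carbons used
#' for superposition. The default corresponds to the tandem-SH3 reference
#' crystal structure regions 160-211 and 229-283 (the two SH3 domains,
#' excluding the flexible linker).
#'
#' @param ranges List of `c(start, end)` integer pairs.
#' @return Object of class `region_spec` (integer vector of residue ids).
#' @export
region_spec <- function(ranges = list(c(160L, 211L), c(229L, 283L))) {
  mat <- do.call(rbind, lapply(ranges, function(r) {
    if (length(r) != 2L || r[1] > r[2]) {
      abort("Each range must be c(start, end) with start <= end.")
    }
    as.integer(r)
  }))
  mat <- mat[order(mat[, 1]), , drop = FALSE]
  if (nrow(mat) > 1L && any(mat[-1L, 1] <= mat[-nrow(mat), 2])) {
    abort("Region ranges must be non-overlapping.")
  }
  structure(unlist(apply(mat, 1, function(r) seq(r[1], r[2]),
                         simplify = FALSE)),
            ranges = mat, class = "region_spec")
}

#' Read a conformer ensemble from a multi-model PDB file
#'
#' Extracts alpha-carbon coordinates per MODEL record. All models must
#' provide the same residue set.
#'
#' @param path Multi-model PDB file.
#' @param label Construct label (defaults to the file name).
#' @return Object of class `conformer_set`: list with `label` and `models`,
#'   a list of n x 3 coordinate matrices with residue numbers as rownames.
#' @export
read_conformers_pdb <- function(path, label = basename(path)) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  ca <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
  resno <- pdb$atom$resno[ca$atom]
  xyz <- pdb$xyz[, ca$xyz, drop = FALSE]
  models <- lapply(seq_len(nrow(xyz)), function(i) {
    m <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    rownames(m) <- resno
    m
  })
  conformer_set(label, models)
}

#' @rdname read_conformers_pdb
#' @param models List of n x 3 matrices with residue-id rownames.
#' @export
conformer_set <- function(label, models) {
  if (!length(models)) abort("A conformer set needs at least one model.")
  ids <- rownames(models[[1]])
  if (is.null(ids)) abort("Models must carry residue ids as rownames.")
  same <- vapply(models, function(m) identical(rownames(m), ids), logical(1))
  if (!all(same)) {
    abort("All models in a conformer set must share the same residue ids.")
  }
  structure(list(label = label, models = models), class = "conformer_set")
}

#' @export
print.conformer_set <- function(x, ...) {
  cat(sprintf("<conformer_set> '%s': %d models, %d residues\n",
              x$label, length(x$models), nrow(x$models[[1]])))
  invisible(x)
}

#' Per-model RMSD of an ensemble to a reference region
#'
#' Superposes every model onto the reference over the region's
#' alpha-carbons (least-squares, no rejection cycles) and returns the
#' minimised RMSD per model.
#'
#' @param conformers A [conformer_set()].
#' @param reference n x 3 matrix with residue-id rownames (the reference
#'   coordinates).
#' @param region A [region_spec()]; defaults to all residues shared by the
#'   reference and the models.
#' @return Numeric vector of RMSDs (one per model, in input units).
#' @export
rmsd_to_reference <- function(conformers, reference, region = NULL) {
  stopifnot(inherits(conformers, "conformer_set"))
  ref_ids <- rownames(reference)
  if (is.null(ref_ids)) abort("`reference` must carry residue-id rownames.")
  want <- if (is.null(region)) {
    intersect(ref_ids, rownames(conformers$models[[1]]))
  } else {
    as.character(unclass(region))
  }
  miss_ref <- setdiff(want, ref_ids)
  if (length(miss_ref)) {
    abort(sprintf("Reference is missing region residue(s): %s.",
                  paste(head(miss_ref, 5), collapse = ", ")))
  }
  ref_sel <- reference[match(want, ref_ids), , drop = FALSE]
  vapply(seq_along(conformers$models), function(i) {
    m <- conformers$models[[i]]
    miss <- setdiff(want, rownames(m))
    if (length(miss)) {
      abort(sprintf("Model %d is missing region residue(s): %s.",
                    i, paste(head(miss, 5), collapse = ", ")))
    }
    superpose(m[match(want, rownames(m)), , drop = FALSE], ref_sel)$rmsd
  }, numeric(1))
}

#' Compare two conformer ensembles by their RMSD distributions
#'
#' Classifies each conformer as tandem-like when its RMSD to the reference
#' region is below `threshold` (5 Angstrom by default), reports the tandem
#' fraction of each ensemble, and tests the two raw RMSD distributions
#' against each other with a two-sided Welch two-sample t-test.
#'
#' @param a,b Numeric vectors of per-model RMSDs (length >= 2 each).
#' @param threshold Tandem RMSD cutoff in Angstrom (default 5.0; the
#'   fraction counts strict `rmsd < threshold`).
#' @param labels Length-2 character vector naming the constructs.
#' @return Object of class `ensemble_comparison` with fields `rmsds_a`,
#'   `rmsds_b`, `fraction_tandem_a`, `fraction_tandem_b`, `threshold`,
#'   `t_statistic`, `p_value`, `labels`. When both samples have zero
#'   variance, `p = 1` with `t = 0` if the means are equal (degenerate
#'   means-differ case: `t = +/-Inf`, `p = 0`).
#' @examples
#' compare_ensembles(c(2, 2.1, 1.9), c(10, 10.2, 9.8))
#' @export
compare_ensembles <- function(a, b, threshold = 5.0,
                              labels = c("a", "b")) {
  if (length(a) < 2L || length(b) < 2L) {
    abort("Each RMSD list must have at least 2 values.")
  }
  if (sd(a) == 0 && sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      tstat <- 0; pval <- 1
    } else {
      tstat <- sign(mean(a) - mean(b)) * Inf; pval <- 0
    }
  } else {
    tt <- t.test(a, b, var.equal = FALSE)
    tstat <- unname(tt$statistic); pval <- tt$p.value
  }
  structure(
    list(
      rmsds_a = a, rmsds_b = b,
      fraction_tandem_a = mean(a < threshold),
      fraction_tandem_b = mean(b < threshold),
      threshold = threshold,
      t_statistic = tstat, p_value = pval,
      labels = labels
    ),
    class = "ensemble_comparison"
  )
}

#' @export
print.ensemble_comparison <- function(x, ...) {
  cat(sprintf(
    "<ensemble_comparison> %s vs %s: tandem fractions %.2f / %.2f (RMSD < %.1f A); Welch t = %.3f, p = %.3g\n",
    x$labels[1], x$labels[2], x$fraction_tandem_a, x$fraction_tandem_b,
    x$threshold, x$t_statistic, x$p_value
  ))
  invisible(x)
}

#' @export
tidy.ensemble_comparison <- function(x, ...) {
  bind_rows(
    tibble(construct = x$labels[1], model = seq_along(x$rmsds_a),
           rmsd = x$rmsds_a, tandem = x$rmsds_a < x$threshold),
    tibble(construct = x$labels[2], model = seq_along(x$rmsds_b),
           rmsd = x$rmsds_b, tandem = x$rmsds_b < x$threshold)
  )
}

#' @export
glance.ensemble_comparison <- function(x, ...) {
  tibble(
    construct_a = x$labels[1], construct_b = x$labels[2],
    n_a = length(x$rmsds_a), n_b = length(x$rmsds_b),
    fraction_tandem_a = x$fraction_tandem_a,
    fraction_tandem_b = x$fraction_tandem_b,
    threshold = x$threshold,
    t_statistic = x$t_statistic, p_value = x$p_value
  )
}

#' Distance between the GWW signature glycines of two domains
#'
#' Euclidean distance between the alpha-carbons of the two Gly residues of
#' the GWW triplets, the quantity that separates intrachain tandemization
#' (glycines in contact range) from interchain SH3 clustering (glycines far
#' apart).
#'
#' @param model n x 3 coordinate matrix with residue-id rownames.
#' @param gly_position_n,gly_position_c Residue ids of the N- and C-domain
#'   signature glycines.
#' @return Distance in input units (Angstrom).
#' @export
gww_gly_distance <- function(model, gly_position_n, gly_position_c) {
  ids <- rownames(model)
  i <- match(as.character(gly_position_n), ids)
  j <- match(as.character(gly_position_c), ids)
  if (is.na(i) || is.na(j)) {
    abort("Both glycine residues must be present in the model.")
  }
  sqrt(sum((model[i, ] - model[j, ])^2))
}

#' Write per-model ensemble results to TSV
#'
#' @param x An `ensemble_comparison`.
#' @param path Output path for the per-model table; the comparison summary
#'   is written next to it with suffix `.summary.tsv`.
#' @return `path`, invisibly.
#' @export
write_ensemble_tsv <- function(x, path) {
  write_tsv_dot(tidy(x), path)
  write_tsv_dot(glance(x), paste0(path, ".summary.tsv"))
  invisible(path)
}
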