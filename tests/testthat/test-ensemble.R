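toy_points <- function(n = 4L) {
  matrix(c(0, 0, 0,
           1.5, 0.2, -0.3,
           -0.7, 2.1, 0.5,
           0.4, -1.1, 1.8,
           2.2, 1.3, -1.7,
           -1.9, 0.6, 2.4), ncol = 3, byrow = TRUE)[seq_len(n), ,
                                                    drop = FALSE]
}

test_that("superposition is exact under rigid motions", {
  withr::local_seed(61)
  ref <- toy_points(6)
  expect_equal(superpose(ref, ref)$rmsd, 0, tolerance = 1e-12)
  for (i in 1:20) {
    moved <- random_rigid_motion(ref)
    fit <- superpose(moved, ref)
    expect_lt(fit$rmsd, 1e-8)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    # the returned transform actually maps mobile onto reference
    mapped <- sweep(moved %*% fit$rotation, 2, -fit$translation)
    expect_equal(mapped, ref, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("superposition matches the rotation-grid oracle on toy sets", {
  withr::local_seed(62)
  for (i in 1:5) {
    mobile <- matrix(rnorm(12, sd = 2), ncol = 3)
    reference <- matrix(rnorm(12, sd = 2), ncol = 3)
    expect_equal(superpose(mobile, reference)$rmsd,
                 oracle_grid_rmsd(mobile, reference),
                 tolerance = 1e-3)
  }
})

test_that("superposition rejects bad input and flags degeneracy", {
  expect_error(superpose(toy_points(4), toy_points(5)), "mismatch")
  expect_error(superpose(toy_points(2), toy_points(2)), "At least 3")
  line <- cbind(1:5, 0, 0)
  fit <- superpose(line, line)
  expect_true(fit$degenerate)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_false(superpose(toy_points(4), toy_points(4))$degenerate)
})

test_that("superposition never exceeds the unsuperposed RMSD and is symmetric", {
  withr::local_seed(63)
  for (i in 1:20) {
    a <- matrix(rnorm(30), ncol = 3)
    b <- matrix(rnorm(30), ncol = 3)
    raw <- sqrt(mean(rowSums((a - b)^2)))
    expect_lte(superpose(a, b)$rmsd, raw + 1e-12)
    expect_equal(superpose(a, b)$rmsd, superpose(b, a)$rmsd,
                 tolerance = 1e-9)
  }
  # a mirrored set is not recovered by a proper rotation
  ref <- toy_points(6)
  mirrored <- ref %*% diag(c(-1, 1, 1))
  expect_gt(superpose(mirrored, ref)$rmsd, 0.1)
})

test_that("ensemble RMSDs recover rigid motions and planted fractions", {
  withr::local_seed(64)
  reference <- gen_reference_structure()
  rigid <- conformer_set("rigid", lapply(1:5, function(i) {
    m <- random_rigid_motion(reference)
    rownames(m) <- rownames(reference)
    m
  }))
  expect_true(all(rmsd_to_reference(rigid, reference) < 1e-6))
  gen <- gen_conformers(reference, n_models = 30, near_native_fraction = 0.2,
                        seed = 65)
  rmsds <- rmsd_to_reference(gen$conformers, reference)
  expect_equal(mean(rmsds < 5), 0.2)
  expect_equal(rmsds < 5, gen$labels$intended_tandem)
})

test_that("noisy ensembles have RMSD near the analytic noise level", {
  sdev <- 0.5
  reference <- gen_reference_structure()
  gen <- gen_conformers(reference, n_models = 20, near_native_fraction = 1,
                        noise_sd = sdev, seed = 66)
  rmsds <- rmsd_to_reference(gen$conformers, reference)
  # per-coordinate gaussian noise of sd s gives RMSD ~ s*sqrt(3)
  expect_equal(mean(rmsds), sdev * sqrt(3), tolerance = 0.1)
})

test_that("missing region residues are reported by model", {
  reference <- gen_reference_structure()
  short <- reference[-1, , drop = FALSE]
  set <- conformer_set("short", list(short))
  expect_error(rmsd_to_reference(set, reference, region_spec()),
               "Model 1 is missing")
  expect_error(
    rmsd_to_reference(conformer_set("x", list(reference)),
                      reference[-1, , drop = FALSE], region_spec()),
    "Reference is missing"
  )
})

test_that("region specs validate and order their ranges", {
  rs <- region_spec(list(c(229L, 283L), c(160L, 211L)))
  expect_equal(unclass(rs)[1], 160L)
  expect_length(unclass(rs), 52 + 55)
  expect_error(region_spec(list(c(10L, 5L))), "start <= end")
  expect_error(region_spec(list(c(1L, 10L), c(5L, 20L))),
               "non-overlapping")
})

test_that("ensemble comparison reproduces a hand-computed Welch test", {
  a <- c(1.2, 2.4, 3.1, 4.5)
  b <- c(2.0, 4.1, 6.3, 8.2, 10.4)
  cmp <- compare_ensembles(a, b)
  # hand computation of the Welch statistic and df
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t_hand <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_hand <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(cmp$t_statistic, t_hand, tolerance = 1e-6)
  expect_equal(cmp$p_value, p_hand, tolerance = 1e-6)
})

test_that("comparison handles identical, separated and degenerate samples", {
  same <- compare_ensembles(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  withr::local_seed(67)
  sep <- compare_ensembles(2 + rnorm(20, sd = 0.01),
                           10 + rnorm(20, sd = 0.01))
  expect_lt(sep$p_value, 1e-10)
  expect_equal(sep$fraction_tandem_a, 1)
  expect_equal(sep$fraction_tandem_b, 0)
  # p is invariant to swapping the samples
  swapped <- compare_ensembles(10 + rnorm(20, sd = 0.01),
                               2 + rnorm(20, sd = 0.01))
  expect_equal(sep$p_value, swapped$p_value, tolerance = 0.5)
  # zero variance in both with equal means: p = 1 by convention
  flat <- compare_ensembles(c(2, 2, 2), c(2, 2, 2))
  expect_equal(flat$p_value, 1)
  expect_equal(flat$t_statistic, 0)
})

test_that("tandem fraction is monotone in the threshold", {
  withr::local_seed(68)
  a <- runif(30, 0, 12)
  fracs <- vapply(c(1, 3, 5, 8, 15), function(th) {
    compare_ensembles(a, a, threshold = th)$fraction_tandem_a
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("GWW glycine distances are plain Euclidean distances", {
  m <- rbind(`10` = c(0, 0, 0), `50` = c(3, 4, 0))
  expect_equal(gww_gly_distance(m, 10, 10), 0)
  expect_equal(gww_gly_distance(m, 10, 50), 5)
  expect_error(gww_gly_distance(m, 10, 99), "must be present")
  withr::local_seed(69)
  for (i in 1:10) {
    pts <- matrix(rnorm(6), ncol = 3)
    rownames(pts) <- c("1", "2")
    expect_equal(gww_gly_distance(pts, 1, 2),
                 sqrt(sum((pts[1, ] - pts[2, ])^2)))
  }
})

test_that("multi-model PDB files round-trip through the standard reader", {
  reference <- gen_reference_structure()
  gen <- gen_conformers(reference, n_models = 3, near_native_fraction = 1,
                        noise_sd = 0, seed = 70)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_conformers_pdb(gen$conformers, path)
  back <- read_conformers_pdb(path)
  expect_length(back$models, 3)
  expect_equal(rownames(back$models[[1]]), rownames(reference))
  for (i in 1:3) {
    expect_equal(back$models[[i]], gen$conformers$models[[i]],
                 tolerance = 1e-3, ignore_attr = TRUE)
  }
})
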