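# Independent oracles used across the suite. These deliberately avoid the
# package's matching/superposition code paths.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Positional classes of the built-in definitions, written out literally.
ORACLE_DEFS <- list(
  strong = list(
    core = list(c("P", "A", "V", "I", "L"), "P", "P", "R", c("P", "R")),
    excl = list(c("D", "E"), c("D", "E")),
    full = TRUE
  ),
  weak = list(
    core = list(c("P", "A", "V", "I", "L"), "P", c("P", "T", "A", "V"),
                "R", c("R", "P")),
    excl = list(c("D", "E"), c("D", "E")),
    full = TRUE
  ),
  core = list(
    core = list(c("P", "A", "V", "I", "L"), "P", "P", "R", c("P", "R")),
    excl = list(character(), character()),
    full = FALSE
  )
)

# Brute-force window oracle: tests every window position by position.
oracle_scan_starts <- function(sequence, def_name) {
  def <- ORACLE_DEFS[[def_name]]
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(chars)
  out <- integer()
  for (s in seq_len(max(0L, L - 4L))) {
    ok <- TRUE
    for (j in 1:5) {
      if (!(chars[s + j - 1L] %in% def$core[[j]])) ok <- FALSE
    }
    if (ok && def$full) {
      if (s + 6L > L) {
        ok <- FALSE
      } else {
        for (j in 1:2) {
          res <- chars[s + 4L + j]
          if (res %in% def$excl[[j]] || res == "X") ok <- FALSE
        }
      }
    }
    if (ok) out <- c(out, s)
  }
  out
}

# Window oracle for the Px[PAV]xPR 6-mer.
oracle_pxpavxpr_starts <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(chars)
  out <- integer()
  for (s in seq_len(max(0L, L - 5L))) {
    w <- chars[s:(s + 5L)]
    if (w[1] == "P" && w[2] %in% AA20 && w[3] %in% c("P", "A", "V") &&
        w[4] %in% AA20 && w[5] == "P" && w[6] == "R") {
      out <- c(out, s)
    }
  }
  out
}

# Exact expected motif count per window for a uniform random permutation of
# the sequence's residue multiset: recursive sum over residue draws without
# replacement; total expectation is (windows) * P(single window matches), by
# exchangeability of window positions under permutation.
oracle_perm_expected_count <- function(sequence, def_name) {
  def <- ORACLE_DEFS[[def_name]]
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  counts <- table(chars)
  classes <- def$core
  if (def$full) {
    classes <- c(classes, lapply(def$excl, function(e) {
      setdiff(AA20, e)
    }))
  }
  L <- length(chars)
  w <- L - length(classes) + 1L
  if (w < 1L) return(0)
  prob <- function(cnt, depth) {
    if (depth > length(classes)) return(1)
    total <- sum(cnt)
    p <- 0
    for (res in intersect(names(cnt)[cnt > 0], classes[[depth]])) {
      cnt2 <- cnt
      cnt2[res] <- cnt2[res] - 1
      p <- p + (cnt[[res]] / total) * prob(cnt2, depth + 1L)
    }
    p
  }
  cnt <- as.vector(counts); names(cnt) <- names(counts)
  w * prob(cnt, 1L)
}

# Brute-force superposition oracle: minimise RMSD over a rotation grid
# (Euler angles) with local polish; independent of the SVD solution.
oracle_grid_rmsd <- function(mobile, reference, coarse = 24L) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  rot <- function(a, b, g) {
    Rz1 <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
    Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3)
    Rz2 <- matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3)
    Rz1 %*% Ry %*% Rz2
  }
  obj <- function(ang) {
    R <- rot(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((P %*% R - Q)^2)))
  }
  best <- NULL; best_val <- Inf
  as_grid <- seq(0, 2 * pi, length.out = coarse + 1L)[-(coarse + 1L)]
  bs_grid <- seq(0, pi, length.out = coarse %/% 2 + 1L)
  for (a in as_grid) for (b in bs_grid) for (g in as_grid) {
    v <- obj(c(a, b, g))
    if (v < best_val) { best_val <- v; best <- c(a, b, g) }
  }
  polish <- stats::optim(best, obj, method = "Nelder-Mead",
                         control = list(reltol = 1e-14, maxit = 5000))
  min(best_val, polish$value)
}

random_aa_string <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Proper random rotation + translation applied to a coordinate matrix.
random_rigid_motion <- function(coords) {
  M <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  shift <- runif(3, -50, 50)
  sweep(coords %*% Q, 2, -shift)
}
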