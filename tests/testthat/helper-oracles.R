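# Independent brute-force oracles used to freeze expected values.
# These deliberately re-derive results from first principles and never
# call the implementation paths they check.

# Count lysine-centered windows by direct position scan.
oracle_window_count <- function(seq, window_length = 7L, center_index = 4L) {
  chars <- strsplit(toupper(seq), "")[[1]]
  before <- center_index - 1L
  after <- window_length - center_index
  sum(chars == "K" &
        seq_along(chars) > before &
        seq_along(chars) <= length(chars) - after)
}

# Distinct 7-mers via set membership.
oracle_distinct <- function(peptides) length(unique(peptides))

# Closed-form screened Coulomb energy for a single pair.
oracle_pair_energy <- function(q1, q2, r, eps) 332.0637 * q1 * q2 / (eps * r)

# Pearson r and two-sided t-test p-value from the defining formulas.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2), n = n)
}

# Sliding-window motif check without regular expressions.
oracle_motif_hits <- function(seq, motif_id) {
  chars <- strsplit(toupper(seq), "")[[1]]
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  check <- switch(motif_id,
    "ELxF/YDY" = function(w) {
      length(w) == 6 && w[1] == "E" && w[2] == "L" && w[3] %in% std &&
        w[4] %in% c("F", "Y") && w[5] == "D" && w[6] == "Y"
    },
    "NHS/CxxPN" = function(w) {
      length(w) == 7 && w[1] == "N" && w[2] == "H" && w[3] %in% c("S", "C") &&
        w[4] %in% std && w[5] %in% std && w[6] == "P" && w[7] == "N"
    })
  width <- if (motif_id == "ELxF/YDY") 6L else 7L
  starts <- integer()
  for (i in seq_len(max(0L, length(chars) - width + 1L))) {
    if (check(chars[i:(i + width - 1L)])) starts <- c(starts, i)
  }
  starts
}

# Affine-gap global alignment score by exhaustive Gotoh dynamic
# programming (gap of length L costs go + L * ge, the Biostrings
# convention). Independent of Biostrings::pairwiseAlignment.
oracle_global_score <- function(q, r, submat, go = 10, ge = 0.5) {
  q <- strsplit(q, "")[[1]]; r <- strsplit(r, "")[[1]]
  n <- length(q); m <- length(r)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in reference (consumes query)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in query (consumes reference)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(go + i * ge)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(go + j * ge)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[q[i], r[j]]
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - go - ge, Ix[i, j + 1] - ge)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - go - ge, Iy[i + 1, j] - ge)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Random amino-acid sequence (standard residues only).
random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, TRUE),
        collapse = "")
}

# Rigid transform: random rotation (QR of a Gaussian matrix) + translation.
random_rigid_transform <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, 0, 20))
}

apply_rigid <- function(model, tf) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(tf$R) + matrix(tf$t, nrow(xyz), 3, byrow = TRUE)
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

# A reference annotation built on a reproducible synthetic sequence with
# tyrosines planted at the canonical active-site positions.
synthetic_reference <- function(seed = 42L, len = 400L,
                                pos = c(276L, 341L, 357L)) {
  set.seed(seed)
  chars <- sample(strsplit("ACDEFGHIKLMNPQRSTVW", "")[[1]], len, TRUE)
  chars[pos] <- "Y"
  reference_annotation(paste(chars, collapse = ""), pos)
}

# Mutate given positions of a sequence to `to`.
mutate_at <- function(seq, positions, to = "A") {
  chars <- strsplit(seq, "")[[1]]
  chars[positions] <- to
  paste(chars, collapse = "")
}
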