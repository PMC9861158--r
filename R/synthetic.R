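#' Synthetic enzyme-peptide-cofactor complex with controlled geometry
#'
#' Builds a minimal complex in which the catalytic geometry is exact by
#' construction: substrate Lys NZ at the origin, SAM SD at `d_mt`
#' Angstrom, the transferable methyl carbon CE placed so the NZ-CE-SD
#' attack angle equals `attack_angle`, and a catalytic Tyr OH at `d_pt`
#' from NZ. Optionally an arginine is placed with minimum heavy-atom
#' distance `arg_distance` to the cofactor, and a charged "binder"
#' residue near the peptide lysine realizes one of three charge schemes:
#' \describe{
#'   \item{strong_binder}{a Glu carboxylate close to the Lys ammonium
#'     (attractive; negative LRA score by construction)}
#'   \item{null}{no binder residue (score dominated by the mild
#'     sulfonium-ammonium repulsion)}
#'   \item{decoy}{an Arg guanidinium close to the Lys ammonium
#'     (repulsive; most positive score)}
#' }
#' Residues carry only the atoms the pipeline reads plus backbone stubs;
#' Gaussian coordinate noise (`noise_sigma`, seeded) is applied after
#' exact placement. The peptide is chain P (Lys flanked by Gly stubs),
#' enzyme and cofactor are chain A with SAM as a HETATM residue.
#'
#' @param d_mt SD-NZ methyl-transfer distance, Angstrom (default 4.4).
#' @param d_pt OH-NZ proton-transfer distance, Angstrom (default 3.0).
#' @param attack_angle NZ-CE-SD angle, degrees in (0, 180] (default 180).
#' @param include_arg Place the cofactor-contacting arginine? (default TRUE)
#' @param arg_distance Min heavy-atom Arg-cofactor distance (default 3.5).
#' @param charge_scheme `"null"`, `"strong_binder"` or `"decoy"`.
#' @param binder_distance Binder-group distance from NZ (default 3.0).
#' @param noise_sigma Gaussian coordinate noise, Angstrom (default 0).
#' @param seed RNG seed for the noise (`NULL` = use current RNG state).
#' @return An object of class `synthetic_complex`: `model` (a
#'   `complex_model`), `pdb` (PDB text), and `truth` (the requested
#'   ground-truth geometry and scheme).
#' @export
gen_complex <- function(d_mt = 4.4, d_pt = 3.0, attack_angle = 180,
                        include_arg = TRUE, arg_distance = 3.5,
                        charge_scheme = c("null", "strong_binder", "decoy"),
                        binder_distance = 3.0, noise_sigma = 0, seed = 0L) {
  charge_scheme <- match.arg(charge_scheme)
  stopifnot(d_mt > 0, d_pt > 0, arg_distance > 0, binder_distance > 0,
            attack_angle > 0, attack_angle <= 180, noise_sigma >= 0)
  b_sc <- 1.8  # S-C bond length used for the SD-CE placement
  if (d_mt <= b_sc) {
    stop("infeasible geometry: d_mt must exceed the S-C bond length (1.8 A)")
  }

  nz <- c(0, 0, 0)
  sd_pos <- c(d_mt, 0, 0)
  ce <- place_methyl_carbon(nz, sd_pos, b_sc, attack_angle)
  # Tyr OH off to the side of the NZ..SD axis
  u_oh <- c(cos(110 * pi / 180), sin(110 * pi / 180), 0)
  oh <- nz + d_pt * u_oh

  atom <- function(rec, name, resid, chain, resno, pos) {
    data.frame(rec = rec, elety = name, resid = resid, chain = chain,
               resno = resno, x = pos[1], y = pos[2], z = pos[3],
               stringsAsFactors = FALSE)
  }
  rows <- list(
    # peptide chain P: Gly-Lys-Gly with minimal backbone stubs
    atom("ATOM", "CA", "GLY", "P", 3L, c(-3.5, -2.5, 0)),
    atom("ATOM", "N",  "LYS", "P", 4L, c(-1.6, -3.2, 0)),
    atom("ATOM", "CA", "LYS", "P", 4L, c(-0.8, -2.0, 0)),
    atom("ATOM", "NZ", "LYS", "P", 4L, nz),
    atom("ATOM", "CA", "GLY", "P", 5L, c(1.5, -3.0, 0)),
    # catalytic tyrosine
    atom("ATOM", "CA", "TYR", "A", 357L, oh + 4.0 * u_oh),
    atom("ATOM", "CZ", "TYR", "A", 357L, oh + 1.4 * u_oh),
    atom("ATOM", "OH", "TYR", "A", 357L, oh),
    # SAM cofactor
    atom("HETATM", "SD", "SAM", "A", 400L, sd_pos),
    atom("HETATM", "CE", "SAM", "A", 400L, ce),
    atom("HETATM", "CG", "SAM", "A", 400L, sd_pos + c(-0.5, -1.7, 0)))
  if (include_arg) {
    rows <- c(rows, list(
      atom("ATOM", "NH1", "ARG", "A", 147L, sd_pos + c(0, 0, arg_distance)),
      atom("ATOM", "CZ",  "ARG", "A", 147L, sd_pos + c(0, 0, arg_distance + 1.33)),
      atom("ATOM", "NH2", "ARG", "A", 147L, sd_pos + c(1.2, 0, arg_distance + 1.9))))
  }
  if (charge_scheme == "strong_binder") {
    base <- nz + c(0, 0, -binder_distance)
    rows <- c(rows, list(
      atom("ATOM", "CD",  "GLU", "A", 50L, base + c(0.6, 0, -1.2)),
      atom("ATOM", "OE1", "GLU", "A", 50L, base),
      atom("ATOM", "OE2", "GLU", "A", 50L, base + c(1.2, 0, 0))))
  } else if (charge_scheme == "decoy") {
    base <- nz + c(0, 0, -binder_distance)
    rows <- c(rows, list(
      atom("ATOM", "CZ",  "ARG", "A", 50L, base),
      atom("ATOM", "NH1", "ARG", "A", 50L, base + c(1.2, 0, 0)),
      atom("ATOM", "NH2", "ARG", "A", 50L, base + c(-0.6, 1.1, 0))))
  }
  atoms <- do.call(rbind, rows)

  if (noise_sigma > 0) {
    jitter <- function() {
      n <- nrow(atoms)
      atoms$x <<- atoms$x + rnorm(n, 0, noise_sigma)
      atoms$y <<- atoms$y + rnorm(n, 0, noise_sigma)
      atoms$z <<- atoms$z + rnorm(n, 0, noise_sigma)
    }
    if (is.null(seed)) jitter() else with_seed(seed, jitter())
  }

  atoms$elesy <- toupper(substr(gsub("[0-9]", "", atoms$elety), 1L, 1L))
  model <- resolve_roles(atoms[, c("elety", "resid", "chain", "resno",
                                   "x", "y", "z", "elesy")],
                         cofactor = "A:400", substrate_lys = "P:4",
                         tyr = "A:357",
                         arg = if (include_arg) "A:147" else NULL)
  structure(list(model = model,
                 pdb = format_pdb(atoms),
                 truth = list(d_mt = d_mt, d_pt = d_pt,
                              attack_angle = attack_angle,
                              arg_contact_min = if (include_arg) arg_distance
                                                else NA_real_,
                              charge_scheme = charge_scheme,
                              noise_sigma = noise_sigma, seed = seed)),
            class = "synthetic_complex")
}

# CE on the circle of radius `b` around SD (in the z = 0 plane) such that
# the NZ-CE-SD angle equals `theta` degrees. For theta = 180 CE lies on
# the NZ..SD segment; otherwise the placement angle is solved numerically.
place_methyl_carbon <- function(nz, sd_pos, b, theta) {
  ce_at <- function(phi) sd_pos + b * c(-cos(phi), sin(phi), 0)
  if (theta >= 180) return(ce_at(0))
  f <- function(phi) vangle(nz, ce_at(phi), sd_pos) - theta
  sol <- tryCatch(stats::uniroot(f, c(1e-9, pi - 1e-9), tol = 1e-12),
                  error = function(e)
                    stop("infeasible geometry: no CE placement achieves the requested attack angle"))
  ce_at(sol$root)
}

# Serialize the atom table as fixed-column PDB text.
format_pdb <- function(atoms) {
  name4 <- ifelse(nchar(atoms$elety) < 4L,
                  sprintf("%-4s", paste0(" ", atoms$elety)),
                  atoms$elety)
  lines <- sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   atoms$rec, seq_len(nrow(atoms)), name4, atoms$resid,
                   atoms$chain, atoms$resno, atoms$x, atoms$y, atoms$z,
                   1.00, 0.00,
                   toupper(substr(gsub("[0-9]", "", atoms$elety), 1L, 1L)))
  paste(c(lines, "END"), collapse = "\n")
}

#' Write a synthetic complex to a PDB file
#'
#' @param x A `synthetic_complex` from [gen_complex()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_complex_pdb <- function(x, path) {
  stopifnot(inherits(x, "synthetic_complex"))
  writeLines(x$pdb, path)
  invisible(path)
}

#' Synthetic model ensemble with known competent/decoy labels
#'
#' Generates `round(n * frac_competent)` catalytically competent models
#' (from `competent_spec`) and the remainder as geometric decoys (from
#' `decoy_spec`, default: far-off MT and PT distances), shuffles them
#' deterministically, and returns the models with their ground-truth
#' labels for filter validation.
#'
#' @param n Ensemble size.
#' @param frac_competent Fraction of competent models in \[0, 1\].
#' @param competent_spec,decoy_spec Argument lists for [gen_complex()].
#' @param seed Integer RNG seed (shuffling and any noise).
#' @return A list with `models` (list of `synthetic_complex`), `labels`
#'   (logical, `TRUE` = competent) and `n_competent`.
#' @export
gen_ensemble <- function(n, frac_competent,
                         competent_spec = list(),
                         decoy_spec = list(d_mt = 8.0, d_pt = 6.0),
                         seed = 1L) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  stopifnot(frac_competent >= 0, frac_competent <= 1)
  n_comp <- as.integer(round(n * frac_competent))
  with_seed(seed, {
    labels <- sample(rep(c(TRUE, FALSE), c(n_comp, n - n_comp)))
    models <- lapply(labels, function(comp) {
      spec <- if (comp) competent_spec else decoy_spec
      spec$seed <- NULL
      do.call(gen_complex, c(spec, list(seed = NULL)))
    })
    list(models = models, labels = labels, n_competent = n_comp)
  })
}

#' Gene-by-cell-line matrix with planted correlations
#'
#' Fills an `n_genes` x `n_cols` matrix with independent standard
#' Gaussian noise, then rewrites each planted pair (a, b, r_true) by the
#' bivariate-Gaussian construction `b = r_true * a + sqrt(1 - r_true^2) *
#' e`, which has expected Pearson correlation `r_true`. Deterministic per
#' seed.
#'
#' @param n_genes,n_cols Matrix dimensions (`n_cols >= 3`).
#' @param planted_pairs `data.frame(gene_a, gene_b, r_true)` with
#'   `|r_true| < 1`; gene names not already present replace auto-generated
#'   row names. Duplicate (unordered) pairs are an error.
#' @param seed Integer RNG seed.
#' @param gene_ids,col_ids Optional identifier vectors.
#' @return A list with `matrix` (rownames = genes, colnames = cell lines)
#'   and `truth` (the planted pairs).
#' @export
gen_planted_matrix <- function(n_genes, n_cols, planted_pairs = NULL,
                               seed = 1L, gene_ids = NULL, col_ids = NULL) {
  n_genes <- as.integer(n_genes); n_cols <- as.integer(n_cols)
  stopifnot(n_genes >= 1L, n_cols >= 3L)
  gene_ids <- gene_ids %||% sprintf("G%04d", seq_len(n_genes))
  col_ids <- col_ids %||% sprintf("CL%04d", seq_len(n_cols))
  stopifnot(length(gene_ids) == n_genes, length(col_ids) == n_cols,
            !anyDuplicated(gene_ids), !anyDuplicated(col_ids))
  if (!is.null(planted_pairs)) {
    stopifnot(all(abs(planted_pairs$r_true) < 1))
    key <- apply(planted_pairs[, c("gene_a", "gene_b")], 1L,
                 function(p) paste(sort(p), collapse = "|"))
    if (anyDuplicated(key)) stop("duplicate planted pair")
    wanted <- unique(c(planted_pairs$gene_a, planted_pairs$gene_b))
    missing <- setdiff(wanted, gene_ids)
    if (length(missing) > n_genes - length(intersect(wanted, gene_ids))) {
      stop("more planted genes than rows")
    }
    # give planted genes the first unclaimed auto-generated rows
    free <- which(!gene_ids %in% wanted)
    gene_ids[free[seq_along(missing)]] <- missing
  }
  with_seed(seed, {
    m <- matrix(rnorm(n_genes * n_cols), nrow = n_genes,
                dimnames = list(gene_ids, col_ids))
    if (!is.null(planted_pairs)) {
      for (i in seq_len(nrow(planted_pairs))) {
        a <- planted_pairs$gene_a[i]; b <- planted_pairs$gene_b[i]
        r <- planted_pairs$r_true[i]
        m[b, ] <- r * m[a, ] + sqrt(1 - r^2) * rnorm(n_cols)
      }
    }
    list(matrix = m, truth = planted_pairs)
  })
}
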