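#' Simplified LRA electrostatic binding score
#'
#' The binding free energy of a peptide to the enzyme-cofactor complex is
#' estimated in the linear response approximation (LRA) as
#' \deqn{\Delta G_{bind} = \tfrac12(\langle U\rangle_{charged} +
#'   \langle U\rangle_{uncharged})}
#' where U is the screened Coulomb interaction energy between the peptide
#' (solute) and the rest of the complex, averaged over configurations
#' generated with the solute charges on and off. Interactions use a
#' dielectric constant of 4 for the neutral protein environment and an
#' effective dielectric of 60 for charge-charge interactions between
#' ionizable groups (and the cofactor sulfonium). Configurations are
#' generated by Gaussian positional perturbation of the input geometry.
#'
#' This scorer deliberately keeps only the electrostatic, rigid-geometry
#' part of a full semi-macroscopic PDLD/S-LRA treatment: no explicit or
#' Langevin-dipole solvent, no molecular dynamics sampling, no solvation
#' or entropy terms. It yields a self-consistent, reproducible ranking
#' surface, not absolute transfer free energies.
#'
#' @name lra_scoring
NULL

# Coulomb constant in kcal * Angstrom / (mol * e^2)
COULOMB_K <- 332.0637

#' Assign partial charges to every atom of a complex model
#'
#' Formal-charge rules for ionizable groups at physiological pH: Lys +1 on
#' NZ, Arg +1 on CZ, Asp -1 split -0.5/-0.5 over OD1/OD2, Glu -1 split
#' over OE1/OE2, and the SAM sulfonium +1 on SD (SAH is neutral). Atoms
#' not covered by a rule take values from an optional user charge table
#' (`data.frame` with columns resid, elety, charge) and default to 0.
#'
#' @param model A `complex_model`.
#' @param charge_table Optional `data.frame(resid, elety, charge)` for
#'   non-ionizable atoms.
#' @return The atom table of `model` with numeric `charge` and logical
#'   `ionizable` columns appended.
#' @export
assign_charges <- function(model, charge_table = NULL) {
  stopifnot(inherits(model, "complex_model"))
  a <- model$atoms
  q <- numeric(nrow(a))
  ion <- logical(nrow(a))
  rule <- function(resid, elety, charge) {
    i <- a$resid == resid & a$elety %in% elety
    q[i] <<- charge
    ion[i] <<- TRUE
  }
  rule("LYS", "NZ", +1)
  rule("ARG", "CZ", +1)
  rule("ASP", c("OD1", "OD2"), -0.5)
  rule("GLU", c("OE1", "OE2"), -0.5)
  rule("SAM", "SD", +1)  # sulfonium; SAH has transferred its methyl, neutral
  if (!is.null(charge_table)) {
    for (r in seq_len(nrow(charge_table))) {
      i <- a$resid == charge_table$resid[r] &
        a$elety == charge_table$elety[r] & !ion
      q[i] <- charge_table$charge[r]
    }
  }
  a$charge <- q
  a$ionizable <- ion
  a
}

#' Screened Coulomb interaction energy between two atom groups
#'
#' \deqn{U = \sum_{i \in a, j \in b} 332.0637 \, q_i q_j /
#'   (\epsilon_{ij} r_{ij})} in kcal/mol, with
#' \eqn{\epsilon_{ij} = \epsilon_{cc}} when both atoms belong to
#' ionizable groups (or the cofactor sulfonium) and
#' \eqn{\epsilon_{neutral}} otherwise.
#'
#' @param group_a,group_b Disjoint atom tables with columns x, y, z,
#'   charge, ionizable (as from [assign_charges()]).
#' @param eps_neutral Dielectric for neutral environment (default 4).
#' @param eps_cc Effective dielectric for charge-charge interactions
#'   (default 60).
#' @return Interaction energy in kcal/mol.
#' @export
interaction_energy <- function(group_a, group_b, eps_neutral = 4,
                               eps_cc = 60) {
  if (!nrow(group_a) || !nrow(group_b)) return(0)
  pa <- as.matrix(group_a[, c("x", "y", "z")])
  pb <- as.matrix(group_b[, c("x", "y", "z")])
  qa <- group_a$charge; qb <- group_b$charge
  # only pairs with both charges nonzero contribute
  ia <- which(qa != 0); ib <- which(qb != 0)
  if (!length(ia) || !length(ib)) return(0)
  u <- 0
  for (i in ia) {
    d <- sqrt(colSums((t(pb[ib, , drop = FALSE]) - pa[i, ])^2))
    if (any(d < 1e-9)) stop("coincident charged atoms across groups (singular pair)")
    eps <- ifelse(group_a$ionizable[i] & group_b$ionizable[ib], eps_cc,
                  eps_neutral)
    u <- u + sum(COULOMB_K * qa[i] * qb[ib] / (eps * d))
  }
  u
}

#' LRA binding free energy of the peptide in a complex model
#'
#' Generates `n_configs` configurations each for the solute-charged and
#' solute-uncharged states by Gaussian perturbation of all atomic
#' coordinates (`perturbation_sigma` Angstrom, seeded), evaluates the
#' peptide-versus-rest interaction energy in each, and returns
#' \eqn{\Delta G = \tfrac12 (\langle U \rangle_{on} +
#' \langle U \rangle_{off})}. In the uncharged state all solute (peptide
#' chain) charges are zeroed. Deterministic for a fixed seed.
#'
#' @param model A `complex_model`.
#' @param n_configs Configurations per state (default 4).
#' @param perturbation_sigma Coordinate noise, Angstrom (default 0.3).
#' @param seed Integer RNG seed.
#' @param peptide_chain Chain holding the solute peptide (default `"P"`).
#' @param charge_table Passed to [assign_charges()].
#' @param eps_neutral,eps_cc Dielectric constants (defaults 4 and 60).
#' @return An object of class `lra_score`: `dG_bind`, `mean_U_charged`,
#'   `mean_U_uncharged` (kcal/mol), plus the parameters used.
#' @export
lra_binding <- function(model, n_configs = 4L, perturbation_sigma = 0.3,
                        seed = 1L, peptide_chain = "P", charge_table = NULL,
                        eps_neutral = 4, eps_cc = 60) {
  stopifnot(inherits(model, "complex_model"), perturbation_sigma >= 0)
  n_configs <- as.integer(n_configs)
  if (n_configs < 1L) stop("n_configs must be >= 1")
  atoms <- assign_charges(model, charge_table)
  is_pep <- atoms$chain == peptide_chain
  if (!any(is_pep)) stop(sprintf("no atoms in peptide chain '%s'", peptide_chain))

  energy_one <- function(at, zero_solute) {
    pep <- at[is_pep, , drop = FALSE]
    env <- at[!is_pep, , drop = FALSE]
    if (zero_solute) pep$charge <- 0
    interaction_energy(pep, env, eps_neutral, eps_cc)
  }
  with_seed(seed, {
    u_on <- numeric(n_configs); u_off <- numeric(n_configs)
    for (k in seq_len(n_configs)) {
      at <- atoms
      if (perturbation_sigma > 0) {
        n <- nrow(at)
        at$x <- at$x + rnorm(n, 0, perturbation_sigma)
        at$y <- at$y + rnorm(n, 0, perturbation_sigma)
        at$z <- at$z + rnorm(n, 0, perturbation_sigma)
      }
      u_on[k] <- energy_one(at, FALSE)
    }
    for (k in seq_len(n_configs)) {
      at <- atoms
      if (perturbation_sigma > 0) {
        n <- nrow(at)
        at$x <- at$x + rnorm(n, 0, perturbation_sigma)
        at$y <- at$y + rnorm(n, 0, perturbation_sigma)
        at$z <- at$z + rnorm(n, 0, perturbation_sigma)
      }
      u_off[k] <- energy_one(at, TRUE)
    }
    structure(list(dG_bind = 0.5 * (mean(u_on) + mean(u_off)),
                   mean_U_charged = mean(u_on),
                   mean_U_uncharged = mean(u_off),
                   n_configs_per_state = n_configs,
                   perturbation_sigma = perturbation_sigma,
                   eps_neutral = eps_neutral, eps_cc = eps_cc, seed = seed),
              class = "lra_score")
  })
}

#' Rank a peptide repertoire by binding energy
#'
#' Sorts ascending (most negative = strongest binder = rank 1); ties are
#' broken lexicographically by peptide sequence. Every entry must carry a
#' binding energy.
#'
#' @param table A [repertoire_table] with `binding_energy` set.
#' @return The table sorted, with a leading 1-based `rank` column.
#' @export
rank_peptides <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) >= 1L)
  if (anyNA(table$binding_energy)) {
    stop(sprintf("missing binding energy for peptide(s): %s",
                 paste(table$peptide[is.na(table$binding_energy)],
                       collapse = ", ")))
  }
  o <- order(table$binding_energy, table$peptide)
  out <- table[o, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "provenance") <- attr(table, "provenance")
  class(out) <- c("repertoire_table", "data.frame")
  out
}

#' Rank of a reference binding energy within a repertoire
#'
#' The rank a reference substrate would take in the repertoire:
#' 1 + the number of entries strictly more negative than it. A reference
#' equal to the best entry therefore ranks 1; one weaker than all entries
#' ranks n + 1.
#'
#' @param reference_energy Reference binding energy, kcal/mol.
#' @param table A [repertoire_table] with energies.
#' @return Integer 1-based rank.
#' @export
reference_rank <- function(reference_energy, table) {
  stopifnot(is.data.frame(table), nrow(table) >= 1L,
            !anyNA(table$binding_energy))
  1L + sum(table$binding_energy < reference_energy)
}
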