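two_atom_groups <- function(q1, q2, r, ionizable = TRUE) {
  a <- data.frame(x = 0, y = 0, z = 0, charge = q1, ionizable = ionizable)
  b <- data.frame(x = r, y = 0, z = 0, charge = q2, ionizable = ionizable)
  list(a = a, b = b)
}

test_that("formal charges follow the ionizable-group rules", {
  qa <- assign_charges(gen_complex(charge_scheme = "strong_binder")$model)
  lys_nz <- qa$resid == "LYS" & qa$elety == "NZ"
  expect_equal(qa$charge[lys_nz], 1)
  expect_equal(qa$charge[qa$resid == "SAM" & qa$elety == "SD"], 1)
  expect_equal(sort(qa$charge[qa$resid == "GLU"]), c(-0.5, -0.5, 0))
  expect_equal(sum(qa$charge[qa$resid == "GLU"]), -1)
  # peptide net charge equals the sum of its ionizable formal charges
  pep <- qa[qa$chain == "P", ]
  expect_equal(sum(pep$charge), sum(pep$charge[pep$ionizable]))
  expect_equal(sum(pep$charge), 1)  # a single lysine
  # everything not covered by a rule is neutral
  expect_true(all(qa$charge[!qa$ionizable] == 0))
})

test_that("interaction energy matches the closed-form Coulomb expression", {
  # hand-derived spot value: +1/+1 at r chosen so U = 100/60 kcal/mol
  g <- two_atom_groups(1, 1, 3.320637)
  expect_equal(interaction_energy(g$a, g$b), 100 / 60, tolerance = 1e-9)

  # full grid against the closed form, both dielectric regimes
  for (r in c(1, 2.5, 5, 10, 20)) {
    for (q1 in c(-1, -0.5, 0.5, 1)) {
      for (q2 in c(-1, -0.5, 0.5, 1)) {
        gi <- two_atom_groups(q1, q2, r, ionizable = TRUE)
        expect_equal(interaction_energy(gi$a, gi$b),
                     oracle_pair_energy(q1, q2, r, 60), tolerance = 1e-9)
        gn <- two_atom_groups(q1, q2, r, ionizable = FALSE)
        expect_equal(interaction_energy(gn$a, gn$b),
                     oracle_pair_energy(q1, q2, r, 4), tolerance = 1e-9)
      }
    }
  }
})

test_that("interaction energy obeys the 1/r law, symmetry and linearity", {
  g1 <- two_atom_groups(1, -1, 4)
  g2 <- two_atom_groups(1, -1, 8)
  expect_equal(interaction_energy(g2$a, g2$b),
               interaction_energy(g1$a, g1$b) / 2, tolerance = 1e-12)
  expect_equal(interaction_energy(g1$a, g1$b),
               interaction_energy(g1$b, g1$a), tolerance = 1e-12)
  g3 <- two_atom_groups(3, -1, 4)
  expect_equal(interaction_energy(g3$a, g3$b),
               3 * interaction_energy(g1$a, g1$b), tolerance = 1e-12)
  # null charges contribute nothing
  g0 <- two_atom_groups(0, 5, 2)
  expect_equal(interaction_energy(g0$a, g0$b), 0)
  # coincident charged atoms are singular
  gs <- two_atom_groups(1, 1, 0)
  expect_error(interaction_energy(gs$a, gs$b), "singular")
})

test_that("the LRA identity and determinism hold for any seed", {
  m <- gen_complex(charge_scheme = "strong_binder")$model
  for (seed in c(1, 7, 123)) {
    s <- lra_binding(m, seed = seed)
    expect_equal(s$dG_bind,
                 0.5 * (s$mean_U_charged + s$mean_U_uncharged),
                 tolerance = 1e-9)
  }
  expect_identical(lra_binding(m, seed = 11), lra_binding(m, seed = 11))
})

test_that("a zero-charge solute scores exactly zero", {
  x <- gen_complex(charge_scheme = "strong_binder")
  m <- x$model
  m$atoms$resid[m$atoms$chain == "P"] <- "GLY"  # strip the lysine charge
  for (seed in c(1, 2, 3)) {
    expect_identical(lra_binding(m, seed = seed)$dG_bind, 0)
  }
})

test_that("at zero perturbation the score is half the single-geometry energy", {
  m <- gen_complex(charge_scheme = "strong_binder")$model
  at <- assign_charges(m)
  pep <- at[at$chain == "P", ]
  env <- at[at$chain != "P", ]
  u_single <- interaction_energy(pep, env)
  s <- lra_binding(m, perturbation_sigma = 0, seed = 99)
  expect_equal(s$mean_U_charged, u_single, tolerance = 1e-9)
  expect_equal(s$mean_U_uncharged, 0)
  expect_equal(s$dG_bind, 0.5 * u_single, tolerance = 1e-9)
})

test_that("charge schemes order as attraction < none < repulsion across seeds", {
  strong <- gen_complex(charge_scheme = "strong_binder")$model
  null_m <- gen_complex(charge_scheme = "null")$model
  decoy <- gen_complex(charge_scheme = "decoy")$model
  for (seed in 1:10) {
    d_s <- lra_binding(strong, seed = seed)$dG_bind
    d_n <- lra_binding(null_m, seed = seed)$dG_bind
    d_d <- lra_binding(decoy, seed = seed)$dG_bind
    expect_lt(d_s, d_n)
    expect_lt(d_n, d_d)
  }
})

test_that("ranking sorts ascending with lexicographic tie-break", {
  tab <- load_fixture_table1()
  rk <- rank_peptides(tab)
  expect_equal(rk$peptide[1:6],
               c("GGVKKPH", "ARTKQTA", "ATPKKSA", "PAEKAPV", "KPKKAAK",
                 "AGVKKVA"))
  expect_equal(rk$binding_energy[1:6],
               c(-1.66, -1.42, -1.30, -0.75, -0.46, -0.44))
  expect_true(all(diff(rk$binding_energy) >= 0))
  # permutation: multiset of energies preserved; re-ranking is idempotent
  expect_equal(sort(rk$binding_energy), sort(tab$binding_energy))
  rk2 <- rank_peptides(rk[, setdiff(names(rk), "rank")])
  expect_equal(rk2$peptide, rk$peptide)

  ties <- metscreen:::new_repertoire(data.frame(
    peptide = c("CCCKCCC", "AAAKAAA", "DDDKDDD"),
    stringsAsFactors = FALSE))
  ties$binding_energy <- c(1, 1, 0)
  tied <- rank_peptides(ties)
  expect_equal(tied$peptide[2:3], c("AAAKAAA", "CCCKCCC"))

  single <- ties[3, , drop = FALSE]
  expect_equal(rank_peptides(single)$rank, 1L)

  bad <- ties
  bad$binding_energy[2] <- NA
  expect_error(rank_peptides(bad), "AAAKAAA")
})

test_that("reference ranking counts strictly stronger binders", {
  tab <- load_fixture_table1()
  expect_equal(reference_rank(-2.73, tab), 1L)
  expect_equal(reference_rank(min(tab$binding_energy), tab), 1L)
  expect_equal(reference_rank(max(tab$binding_energy) + 1, tab), 65L)
})
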