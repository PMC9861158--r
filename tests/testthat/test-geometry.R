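test_that("distances are plain Euclidean norms (hand computation)", {
  # NZ at the origin, SD five Angstrom away on a 3-4-5 triangle
  pdb <- c(
    "ATOM      1  NZ  LYS P   4       0.000   0.000   0.000  1.00  0.00           N",
    "HETATM    2  SD  SAM A 400       3.000   4.000   0.000  1.00  0.00           S",
    "HETATM    3  CE  SAM A 400       2.000   2.500   0.000  1.00  0.00           C",
    "ATOM      4  OH  TYR A 357       0.000   2.000   0.000  1.00  0.00           O",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  m <- load_complex(f)
  r <- measure_geometry(m)
  expect_equal(r$d_mt, 5.0, tolerance = 1e-9)
  expect_equal(unname(r$d_pt_per_tyr), 2.0, tolerance = 1e-9)
})

test_that("a collinear NZ-CE-SD arrangement measures a 180 degree attack angle", {
  r <- measure_geometry(gen_complex(attack_angle = 180)$model)
  expect_equal(r$attack_angle, 180, tolerance = 1e-9)
})

test_that("measurement recovers generator geometry exactly at zero noise", {
  for (d_mt in c(2.5, 4.4, 7, 10)) {
    for (d_pt in c(2, 3, 6, 10)) {
      r <- measure_geometry(gen_complex(d_mt = d_mt, d_pt = d_pt)$model)
      expect_equal(r$d_mt, d_mt, tolerance = 1e-6)
      expect_equal(unname(r$d_pt_per_tyr), d_pt, tolerance = 1e-6)
    }
  }
  for (ang in c(90, 120, 150, 179, 180)) {
    r <- measure_geometry(gen_complex(attack_angle = ang)$model)
    expect_equal(r$attack_angle, ang, tolerance = 1e-6)
  }
  r <- measure_geometry(gen_complex(arg_distance = 3.7)$model)
  expect_equal(r$arg_contact_min, 3.7, tolerance = 1e-6)
})

test_that("all measured quantities are invariant under rigid transforms", {
  set.seed(5)
  m <- gen_complex()$model
  r0 <- measure_geometry(m)
  for (i in 1:5) {
    r1 <- measure_geometry(apply_rigid(m, random_rigid_transform()))
    expect_equal(r1$d_mt, r0$d_mt, tolerance = 1e-6)
    expect_equal(r1$d_pt_per_tyr, r0$d_pt_per_tyr, tolerance = 1e-6)
    expect_equal(r1$attack_angle, r0$attack_angle, tolerance = 1e-6)
    expect_equal(r1$arg_contact_min, r0$arg_contact_min, tolerance = 1e-6)
  }
})

test_that("criteria windows judge reports as specified", {
  crit <- geometry_criteria()
  good <- apply_criteria(measure_geometry(gen_complex()$model), crit)
  expect_true(good$pass_mt && good$pass_pt && good$pass_overall)

  far <- apply_criteria(measure_geometry(gen_complex(d_mt = 8)$model), crit)
  expect_false(far$pass_mt)
  expect_false(far$pass_overall)

  # one tyrosine inside the proton-transfer window suffices
  rep_multi <- structure(list(
    d_mt = 4.4, d_pt_per_tyr = c(a = 2.6, b = 5.1), attack_angle = 180,
    arg_contact_min = NA_real_, pass_mt = NA, pass_pt = NA, pass_angle = NA,
    pass_arg = NA, pass_overall = NA), class = "geometry_report")
  judged <- apply_criteria(rep_multi, crit)
  expect_true(judged$pass_pt)
  expect_true(judged$pass_overall)
})

test_that("auxiliary angle and arginine criteria gate only when required", {
  bent <- measure_geometry(gen_complex(attack_angle = 120)$model)
  expect_true(apply_criteria(bent, geometry_criteria())$pass_overall)
  strict <- geometry_criteria(require_attack_angle = TRUE)
  expect_false(apply_criteria(bent, strict)$pass_overall)

  loose_arg <- measure_geometry(gen_complex(arg_distance = 6)$model)
  expect_true(apply_criteria(loose_arg, geometry_criteria())$pass_overall)
  expect_false(apply_criteria(
    loose_arg, geometry_criteria(require_arg_contact = TRUE))$pass_overall)
  expect_true(apply_criteria(
    measure_geometry(gen_complex(arg_distance = 3.5)$model),
    geometry_criteria(require_arg_contact = TRUE))$pass_overall)
})

test_that("SAH complexes carry no attack angle (methyl already transferred)", {
  x <- gen_complex()
  lines <- strsplit(x$pdb, "\n")[[1]]
  lines <- gsub("SAM", "SAH", lines[!grepl(" CE ", lines)])
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  m <- load_complex(f)
  expect_identical(m$cofactor$resid, "SAH")
  expect_true(is.na(measure_geometry(m)$attack_angle))
})

test_that("role resolution fails loudly on bad selectors and missing atoms", {
  f <- tempfile(fileext = ".pdb")
  writeLines(strsplit(gen_complex()$pdb, "\n")[[1]], f)
  expect_error(load_complex(f, substrate_lys = "P:99"), "substrate lysine")
  expect_error(load_complex(f, cofactor = "B:400"), "cofactor")
  # a structure whose lysine lacks NZ violates the model contract
  lines <- strsplit(gen_complex()$pdb, "\n")[[1]]
  writeLines(lines[!grepl(" NZ ", lines)], f)
  expect_error(load_complex(f), "NZ")
})

test_that("ensemble filtering matches ground-truth labels and counts", {
  ens <- gen_ensemble(60, 0.25, seed = 3L)
  res <- filter_ensemble(lapply(ens$models, function(m) m$model))
  expect_equal(res$summary$n_pass, sum(ens$labels))
  expect_equal(res$reports$pass_overall, ens$labels)
  # input order preserved in the report table
  expect_equal(res$reports$model, seq_along(ens$models))

  all_good <- gen_ensemble(10, 1, seed = 4L)
  res2 <- filter_ensemble(lapply(all_good$models, function(m) m$model))
  expect_equal(res2$summary$n_pass, 10L)

  none <- gen_ensemble(10, 0, seed = 5L)
  res3 <- filter_ensemble(lapply(none$models, function(m) m$model))
  expect_equal(res3$summary$n_pass, 0L)
})

test_that("pass counts are monotone non-decreasing in the tolerances", {
  ens <- gen_ensemble(40, 0.5, seed = 9L,
                      competent_spec = list(noise_sigma = 0.4),
                      decoy_spec = list(d_mt = 6.5, d_pt = 4.5,
                                        noise_sigma = 0.4))
  models <- lapply(ens$models, function(m) m$model)
  tols <- c(0.05, 0.2, 0.5, 1.0, 2.0)
  passes <- vapply(tols, function(tol) {
    filter_ensemble(models, geometry_criteria(
      d_mt_tol = tol, d_pt_tol = tol))$summary$n_pass
  }, numeric(1))
  expect_true(all(diff(passes) >= 0))
  # degenerate tolerance on a noisy ensemble admits nothing
  tiny <- filter_ensemble(models, geometry_criteria(d_mt_tol = 1e-9,
                                                    d_pt_tol = 1e-9))
  expect_equal(tiny$summary$n_pass, 0L)
})
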