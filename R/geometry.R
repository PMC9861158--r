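#' Catalytic-competence geometry criteria
#'
#' Geometric windows a complex model must satisfy to be considered
#' catalytically competent for SN2 methyl transfer:
#' \itemize{
#'   \item methyl transfer (MT): sulfonium-to-amine distance, SAM SD to
#'     substrate Lys NZ, near 4.4 Angstrom for the in-line attack;
#'   \item proton transfer (PT): a catalytic Tyr hydroxyl oxygen (OH)
#'     within about 3 Angstrom of NZ so the lysine can be deprotonated;
#'   \item optionally, the NZ-CE-SD attack angle near 180 degrees;
#'   \item optionally, a cofactor-contacting arginine within a heavy-atom
#'     contact cutoff of the cofactor.
#' }
#' Targets carry "around"-style tolerances; defaults are +/- 0.5 Angstrom
#' on distances and +/- 30 degrees on the angle, all configurable. The
#' angle and arginine checks are off by default: the two distance criteria
#' are the primary selection surface, the other two are auxiliary.
#'
#' @param d_mt_target,d_mt_tol MT distance window (Angstrom).
#' @param d_pt_target,d_pt_tol PT distance window (Angstrom).
#' @param attack_angle_target,attack_angle_tol Attack-angle window (degrees).
#' @param arg_contact_cutoff Max heavy-atom Arg-cofactor distance (Angstrom).
#' @param require_attack_angle,require_arg_contact Include the auxiliary
#'   checks in the overall verdict?
#' @return An object of class `geometry_criteria`.
#' @export
geometry_criteria <- function(d_mt_target = 4.4, d_mt_tol = 0.5,
                              d_pt_target = 3.0, d_pt_tol = 0.5,
                              attack_angle_target = 180, attack_angle_tol = 30,
                              arg_contact_cutoff = 4.0,
                              require_attack_angle = FALSE,
                              require_arg_contact = FALSE) {
  stopifnot(d_mt_target > 0, d_pt_target > 0, d_mt_tol > 0, d_pt_tol > 0,
            attack_angle_tol > 0, arg_contact_cutoff > 0,
            attack_angle_target > 0, attack_angle_target <= 180)
  structure(list(d_mt_target = d_mt_target, d_mt_tol = d_mt_tol,
                 d_pt_target = d_pt_target, d_pt_tol = d_pt_tol,
                 attack_angle_target = attack_angle_target,
                 attack_angle_tol = attack_angle_tol,
                 arg_contact_cutoff = arg_contact_cutoff,
                 require_attack_angle = require_attack_angle,
                 require_arg_contact = require_arg_contact),
            class = "geometry_criteria")
}

# Internal constructor for an annotated complex model. `atoms` is a
# data.frame with columns elety, resid, chain, resno, x, y, z, elesy;
# roles are lists with chain/resno (resolved residue references).
new_complex_model <- function(atoms, cofactor, substrate_lys,
                              catalytic_tyr = list(), contact_arg = NULL) {
  m <- structure(list(atoms = atoms, cofactor = cofactor,
                      substrate_lys = substrate_lys,
                      catalytic_tyr = catalytic_tyr,
                      contact_arg = contact_arg),
                 class = "complex_model")
  validate_complex_model(m)
}

validate_complex_model <- function(m) {
  if (is.null(get_atom(m, m$cofactor, "SD"))) {
    stop(sprintf("cofactor %s:%d lacks atom SD", m$cofactor$chain,
                 m$cofactor$resno))
  }
  if (is.null(get_atom(m, m$substrate_lys, "NZ"))) {
    stop(sprintf("substrate lysine %s:%d lacks atom NZ",
                 m$substrate_lys$chain, m$substrate_lys$resno))
  }
  if (identical(m$cofactor$resid, "SAM") &&
      is.null(get_atom(m, m$cofactor, "CE"))) {
    stop("SAM cofactor lacks the transferable methyl carbon CE")
  }
  m
}

res_atoms <- function(model, ref) {
  a <- model$atoms
  a[a$chain == ref$chain & a$resno == ref$resno, , drop = FALSE]
}

get_atom <- function(model, ref, name) {
  a <- res_atoms(model, ref)
  a <- a[a$elety == name, , drop = FALSE]
  if (!nrow(a)) return(NULL)
  as.numeric(a[1L, c("x", "y", "z")])
}

#' Load an enzyme-peptide-cofactor complex from a PDB file
#'
#' Parses ATOM/HETATM records (via \pkg{bio3d}) and resolves the catalytic
#' roles the pipeline measures: the methyl-donor cofactor (residue SAM or
#' SAH), the substrate lysine, the catalytic tyrosine(s) and, optionally,
#' a cofactor-contacting arginine. Selectors are `"chain:resno"` strings;
#' when omitted, roles are auto-detected (first SAM/SAH residue; first LYS
#' in the peptide chain `P`; all TYR residues; no arginine). Multi-MODEL
#' files yield one model per MODEL block.
#'
#' Coordinates are used as-is (Angstrom); only the first alternate
#' location is kept and hydrogens are ignored for contact distances.
#'
#' @param structure_file Path to a PDB file.
#' @param cofactor,substrate_lys,arg `"chain:resno"` selectors (or `NULL`
#'   to auto-detect; `arg = NULL` means no arginine role).
#' @param tyr Character vector of `"chain:resno"` selectors, or `NULL` to
#'   take every TYR residue.
#' @return A `complex_model`, or a list of them for multi-MODEL files.
#' @export
load_complex <- function(structure_file, cofactor = NULL,
                         substrate_lys = NULL, tyr = NULL, arg = NULL) {
  pdb <- bio3d::read.pdb(structure_file, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  n_models <- nrow(pdb$xyz)
  build_one <- function(k) {
    atoms <- data.frame(elety = at$elety, resid = at$resid,
                        chain = at$chain, resno = at$resno,
                        elesy = atom_element(at),
                        stringsAsFactors = FALSE)
    xyz <- matrix(pdb$xyz[k, ], ncol = 3L, byrow = TRUE)
    atoms$x <- xyz[, 1L]; atoms$y <- xyz[, 2L]; atoms$z <- xyz[, 3L]
    # first alternate location only
    if (!is.null(at$alt)) {
      keep <- is.na(at$alt) | at$alt %in% c("", "A")
      atoms <- atoms[keep, , drop = FALSE]
    }
    resolve_roles(atoms, cofactor, substrate_lys, tyr, arg)
  }
  if (n_models == 1L) build_one(1L) else lapply(seq_len(n_models), build_one)
}

atom_element <- function(at) {
  e <- at$elesy
  if (is.null(e)) e <- rep(NA_character_, nrow(at))
  miss <- is.na(e) | e == ""
  # fall back to the first letter of the atom name (PDB convention for
  # single-letter elements; adequate for the atoms this pipeline reads)
  e[miss] <- substr(gsub("[0-9 ]", "", at$elety[miss]), 1L, 1L)
  toupper(e)
}

parse_selector <- function(sel, what) {
  if (is.list(sel)) return(sel)
  parts <- strsplit(sel, ":")[[1]]
  if (length(parts) < 2L) stop(sprintf("cannot parse %s selector '%s'", what, sel))
  # accept chain:resno or chain:RESID:resno
  list(chain = parts[1L], resno = as.integer(parts[length(parts)]))
}

resolve_roles <- function(atoms, cofactor, substrate_lys, tyr, arg) {
  find_res <- function(ref, what, resid_filter = NULL) {
    hit <- atoms$chain == ref$chain & atoms$resno == ref$resno
    if (!is.null(resid_filter)) hit <- hit & atoms$resid %in% resid_filter
    if (!any(hit)) {
      stop(sprintf("selector for %s (%s:%d) matches no residue",
                   what, ref$chain, ref$resno))
    }
    list(chain = ref$chain, resno = ref$resno,
         resid = atoms$resid[which(hit)[1L]])
  }
  if (is.null(cofactor)) {
    i <- which(atoms$resid %in% c("SAM", "SAH"))
    if (!length(i)) stop("no SAM/SAH cofactor residue found")
    cof <- list(chain = atoms$chain[i[1L]], resno = atoms$resno[i[1L]],
                resid = atoms$resid[i[1L]])
  } else cof <- find_res(parse_selector(cofactor, "cofactor"), "cofactor",
                         c("SAM", "SAH"))
  if (is.null(substrate_lys)) {
    i <- which(atoms$resid == "LYS" & atoms$chain == "P")
    if (!length(i)) stop("no substrate lysine found in peptide chain P")
    lys <- list(chain = atoms$chain[i[1L]], resno = atoms$resno[i[1L]],
                resid = "LYS")
  } else lys <- find_res(parse_selector(substrate_lys, "substrate lysine"),
                         "substrate lysine", "LYS")
  if (is.null(tyr)) {
    i <- which(atoms$resid == "TYR" & !duplicated(paste(atoms$chain, atoms$resno)))
    tyrs <- lapply(i, function(j) list(chain = atoms$chain[j],
                                       resno = atoms$resno[j], resid = "TYR"))
  } else {
    tyrs <- lapply(tyr, function(s)
      find_res(parse_selector(s, "catalytic tyrosine"), "catalytic tyrosine",
               "TYR"))
  }
  arg_ref <- if (is.null(arg)) NULL else
    find_res(parse_selector(arg, "contact arginine"), "contact arginine", "ARG")
  new_complex_model(atoms, cof, lys, tyrs, arg_ref)
}

vdist <- function(a, b) sqrt(sum((a - b)^2))

# Angle (degrees) at vertex v between points a and b.
vangle <- function(a, v, b) {
  u1 <- a - v; u2 <- b - v
  cosang <- sum(u1 * u2) / (sqrt(sum(u1^2)) * sqrt(sum(u2^2)))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Measure catalytic geometry of a complex model
#'
#' Computes, without judging them: `d_mt`, the SD-NZ distance (Angstrom);
#' `d_pt_per_tyr`, the OH-NZ distance for every catalytic tyrosine (a Tyr
#' lacking its OH atom is reported as `NA` with a warning);
#' `attack_angle`, the NZ-CE-SD angle in degrees (`NA` when the cofactor
#' has no CE, as for SAH); and `arg_contact_min`, the minimum heavy-atom
#' distance between the contact arginine and the cofactor (`NA` when no
#' arginine role is assigned). Pass flags are set by [apply_criteria()].
#'
#' @param model A `complex_model` from [load_complex()] or [gen_complex()].
#' @return An object of class `geometry_report`.
#' @export
measure_geometry <- function(model) {
  stopifnot(inherits(model, "complex_model"))
  nz <- get_atom(model, model$substrate_lys, "NZ")
  sd <- get_atom(model, model$cofactor, "SD")
  ce <- get_atom(model, model$cofactor, "CE")

  d_mt <- vdist(sd, nz)
  d_pt <- vapply(model$catalytic_tyr, function(ty) {
    oh <- get_atom(model, ty, "OH")
    if (is.null(oh)) {
      warning(sprintf("TYR %s:%d lacks atom OH; PT distance unavailable",
                      ty$chain, ty$resno))
      return(NA_real_)
    }
    vdist(oh, nz)
  }, numeric(1))
  names(d_pt) <- vapply(model$catalytic_tyr,
                        function(ty) paste0(ty$chain, ":", ty$resno),
                        character(1))
  angle <- if (is.null(ce)) NA_real_ else vangle(nz, ce, sd)
  arg_min <- NA_real_
  if (!is.null(model$contact_arg)) {
    aa <- res_atoms(model, model$contact_arg)
    ca <- res_atoms(model, model$cofactor)
    aa <- aa[aa$elesy != "H", , drop = FALSE]
    ca <- ca[ca$elesy != "H", , drop = FALSE]
    d <- outer(seq_len(nrow(aa)), seq_len(nrow(ca)), Vectorize(function(i, j)
      vdist(as.numeric(aa[i, c("x", "y", "z")]),
            as.numeric(ca[j, c("x", "y", "z")]))))
    arg_min <- min(d)
  }
  structure(list(d_mt = d_mt, d_pt_per_tyr = d_pt, attack_angle = angle,
                 arg_contact_min = arg_min,
                 pass_mt = NA, pass_pt = NA, pass_angle = NA, pass_arg = NA,
                 pass_overall = NA),
            class = "geometry_report")
}

#' Judge a geometry report against selection criteria
#'
#' Sets the pass flags: `pass_mt` iff `d_mt` lies within the MT window;
#' `pass_pt` iff at least one tyrosine OH lies within the PT window (one
#' conserved tyrosine suffices for one deprotonation); `pass_angle` and
#' `pass_arg` analogously, vacuously `TRUE` when their check is not
#' required or the quantity is unavailable because the role is absent.
#' `pass_overall` is the conjunction of the required flags.
#'
#' @param report A `geometry_report` from [measure_geometry()].
#' @param criteria A [geometry_criteria()] object.
#' @return The report with flags set.
#' @export
apply_criteria <- function(report, criteria = geometry_criteria()) {
  stopifnot(inherits(report, "geometry_report"),
            inherits(criteria, "geometry_criteria"))
  report$pass_mt <- isTRUE(abs(report$d_mt - criteria$d_mt_target) <=
                             criteria$d_mt_tol)
  dpt <- report$d_pt_per_tyr[!is.na(report$d_pt_per_tyr)]
  report$pass_pt <- length(dpt) > 0 &&
    any(abs(dpt - criteria$d_pt_target) <= criteria$d_pt_tol)
  report$pass_angle <- if (!criteria$require_attack_angle) TRUE else
    isTRUE(abs(report$attack_angle - criteria$attack_angle_target) <=
             criteria$attack_angle_tol)
  report$pass_arg <- if (!criteria$require_arg_contact) TRUE else
    isTRUE(report$arg_contact_min <= criteria$arg_contact_cutoff)
  report$pass_overall <- report$pass_mt && report$pass_pt &&
    report$pass_angle && report$pass_arg
  report
}

#' Filter a model ensemble by catalytic-competence criteria
#'
#' Measures every model, applies the criteria, and returns the passing
#' subset (input order preserved) together with a per-model report table
#' and summary counts. Models given as file paths that fail to parse are
#' excluded and counted; if every model fails to parse the call is an
#' error.
#'
#' @param models A list of `complex_model` objects and/or PDB file paths.
#' @param criteria A [geometry_criteria()] object.
#' @param ... Role selectors passed to [load_complex()] for path inputs.
#' @return A list with `passing` (models), `reports` (data.frame with one
#'   row per parsed model: d_mt, d_pt_min, attack_angle, arg_contact_min
#'   and the pass flags), and `summary` (n_input, n_parsed, n_pass and
#'   per-criterion failure counts).
#' @export
filter_ensemble <- function(models, criteria = geometry_criteria(), ...) {
  stopifnot(length(models) >= 1L)
  if (inherits(models, "complex_model")) models <- list(models)
  parsed <- vector("list", length(models))
  for (i in seq_along(models)) {
    m <- models[[i]]
    if (inherits(m, "complex_model")) { parsed[[i]] <- m; next }
    parsed[[i]] <- tryCatch(load_complex(m, ...), error = function(e) {
      message(sprintf("model %d (%s) excluded: %s", i, as.character(m),
                      conditionMessage(e)))
      NULL
    })
  }
  ok <- !vapply(parsed, is.null, logical(1))
  if (!any(ok)) stop("no model in the ensemble could be parsed")
  reports <- lapply(parsed[ok], function(m)
    apply_criteria(measure_geometry(m), criteria))
  tab <- do.call(rbind, lapply(seq_along(reports), function(j) {
    r <- reports[[j]]
    data.frame(model = which(ok)[j], d_mt = r$d_mt,
               d_pt_min = if (all(is.na(r$d_pt_per_tyr))) NA_real_ else
                 min(r$d_pt_per_tyr, na.rm = TRUE),
               attack_angle = r$attack_angle,
               arg_contact_min = r$arg_contact_min,
               pass_mt = r$pass_mt, pass_pt = r$pass_pt,
               pass_angle = r$pass_angle, pass_arg = r$pass_arg,
               pass_overall = r$pass_overall)
  }))
  pass_idx <- which(ok)[tab$pass_overall]
  list(passing = parsed[pass_idx],
       reports = tab,
       summary = list(n_input = length(models), n_parsed = sum(ok),
                      n_unparseable = sum(!ok), n_pass = sum(tab$pass_overall),
                      n_fail_mt = sum(!tab$pass_mt),
                      n_fail_pt = sum(!tab$pass_pt),
                      n_fail_angle = sum(!tab$pass_angle),
                      n_fail_arg = sum(!tab$pass_arg)))
}
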