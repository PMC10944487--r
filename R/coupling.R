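# Electronic couplings between pigments: transition-charge (TrEsp) Coulomb
# sums with a distance-dependent environmental screening factor, plus the
# ideal point-dipole formula used as a far-field validation oracle.

#' Construct a transition-charge set
#'
#' Atomic point charges (units of elementary charge e) reproducing a pigment's
#' transition density. If `target_dipole` is set, charges are rescaled when
#' placed on a pigment's geometry so the placed dipole magnitude (Debye)
#' equals it.
#'
#' @param charges Named numeric vector, atom name -> charge in e.
#' @param pigment_type Pigment type label (e.g. `"CHL_A"`).
#' @param target_dipole Optional target transition-dipole magnitude in Debye.
#' @param label Free-text provenance label.
#' @return A `charge_set` object.
#' @export
charge_set <- function(charges, pigment_type = "CHL_A",
                       target_dipole = NULL, label = "") {
  if (is.null(names(charges)) || any(names(charges) == ""))
    stop("charges must be a named vector (atom name -> charge)")
  if (anyDuplicated(names(charges)))
    stop("duplicate atom name in charge set: ",
         paste(unique(names(charges)[duplicated(names(charges))]),
               collapse = ", "))
  if (!is.numeric(charges) || any(!is.finite(charges)))
    stop("charges must be finite numeric")
  if (length(charges) < 1L) stop("charge set needs at least one atom")
  if (!is.null(target_dipole) && target_dipole <= 0)
    stop("target_dipole must be positive (Debye)")
  structure(list(charges = charges, pigment_type = pigment_type,
                 target_dipole = target_dipole, label = label),
            class = "charge_set")
}

#' @export
print.charge_set <- function(x, ...) {
  cat("<charge_set> ", x$pigment_type, ": ", length(x$charges), " atoms",
      if (!is.null(x$target_dipole))
        sprintf(", target dipole %.3f D", x$target_dipole), "\n", sep = "")
  invisible(x)
}

#' Load a charge set from TSV
#'
#' Format: two columns `atom_name<TAB>charge_e` with a header row; optional
#' directives `#pigment_type=` and `#target_dipole_debye=` before the header.
#'
#' @param path TSV file.
#' @return A `charge_set`.
#' @export
load_charge_set <- function(path) {
  lines <- readLines(path)
  dirs <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  getdir <- function(key) {
    hit <- grep(paste0("^#", key, "="), dirs, value = TRUE)
    if (length(hit)) sub(paste0("^#", key, "="), "", hit[1]) else NULL
  }
  df <- utils::read.table(text = body, sep = "\t", header = TRUE,
                          colClasses = c("character", "character"),
                          stringsAsFactors = FALSE)
  if (!all(c("atom_name", "charge_e") %in% names(df)))
    stop("charge-set file must have columns atom_name, charge_e: ", path)
  q <- suppressWarnings(as.numeric(df$charge_e))
  if (any(is.na(q)))
    stop("non-numeric charge for atom(s): ",
         paste(df$atom_name[is.na(q)], collapse = ", "))
  names(q) <- df$atom_name
  td <- getdir("target_dipole_debye")
  charge_set(q,
             pigment_type = getdir("pigment_type") %||% "CHL_A",
             target_dipole = if (!is.null(td)) as.numeric(td),
             label = path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a charge set to TSV
#' @param cs A `charge_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_charge_set <- function(cs, path) {
  stopifnot(inherits(cs, "charge_set"))
  hdr <- c(sprintf("#pigment_type=%s", cs$pigment_type),
           if (!is.null(cs$target_dipole))
             sprintf("#target_dipole_debye=%.10g", cs$target_dipole))
  writeLines(c(hdr, "atom_name\tcharge_e",
               sprintf("%s\t%.10g", names(cs$charges), cs$charges)), path)
  invisible(path)
}

#' Place a charge set on a pigment's geometry
#'
#' Resolves each charge-set atom name against the pigment's atom coordinates
#' and applies dipole rescaling when the charge set carries a target dipole.
#'
#' @param pigment A pigment record (from a `pigment_set`).
#' @param cs A `charge_set`.
#' @param allow_missing Drop charge atoms absent from the model (with a
#'   warning, no charge renormalisation) instead of erroring.
#' @return List with `coords` (n x 3), `charges` (length n, e), and
#'   `dipole_debye` (3-vector of the placed transition dipole).
#' @export
place_charges <- function(pigment, cs, allow_missing = FALSE) {
  stopifnot(inherits(cs, "charge_set"))
  want <- names(cs$charges)
  have <- want %in% rownames(pigment$atom_coords)
  if (!all(have)) {
    if (!allow_missing)
      stop("pigment ", pigment$id, ": no coordinate for charge atom(s) ",
           paste(want[!have], collapse = ", "))
    warning("pigment ", pigment$id, ": dropping charge atom(s) ",
            paste(want[!have], collapse = ", "))
    want <- want[have]
  }
  coords <- pigment$atom_coords[want, , drop = FALSE]
  q <- cs$charges[want]
  mu <- colSums(coords * q) * .eet_const$debye_per_e_ang  # Debye
  if (!is.null(cs$target_dipole)) {
    m <- sqrt(sum(mu^2))
    if (m == 0) stop("pigment ", pigment$id,
                     ": zero placed dipole, cannot rescale")
    q <- q * cs$target_dipole / m
    mu <- mu * cs$target_dipole / m
  }
  list(coords = coords, charges = q, dipole_debye = mu)
}

#' Environmental screening parameters
#'
#' Piecewise distance-dependent screening of the Coulombic coupling:
#' `f_inner` for `R <= r_inner`; `A*exp(-beta*R) + f_outer` for
#' `r_inner < R < r_outer`; `f_outer` for `R >= r_outer`.
#' The defaults use the inner/outer cutoffs 6.6/20 Angstrom with unity inner
#' screening and 0.54 asymptote, and the literature exponential-fit constants
#' `A = 2.68`, `beta = 0.27` per Angstrom for the transition region.
#'
#' @param A Dimensionless prefactor of the exponential branch.
#' @param beta Decay constant (Angstrom^-1).
#' @param f_inner Screening value for `R <= r_inner`.
#' @param f_outer Asymptotic value for `R >= r_outer`.
#' @param r_inner,r_outer Branch cutoffs (Angstrom).
#' @return A `screening_params` object.
#' @export
screening_params <- function(A = 2.68, beta = 0.27, f_inner = 1,
                             f_outer = 0.54, r_inner = 6.6, r_outer = 20) {
  if (!(r_inner < r_outer)) stop("r_inner must be < r_outer")
  if (f_outer <= 0) stop("f_outer must be positive")
  structure(list(A = A, beta = beta, f_inner = f_inner, f_outer = f_outer,
                 r_inner = r_inner, r_outer = r_outer),
            class = "screening_params")
}

#' Environmental screening factor
#'
#' @param R Center-to-center distance(s), Angstrom; must be positive.
#' @param params A [screening_params()] object.
#' @return Dimensionless screening factor(s), same length as `R`.
#' @examples
#' screening_factor(5)    # inner branch: 1
#' screening_factor(25)   # outer branch: 0.54
#' @export
screening_factor <- function(R, params = screening_params()) {
  stopifnot(inherits(params, "screening_params"))
  if (any(!is.finite(R)) || any(R <= 0))
    stop("R must be positive and finite (Angstrom)")
  f <- ifelse(R <= params$r_inner, params$f_inner,
       ifelse(R >= params$r_outer, params$f_outer,
              params$A * exp(-params$beta * R) + params$f_outer))
  unname(f)
}

.pair_screen <- function(R, screening) {
  if (is.null(screening)) 1 else screening_factor(R, screening)
}

#' TrEsp electronic coupling between two pigments
#'
#' Screened Coulomb sum over transition charges:
#' `V = f(R_centers) * sum_{l in m, l' in n} q_l q_l' / |R_{l,l'}|`,
#' converted from e^2/Angstrom to cm^-1. One screening factor, evaluated at
#' the center-to-center distance, multiplies the whole sum.
#'
#' @param pig_m,pig_n Pigment records (distinct).
#' @param cs_m,cs_n Charge sets for the two pigments.
#' @param screening A [screening_params()] object, or `NULL` for unscreened
#'   (`f = 1`) coupling.
#' @param allow_missing Passed to [place_charges()].
#' @param min_atom_separation Any inter-pigment atom pair closer than this
#'   (Angstrom) raises a clash error.
#' @return Coupling V in cm^-1 (sign preserved).
#' @export
tresp_coupling <- function(pig_m, pig_n, cs_m, cs_n,
                           screening = screening_params(),
                           allow_missing = FALSE,
                           min_atom_separation = 0.5) {
  if (identical(pig_m$id, pig_n$id)) stop("pigments must be distinct")
  pm <- place_charges(pig_m, cs_m, allow_missing)
  pn <- place_charges(pig_n, cs_n, allow_missing)
  .tresp_pair(pm, pn, pig_m, pig_n, screening, min_atom_separation)$V
}

.tresp_pair <- function(pm, pn, pig_m, pig_n, screening, min_sep = 0.5) {
  d2 <- outer(rowSums(pm$coords^2), rowSums(pn$coords^2), `+`) -
    2 * pm$coords %*% t(pn$coords)
  d <- sqrt(pmax(d2, 0))
  if (any(d < min_sep))
    stop("atomic clash (< ", min_sep, " Angstrom) between ", pig_m$id,
         " and ", pig_n$id)
  R <- sqrt(sum((pig_m$center - pig_n$center)^2))
  f <- .pair_screen(R, screening)
  V <- f * sum(outer(pm$charges, pn$charges) / d) *
    .eet_const$coulomb_cm1_e2_ang
  list(V = V, R = R, f = f)
}

#' Ideal point-dipole coupling between two pigments
#'
#' Far-field limit of the transition-charge sum:
#' `V = f * K_dd * mu_m * mu_n * kappa / R^3` with orientation factor
#' `kappa = e_m . e_n - 3 (e_m . Rhat)(e_n . Rhat)` over the unit Qy axes.
#'
#' @param pig_m,pig_n Pigment records with unit `qy_axis`.
#' @param mu_m,mu_n Transition dipole magnitudes (Debye).
#' @param screening A [screening_params()] or `NULL` for `f = 1`.
#' @return Coupling V in cm^-1.
#' @export
dipole_coupling <- function(pig_m, pig_n, mu_m, mu_n,
                            screening = screening_params()) {
  e_m <- pig_m$qy_axis; e_n <- pig_n$qy_axis
  if (sqrt(sum(e_m^2)) == 0 || sqrt(sum(e_n^2)) == 0)
    stop("zero-length Qy axis")
  Rv <- pig_n$center - pig_m$center
  R <- sqrt(sum(Rv^2))
  if (R == 0) stop("coincident pigment centers")
  rhat <- Rv / R
  kappa <- sum(e_m * e_n) - 3 * sum(e_m * rhat) * sum(e_n * rhat)
  f <- .pair_screen(R, screening)
  f * .eet_const$dd_cm1_d2_ang3 * mu_m * mu_n * kappa / R^3
}

#' Full pairwise coupling matrix over a pigment set
#'
#' @param pigments A `pigment_set` (>= 2 pigments).
#' @param charge_library Named list, pigment type -> `charge_set`; every
#'   pigment type in the set must be present.
#' @param screening A [screening_params()] or `NULL`.
#' @param method `"tresp"` (transition-charge sum) or `"dipole"` (point
#'   dipoles placed on each pigment's Qy axis with magnitudes from the placed
#'   charge-set dipoles).
#' @param allow_missing Passed to [place_charges()].
#' @return A `coupling_matrix`: list with symmetric matrices `V` (cm^-1),
#'   `R` (Angstrom) and `f` (per-pair screening), the `method` tag and the
#'   screening parameters used.
#' @export
coupling_matrix <- function(pigments, charge_library,
                            screening = screening_params(),
                            method = c("tresp", "dipole"),
                            allow_missing = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(pigments, "pigment_set"))
  types <- unique(vapply(pigments$pigments, `[[`, "", "type"))
  missing_t <- setdiff(types, names(charge_library))
  if (length(missing_t))
    stop("charge_library lacks pigment type(s): ",
         paste(missing_t, collapse = ", "))
  ids <- names(pigments$pigments)
  n <- length(ids)
  if (n < 2L) stop("need at least 2 pigments")
  placed <- lapply(pigments$pigments, function(p)
    place_charges(p, charge_library[[p$type]], allow_missing))
  V <- Rm <- Fm <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    pi_ <- pigments$pigments[[i]]; pj <- pigments$pigments[[j]]
    if (method == "tresp") {
      pr <- tryCatch(
        .tresp_pair(placed[[i]], placed[[j]], pi_, pj, screening),
        error = function(e) stop("pair (", ids[i], ", ", ids[j], "): ",
                                 conditionMessage(e), call. = FALSE))
      V[i, j] <- pr$V; Rm[i, j] <- pr$R; Fm[i, j] <- pr$f
    } else {
      mu_i <- sqrt(sum(placed[[i]]$dipole_debye^2))
      mu_j <- sqrt(sum(placed[[j]]$dipole_debye^2))
      Rm[i, j] <- sqrt(sum((pi_$center - pj$center)^2))
      Fm[i, j] <- .pair_screen(Rm[i, j], screening)
      V[i, j] <- dipole_coupling(pi_, pj, mu_i, mu_j, screening)
    }
    V[j, i] <- V[i, j]; Rm[j, i] <- Rm[i, j]; Fm[j, i] <- Fm[i, j]
  }
  structure(list(V = V, R = Rm, f = Fm, method = toupper(method),
                 screening = screening,
                 constants_version = .eet_const$version),
            class = "coupling_matrix")
}

#' @export
print.coupling_matrix <- function(x, ...) {
  cat("<coupling_matrix> ", nrow(x$V), " pigments, method ", x$method,
      ", max |V| = ", format(max(abs(x$V)), digits = 4), " cm^-1\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.coupling_matrix <- function(x, ...) {
  ids <- rownames(x$V)
  ut <- which(upper.tri(x$V), arr.ind = TRUE)
  data.frame(pigment_m = ids[ut[, 1]], pigment_n = ids[ut[, 2]],
             R_angstrom = x$R[ut], f = x$f[ut], V_cm1 = x$V[ut],
             stringsAsFactors = FALSE)
}

#' Export a coupling matrix as long-form CSV
#' @param couplings A `coupling_matrix`.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_couplings <- function(couplings, path) {
  utils::write.csv(as.data.frame(couplings), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
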