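# Generalized Forster theory: donors and acceptors are multi-pigment
# aggregates. Each aggregate's exciton Hamiltonian (site energies on the
# diagonal, intra-aggregate couplings off it) is diagonalised; transfer
# proceeds between Boltzmann-weighted donor exciton states and acceptor
# exciton states:
#   k_DA = (2*pi/hbar) sum_{a in D} sum_{b in A}
#          [exp(-eps_a / kB T) / Z] |V_ab|^2 int S_a^D(w) S_b^A(w) dw
# with Z = sum_a exp(-eps_a / kB T).

#' Build an exciton domain (aggregate Hamiltonian + Boltzmann weights)
#'
#' @param domain_id Identifier of the aggregate.
#' @param member_ids Pigment ids belonging to the aggregate (ordered).
#' @param pigments The full `pigment_set`.
#' @param couplings A [coupling_matrix()] over (at least) the members;
#'   off-diagonal intra-domain couplings enter the Hamiltonian.
#' @param site_energies Site-energy/lineshape table.
#' @param temperature Temperature in K (> 0).
#' @param sigma_mode Passed to [lineshape_params()].
#' @return An `exciton_domain`: Hamiltonian `H` (cm^-1), ascending
#'   eigenvalues `evals`, eigenvector coefficient matrix `coeffs` (columns =
#'   exciton states), Boltzmann `weights`, partition function `Z`,
#'   per-member lineshape params, temperature.
#' @export
build_domain <- function(domain_id, member_ids, pigments, couplings,
                         site_energies = default_site_energies(),
                         temperature = 300, sigma_mode = "fwhm") {
  if (temperature <= 0) stop("temperature must be > 0 K")
  stopifnot(inherits(pigments, "pigment_set"),
            inherits(couplings, "coupling_matrix"))
  missing_p <- setdiff(member_ids, names(pigments$pigments))
  if (length(missing_p))
    stop("unknown pigment id(s) in domain ", domain_id, ": ",
         paste(missing_p, collapse = ", "))
  members <- pigments$pigments[member_ids]
  ls <- lapply(members, lineshape_for, site_energies = site_energies,
               sigma_mode = sigma_mode)
  n <- length(member_ids)
  H <- matrix(0, n, n, dimnames = list(member_ids, member_ids))
  if (n > 1L) H <- couplings$V[member_ids, member_ids, drop = FALSE]
  diag(H) <- vapply(ls, `[[`, 0, "omega0")
  eig <- eigen((H + t(H)) / 2, symmetric = TRUE)
  ord <- order(eig$values)           # ascending
  evals <- eig$values[ord]
  coeffs <- eig$vectors[, ord, drop = FALSE]
  rownames(coeffs) <- member_ids
  kT <- .eet_const$kB_cm1_K * temperature
  boltz <- exp(-(evals - evals[1]) / kT)   # shifted for numerical safety
  Z <- sum(boltz)
  structure(list(domain_id = domain_id, member_ids = member_ids,
                 H = H, evals = evals, coeffs = coeffs,
                 weights = boltz / Z, Z = Z, e_ref = evals[1],
                 member_lineshapes = ls, temperature = temperature,
                 sigma_mode = sigma_mode),
            class = "exciton_domain")
}

#' @export
print.exciton_domain <- function(x, ...) {
  cat("<exciton_domain> ", x$domain_id, ": ", length(x$member_ids),
      " pigments, eigenvalues [",
      format(min(x$evals), digits = 6), ", ",
      format(max(x$evals), digits = 6), "] cm^-1 at ",
      x$temperature, " K\n", sep = "")
  invisible(x)
}

#' Exciton-basis couplings between two domains
#'
#' Transforms the site-basis inter-domain couplings into the exciton basis:
#' `V_ab = sum_{i in D} sum_{j in A} c_ia c_jb V_ij`.
#'
#' @param D,A `exciton_domain` objects (disjoint member sets).
#' @param inter A [coupling_matrix()] containing all cross-domain pairs.
#' @return Matrix `V_ab` (cm^-1), rows = donor exciton states, columns =
#'   acceptor exciton states.
#' @export
exciton_coupling <- function(D, A, inter) {
  stopifnot(inherits(D, "exciton_domain"), inherits(A, "exciton_domain"),
            inherits(inter, "coupling_matrix"))
  if (length(intersect(D$member_ids, A$member_ids)))
    stop("donor and acceptor domains share pigments")
  Vij <- inter$V[D$member_ids, A$member_ids, drop = FALSE]
  t(D$coeffs) %*% Vij %*% A$coeffs
}

#' Lineshape of one exciton state
#'
#' The aggregate's exciton states are given Gaussian lineshapes centred at
#' the exciton eigenenergy; width and Stokes shift are the
#' coefficient-squared-weighted mix of the member pigments' monomer
#' parameters (`mix_mode = "weighted"`), or the plain mean of the monomer
#' parameters (`mix_mode = "monomer"`).
#'
#' @param domain An `exciton_domain`.
#' @param alpha Exciton state index (1 = lowest energy).
#' @param mix_mode `"weighted"` or `"monomer"`.
#' @return A [lineshape_params()] object (absorption peak at the exciton
#'   energy; emission displaced by the mixed Stokes shift).
#' @export
exciton_lineshape <- function(domain, alpha,
                              mix_mode = c("weighted", "monomer")) {
  mix_mode <- match.arg(mix_mode)
  stopifnot(inherits(domain, "exciton_domain"),
            alpha >= 1, alpha <= length(domain$evals))
  w <- if (mix_mode == "weighted") domain$coeffs[, alpha]^2
       else rep(1 / length(domain$member_ids), length(domain$member_ids))
  fwhm <- sum(w * vapply(domain$member_lineshapes, `[[`, 0, "fwhm"))
  stokes <- sum(w * vapply(domain$member_lineshapes, `[[`, 0, "stokes"))
  lineshape_params(domain$evals[alpha], fwhm, stokes, domain$sigma_mode)
}

#' Aggregate-to-aggregate generalized Forster rate
#'
#' Boltzmann-weighted double sum over donor/acceptor exciton pairs, using the
#' same rate prefactor as the classical pairwise rate. Donor states
#' contribute emission lineshapes, acceptor states absorption lineshapes.
#'
#' @param D,A `exciton_domain` objects at the same temperature.
#' @param V_ab Exciton coupling matrix from [exciton_coupling()].
#' @param mix_mode Passed to [exciton_lineshape()].
#' @return Rate k_DA in ps^-1.
#' @export
domain_rate <- function(D, A, V_ab, mix_mode = "weighted") {
  stopifnot(inherits(D, "exciton_domain"), inherits(A, "exciton_domain"))
  if (D$temperature != A$temperature)
    stop("donor and acceptor domains have different temperatures")
  if (!all(dim(V_ab) == c(length(D$evals), length(A$evals))))
    stop("V_ab dimensions do not match the domains")
  ls_D <- lapply(seq_along(D$evals), function(a)
    exciton_lineshape(D, a, mix_mode))
  ls_A <- lapply(seq_along(A$evals), function(b)
    exciton_lineshape(A, b, mix_mode))
  k <- 0
  for (a in seq_along(D$evals)) {
    if (D$weights[a] == 0) next
    for (b in seq_along(A$evals)) {
      J <- overlap_integral(ls_D[[a]], ls_A[[b]], "closed_form")
      k <- k + D$weights[a] * pairwise_rate(V_ab[a, b], J)
    }
  }
  k
}

#' Domain-to-domain rate matrix over a partition
#'
#' Builds one exciton domain per partition block and computes the directional
#' generalized Forster rate for every ordered domain pair.
#'
#' @param partition A `domain_partition` from [assign_domains()].
#' @param pigments The `pigment_set`.
#' @param couplings A [coupling_matrix()] over the full set (intra-domain
#'   blocks feed the Hamiltonians, inter-domain blocks the couplings).
#' @param site_energies Site-energy/lineshape table.
#' @param temperature Temperature in K.
#' @param sigma_mode,mix_mode See [build_domain()], [exciton_lineshape()].
#' @return A `domain_rate_matrix`: list with `rate` (k_DA, ps^-1, `NA`
#'   diagonal), `tau`, the built `domains`, `roles`, and metadata.
#' @export
all_domain_rates <- function(partition, pigments, couplings,
                             site_energies = default_site_energies(),
                             temperature = 300, sigma_mode = "fwhm",
                             mix_mode = "weighted") {
  validate_partition(partition, pigments)
  dom_ids <- names(partition$domains)
  domains <- lapply(dom_ids, function(d)
    build_domain(d, partition$domains[[d]], pigments, couplings,
                 site_energies, temperature, sigma_mode))
  names(domains) <- dom_ids
  n <- length(dom_ids)
  k <- matrix(NA_real_, n, n, dimnames = list(dom_ids, dom_ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    V_ab <- exciton_coupling(domains[[i]], domains[[j]], couplings)
    k[i, j] <- domain_rate(domains[[i]], domains[[j]], V_ab, mix_mode)
  }
  tau <- ifelse(is.na(k), NA_real_, ifelse(k > 0, 1 / k, Inf))
  structure(list(rate = k, tau = tau, domains = domains,
                 roles = partition$roles, display = partition$display,
                 meta = list(temperature = temperature,
                             sigma_mode = sigma_mode, mix_mode = mix_mode,
                             kB_cm1_K = .eet_const$kB_cm1_K,
                             constants_version = .eet_const$version)),
            class = "domain_rate_matrix")
}

#' @export
print.domain_rate_matrix <- function(x, ...) {
  finite <- x$tau[is.finite(x$tau) & !is.na(x$tau)]
  cat("<domain_rate_matrix> ", nrow(x$rate), " domains at ",
      x$meta$temperature, " K; fastest tau = ",
      format(min(finite), digits = 3), " ps\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.domain_rate_matrix <- function(x, ...) {
  ids <- rownames(x$rate)
  sizes <- vapply(x$domains, function(d) length(d$member_ids), 0L)
  idx <- which(row(x$rate) != col(x$rate), arr.ind = TRUE)
  data.frame(donor_domain = ids[idx[, 1]], acceptor_domain = ids[idx[, 2]],
             k_per_ps = x$rate[idx], tau_ps = x$tau[idx],
             n_donor_pigments = sizes[idx[, 1]],
             n_acceptor_pigments = sizes[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' Export domain rates as CSV
#' @param domain_rates A `domain_rate_matrix`.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_domain_rates <- function(domain_rates, path) {
  utils::write.csv(as.data.frame(domain_rates), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Per-domain exciton report (eigenvalues and Boltzmann weights)
#' @param domain_rates A `domain_rate_matrix`.
#' @return Named list (per domain) of eigenvalues, weights, partition
#'   function and temperature; suitable for JSON export.
#' @export
exciton_report <- function(domain_rates) {
  lapply(domain_rates$domains, function(d)
    list(eigenvalues_cm1 = unname(d$evals),
         boltzmann_weights = unname(d$weights),
         partition_function = d$Z,
         temperature_K = d$temperature))
}
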