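# Classical pairwise Forster rates: T = (2*pi/hbar) |V|^2 J, with V in cm^-1
# and J in (cm^-1)^-1, expressed in ps^-1.

#' Pairwise Forster rate from coupling and spectral overlap
#'
#' `T = C_rate * V^2 * J` with `C_rate = 2*pi/hbar` expressed so that
#' (cm^-1)^2 * (cm^-1)^-1 yields ps^-1 (see [eet_constants()]).
#'
#' @param V Electronic coupling(s), cm^-1.
#' @param J Spectral overlap(s), (cm^-1)^-1; must be >= 0.
#' @return Transfer rate(s) in ps^-1.
#' @examples
#' pairwise_rate(10, 2.8209e-3)   # ~0.334 ps^-1, i.e. tau ~ 3 ps
#' @export
pairwise_rate <- function(V, J) {
  if (any(!is.finite(J)) || any(J < 0)) stop("overlap J must be >= 0")
  .eet_const$rate_ps_per_cm1 * V^2 * J
}

#' Directional pairwise rate matrix over all chlorophyll pairs
#'
#' Combines a coupling matrix with per-pigment Gaussian lineshapes (and any
#' experimental overlap-table overrides, applied per ordered type pair) into
#' the full donor -> acceptor rate matrix. Rates are directional whenever
#' donor and acceptor lineshapes differ.
#'
#' @param couplings A [coupling_matrix()].
#' @param pigments The `pigment_set` the couplings were computed on.
#' @param site_energies Site-energy/lineshape table
#'   (see [default_site_energies()]).
#' @param table Optional [overlap_table()] of experimental overrides.
#' @param sigma_mode Passed to [lineshape_params()].
#' @return A `rate_matrix`: list with `rate` (T, ps^-1, `NA` diagonal),
#'   `tau` (1/T, ps, `Inf` where T = 0), per-pair `J`, pigment `ids` and
#'   `types`, and metadata.
#' @export
rate_matrix <- function(couplings, pigments,
                        site_energies = default_site_energies(),
                        table = NULL, sigma_mode = "fwhm") {
  stopifnot(inherits(couplings, "coupling_matrix"),
            inherits(pigments, "pigment_set"))
  ids <- rownames(couplings$V)
  stopifnot(identical(ids, names(pigments$pigments)))
  ls <- lapply(pigments$pigments, lineshape_for,
               site_energies = site_energies, sigma_mode = sigma_mode)
  types <- vapply(pigments$pigments, `[[`, "", "type")
  n <- length(ids)
  J <- matrix(0, n, n, dimnames = list(ids, ids))
  # vectorised Gaussian closed form over all ordered pairs
  sig <- vapply(ls, `[[`, 0, "sigma")
  w0 <- vapply(ls, `[[`, 0, "omega0")
  st <- vapply(ls, `[[`, 0, "stokes")
  s2 <- outer(sig^2, sig^2, `+`)
  det <- outer(w0 - st, w0, `-`)
  J <- exp(-det^2 / (2 * s2)) / sqrt(2 * pi * s2)
  if (!is.null(table) && nrow(table)) {
    for (k in seq_len(nrow(table))) {
      hit_d <- types == table$donor_type[k]
      hit_a <- types == table$acceptor_type[k]
      J[hit_d, hit_a] <- table$J[k]
    }
  }
  Tm <- pairwise_rate(couplings$V, J)
  diag(Tm) <- NA_real_
  diag(J) <- NA_real_
  tau <- ifelse(Tm > 0, 1 / Tm, Inf)
  structure(list(rate = Tm, tau = tau, J = J, V = couplings$V, ids = ids,
                 types = types,
                 meta = list(sigma_mode = sigma_mode,
                             method = couplings$method,
                             screening = couplings$screening,
                             constants_version = .eet_const$version)),
            class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  finite <- x$tau[is.finite(x$tau)]
  cat("<rate_matrix> ", length(x$ids), " pigments; fastest tau = ",
      format(min(finite), digits = 3), " ps\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.rate_matrix <- function(x, ...) {
  n <- length(x$ids)
  idx <- which(row(x$rate) != col(x$rate), arr.ind = TRUE)
  data.frame(donor_id = x$ids[idx[, 1]], acceptor_id = x$ids[idx[, 2]],
             V_cm1 = x$V[idx], J_inv_cm1 = x$J[idx],
             T_per_ps = x$rate[idx], tau_ps = x$tau[idx],
             stringsAsFactors = FALSE)
}

#' Export a rate matrix as long-form CSV
#'
#' Rates below `floor` (ps^-1) are written as 0 in the export (the dense
#' matrix in memory is untouched); this mirrors the practice of omitting
#' immeasurably slow pairs from transfer maps, at a far looser threshold.
#'
#' @param rates A `rate_matrix`.
#' @param path Output CSV.
#' @param floor Sparsity floor in ps^-1 (default 1e-6, i.e. tau > 1e6 ps).
#' @return `path`, invisibly.
#' @export
write_rates <- function(rates, path, floor = 1e-6) {
  df <- as.data.frame(rates)
  drop <- df$T_per_ps < floor
  df$T_per_ps[drop] <- 0
  df$tau_ps[drop] <- Inf
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
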