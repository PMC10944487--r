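# helpers: small aggregates with controllable geometry and energies

gf_fixture <- function(centers, axes = NULL, types = "CHL_A",
                       site = default_site_energies()) {
  n <- nrow(centers)
  if (is.null(axes)) axes <- matrix(rep(c(0, 0, 1), n), ncol = 3,
                                    byrow = TRUE)
  ps <- synth_set(centers, axes, types = types)
  lib <- lapply(stats::setNames(nm = unique(rep_len(types, n))),
                function(t) make_charge_set(4, 1, t))
  list(ps = ps, cm = coupling_matrix(ps, lib), site = site)
}

test_that("single-pigment domains reduce to trivial exciton structure", {
  fx <- gf_fixture(rbind(c(0, 0, 0), c(30, 0, 0)))
  d <- build_domain("D", "A:1:CLA", fx$ps, fx$cm, fx$site)
  expect_equal(d$evals, 14900)
  expect_equal(abs(as.numeric(d$coeffs)), 1)
  expect_equal(d$weights, 1)
  expect_equal(d$Z, 1)
  expect_error(build_domain("D", "A:1:CLA", fx$ps, fx$cm, fx$site,
                            temperature = 0), "temperature")
  expect_error(build_domain("D", "Z:9:CLA", fx$ps, fx$cm, fx$site),
               "Z:9:CLA")
  bad_site <- data.frame(key = "CHL_C", omega0_cm1 = 1, fwhm_cm1 = 1,
                         stokes_cm1 = 0)
  expect_error(build_domain("D", "A:1:CLA", fx$ps, fx$cm, bad_site),
               "A:1:CLA")
})

test_that("symmetric homodimer splits into E -/+ |V| with +/- 1/sqrt(2) coefficients", {
  fx <- gf_fixture(rbind(c(0, 0, 0), c(10, 0, 0)))
  V <- fx$cm$V["A:1:CLA", "B:2:CLA"]
  d <- build_domain("D", c("A:1:CLA", "B:2:CLA"), fx$ps, fx$cm, fx$site)
  expect_equal(d$evals, c(14900 - abs(V), 14900 + abs(V)), tolerance = 1e-12)
  expect_equal(abs(d$coeffs), matrix(1 / sqrt(2), 2, 2,
                                     dimnames = dimnames(d$coeffs)),
               tolerance = 1e-12)
  # orthonormal eigenvectors, normalised Boltzmann weights
  expect_equal(crossprod(d$coeffs), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sum(d$weights), 1, tolerance = 1e-12)
  # weights follow the Boltzmann ratio at the domain temperature
  kT <- eet_constants()$kB_cm1_K * 300
  expect_equal(d$weights[2] / d$weights[1],
               exp(-(d$evals[2] - d$evals[1]) / kT), tolerance = 1e-12)
})

test_that("random 5-mer eigenpairs match a characteristic-polynomial oracle", {
  set.seed(23)
  centers <- matrix(stats::runif(15, 0, 40), ncol = 3)
  axes <- t(replicate(5, rand_unit()))
  fx <- gf_fixture(centers, axes)
  d <- build_domain("D", names(fx$ps$pigments), fx$ps, fx$cm, fx$site)
  # independent eigenvalues: roots of det(H - lambda I) via pracma::charpoly
  H <- fx$cm$V[names(fx$ps$pigments), names(fx$ps$pigments)]
  diag(H) <- 14900
  # centre the spectrum before polyroot so the polynomial is well conditioned
  roots <- sort(Re(polyroot(rev(pracma::charpoly(H - diag(14900, 5)))))) +
    14900
  expect_equal(d$evals, roots, tolerance = 1e-8)
  # eigenpairs satisfy H c = eps c
  for (a in 1:5)
    expect_lt(max(abs(H %*% d$coeffs[, a] - d$evals[a] * d$coeffs[, a])),
              1e-8)
  expect_equal(crossprod(d$coeffs), diag(5), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("exciton couplings transform as the coefficient-weighted double sum", {
  fx <- gf_fixture(rbind(c(0, 0, 0), c(9, 0, 0), c(40, 0, 0), c(49, 0, 0)))
  ids <- names(fx$ps$pigments)
  D <- build_domain("D", ids[1:2], fx$ps, fx$cm, fx$site)
  A <- build_domain("A", ids[3:4], fx$ps, fx$cm, fx$site)
  V_ab <- exciton_coupling(D, A, fx$cm)
  # brute-force double sum, evaluated independently
  for (a in 1:2) for (b in 1:2) {
    acc <- 0
    for (i in 1:2) for (j in 1:2)
      acc <- acc + D$coeffs[i, a] * A$coeffs[j, b] *
        fx$cm$V[ids[i], ids[2 + j]]
    expect_equal(unname(V_ab[a, b]), unname(acc), tolerance = 1e-12)
  }
  # single-pigment domains: exciton coupling equals the site coupling
  D1 <- build_domain("D1", ids[1], fx$ps, fx$cm, fx$site)
  A1 <- build_domain("A1", ids[3], fx$ps, fx$cm, fx$site)
  expect_equal(abs(as.numeric(exciton_coupling(D1, A1, fx$cm))),
               abs(fx$cm$V[ids[1], ids[3]]), tolerance = 1e-12)
  # zero inter-domain couplings give zero exciton couplings
  cm0 <- fx$cm
  cm0$V[ids[1:2], ids[3:4]] <- 0
  cm0$V[ids[3:4], ids[1:2]] <- 0
  expect_equal(max(abs(exciton_coupling(D, A, cm0))), 0)
  expect_error(exciton_coupling(D, D, fx$cm), "share")
})

test_that("exciton lineshapes mix monomer parameters convexly", {
  # single-pigment domain: identical to the monomer lineshape
  fx <- gf_fixture(rbind(c(0, 0, 0), c(10, 0, 0)))
  D1 <- build_domain("D", "A:1:CLA", fx$ps, fx$cm, fx$site)
  ls1 <- exciton_lineshape(D1, 1)
  mono <- lineshape_for(fx$ps$pigments[["A:1:CLA"]], fx$site)
  expect_equal(ls1$fwhm, mono$fwhm)
  expect_equal(ls1$stokes, mono$stokes)
  expect_equal(ls1$omega0, mono$omega0)

  # homodimer: width equals the monomer width (weights sum to 1)
  D2 <- build_domain("D", c("A:1:CLA", "B:2:CLA"), fx$ps, fx$cm, fx$site)
  expect_equal(exciton_lineshape(D2, 1)$fwhm, 240)
  expect_equal(exciton_lineshape(D2, 2)$fwhm, 240)

  # heterodimer with distinct widths: mixed width between the monomer values
  site <- rbind(data.frame(key = "A:1:CLA", omega0_cm1 = 14900,
                           fwhm_cm1 = 200, stokes_cm1 = 160),
                data.frame(key = "B:2:CLA", omega0_cm1 = 15100,
                           fwhm_cm1 = 400, stokes_cm1 = 160))
  D3 <- build_domain("D", c("A:1:CLA", "B:2:CLA"), fx$ps, fx$cm, site)
  for (a in 1:2) {
    w <- exciton_lineshape(D3, a)$fwhm
    expect_gte(w, 200); expect_lte(w, 400)
  }
  # absorption centred at the exciton energy, emission Stokes-shifted
  expect_equal(exciton_lineshape(D3, 1)$omega0, D3$evals[1])
})

test_that("generalized rate reduces to the classical rate for single pigments", {
  set.seed(31)
  for (Tk in c(77, 300, 500)) {
    centers <- rbind(c(0, 0, 0), c(stats::runif(1, 15, 40), 0, 0))
    axes <- rbind(rand_unit(), rand_unit())
    fx <- gf_fixture(centers, axes)
    ids <- names(fx$ps$pigments)
    D <- build_domain("D", ids[1], fx$ps, fx$cm, fx$site, temperature = Tk)
    A <- build_domain("A", ids[2], fx$ps, fx$cm, fx$site, temperature = Tk)
    k <- domain_rate(D, A, exciton_coupling(D, A, fx$cm))
    lm <- lineshape_for(fx$ps$pigments[[1]], fx$site)
    ln <- lineshape_for(fx$ps$pigments[[2]], fx$site)
    classical <- pairwise_rate(fx$cm$V[ids[1], ids[2]],
                               overlap_integral(lm, ln))
    expect_equal(k, classical, tolerance = 1e-10)
  }
})

test_that("domain rates vanish without coupling and respect Boltzmann limits", {
  fx <- gf_fixture(rbind(c(0, 0, 0), c(10, 0, 0), c(300, 0, 0)))
  ids <- names(fx$ps$pigments)
  D <- build_domain("D", ids[1:2], fx$ps, fx$cm, fx$site)
  A <- build_domain("A", ids[3], fx$ps, fx$cm, fx$site)
  V_ab <- exciton_coupling(D, A, fx$cm)
  expect_equal(domain_rate(D, A, V_ab * 0), 0)
  expect_error(domain_rate(D, A, t(V_ab)), "dimensions")

  # infinite-temperature limit: both homodimer donor states weighted 1/2
  Dhot <- build_domain("D", ids[1:2], fx$ps, fx$cm, fx$site,
                       temperature = 1e9)
  expect_equal(Dhot$weights, c(0.5, 0.5), tolerance = 1e-6)
})

test_that("aggregate rates are invariant to member ordering", {
  net <- make_grouped_network(synthetic_spec(n_clusters = 2,
                                             pigments_per_cluster = 4,
                                             centroid_spacing = 50,
                                             orientation = "random",
                                             seed = 13))
  cm <- coupling_matrix(net$pigments, net$charge_library)
  dr1 <- all_domain_rates(net$partition, net$pigments, cm)
  part2 <- net$partition
  part2$domains <- lapply(part2$domains, rev)
  dr2 <- all_domain_rates(part2, net$pigments, cm)
  expect_equal(dr1$rate, dr2$rate, tolerance = 1e-10)
})

test_that("degenerate exciton subspaces do not affect aggregate rates", {
  # equilateral homotrimer donor: the upper exciton level is doubly
  # degenerate; rates must be invariant to the arbitrary basis returned by
  # the solver, probed by rotating the pigment labelling around the triangle
  r <- 10 / sqrt(3)
  tri <- t(sapply(0:2, function(k)
    c(r * cos(2 * pi * k / 3), r * sin(2 * pi * k / 3), 0)))
  acc <- c(0, 0, 40)
  fx <- gf_fixture(rbind(tri, acc))
  ids <- names(fx$ps$pigments)
  D0 <- build_domain("D", ids[1:3], fx$ps, fx$cm, fx$site)
  expect_equal(D0$evals[1], D0$evals[2], tolerance = 1e-9)
  A <- build_domain("A", ids[4], fx$ps, fx$cm, fx$site)
  k0 <- domain_rate(D0, A, exciton_coupling(D0, A, fx$cm))
  for (perm in list(c(2, 3, 1), c(3, 1, 2))) {
    Dp <- build_domain("D", ids[perm], fx$ps, fx$cm, fx$site)
    kp <- domain_rate(Dp, A, exciton_coupling(Dp, A, fx$cm))
    expect_equal(kp, k0, tolerance = 1e-10)
  }
})

test_that("raising temperature speeds transfer from a bottom-weighted donor", {
  # two-state donor whose lower exciton is both detuned from and less
  # coupled to the acceptor: populating the upper state helps
  site <- rbind(data.frame(key = "A:1:CLA", omega0_cm1 = 14600,
                           fwhm_cm1 = 240, stokes_cm1 = 0),
                data.frame(key = "B:2:CLA", omega0_cm1 = 15200,
                           fwhm_cm1 = 240, stokes_cm1 = 0),
                data.frame(key = "C:3:CLA", omega0_cm1 = 15200,
                           fwhm_cm1 = 240, stokes_cm1 = 0))
  centers <- rbind(c(0, 0, 0), c(12, 0, 0), c(27, 0, 0))
  fx <- gf_fixture(centers, site = site)
  ids <- names(fx$ps$pigments)
  ks <- vapply(c(150, 300, 600), function(Tk) {
    D <- build_domain("D", ids[1:2], fx$ps, fx$cm, site, temperature = Tk)
    A <- build_domain("A", ids[3], fx$ps, fx$cm, site, temperature = Tk)
    domain_rate(D, A, exciton_coupling(D, A, fx$cm))
  }, 0)
  expect_true(all(diff(ks) > 0))
})

test_that("domain-rate matrices export cleanly with exciton reports", {
  net <- make_grouped_network(synthetic_spec(n_clusters = 3,
                                             pigments_per_cluster = 3,
                                             seed = 2))
  cm <- coupling_matrix(net$pigments, net$charge_library)
  dr <- all_domain_rates(net$partition, net$pigments, cm)
  df <- as.data.frame(dr)
  expect_equal(nrow(df), 6)
  expect_true(all(df$n_donor_pigments == 3))
  expect_true(all(df$k_per_ps >= 0))
  rep_ <- exciton_report(dr)
  expect_equal(length(rep_), 3)
  expect_equal(sum(rep_$D01$boltzmann_weights), 1, tolerance = 1e-12)
  expect_equal(length(rep_$D01$eigenvalues_cm1), 3)
})
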