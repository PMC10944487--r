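# Synthetic pigment networks with planted ground truth. Pigments are
# two-point transition dipoles carried by pseudo-atoms (P1/P2 for the
# charges, MG for the center, NB/ND for the Qy axis), so the same charge-set
# and axis machinery runs unchanged on real and synthetic inputs.

#' Two-point synthetic charge set with an exact dipole
#'
#' Charges +q/-q on pseudo-atoms P1/P2 placed `separation` apart along the Qy
#' axis, with `q = dipole / (debye_per_e_ang * separation)` so the placed
#' dipole magnitude equals the request exactly.
#'
#' @param dipole Transition dipole magnitude, Debye (> 0).
#' @param separation Charge separation, Angstrom (> 0).
#' @param pigment_type Type label for the set.
#' @return A [charge_set()] (no rescaling metadata: the dipole is exact by
#'   construction). The separation is recorded as attribute `"separation"`.
#' @examples
#' make_charge_set(4.8032, 1)   # q ~ +/- 0.5 e... (1 e*A ~ 4.8032 D)
#' @export
make_charge_set <- function(dipole, separation = 1, pigment_type = "CHL_A") {
  if (!is.finite(dipole) || dipole <= 0) stop("dipole must be > 0 Debye")
  if (!is.finite(separation) || separation <= 0)
    stop("separation must be > 0 Angstrom")
  q <- dipole / (.eet_const$debye_per_e_ang * separation)
  cs <- charge_set(c(P1 = q, P2 = -q), pigment_type = pigment_type,
                   label = sprintf("synthetic two-point dipole %.4g D", dipole))
  attr(cs, "separation") <- separation
  cs
}

.synth_pigment <- function(id, chain, resno, center, axis, type = "CHL_A",
                           separation = 1, resid = "CLA") {
  axis <- axis / sqrt(sum(axis^2))
  coords <- rbind(
    P1 = center + axis * separation / 2,
    P2 = center - axis * separation / 2,
    MG = center,
    NB = center - axis,    # axis convention NB -> ND
    ND = center + axis)
  list(id = id, chain = chain, resno = resno, resid = resid, type = type,
       atom_coords = coords, center = center, qy_axis = axis)
}

#' Synthetic two-pigment fixture with a known orientation factor
#'
#' @param R Center-to-center distance, Angstrom; must exceed twice the charge
#'   separation.
#' @param geometry `"stacked"` (parallel axes perpendicular to the separation
#'   vector, orientation factor kappa = 1), `"collinear"` (head-to-tail along
#'   the separation vector, kappa = -2), or `"custom"` with explicit `axes`.
#' @param separation Charge separation of the two-point dipoles, Angstrom.
#' @param axes For `"custom"`: 2 x 3 matrix of (unnormalised) Qy axes.
#' @param types Pigment types of the two pigments.
#' @return A `pigment_set` of 2 pigments; the analytic kappa is recorded as
#'   attribute `"kappa"`.
#' @export
make_dimer <- function(R, geometry = c("stacked", "collinear", "custom"),
                       separation = 1, axes = NULL,
                       types = c("CHL_A", "CHL_A")) {
  geometry <- match.arg(geometry)
  if (R <= 2 * separation)
    stop("R must exceed twice the charge separation")
  rhat <- c(1, 0, 0)
  ax <- switch(geometry,
    stacked = rbind(c(0, 0, 1), c(0, 0, 1)),
    collinear = rbind(c(1, 0, 0), c(1, 0, 0)),
    custom = {
      if (is.null(axes) || !all(dim(axes) == c(2, 3)))
        stop("custom geometry needs a 2 x 3 axes matrix")
      axes
    })
  ax <- ax / sqrt(rowSums(ax^2))
  kappa <- sum(ax[1, ] * ax[2, ]) -
    3 * sum(ax[1, ] * rhat) * sum(ax[2, ] * rhat)
  pigs <- list(
    .synth_pigment("A:1:CLA", "A", 1L, c(0, 0, 0), ax[1, ], types[1],
                   separation),
    .synth_pigment("B:1:CLA", "B", 1L, c(R, 0, 0), ax[2, ], types[2],
                   separation))
  ps <- pigment_set(pigs, source = "synthetic",
                    provenance = sprintf("synthetic:dimer:%s", geometry))
  attr(ps, "kappa") <- kappa
  ps
}

#' Specification for a synthetic grouped pigment network
#'
#' Defines clusters of pigments (one cluster per domain) laid out on a ring
#' of cluster centroids, emulating an antenna-ring-plus-core topology at
#' reduced scale.
#'
#' @param n_clusters Number of clusters.
#' @param pigments_per_cluster Pigments in each cluster (recycled).
#' @param centroid_spacing Distance between adjacent cluster centroids,
#'   Angstrom.
#' @param intra_spacing Distance between adjacent pigments within a cluster,
#'   Angstrom (> 1).
#' @param orientation `"aligned"` (all Qy axes along z) or `"random"`
#'   (seeded isotropic axes).
#' @param dipole_debye Transition dipole magnitude of every pigment, Debye.
#' @param separation Two-point charge separation, Angstrom.
#' @param types Pigment type per cluster (recycled).
#' @param core_cluster Index of the cluster to tag CORE, or `NA` for none.
#' @param link_tau_ps Planted-group link threshold: two clusters are in the
#'   same planted group when the dipole-limit time constant of their closest
#'   pigment pair (best direction) is at or below this, ps.
#' @param site_energies Site-energy table used for the planted-truth rate
#'   estimates.
#' @param seed Integer seed; fixed seed gives byte-identical networks.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_clusters = 3, pigments_per_cluster = 5,
                           centroid_spacing = 80, intra_spacing = 12,
                           orientation = c("aligned", "random"),
                           dipole_debye = 4, separation = 1,
                           types = "CHL_A", core_cluster = NA,
                           link_tau_ps = 20,
                           site_energies = default_site_energies(),
                           seed = 1L) {
  orientation <- match.arg(orientation)
  if (intra_spacing <= 1) stop("intra_spacing must exceed 1 Angstrom")
  if (centroid_spacing <= 0) stop("centroid_spacing must be positive")
  structure(list(
    n_clusters = n_clusters,
    pigments_per_cluster = rep_len(pigments_per_cluster, n_clusters),
    centroid_spacing = centroid_spacing, intra_spacing = intra_spacing,
    orientation = orientation, dipole_debye = dipole_debye,
    separation = separation, types = rep_len(types, n_clusters),
    core_cluster = core_cluster, link_tau_ps = link_tau_ps,
    site_energies = site_energies, seed = as.integer(seed)),
    class = "synthetic_spec")
}

.ring_points <- function(n, spacing, center = c(0, 0, 0)) {
  if (n == 1L) return(matrix(center, 1, 3))
  radius <- spacing / (2 * sin(pi / n))   # adjacent chord = spacing
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th),
        center[3])
}

#' Generate a grouped synthetic pigment network with planted ground truth
#'
#' Cluster centroids sit on a ring with adjacent spacing
#' `centroid_spacing`; within each cluster, pigments sit on a smaller ring
#' with adjacent spacing `intra_spacing`. Each cluster becomes one domain.
#' The ground truth records the planted partition, the planted groups
#' (connected components of the cluster graph linked where the closest-pair
#' dipole-limit time constant is within `link_tau_ps`), and the analytic
#' dipole-limit coupling of every inter-cluster closest pair.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `pigments` (a `pigment_set`), `partition`
#'   (a `domain_partition`), `charge_library` (type -> two-point
#'   [charge_set()]), and `truth` (planted domains, groups, closest-pair
#'   couplings).
#' @export
make_grouped_network <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  k <- spec$n_clusters
  centroids <- .ring_points(k, spec$centroid_spacing)
  rng_axes <- .with_seed(spec$seed, {
    matrix(stats::rnorm(3 * sum(spec$pigments_per_cluster)), ncol = 3)
  })
  pigs <- list()
  dom_of <- character()
  ai <- 0L
  for (ci in seq_len(k)) {
    n <- spec$pigments_per_cluster[ci]
    pts <- .ring_points(n, spec$intra_spacing, centroids[ci, ])
    chain <- LETTERS[ci]
    for (pj in seq_len(n)) {
      ai <- ai + 1L
      axis <- if (spec$orientation == "aligned") c(0, 0, 1)
              else rng_axes[ai, ]
      resid <- if (spec$types[ci] == "CHL_C") "KC1" else "CLA"
      id <- .pigment_id(chain, pj, resid)
      pigs[[id]] <- .synth_pigment(id, chain, pj, pts[pj, ], axis,
                                   spec$types[ci], spec$separation, resid)
      dom_of[id] <- sprintf("D%02d", ci)
    }
  }
  ps <- pigment_set(pigs, source = "synthetic",
                    provenance = sprintf("synthetic:%d", spec$seed))
  d <- pairwise_geometry(ps, min_separation = 0)
  if (any(d[upper.tri(d)] < 2))
    stop("overlapping clusters: pigments closer than 2 Angstrom")
  chain_roles <- data.frame(
    chain = LETTERS[seq_len(k)],
    domain_id = sprintf("D%02d", seq_len(k)),
    role = ifelse(seq_len(k) == spec$core_cluster & !is.na(spec$core_cluster),
                  "CORE", "ANTENNA"),
    stringsAsFactors = FALSE)
  partition <- assign_domains(ps, chain_roles)
  # planted truth: closest-pair dipole-limit couplings and tau per cluster pair
  types_u <- unique(spec$types)
  charge_library <- stats::setNames(
    lapply(types_u, function(tp)
      make_charge_set(spec$dipole_debye, spec$separation, tp)), types_u)
  truth_pairs <- NULL
  linked <- matrix(FALSE, k, k)
  ids <- names(ps$pigments)
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    if (k < 2L) break
    ii <- ids[dom_of == sprintf("D%02d", i)]
    jj <- ids[dom_of == sprintf("D%02d", j)]
    sub <- d[ii, jj, drop = FALSE]
    w <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    pm <- ps$pigments[[ii[w[1]]]]; pn <- ps$pigments[[jj[w[2]]]]
    V <- dipole_coupling(pm, pn, spec$dipole_debye, spec$dipole_debye)
    lm <- lineshape_for(pm, spec$site_energies)
    ln <- lineshape_for(pn, spec$site_energies)
    tau_ij <- 1 / pairwise_rate(V, overlap_integral(lm, ln))
    tau_ji <- 1 / pairwise_rate(V, overlap_integral(ln, lm))
    linked[i, j] <- linked[j, i] <- min(tau_ij, tau_ji) <= spec$link_tau_ps
    truth_pairs <- rbind(truth_pairs, data.frame(
      cluster_i = i, cluster_j = j, pigment_i = pm$id, pigment_j = pn$id,
      distance_angstrom = min(sub), V_dipole_cm1 = V,
      tau_best_ps = min(tau_ij, tau_ji), stringsAsFactors = FALSE))
  }
  gcomp <- igraph::components(igraph::graph_from_adjacency_matrix(
    linked, mode = "undirected"))
  dom_ids <- sprintf("D%02d", seq_len(k))
  groups <- lapply(split(dom_ids, gcomp$membership), sort)
  groups <- groups[order(vapply(groups, `[`, "", 1L))]
  list(pigments = ps, partition = partition,
       charge_library = charge_library,
       truth = list(domains = dom_of, groups = unname(groups),
                    closest_pairs = truth_pairs,
                    link_tau_ps = spec$link_tau_ps, seed = spec$seed))
}

# evaluate expr under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write a pigment set as a minimal PDB fixture
#'
#' Emits HETATM records (CLA/KC1 residue codes, pseudo-atom names) that
#' [read_structure()] + [extract_pigments()] round-trip losslessly for
#' centers and axes to within the PDB coordinate precision (1e-3 Angstrom).
#'
#' @param pigments A `pigment_set`.
#' @param path Output `.pdb` file.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(pigments, path) {
  stopifnot(inherits(pigments, "pigment_set"))
  rows <- do.call(rbind, lapply(pigments$pigments, function(p) {
    data.frame(elety = rownames(p$atom_coords),
               x = p$atom_coords[, 1], y = p$atom_coords[, 2],
               z = p$atom_coords[, 3],
               resno = p$resno, chain = p$chain, resid = p$resid,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  elesy <- ifelse(rows$elety == "MG", "MG",
           ifelse(rows$elety %in% c("NB", "ND", "NA", "NC"), "N", "C"))
  xyz <- as.numeric(t(as.matrix(rows[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, type = "HETATM",
                   resno = rows$resno, resid = rows$resid,
                   chain = rows$chain, elety = rows$elety, elesy = elesy,
                   eleno = seq_len(nrow(rows)),
                   o = rep(1, nrow(rows)), b = rep(0, nrow(rows)))
  invisible(path)
}
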