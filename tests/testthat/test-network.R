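# build a domain_rate_matrix directly from a tau matrix (white-box fixture)
drm_from_tau <- function(tau, roles = NULL) {
  k <- 1 / tau
  diag(k) <- NA_real_
  diag(tau) <- NA_real_
  if (is.null(roles))
    roles <- stats::setNames(rep("ANTENNA", nrow(tau)), rownames(tau))
  structure(list(rate = k, tau = tau, domains = list(), roles = roles,
                 display = stats::setNames(rownames(tau), rownames(tau)),
                 meta = list(temperature = 300)),
            class = "domain_rate_matrix")
}

tau_mat <- function(ids, default = Inf) {
  matrix(default, length(ids), length(ids), dimnames = list(ids, ids))
}

test_that("edges are classified into half-open time-constant bins", {
  ids <- c("A", "B", "C", "D")
  tau <- tau_mat(ids)
  tau["A", "B"] <- 0.5    # FAST
  tau["B", "A"] <- 1.0    # boundary: MID under the half-open convention
  tau["A", "C"] <- 9.999  # MID
  tau["C", "A"] <- 10     # SLOW
  tau["B", "C"] <- 19.99  # SLOW
  tau["C", "D"] <- 25     # OMITTED
  cls <- classify_edges(drm_from_tau(tau))
  get <- function(d, a) as.character(cls$class[cls$donor == d &
                                                 cls$acceptor == a])
  expect_equal(get("A", "B"), "FAST")
  expect_equal(get("B", "A"), "MID")
  expect_equal(get("A", "C"), "MID")
  expect_equal(get("C", "A"), "SLOW")
  expect_equal(get("B", "C"), "SLOW")
  expect_equal(get("C", "D"), "OMITTED")
  # exhaustive and mutually exclusive over every directed pair
  expect_equal(nrow(cls), 12)
  expect_true(all(!is.na(cls$class)))
  expect_error(classify_edges(drm_from_tau(tau), bins = c(10, 1, 20)),
               "ascending")
  expect_error(classify_edges(drm_from_tau(tau), bins = c(-1, 10)),
               "ascending|positive")
})

test_that("classification works directly on pigment-level rate matrices", {
  centers <- rbind(c(0, 0, 0), c(10, 0, 0))
  ps <- synth_set(centers, matrix(rep(c(0, 0, 1), 2), ncol = 3, byrow = TRUE))
  cm <- coupling_matrix(ps, list(CHL_A = make_charge_set(4, 1)))
  rm_ <- rate_matrix(cm, ps)
  cls <- classify_edges(rm_)
  expect_equal(nrow(cls), 2)
  expect_true(all(cls$class %in% c("FAST", "MID", "SLOW", "OMITTED")))
})

test_that("antenna grouping finds connected components under the cutoff", {
  ids <- c("CORE", "X1", "X2", "Y1", "Z1")
  tau <- tau_mat(ids)
  tau["X1", "X2"] <- 5; tau["X2", "X1"] <- 30   # min = 5: linked
  tau["Y1", "X1"] <- 50; tau["X1", "Y1"] <- 60  # too slow: separate
  tau["X1", "CORE"] <- 1                        # core never grouped
  tau["Z1", "CORE"] <- 2
  tau["Z1", "Y1"] <- 80                         # reachable only at cutoffs > 80
  dr <- drm_from_tau(tau, roles = stats::setNames(
    c("CORE", rep("ANTENNA", 4)), ids))
  groups <- group_antennae(dr, cutoff = 20, core_id = "CORE")
  expect_equal(groups, list(c("X1", "X2"), "Y1", "Z1"))
  # cutoff below every tau: singletons; cutoff above every tau: one group
  expect_equal(lengths(group_antennae(dr, cutoff = 1, core_id = "CORE")),
               rep(1L, 4))
  expect_equal(group_antennae(dr, cutoff = 100, core_id = "CORE"),
               list(c("X1", "X2", "Y1", "Z1")))
  expect_error(group_antennae(dr, core_id = "NOPE"), "NOPE")
})

test_that("planted synthetic groups are recovered end to end", {
  net <- make_grouped_network(synthetic_spec(n_clusters = 3,
                                             pigments_per_cluster = 4,
                                             centroid_spacing = 80,
                                             intra_spacing = 12, seed = 17))
  cm <- coupling_matrix(net$pigments, net$charge_library)
  dr <- all_domain_rates(net$partition, net$pigments, cm)
  groups <- group_antennae(dr, cutoff = 20, core_id = NULL)
  expect_equal(groups, net$truth$groups)
})

test_that("routes are ranked by bottleneck with deterministic tie-breaks", {
  ids <- c("A", "M", "B", "N")
  tau <- tau_mat(ids)
  tau["A", "B"] <- 30                       # slow direct edge
  tau["A", "M"] <- 2; tau["M", "B"] <- 3    # fast mediated route
  tau["A", "N"] <- 4; tau["N", "B"] <- 4
  dr <- drm_from_tau(tau)
  routes <- rank_routes(dr, "A", "B", max_steps = 2)
  expect_equal(routes$route[1], "A -> M -> B")
  expect_equal(routes$bottleneck_tau_ps[1], 3)
  expect_equal(routes$step_tau_ps[[1]], c(2, 3))
  expect_equal(nrow(routes), 3)
  # max_steps = 1 keeps only the direct route
  direct <- rank_routes(dr, "A", "B", max_steps = 1)
  expect_equal(direct$route, "A -> B")
  # a fast direct edge outranks any mediated path
  tau2 <- tau; tau2["A", "B"] <- 1
  expect_equal(rank_routes(drm_from_tau(tau2), "A", "B", 2)$route[1],
               "A -> B")
  # summed-tau scoring is available behind the flag
  tau3 <- tau_mat(ids)
  tau3["A", "M"] <- 10; tau3["M", "B"] <- 1   # bottleneck 10, total 11
  tau3["A", "B"] <- 11.5                      # bottleneck 11.5, total 11.5
  tau3["A", "N"] <- 6; tau3["N", "B"] <- 7    # bottleneck 7, total 13
  dr3 <- drm_from_tau(tau3)
  expect_equal(rank_routes(dr3, "A", "B", 2)$route[1], "A -> N -> B")
  expect_equal(rank_routes(dr3, "A", "B", 2, score = "total")$route[1],
               "A -> M -> B")
  expect_error(rank_routes(dr, "A", "A", 2), "differ")
  expect_error(rank_routes(dr, "A", "Q", 2), "Q")
  expect_equal(nrow(rank_routes(dr, "N", "M", 1)), 0)
  expect_equal(nrow(rank_routes(dr, "A", "B", 2, top_k = 1)), 1)
})

test_that("route enumeration agrees with an exhaustive oracle on small graphs", {
  set.seed(47)
  for (trial in 1:8) {
    n <- sample(3:6, 1)
    ids <- LETTERS[1:n]
    tau <- tau_mat(ids)
    # random sparse directed graph with random time constants
    for (i in ids) for (j in ids) if (i != j && stats::runif(1) < 0.5)
      tau[i, j] <- stats::runif(1, 0.5, 40)
    dr <- drm_from_tau(tau)
    src <- ids[1]; tgt <- ids[n]
    for (ms in 1:(n - 1)) {
      got <- rank_routes(dr, src, tgt, max_steps = ms)
      want <- enumerate_paths(tau, src, tgt, ms)
      expect_equal(nrow(got), length(want))
      if (!length(want)) next
      # same path set
      expect_setequal(got$route,
                      vapply(want, paste, "", collapse = " -> "))
      # ranking is ascending in bottleneck
      bn <- vapply(want, function(p)
        max(vapply(seq_len(length(p) - 1L),
                   function(i) tau[p[i], p[i + 1L]], 0)), 0)
      expect_equal(got$bottleneck_tau_ps, sort(bn))
    }
  }
})

test_that("network export writes CSV, parseable GraphML and deterministic JSON", {
  ids <- c("A", "B", "C")
  tau <- tau_mat(ids)
  tau["A", "B"] <- 0.5; tau["B", "A"] <- 5
  tau["B", "C"] <- 15; tau["A", "C"] <- 25
  dr <- drm_from_tau(tau)
  cls <- classify_edges(dr)
  groups <- group_antennae(dr, core_id = NULL)
  dir1 <- withr::local_tempdir()
  files <- export_network(dr, cls, groups, dir1)
  df <- utils::read.csv(files[["edges"]])
  expect_equal(nrow(df), 6)                      # OMITTED rows kept in CSV
  expect_true("OMITTED" %in% df$class)
  g <- igraph::read_graph(files[["graphml"]], format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 3)             # OMITTED edge absent
  el <- igraph::as_data_frame(g)
  expect_false(any(el$from == "A" & el$to == "C"))
  js <- jsonlite::read_json(files[["summary"]])
  expect_equal(js$n_edges_kept, 3)
  expect_equal(unlist(js$bins_ps), c(1, 10, 20))
  # byte-identical JSON on a second run with the same inputs
  dir2 <- withr::local_tempdir()
  files2 <- export_network(dr, cls, groups, dir2)
  expect_identical(readLines(files[["summary"]]),
                   readLines(files2[["summary"]]))
})
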