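#!/usr/bin/env Rscript
# Network products: classify the domain-level edges into time-constant bins,
# group the antennae by coupling reach, rank the transfer routes from the
# antenna farthest from the core, and export the network.

suppressPackageStartupMessages(library(eetnet))

model <- read_structure("results/network.pdb")
pigments <- extract_pigments(model)
charge_library <- list(
  CHL_A = load_charge_set("results/charges_chl_a.tsv"),
  CHL_C = load_charge_set("results/charges_chl_c.tsv"))
site <- read_site_energies("results/site_energies.tsv")
partition <- assign_domains(pigments, core_chains = "A")
cm <- coupling_matrix(pigments, charge_library)
dr <- all_domain_rates(partition, pigments, cm, site_energies = site)

cls <- classify_edges(dr, bins = c(1, 10, 20))
cat("Domain-level edges per class:\n")
print(table(cls$class))

groups <- group_antennae(dr, cutoff = 20, core_id = "CORE")
cat("Antenna groups (connected at the 20 ps reach cutoff):\n")
for (g in groups) cat("  -", paste(g, collapse = ", "), "\n")

# the ring antenna geometrically farthest from the core centroid
ctr <- sapply(names(partition$domains), function(d)
  colMeans(t(sapply(partition$domains[[d]],
                    function(id) pigments$pigments[[id]]$center))))
far <- names(which.max(colSums((ctr - ctr[, "CORE"])^2)))
routes <- rank_routes(dr, far, "CORE", max_steps = 4, top_k = 5)
cat("Top routes from", far, "to the core (bottleneck tau, ps):\n")
print(routes[, c("rank", "route", "bottleneck_tau_ps")], row.names = FALSE)

files <- export_network(dr, cls, groups, "results/network")
cat("Wrote", paste(basename(files), collapse = ", "), "to results/network/\n")
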