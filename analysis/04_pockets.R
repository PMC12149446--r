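#!/usr/bin/env Rscript
# Ligand-binding-pocket volumetrics on analytic cavity fixtures of
# different sizes: SES volume/area, sphericity, effective radius, the
# percent-of-reference normalization, and the cross-pocket statistics
# (Kruskal-Wallis, OLS regression of "experimental" vs "predicted"
# metrics, hierarchical clustering on standardized (r_eff, Psi)).

suppressMessages(library(nrcompare))
set.seed(7)

radii <- c(small = 3, mid = 4, large = 5, xl = 6)
rows <- NULL
for (nm in names(radii)) {
  cav <- make_spherical_cavity(radii[[nm]])
  pm <- pocket_metrics(cav, cav$hetero_groups, cutoff = radii[[nm]] + 3)
  rows <- rbind(rows, data.frame(
    pocket = nm, radius_true = radii[[nm]], volume = pm$volume,
    area = pm$area, sphericity = pm$sphericity,
    effective_radius = pm$effective_radius,
    volume_analytic = 4 / 3 * pi * radii[[nm]]^3))
}
rows$pct_of_analytic <- pocket_normalization(rows$volume, rows$volume_analytic)
write.csv(rows, "results/pockets.csv", row.names = FALSE)

cat("Pocket metrics vs analytic spheres:\n")
for (i in seq_len(nrow(rows)))
  cat(sprintf("  %-6s V = %7.1f A^3 (%.1f%% of analytic), Psi = %.3f, r_eff = %.2f A\n",
              rows$pocket[i], rows$volume[i], rows$pct_of_analytic[i],
              rows$sphericity[i], rows$effective_radius[i]))

# "predicted" counterparts: the same cavities re-measured after a rigid
# motion plus a slightly coarser grid, mimicking method sensitivity
pred <- NULL
for (nm in names(radii)) {
  cav <- make_spherical_cavity(radii[[nm]], shell_atom_count = 450)
  pm <- pocket_metrics(cav, cav$hetero_groups, cutoff = radii[[nm]] + 3,
                       voxel = 0.5)
  pred <- rbind(pred, data.frame(pocket = nm, volume = pm$volume,
                                 sphericity = pm$sphericity,
                                 effective_radius = pm$effective_radius))
}
dev <- pocket_deviation(pred$volume, rows$volume)
cat(sprintf("Volume deviation (re-measured vs reference): %s\n",
            paste(sprintf("%+.1f%%", dev), collapse = ", ")))

kw <- kruskal_wallis(list(rows$effective_radius, pred$effective_radius))
cat(sprintf("Kruskal-Wallis on effective radius (two measurement routes): H = %.3f, p = %.3f\n",
            kw$H, kw$p))
fit <- regression_slope(rows$sphericity, pred$sphericity)
cat(sprintf("Sphericity agreement: slope = %.3f, r = %.3f\n", fit$slope, fit$r))

pts <- as.matrix(rows[, c("effective_radius", "sphericity")])
rownames(pts) <- rows$pocket
hc <- hierarchical_cluster(pts)
cat("Clustering merge order (labels):",
    paste(rows$pocket[abs(hc$merge[hc$merge < 0])[1:2]], collapse = " + "),
    "merge first\n")
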