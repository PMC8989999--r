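#!/usr/bin/env Rscript
# Population statistics at the study's single-cell regimes: ON/OFF calling
# against a non-tagged control for the three activation levels (Cad 83%,
# Adi 47.7%, Gad 99%), latent-correlation recovery for the inter-system
# Pearson coefficients, and the chi-square histogram comparison between a
# right-skewed and a Gaussian-like channel.
# Outputs: results/on_fractions.csv, results/correlations_recovered.csv

suppressMessages(library(acidhet))
dir.create("results", showWarnings = FALSE)

## ON fractions
on_regimes <- c(cad = 0.83, adi = 0.477, gad = 0.99)
set.seed(42)
rows <- lapply(names(on_regimes), function(ch) {
  sp <- population_spec(
    list(channel_spec(ch, on_regimes[[ch]], "lognormal", loc = 5,
                      scale = 0.4, off_level = 2)),
    background_mean = 3, background_sd = 0.5, cells_per_field = 1000,
    seed = 50 + match(ch, names(on_regimes)))
  cells <- simulate_population(sp)
  control <- 2 + rnorm(500, 3, 0.5)
  call <- call_on_off(cells[[paste0(ch, "_raw")]], control)
  data.frame(channel = ch, generating = on_regimes[[ch]],
             threshold = call$threshold, on_fraction = call$on_fraction)
})
on_tab <- do.call(rbind, rows)
write.csv(on_tab, "results/on_fractions.csv", row.names = FALSE)
cat("ON fractions (control threshold = mean + 3 sd):\n")
print(on_tab, digits = 3)

## correlation recovery at the t300 structure
corr <- matrix(c(1, 0.45, 0.10, 0.45, 1, -0.07, 0.10, -0.07, 1), 3, 3)
sp <- population_spec(
  list(channel_spec("gad", 1, "normal", loc = 200, scale = 35),
       channel_spec("adi", 1, "normal", loc = 110, scale = 22),
       channel_spec("cad", 1, "normal", loc = 150, scale = 30)),
  correlation = corr, cells_per_field = 1000, seed = 60)
cells <- simulate_population(sp)
pairs <- list(c("gad", "adi", 0.45), c("adi", "cad", -0.07),
              c("gad", "cad", 0.10))
ct <- do.call(rbind, lapply(pairs, function(p) {
  r <- pearson(cells[[paste0(p[[1]], "_raw")]],
               cells[[paste0(p[[2]], "_raw")]], p[[1]], p[[2]])
  data.frame(channel_x = p[[1]], channel_y = p[[2]],
             latent = as.numeric(p[[3]]), r = r$r, p_value = r$p_value)
}))
write.csv(ct, "results/correlations_recovered.csv", row.names = FALSE)
cat("\nPearson correlations vs latent targets:\n")
print(ct, digits = 3)

## distribution-shape comparison
sk_cad <- skewness_g1(cells$cad_raw)
cmp <- chi_square_compare(
  simulate_population(population_spec(
    list(channel_spec("c", 1, "lognormal", loc = 5, scale = 0.6)),
    cells_per_field = 1000, seed = 61))$c_raw,
  simulate_population(population_spec(
    list(channel_spec("g", 1, "normal", loc = 160, scale = 35)),
    cells_per_field = 1000, seed = 62))$g_raw)
cat(sprintf("\nRight-skewed vs Gaussian-like histograms: chi2 = %.1f (dof %d, p = %.2e)\n",
            cmp$chi2, cmp$dof, cmp$p_value))
cat("A lognormal (Cad-like) and a normal (Gad-like) channel are clearly",
    "distinguished, as in the reporter histogram comparisons.\n")
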