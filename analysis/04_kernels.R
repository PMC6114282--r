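#!/usr/bin/env Rscript
# Outward- and inward-phase utilization distributions: Gaussian kernel
# densities on an azimuthal-equidistant plane about the colony, with
# 20/40/60/80% smallest-area quantile isopleths.

suppressMessages(library(tawakitrack))

daily <- tibble::as_tibble(utils::read.csv("results/daily.csv"))
daily$date <- as.Date(daily$date)
trips <- tibble::as_tibble(utils::read.csv("results/trips.csv"))
for (cc in c("departure_date", "reversal_date", "landfall_date"))
  trips[[cc]] <- as.Date(trips[[cc]])

kernels <- list()
for (ph in c("outward", "inward")) {
  pts <- phase_points(trips, daily, ph)
  cat(sprintf("%s phase: %d daily positions from %d birds\n", ph,
              nrow(pts), length(unique(pts$bird_id))))
  if (nrow(pts) >= 10) {
    kr <- kde_isopleths(pts, kernel_config(), phase = ph)
    kernels[[ph]] <- kr
    for (iso in kr$isopleths)
      cat(sprintf("  %d%% isopleth: %.0f km2 (contains %.1f%% of mass)\n",
                  iso$quantile, iso$area_km2, 100 * iso$mass_fraction))
  }
}
write_trip_outputs(trips, daily, kernels, dir = "results")
cat("isopleth polygons written to results/isopleths.geojson\n")
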