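#!/usr/bin/env Rscript
# K-select habitat-selection eigenanalysis at the trip destinations:
# composite a synthetic environmental stack on the 57.4 km common grid,
# take each reversal bird's destination-window positions (10 days each
# side of reversal), build per-bird used/available designs, and
# eigen-decompose the weighted marginality cross-product.

suppressMessages(library(tawakitrack))

daily <- tibble::as_tibble(utils::read.csv("results/daily.csv"))
daily$date <- as.Date(daily$date)
trips <- tibble::as_tibble(utils::read.csv("results/trips.csv"))
for (cc in c("departure_date", "reversal_date", "landfall_date"))
  trips[[cc]] <- as.Date(trips[[cc]])

cfg <- habitat_config()
grid <- grid_spec(cell_km = 57.4, nx = 70, ny = 70,
                  x0 = -69 * 57.4 / 2 - 600, y0 = -69 * 57.4 / 2 - 600)
env <- simulate_env(grid, seed = 1)

rev_trips <- trips[!is.na(trips$reversal_date), ]
used <- list(); avail <- list()
for (i in seq_len(nrow(rev_trips))) {
  tr <- rev_trips[i, ]
  wp <- destination_window_points(tr, daily, cfg)
  cells <- cell_of(cbind(wp$lon, wp$lat), grid)
  cells <- cells[!is.na(cells)]
  if (length(cells) < 3) next
  av <- availability_cells(wp, grid, cfg)
  used[[tr$bird_id]] <- cells[cells %in% av]
  avail[[tr$bird_id]] <- av
}
cat(sprintf("K-select over %d birds with a reversal (window +/- %d days, "
            , length(used), cfg$window_days))
cat(sprintf("availability disc %d km)\n", cfg$availability_radius_km))

ks <- kselect(used, avail, env$stack)
frac <- ks$eigenvalues / sum(ks$eigenvalues)
cat(sprintf("Axes 1+2 carry %.0f%% of the mean marginality\n",
            100 * sum(frac[1:2])))
cat("Axis-1 loadings:\n")
print(round(ks$loadings[, 1], 3))

utils::write.csv(data.frame(axis = seq_along(ks$eigenvalues),
                            eigenvalue = ks$eigenvalues,
                            fraction = frac),
                 "results/kselect_eigenvalues.csv", row.names = FALSE)
utils::write.csv(as.data.frame(ks$loadings),
                 "results/kselect_loadings.csv", row.names = TRUE)
utils::write.csv(as.data.frame(ks$projections),
                 "results/kselect_projections.csv", row.names = TRUE)
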