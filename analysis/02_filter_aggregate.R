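#!/usr/bin/env Rscript
# Clean each bird's raw Argos fixes with the speed-distance-angle filter
# (vmax = 2.0 m/s) and collapse the retained fixes to one mean time and
# geographic-mean position per bird-day.

suppressMessages(library(tawakitrack))

fixes <- read_argos_table("results/fixes.csv")
res <- lapply(split(fixes, fixes$bird_id), function(b)
  sda_filter(b[order(b$time), ], filter_config()))

retained <- dplyr::bind_rows(lapply(res, `[[`, "retained"))
removed <- dplyr::bind_rows(lapply(res, `[[`, "removed"))
write_argos_table(retained, "results/fixes_retained.csv")
utils::write.csv(as.data.frame(removed[, c("bird_id", "time", "reason")]),
                 "results/fixes_removed.csv", row.names = FALSE)

daily <- daily_aggregate(retained)
utils::write.csv(as.data.frame(daily), "results/daily.csv",
                 row.names = FALSE)

cat(sprintf("Retained %d of %d fixes (%.1f%%); removal reasons:\n",
            nrow(retained), nrow(fixes),
            100 * nrow(retained) / nrow(fixes)))
print(table(removed$reason))
cat(sprintf("%d daily positions across %d birds\n", nrow(daily),
            length(unique(daily$bird_id))))
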