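#!/usr/bin/env Rscript
# Build the synthetic street-tree city and emit its two census snapshots,
# spatial layers, and ground truth under results/city/.
#
# The city is desk-scale (60 streets x 60 addresses, ~4,100 trees) so the
# whole analysis sequence reruns in well under a minute; the package's
# acceptance script exercises the full ~50,000-tree configuration.

library(streetgrowth)

out <- "results/city"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- city_config(seed = 2015L, n_streets = 60L, addresses_per_street = 60L)
city <- generate_city(cfg)

early <- observe_census(city, "early")
late <- observe_census(city, "late")
readr::write_csv(early, file.path(out, "census_2005.csv"), progress = FALSE)
readr::write_csv(late, file.path(out, "census_2015.csv"), progress = FALSE)

write_geojson_layer(city$segments[, c("segment_id", "name", "st_width", "vertices")],
                    file.path(out, "streets.geojson"))
write_geojson_layer(city$zips[, c("zone_id", "zip", "borough", "rings")],
                    file.path(out, "zips.geojson"))
write_geojson_layer(city$tracts[, c("zone_id", "svi", "pop_density", "rings")],
                    file.path(out, "tracts.geojson"))
write_geojson_layer(city$lots[, c("zone_id", "land_use", "builtFAR", "rings")],
                    file.path(out, "lots.geojson"))
readr::write_csv(city$trees[, c("identity", "address", "zip", "species",
                                "event", "rate_true", "svi", "x", "y")],
                 file.path(out, "ground_truth.csv"), progress = FALSE)

n_orig <- sum(city$trees$event != "replacement")
cat(sprintf("city: %d trees planted at year 0; %.0f%% survive the decade,\n",
            n_orig, 100 * mean(city$trees$event == "survived")),
    sprintf("%d replaced in place by same-species saplings.\n",
            sum(city$trees$event == "replacement")),
    sprintf("early census %d records, late census %d records -> %s\n",
            nrow(early), nrow(late), out))
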