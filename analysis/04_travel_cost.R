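#!/usr/bin/env Rscript
# H3: terrain-adjusted travel analysis on the permanent-scenario synthetic
# terrain -- travel-time surface from the site cell, 10 h isochrones, and
# the minimum-time route to the 2500 m contour with one-way and
# round-trip distances.

suppressPackageStartupMessages(library(paleopuna))
dir.create("results", showWarnings = FALSE)

scen_dir <- "results/sim_inputs/permanent"
if (!file.exists(file.path(scen_dir, "dem.asc")))
  stop("run analysis/01_simulate_inputs.R first")

dem <- read_ascii_grid(file.path(scen_dir, "dem.asc"))
scen <- jsonlite::fromJSON(file.path(scen_dir, "scenario.json"))
src <- c(scen$source_row, scen$source_col)

surface <- travel_time_surface(dem, source_cell = src)
write_ascii_grid(as_dem_raster(surface$times, dem),
                 "results/travel_times.asc")

bands <- isochrones(surface, interval = 10)
write_geojson(bands, dem, "results/isochrones.geojson")
cat("isochrone bands (10 h intervals):",
    paste(sort(unique(as.integer(bands[!is.na(bands)]))), collapse = " "),
    "\n")

route <- time_to_contour(dem, source_cell = src,
                         contour_elevation = scen$contour_elevation,
                         surface = surface)
print(route)
write_geojson(route, dem, "results/route.geojson")
write_travel_summary(route, "results/travel_summary.csv")

rule <- distance_rule_eval(route$round_trip_km)
cat("distance rule at", round(route$round_trip_km, 1), "km round trip:\n")
print(as.data.frame(rule))
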