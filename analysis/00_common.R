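# Shared setup for the numbered analysis scripts: the three particle
# geometries studied throughout (a fully porous silica-like particle, a
# functionalized FPP whose coating restricts access to ~64 %r, and an
# SPP-like hollow shell at f = 0.37), plus output locations.

library(smlmchrom)

RESULTS <- "results"
RUNS <- file.path(RESULTS, "runs")

GEOMETRIES <- list(
  silica_fpp = list(accessible_fraction = 1.00, seed = 1101L),
  coated_fpp = list(accessible_fraction = 0.64, seed = 1102L),
  spp_shell  = list(accessible_fraction = 0.37, seed = 1103L))

run_dir <- function(name) file.path(RUNS, name)

geometry_config <- function(name, stages) {
  g <- GEOMETRIES[[name]]
  list(seed = g$seed,
       stages = stages,
       particle = list(accessible_fraction = g$accessible_fraction),
       inputs = list(
         movie = file.path(run_dir(name), "movie.tif"),
         localizations = file.path(run_dir(name), "localizations.csv"),
         events = file.path(run_dir(name), "events.csv")))
}
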