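# Shared setup for the analysis scripts: one seeded synthetic study at the
# default (paper-like) conditions, cached under scratch/ so the numbered
# scripts can be run independently or in sequence. Run from the repository
# root, e.g. `Rscript analysis/01_simulate_study.R`.

suppressPackageStartupMessages(library(regevo))

STUDY_SEED <- 2026L
RESULTS <- "results"
SCRATCH <- "scratch"
dir.create(RESULTS, showWarnings = FALSE)
dir.create(SCRATCH, showWarnings = FALSE)

cache <- function(name, expr) {
  f <- file.path(SCRATCH, paste0(name, "_seed", STUDY_SEED, ".rds"))
  if (file.exists(f)) return(readRDS(f))
  x <- expr
  saveRDS(x, f)
  x
}

get_world <- function() cache("world", simulate_world(sim_config(seed = STUDY_SEED)))
get_cons <- function() cache("cons", consensus_all(get_world()))
get_profile <- function(ref) {
  cache(paste0("profile_", ref), world_profile(get_world(), get_cons(), ref))
}

write_result <- function(x, name) {
  f <- file.path(RESULTS, name)
  data.table::fwrite(data.table::as.data.table(x), f, sep = "\t")
  message("  wrote ", f)
}
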