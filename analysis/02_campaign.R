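#!/usr/bin/env Rscript

# Step 2 — run the circularization campaign.
#
# Every run starts from an open linear chain and integrates Langevin
# dynamics until the adhesive termini bond (circularization) or the step
# cap is reached (censoring).  Each outcome is classified on the fly and
# appended to a per-batch CSV ledger, so interrupting and re-running this
# script resumes where it stopped.
#
# Defaults are desk-scale: the 100-bead flexible (L) chain over its
# 4-placement grid plus the reference chain, RUNS runs each.  The full
# study configuration (N = 500, 20 placements, 104000 runs per placement
# for the L chain and 24000 for the S chain) is expressible with the
# same code -- set N_BEADS/SPACING/RUNS/REGIME accordingly and distribute
# seed blocks over a cluster.

suppressPackageStartupMessages(library(stickyknots))

cfg <- function(name, default)
  as.numeric(Sys.getenv(name, unset = default))
n_beads <- cfg("N_BEADS", 100)
spacing <- cfg("SPACING", 20)
n_runs <- cfg("RUNS", 150)
regime <- Sys.getenv("REGIME", unset = "L")
kappa_bend <- if (regime == "S") 10 else 0

dir.create("results", showWarnings = FALSE)
dir.create("results/ledgers", showWarnings = FALSE)

params <- model_params(n_beads = n_beads, kappa_bend = kappa_bend)
protocol <- run_protocol(seed = 1, max_steps = 1.5e7)
grid <- enumerate_grid(n_beads, spacing)

tag <- sprintf("%s_N%d", regime, n_beads)
message(sprintf("campaign %s: %d placements + reference, %d runs each",
                tag, nrow(grid), n_runs))

ref_path <- sprintf("results/ledgers/%s_ref.csv", tag)
run_batch(NULL, params, protocol, n_runs = n_runs, seed_base = 100000,
          ledger_path = ref_path)
message(sprintf("reference ledger: %s", ref_path))

for (i in seq_len(nrow(grid))) {
  pl <- grid[i, ]
  path <- sprintf("results/ledgers/%s_lx%d_ly%d.csv", tag, pl$l_x, pl$l_y)
  run_batch(pl, params, protocol, n_runs = n_runs,
            seed_base = 200000 + 10000 * i, ledger_path = path)
  message(sprintf("placement {%d, %d} ledger: %s", pl$l_x, pl$l_y, path))
}
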