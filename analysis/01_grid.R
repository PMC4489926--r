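#!/usr/bin/env Rscript

# Step 1 — enumerate the sticky-site placements.
#
# The study chain has 500 beads and internal adhesive beads restricted to
# a 50-bead grid; after removing coincident sites and chain-reversal
# duplicates, 20 non-redundant placements remain.  A 100-bead, 20-spaced
# grid (4 placements) is the desk-scale analogue used by the demo
# campaign in step 2.

suppressPackageStartupMessages(library(stickyknots))
dir.create("results", showWarnings = FALSE)

g_full <- enumerate_grid(500, 50)
g_demo <- enumerate_grid(100, 20)

write.csv(g_full, "results/grid_full.csv", row.names = FALSE)
write.csv(g_demo, "results/grid_demo.csv", row.names = FALSE)

cat(sprintf("full study grid: %d placements (l_x from %d to %d)\n",
            nrow(g_full), min(g_full$l_x), max(g_full$l_x)))
cat(sprintf("  includes the {50, 300} placement: %s\n",
            any(g_full$l_x == 50 & g_full$l_y == 300)))
cat(sprintf("demo grid (N = 100, spacing 20): %d placements\n",
            nrow(g_demo)))
print(g_demo)
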