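#!/usr/bin/env Rscript
# Build the synthetic study systems: a closed (two-gate) and an open channel
# with the hydrophobic-belt wall pattern, the alkane calibration compounds,
# and a gating trajectory with a known opening event.  Everything downstream
# (02-05) reads these from results/fixtures/.

suppressMessages(library(porescape))
fixdir <- "results/fixtures"
dir.create(fixdir, showWarnings = FALSE, recursive = TRUE)

# hydrophobic belt spanning both gate elevations (|z| <= 10), hydrophilic
# vestibules beyond -- so opening the gates uncovers hydrophobic surface
belt <- function(z) if (abs(z) <= 10) "phobic" else "philic"

# open state: continuous pore
open_spec <- channel_spec(radius_profile = function(z) rep(5, length(z)),
                          ring_pattern = belt)
open_ch <- make_channel(open_spec)
write_structure(open_ch, file.path(fixdir, "channel_open.pdb"))

# closed state: same walls with plug disks at the two gate elevations
closed_spec <- channel_spec(radius_profile = function(z) rep(5, length(z)),
                            ring_pattern = belt, plugs = c(-8, 8))
closed_ch <- make_channel(closed_spec)
write_structure(closed_ch, file.path(fixdir, "channel_closed.pdb"))

# gating trajectory: single-gate channel whose plug clears at frame 6
gate_spec <- channel_spec(radius_profile = function(z) rep(4, length(z)),
                          z_range = c(-10, 10), plugs = 0,
                          ring_pattern = function(z) "phobic")
gating <- make_gating_trajectory(gate_spec, onset_frame = 6, n_frames = 10,
                                 seed = 7)
write_trajectory(gating, file.path(fixdir, "gating_traj.pdb"))
writeLines(c(sprintf("onset_frame\t%d", gating$truth$onset_frame),
             sprintf("plug_z\t%g", gating$truth$plug_z),
             sprintf("active_chain\t%s", gating$truth$active_chain)),
           file.path(fixdir, "gating_truth.tsv"))

# alkane model compounds for the methylene calibration
for (n in 4:7)
  write_structure(make_alkane(n), file.path(fixdir, sprintf("alkane_C%d.pdb", n)))

cat("Fixtures written to", fixdir, "\n")
cat(sprintf("  open channel:   %d atoms\n", n_atoms(open_ch)))
cat(sprintf("  closed channel: %d atoms (plugs at -8/+8 A)\n", n_atoms(closed_ch)))
cat(sprintf("  gating traj:    %d frames, opening at frame %d\n",
            n_frames(gating), gating$truth$onset_frame))
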