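#!/usr/bin/env Rscript
# Residue solvation energetics (ASP x ASA): which residues change their
# solvation energy most when the gate opens.  The closed and open states are
# the pre- and post-onset frames of the gating trajectory, so both share one
# topology and the comparison is atom-for-atom.

suppressMessages(library(porescape))
fixdir <- "results/fixtures"
outdir <- "results/solvation"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

traj <- read_trajectory(file.path(fixdir, "gating_traj.pdb"))
truth <- utils::read.delim(file.path(fixdir, "gating_truth.tsv"),
                           header = FALSE, row.names = 1)
onset <- as.integer(truth["onset_frame", 1])

sub_traj <- function(frames)
  trajectory3d(traj$topology,
               traj$coords[, , frames, drop = FALSE],
               times = traj$times[frames])
closed <- sub_traj(seq_len(onset - 1L))
open <- sub_traj(onset:n_frames(traj))

rk <- rank_solvation_change(closed, open, top_k = 10)
cat("residues with the largest closed -> open solvation-energy change\n")
cat("(PLG = the moving gate residue, HPB = wall rings):\n")
print(rk$ranking, digits = 3)
cat(sprintf("net delta E_solv over the top 10: %.2f kcal/mol\n",
            sum(rk$ranking$delta)))
utils::write.table(rk$ranking, file.path(outdir, "solvation_ranking.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
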