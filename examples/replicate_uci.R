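#!/usr/bin/env Rscript
# Replication on the public basic-hand-movement repository (requires a
# manual download; not part of the test suite).
#
# 1. Download "sEMG for Basic Hand movements" from the UCI Machine Learning
#    Repository and unzip so that
#      <root>/Database1/  holds the five per-subject MAT-files (DB1)
#      <root>/Database2/  holds the three per-day MAT-files (DB2)
# 2. Rscript examples/replicate_uci.R <root> [outdir]
#
# Expected behaviour: 10-fold cross-validated accuracies approaching
# 98.89% (DB1), 94.94% (DB2) and 95.30% (DB3). Exact equality is not
# expected: fold assignment, the standard-deviation convention of the
# ternary threshold and the SVM kernel-scale heuristic are implementation
# choices. This run is compute-heavy (2700 trials x 154 sources).

suppressPackageStartupMessages(library(frustum154))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L) stop("usage: replicate_uci.R <dataset root> [outdir]")
root <- args[1L]
outdir <- if (length(args) >= 2L) args[2L] else "uci_results"

db1 <- load_basic_hand_movements(file.path(root, "Database1"), "DB1")
db2 <- load_basic_hand_movements(file.path(root, "Database2"), "DB2")
db3 <- build_db3(db1, db2)
stopifnot(length(db1) == 900, length(db2) == 1800, length(db3) == 2700)

for (ds in list(db1, db2, db3)) {
  message("=== ", ds$name, " (", length(ds), " trials) ===")
  fit <- frustum154(ds, folds = 10, seed = 0, verbose = TRUE)
  print(fit)
  print(fit$report)
  message("INCA selected size: ", fit$inca$selected_size)
  write_frustum154_artifacts(fit, file.path(outdir, ds$name))
}
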