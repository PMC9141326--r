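#!/usr/bin/env Rscript
# Convenience launcher, equivalent to inst/cli/metatempo.R in the installed
# package. Example:
#   Rscript scripts/metatempo energetics --n1 8 --n2 8 --tau2 4 --m 4 \
#     --cycles 10000 --seed 1 --out runs/e1
suppressPackageStartupMessages(library(metatempo))
status <- metatempo_main(commandArgs(trailingOnly = TRUE))
quit(save = "no", status = if (is.null(status)) 0L else status)
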