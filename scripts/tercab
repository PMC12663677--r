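#!/usr/bin/env Rscript
# Thin command-line wrapper:
#   Rscript scripts/tercab <stage> [--outdir DIR] [--seed N] [--shape R,C]
# where <stage> is one of simulate|storage|nep|balance|trend|corr|
# attribute|geodetect|transfer|report (report = all stages).
suppressPackageStartupMessages(library(tercab))
invisible(tercab_cli())
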