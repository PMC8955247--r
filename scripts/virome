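#!/usr/bin/env Rscript
# Thin shell wrapper around the package CLI.
status <- medflyvirome::virome_cli(commandArgs(trailingOnly = TRUE))
quit(save = "no", status = status)
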