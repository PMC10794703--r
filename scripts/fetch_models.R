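#!/usr/bin/env Rscript
# Optional helper: download the four deposited ATTRv-I84S fibril models
# (closed gate 8TDN, open gate 8TDO, absent gate 8E7E, broken gate 8E7J)
# from the PDB into models/. Requires network access; nothing in the
# package or its tests depends on these files. After downloading, check the
# chain mapping templates in inst/extdata/chainmaps/ against each entry
# before running, e.g.:
#   m <- read_structure("models/8tdn.cif",
#                       mapping = system.file("extdata/chainmaps/8tdn.chainmap",
#                                             package = "fibrilstab"))
#   stabilization_energy(m)
accessions <- c("8tdn", "8tdo", "8e7e", "8e7j")
dir.create("models", showWarnings = FALSE)
for (acc in accessions) {
  dest <- file.path("models", paste0(acc, ".cif"))
  if (file.exists(dest)) next
  url <- sprintf("https://files.rcsb.org/download/%s.cif", toupper(acc))
  message("fetching ", url)
  utils::download.file(url, dest, quiet = TRUE)
}
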