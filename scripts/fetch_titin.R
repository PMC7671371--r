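#!/usr/bin/env Rscript
## Downloads the human Titin benchmark sequence (UniProtKB A0A0A0MTS7,
## 35 991 aa) used by the reference-digestion acceptance test and, when
## present, by scripts/acceptance.R. Network access required; run from the
## repository root:
##   Rscript scripts/fetch_titin.R
## After fetching, reinstall the package so system.file() can find the file.

url <- "https://rest.uniprot.org/uniprotkb/A0A0A0MTS7.fasta"
dest_dir <- file.path("inst", "extdata")
dest <- file.path(dest_dir, "titin_A0A0A0MTS7.fasta")

dir.create(dest_dir, recursive = TRUE, showWarnings = FALSE)
message("fetching ", url)
status <- utils::download.file(url, dest, quiet = TRUE, mode = "wb")
if (status != 0L || !file.exists(dest)) {
  stop("download failed (status ", status, ")")
}
lines <- readLines(dest, warn = FALSE)
n_aa <- sum(nchar(lines[!startsWith(lines, ">")]))
message("wrote ", dest, " (", n_aa, " residues)")
if (n_aa != 35991L) {
  warning("expected 35991 residues, got ", n_aa,
          "; the UniProt entry may have changed")
}
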