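# Packaged reference tables: the printed per-tap group averages and
# per-subject blink widths of the source study's summary tables, transcribed
# verbatim (NaN cells mean "no blinking in that category"). Checksums guard
# against silent corruption of the transcription.

.fixture_md5 <- c(
  table1_tapwise.csv = "9b2edba792df9040f1457aaf11401b75",
  table2_patient_widths.csv = "d04d2b64a49bc7ec4452c91c3e121063",
  table3_hc_widths.csv = "ac202eca5eb71d38d6e1056d0d232963")

#' Load the packaged reference tables
#'
#' Returns the three cohort summary tables shipped with the package:
#' `table1` (per-tap average reflex and non-reflex blink counts for iPD
#' patients before/after medication and healthy controls, long format
#' `tap, group, category, value`), `table2` (per-patient average blink
#' widths in seconds, before/after medication) and `table3` (per-healthy-
#' control average blink widths). `NaN` cells are preserved. Each file is
#' checksummed against the transcription.
#'
#' @return Named list of three `data.frame`s.
#' @export
load_paper_fixtures <- function() {
  dir <- system.file("extdata", package = "gtrflex")
  out <- list()
  for (f in names(.fixture_md5)) {
    path <- file.path(dir, f)
    if (!file.exists(path))
      gtr_stop(sprintf("packaged fixture '%s' is missing", f), "gtr_packaging_error")
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, unname(.fixture_md5[[f]])))
      gtr_stop(sprintf("fixture '%s' fails its checksum (%s)", f, md5),
               "gtr_packaging_error")
    out[[sub("_.*", "", f)]] <- utils::read.csv(path)
  }
  names(out) <- c("table1", "table2", "table3")
  out
}
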