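# cohort serialization: one CSV per assessment, per-participant trace
# CSVs, and a JSON manifest

#' Write a cohort to disk as plain-text files
#'
#' Writes one CSV per tabular assessment (`participant_id, group, age,
#' sex`, then the feature columns), one trace CSV per natural-viewing
#' completer (`snippet_id, t_ms`, then the 10 channel columns), and a
#' `manifest.json` describing the cohort.
#'
#' @param cohort a [FASDCohort].
#' @param dir output directory (created if needed).
#' @param traces also write the (large) trace CSVs (default `TRUE`).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir, traces = TRUE) {
  stopifnot(is(cohort, "FASDCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  part <- participants(cohort)
  for (a in names(cohort@assessments)) {
    ft <- cohort@assessments[[a]]
    ids <- rownames(SummarizedExperiment::colData(ft))
    df <- data.frame(participant_id = ids,
                     group = as.character(groups(ft)),
                     age = ages(ft),
                     sex = as.character(part[ids, "sex"]),
                     featureMatrix(ft), check.names = FALSE)
    write.csv(df, file.path(dir, paste0(a, ".csv")), row.names = FALSE)
  }
  if (traces && length(cohort@traces)) {
    tdir <- file.path(dir, "traces")
    dir.create(tdir, showWarnings = FALSE)
    rate <- cohort@spec@traceSpec$rateHz
    for (id in names(cohort@traces)) {
      snips <- cohort@traces[[id]]
      df <- do.call(rbind, lapply(seq_along(snips), function(s) {
        m <- snips[[s]]
        data.frame(snippet_id = s,
                   t_ms = (seq_len(nrow(m)) - 1) * 1000 / rate,
                   m, check.names = FALSE)
      }))
      write.csv(df, file.path(tdir, paste0(id, ".csv")),
                row.names = FALSE)
    }
  }
  spec <- cohort@spec
  manifest <- list(
    nFASD = spec@nFASD, nControl = spec@nControl, seed = spec@seed,
    assessments = names(cohort@assessments),
    completion = apply(completionMask(cohort), 2, sum),
    completeAll = length(completeAllIds(cohort)),
    traceParticipants = names(cohort@traces),
    snippetDurations = cohort@snippetDurations,
    channels = .TRACE_CHANNELS)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
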