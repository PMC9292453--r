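#' Packaged reference datasets
#'
#' Three small reference tables from the published BCR/ABL1 ddPCR validation
#' study ship with the package as plain CSV under `inst/extdata`:
#'
#' * `diagnostic_comparison.csv` — paired Q-RT-PCR and ddPCR MRD ratios
#'   (percent scale) for 10 diagnostic samples; one sample (DX4) carries both
#'   the p190 and the p210 transcript and contributes one row per transcript.
#' * `followup_crosstab.csv` — the 3x3 POS/PNQ/NEG cross-classification of
#'   88 follow-up samples by the two methods, long format.
#' * `lod_replicates.csv` — the replicate-escalation positivity outcomes of
#'   the limit-of-detection experiment, with both copies-per-well labelings
#'   (see [lod_default_design()]).
#'
#' @param name Fixture file name.
#' @return Path to the installed fixture.
#' @export
ddmrd_fixture <- function(name = c("diagnostic_comparison.csv",
                                   "followup_crosstab.csv",
                                   "lod_replicates.csv")) {
  name <- match.arg(name)
  path <- system.file("extdata", name, package = "ddmrd", mustWork = TRUE)
  path
}

#' Reference diagnostic-sample comparison table
#'
#' @param pairing `"per_transcript"` (default): a dual-transcript sample
#'   contributes one pair per transcript (11 pairs). `"aggregate"`: its two
#'   transcripts are summed into a single pair (10 pairs).
#' @return Data frame with `sample_id`, `transcript`, `qrtpcr_ratio`,
#'   `ddpcr_ratio`.
#' @export
reference_diagnostic_table <- function(pairing = c("per_transcript", "aggregate")) {
  pairing <- match.arg(pairing)
  df <- utils::read.csv(ddmrd_fixture("diagnostic_comparison.csv"),
                        stringsAsFactors = FALSE)
  if (pairing == "aggregate") {
    agg <- stats::aggregate(df[c("qrtpcr_ratio", "ddpcr_ratio")],
                            by = df["sample_id"], FUN = sum)
    agg <- agg[match(unique(df$sample_id), agg$sample_id), ]
    agg$transcript <- vapply(agg$sample_id, function(s) {
      paste(df$transcript[df$sample_id == s], collapse = "/")
    }, "")
    rownames(agg) <- NULL
    df <- agg[c("sample_id", "transcript", "qrtpcr_ratio", "ddpcr_ratio")]
  }
  df
}

#' Reference follow-up cross-tabulation
#'
#' @return A `"crosstab_result"` (see [crosstab_result()]): 3x3 counts, rows
#'   ddPCR POS/PNQ/NEG, columns Q-RT-PCR POS/PNQ/NEG, n = 88.
#' @export
reference_crosstab <- function() {
  df <- utils::read.csv(ddmrd_fixture("followup_crosstab.csv"),
                        stringsAsFactors = FALSE)
  m <- matrix(0L, 3, 3, dimnames = list(ddPCR = c("POS", "PNQ", "NEG"),
                                        QRTPCR = c("POS", "PNQ", "NEG")))
  for (i in seq_len(nrow(df))) {
    m[df$ddpcr_class[i], df$qrtpcr_class[i]] <- as.integer(df$count[i])
  }
  crosstab_result(m)
}

#' Reference limit-of-detection positivity table
#'
#' @return A `"positivity_table"` data frame ordered from the least to the
#'   most dilute point, with both copies-per-well labelings attached.
#' @export
reference_lod_table <- function() {
  df <- utils::read.csv(ddmrd_fixture("lod_replicates.csv"),
                        stringsAsFactors = FALSE)
  positivity_table(df$label, df$n_replicates, df$n_positive,
                   extra = df[c("copies_proportional", "copies_stated")])
}

#' Write the reference fixture files to a directory
#'
#' Copies the packaged reference CSVs (see [ddmrd_fixture()]) into
#' `output_dir`, e.g. to seed an external analysis.
#'
#' @param output_dir Writable directory; created if absent.
#' @return Character vector of the written paths, invisibly.
#' @export
write_reference_fixtures <- function(output_dir) {
  if (!dir.exists(output_dir)) {
    ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", output_dir, call. = FALSE)
  }
  files <- c("diagnostic_comparison.csv", "followup_crosstab.csv",
             "lod_replicates.csv")
  out <- file.path(output_dir, files)
  for (i in seq_along(files)) {
    if (!file.copy(ddmrd_fixture(files[i]), out[i], overwrite = TRUE)) {
      stop("cannot write ", out[i], call. = FALSE)
    }
  }
  invisible(out)
}
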