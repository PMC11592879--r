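#' Bipolar 10-20 montage used throughout the package
#'
#' The 18 longitudinal bipolar channels, in canonical order: the left and
#' right temporal chains, the left and right parasagittal chains, and the
#' two midline channels.
#'
#' @return Character vector of 18 channel names.
#' @export
#' @examples
#' tle_montage()
tle_montage <- function() {
  c("Fp1-F7", "F7-T3", "T3-T5", "T5-O1",
    "Fp2-F8", "F8-T4", "T4-T6", "T6-O2",
    "Fp1-F3", "F3-C3", "C3-P3", "P3-O1",
    "Fp2-F4", "F4-C4", "C4-P4", "P4-O2",
    "FZ-CZ", "CZ-PZ")
}

#' Table of symmetric left/right channel pairs
#'
#' The eight homologous bipolar pairs over which the energy asymmetry
#' score is computed. Rows 1-4 are the temporal chains, rows 5-8 the
#' parasagittal chains; the midline channels (FZ-CZ, CZ-PZ) have no
#' homolog and take no part in lateralization.
#'
#' @return A data.frame with columns `left` and `right` (8 rows).
#' @export
#' @examples
#' symmetric_pair_table()
symmetric_pair_table <- function() {
  data.frame(
    left  = c("Fp1-F7", "F7-T3", "T3-T5", "T5-O1",
              "Fp1-F3", "F3-C3", "C3-P3", "P3-O1"),
    right = c("Fp2-F8", "F8-T4", "T4-T6", "T6-O2",
              "Fp2-F4", "F4-C4", "C4-P4", "P4-O2"),
    stringsAsFactors = FALSE
  )
}

# case-insensitive channel lookup against a recording's channel names;
# errors with the full list of absentees so a truncated file is diagnosable
match_channels <- function(wanted, available) {
  idx <- match(tolower(wanted), tolower(available))
  if (anyNA(idx)) {
    stop("missing channel(s): ", paste(wanted[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  idx
}
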