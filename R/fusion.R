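#' Fuse the three per-analysis labels into a final side
#'
#' The decision rule: the signed encodings of the three analysis labels
#' (LEFT = +1, RIGHT = -1, missing/MRI-negative = 0) are summed; a
#' positive total decides LEFT, otherwise — including a zero tie — RIGHT.
#'
#' @param L1,L2,L3 Sides (`"LEFT"`/`"RIGHT"`/`"NONE"`) or their signed
#'   encodings.
#' @return `"LEFT"` or `"RIGHT"` (vectorized over inputs of equal length).
#' @export
#' @examples
#' fuse("RIGHT", "NONE", "LEFT")  # sum 0 -> RIGHT
fuse <- function(L1, L2, L3) {
  enc <- function(v) if (is.character(v)) encode_side(v) else {
    stopifnot(all(v %in% c(-1, 0, 1))); as.integer(v)
  }
  total <- enc(L1) + enc(L2) + enc(L3)
  ifelse(total > 0, "LEFT", "RIGHT")
}

# map printed cell strings to package sides
parse_analysis_cell <- function(x) {
  x <- trimws(x)
  out <- rep("NONE", length(x))
  out[grepl("^left", x, ignore.case = TRUE)] <- "LEFT"
  out[grepl("^right", x, ignore.case = TRUE)] <- "RIGHT"
  known <- grepl("^left|^right|^nan$|^mri.?negative", x, ignore.case = TRUE)
  if (!all(known)) stop("unrecognized analysis label: ",
                        paste(unique(x[!known]), collapse = ", "))
  out
}

parse_mri_finding <- function(x) {
  x <- trimws(x)
  out <- rep(NA_character_, length(x))
  out[grepl("bilateral", x, ignore.case = TRUE)] <- "BILATERAL"
  out[grepl("^mri.?negative", x, ignore.case = TRUE)] <- "NEGATIVE"
  left <- grepl("^left", x, ignore.case = TRUE)
  right <- grepl("^right", x, ignore.case = TRUE)
  out[left & is.na(out)] <- "LEFT"
  out[right & is.na(out)] <- "RIGHT"
  if (anyNA(out)) stop("unrecognized MRI finding: ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' Read a per-patient label table
#'
#' Reads a CSV in the packaged fixture's layout (patient number, expert
#' EEG and MRI findings, the three analysis decisions, and the final
#' fused decision) and normalizes the printed strings to package sides.
#'
#' @param path CSV path; default the packaged 15-patient fixture.
#' @return A data.frame with columns `patient`, `expert_eeg`
#'   (LEFT/RIGHT), `expert_mri` (LEFT/RIGHT/BILATERAL/NEGATIVE), `L1`,
#'   `L2`, `L3` (LEFT/RIGHT/NONE), `final` (LEFT/RIGHT).
#' @export
#' @examples
#' head(read_label_table())
read_label_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table7.csv", package = "tlefocus",
                        mustWork = TRUE)
  }
  raw <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 7) stop("label table needs 7 columns, got ", ncol(raw),
                          " in ", path)
  parse_side <- function(v, allow_none = FALSE) {
    s <- parse_analysis_cell(v)
    if (!allow_none && any(s == "NONE"))
      stop("expert EEG finding must be lateralized in ", path)
    s
  }
  out <- data.frame(
    patient = as.integer(raw[[1]]),
    expert_eeg = parse_side(raw[[2]]),
    expert_mri = parse_mri_finding(raw[[3]]),
    L1 = parse_analysis_cell(raw[[4]]),
    L2 = parse_analysis_cell(raw[[5]]),
    L3 = parse_analysis_cell(raw[[6]]),
    final = parse_side(raw[[7]]),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$patient)) stop("non-numeric patient id in ", path)
  out
}

#' Apply the fusion rule to every row of a label table
#'
#' @param records Data.frame from [read_label_table()].
#' @return The table with a `fused` column, the package's recomputed
#'   final decision.
#' @export
fuse_table <- function(records) {
  stopifnot(all(c("L1", "L2", "L3") %in% names(records)))
  records$fused <- fuse(records$L1, records$L2, records$L3)
  records
}

# round half up to one decimal (printed percentages use half-up rounding)
round1_half_up <- function(x) floor(x * 10 + 0.5) / 10

#' Overlap ratio between two label columns
#'
#' Eligible records are those where both labels carry a finding: LEFT,
#' RIGHT, or BILATERAL. Missing and negative labels (`NONE`/`NEGATIVE`)
#' remove a record from the denominator, while a BILATERAL finding stays
#' in the denominator but can never match a side. A match requires both
#' labels lateralized (LEFT/RIGHT) and equal. The ratio is
#' matched/eligible as a percentage rounded half-up to one decimal.
#'
#' @param labels_a,labels_b Aligned character vectors of sides.
#' @return List with `matched`, `eligible`, `ratio` (percent). Zero
#'   eligible records is an error (the ratio is undefined).
#' @export
#' @examples
#' overlap_ratio(c("LEFT", "RIGHT", "NONE"), c("LEFT", "LEFT", "RIGHT"))
overlap_ratio <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("label lists must be aligned")
  present <- function(v) v %in% c("LEFT", "RIGHT", "BILATERAL")
  lat <- function(v) v %in% c("LEFT", "RIGHT")
  eligible <- present(labels_a) & present(labels_b)
  if (!any(eligible)) stop("no eligible records; overlap ratio undefined")
  matched <- sum(eligible & lat(labels_a) & lat(labels_b) &
                   labels_a == labels_b)
  list(matched = matched, eligible = sum(eligible),
       ratio = round1_half_up(100 * matched / sum(eligible)))
}

#' Reproduce the overlap report from a label table
#'
#' Computes every pairwise overlap the evaluation reports: expert MRI vs
#' expert EEG (among expert-MRI-positive patients), each analysis vs
#' expert EEG, the fused decision vs expert EEG, Analysis-1 vs expert MRI
#' (expert-MRI-positive patients with an Analysis-1 decision), Analysis-2
#' vs Analysis-3 (Analysis-2-positive patients), plus the two detection
#' rates: the fraction of patients in whom Analysis-2 and the expert,
#' respectively, found an MRI abnormality.
#'
#' @param records Data.frame from [read_label_table()]; the fused
#'   decision is recomputed via [fuse_table()].
#' @return An `overlap_report` data.frame with columns `comparison`,
#'   `matched`, `eligible`, `ratio`.
#' @export
#' @examples
#' reproduce_overlap_table(read_label_table())
reproduce_overlap_table <- function(records) {
  r <- fuse_table(records)
  n <- nrow(r)
  row <- function(name, a, b) {
    ov <- overlap_ratio(a, b)
    data.frame(comparison = name, matched = ov$matched,
               eligible = ov$eligible, ratio = ov$ratio,
               stringsAsFactors = FALSE)
  }
  rate_row <- function(name, k) {
    data.frame(comparison = name, matched = k, eligible = n,
               ratio = round1_half_up(100 * k / n), stringsAsFactors = FALSE)
  }
  out <- rbind(
    row("expert_mri_vs_expert_eeg", r$expert_mri, r$expert_eeg),
    row("analysis1_vs_expert_eeg", r$L1, r$expert_eeg),
    row("analysis2_vs_expert_eeg", r$L2, r$expert_eeg),
    row("analysis3_vs_expert_eeg", r$L3, r$expert_eeg),
    row("decision_tree_vs_expert_eeg", r$fused, r$expert_eeg),
    row("analysis1_vs_expert_mri", r$L1, r$expert_mri),
    row("analysis2_vs_expert_mri", r$L2, r$expert_mri),
    row("analysis2_vs_analysis3", r$L2, r$L3),
    rate_row("analysis2_detection_rate", sum(r$L2 != "NONE")),
    rate_row("expert_mri_detection_rate", sum(r$expert_mri != "NEGATIVE"))
  )
  class(out) <- c("overlap_report", "data.frame")
  out
}

#' @export
print.overlap_report <- function(x, ...) {
  df <- as.data.frame(x)
  df$ratio <- sprintf("%.1f%% (%d/%d)", df$ratio, df$matched, df$eligible)
  print(df[, c("comparison", "ratio")], row.names = FALSE)
  invisible(x)
}
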