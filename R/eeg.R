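#' Signal energy of an EEG segment
#'
#' Energy is the sum of squared samples, the numerator/denominator terms
#' of the asymmetry score.
#'
#' @param x Numeric vector, a channel segment.
#' @return Non-negative scalar in signal-units squared.
#' @export
#' @examples
#' channel_energy(c(1, -1, 2))  # 6
channel_energy <- function(x) {
  if (length(x) == 0) stop("empty segment has no energy")
  sum(x^2)
}

#' Energy asymmetry score of a symmetric channel pair
#'
#' `A = sum(xleft^2) / sum(xright^2)` over aligned ictal segments.
#' A score above 1 indicates higher left-channel energy. Swapping the
#' arguments inverts the score: `A(x, y) * A(y, x) == 1`.
#'
#' @param xleft,xright Aligned numeric segments of equal length.
#' @return Positive scalar, or `NA_real_` (with a warning) when the
#'   right-channel energy is zero — a degenerate flat pair carrying no
#'   lateralization information; callers exclude such pairs from the vote.
#' @export
#' @examples
#' asymmetry_score(c(1, 1), c(1, 2))  # 0.4
asymmetry_score <- function(xleft, xright) {
  if (length(xleft) != length(xright)) stop("segments must be aligned (equal length)")
  er <- channel_energy(xright)
  if (er == 0) {
    warning("zero right-channel energy; asymmetry score undefined")
    return(NA_real_)
  }
  channel_energy(xleft) / er
}

#' Label a channel pair from its asymmetry score
#'
#' +1 when the score exceeds 1 (left energy dominant), otherwise -1;
#' a score of exactly 1 takes the "otherwise" branch and labels -1.
#'
#' @param A Asymmetry score (vectorized).
#' @return Integer vector in \{+1, -1\} (`NA` propagates).
#' @export
pair_label <- function(A) {
  ifelse(is.na(A), NA_integer_, ifelse(A > 1, 1L, -1L))
}

#' Lateralize one seizure recording from its eight pair labels
#'
#' The pair labels are summed; a positive total votes LEFT, otherwise
#' (including a zero tie) RIGHT. Degenerate pairs (`NA`) are excluded
#' from the sum.
#'
#' @param labels Integer vector of pair labels in \{+1, -1\} (`NA` allowed).
#' @return `"LEFT"` or `"RIGHT"`.
#' @export
recording_lateralization <- function(labels) {
  usable <- labels[!is.na(labels)]
  if (length(usable) == 0) stop("no usable channel pairs; recording undetermined")
  if (!all(usable %in% c(-1L, 1L))) stop("pair labels must be +1 or -1")
  if (sum(usable) > 0) "LEFT" else "RIGHT"
}

#' Lateralize a patient from per-recording sides
#'
#' Majority vote over seizure recordings: LEFT when strictly more
#' recordings voted LEFT than RIGHT, otherwise (ties included) RIGHT.
#'
#' @param recording_sides Character vector of `"LEFT"`/`"RIGHT"`.
#' @return `"LEFT"` or `"RIGHT"`.
#' @export
patient_lateralization <- function(recording_sides) {
  if (length(recording_sides) == 0) stop("at least one recording is required")
  stopifnot(all(recording_sides %in% c("LEFT", "RIGHT")))
  if (sum(recording_sides == "LEFT") > sum(recording_sides == "RIGHT"))
    "LEFT" else "RIGHT"
}

# sample index range(s) of the ictal interval(s), clipped to the record
ictal_sample_idx <- function(rec) {
  n <- ncol(rec$signals)
  idx <- unlist(lapply(rec$ictal_intervals, function(iv) {
    i0 <- max(1L, floor(iv[1] * rec$fs) + 1L)
    i1 <- min(n, ceiling(iv[2] * rec$fs))
    if (i1 < i0) integer(0) else i0:i1
  }))
  sort(unique(idx))
}

#' Full symmetry analysis of one seizure recording
#'
#' Computes the asymmetry score for each of the eight symmetric pairs
#' over the annotated ictal interval(s) (energies summed across intervals
#' before the ratio), labels each pair, and votes a recording side.
#' Optionally the ictal samples are cut into fixed-length sub-epochs that
#' each cast a recording-level vote, resolved by the same majority rule.
#'
#' @param rec An `eeg_recording` (see [gen_ictal_eeg()], [load_eeg()]).
#' @param epoch_len Optional sub-epoch length in seconds; `NULL` (default)
#'   scores the full ictal interval as one epoch.
#' @return An `asymmetry_result`: list with `pairs` (data.frame: left,
#'   right, A, label), `recording_side`, `n_degenerate`.
#' @export
#' @examples
#' rec <- gen_ictal_eeg(synth_eeg_config(duration = 6, ictal_interval = c(2, 5)))
#' analyze_recording(rec)$recording_side
analyze_recording <- function(rec, epoch_len = NULL) {
  stopifnot(!is.null(rec$signals), !is.null(rec$fs))
  pt <- symmetric_pair_table()
  li <- match_channels(pt$left, rec$channel_names)
  ri <- match_channels(pt$right, rec$channel_names)
  idx <- ictal_sample_idx(rec)
  if (length(idx) == 0) stop("no ictal samples within the record")

  score_over <- function(cols) {
    A <- vapply(seq_len(nrow(pt)), function(p) {
      suppressWarnings(asymmetry_score(rec$signals[li[p], cols],
                                       rec$signals[ri[p], cols]))
    }, numeric(1))
    A
  }

  if (is.null(epoch_len)) {
    A <- score_over(idx)
    lab <- pair_label(A)
    side <- recording_lateralization(lab)
  } else {
    stopifnot(epoch_len > 0)
    step <- max(1L, round(epoch_len * rec$fs))
    chunks <- split(idx, (seq_along(idx) - 1) %/% step)
    votes <- vapply(chunks, function(cols) {
      recording_lateralization(pair_label(score_over(cols)))
    }, character(1))
    side <- patient_lateralization(votes)
    # report full-interval scores alongside the epoch-vote decision
    A <- score_over(idx)
    lab <- pair_label(A)
  }

  structure(list(pairs = data.frame(left = pt$left, right = pt$right,
                                    A = A, label = lab,
                                    stringsAsFactors = FALSE),
                 recording_side = side,
                 n_degenerate = sum(is.na(A))),
            class = "asymmetry_result")
}

#' @export
print.asymmetry_result <- function(x, ...) {
  cat("<asymmetry_result> recording side:", x$recording_side, "\n")
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' EEG lateralization of a patient across seizure recordings (Analysis-3)
#'
#' @param recordings List of `eeg_recording` objects (all seizures of one
#'   patient).
#' @param epoch_len Passed to [analyze_recording()].
#' @return List with `patient_side`, `recording_sides`, and the per-
#'   recording `asymmetry_result`s.
#' @export
eeg_lateralize <- function(recordings, epoch_len = NULL) {
  if (length(recordings) == 0) stop("at least one recording is required")
  res <- lapply(recordings, analyze_recording, epoch_len = epoch_len)
  sides <- vapply(res, `[[`, character(1), "recording_side")
  list(patient_side = patient_lateralization(sides),
       recording_sides = sides, recordings = res)
}
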