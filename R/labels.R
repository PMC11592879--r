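#' Lateralization labels and their signed integer encoding
#'
#' The package's categorical sides are the strings `"LEFT"`, `"RIGHT"` and
#' `"NONE"` (MRI-negative or missing analysis). The fusion rule operates on
#' a signed encoding: LEFT = +1, RIGHT = -1, NONE = 0, chosen so that a
#' positive label sum means a left-hemisphere focus.
#'
#' @param side Character vector of sides (`"LEFT"`, `"RIGHT"`, `"NONE"`).
#' @return `encode_side()`: integer vector in \{+1, -1, 0\};
#'   `decode_side()`: character vector of sides.
#' @export
#' @examples
#' encode_side(c("LEFT", "RIGHT", "NONE"))
encode_side <- function(side) {
  out <- integer(length(side))
  out[side == "LEFT"] <- 1L
  out[side == "RIGHT"] <- -1L
  bad <- !(side %in% c("LEFT", "RIGHT", "NONE"))
  if (any(bad)) stop("unknown side: ", paste(unique(side[bad]), collapse = ", "))
  out
}

#' @rdname encode_side
#' @param code Integer vector in \{+1, -1, 0\}.
#' @export
decode_side <- function(code) {
  if (!all(code %in% c(-1L, 0L, 1L))) stop("encoding must be in {-1, 0, +1}")
  c("RIGHT", "NONE", "LEFT")[code + 2L]
}
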