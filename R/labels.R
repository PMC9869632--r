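#' Patch-level label vocabulary
#'
#' The six patch-level tissue classes, in fixed channel order:
#' high-grade muscle invasion (HGMI), high-grade non-muscle invasion
#' (HGNMI), low-grade non-muscle invasion (LGNMI), illegible area (IA),
#' normal interstitial area (NIA) and noise area (NA). The first three
#' are the diagnostic classes, which are also the three slide-level
#' categories.
#'
#' @return A data frame with columns `code` (character), `channel_index`
#'   (integer, 0-based, the heatmap channel of that class) and
#'   `diagnostic` (logical).
#' @export
#' @examples
#' label_classes()
label_classes <- function() {
  data.frame(
    code = c("HGMI", "HGNMI", "LGNMI", "IA", "NIA", "NA"),
    channel_index = 0:5,
    diagnostic = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Diagnostic class codes
#'
#' @return Character vector `c("HGMI", "HGNMI", "LGNMI")`.
#' @export
diagnostic_classes <- function() {
  lc <- label_classes()
  lc$code[lc$diagnostic]
}

# validate a label code, returning it invisibly
check_label <- function(code, diagnostic_only = FALSE) {
  valid <- if (diagnostic_only) diagnostic_classes() else label_classes()$code
  bad <- setdiff(code, valid)
  if (length(bad) > 0) {
    stop("unknown label class: ", paste(bad, collapse = ", "),
         " (expected one of ", paste(valid, collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(code)
}

#' Channel index of a label class
#'
#' @param code Character vector of label codes.
#' @return Integer vector of 0-based channel indices.
#' @export
label_channel <- function(code) {
  check_label(code)
  lc <- label_classes()
  lc$channel_index[match(code, lc$code)]
}

# inverse of label_channel
channel_label <- function(channel_index) {
  lc <- label_classes()
  stopifnot(all(channel_index %in% lc$channel_index))
  lc$code[match(channel_index, lc$channel_index)]
}
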