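#' Channel layout of a pooled multiplexed labeling design
#'
#' Describes how reporter channels map onto the two biological groups and
#' which channel is the normalization reference. The default is the pooled
#' 4-plex design used throughout the package: two patient channels
#' (`"113"`, `"115"`) and two control channels (`"114"`, `"116"`), with the
#' `"113"` patient pool as reference so that the reference ratio is
#' identically 1 after normalization.
#'
#' Any k-plex layout with at least one control channel and at least two
#' patient channels (one of which is the reference) is accepted; channel tags
#' are opaque strings.
#'
#' @param channels Character vector of channel tags, in label order.
#' @param groups Character vector, same length as `channels`; each element is
#'   `"patient"` or `"control"`.
#' @param reference Tag of the reference channel; must be one of `channels`.
#'
#' @return An object of class `channel_design` with elements `channels`,
#'   `group_of` (named character vector channel -> group) and `reference`.
#' @examples
#' design <- channel_design()
#' control_channels(design)
#' patient_channels(design, include_reference = FALSE)
#' @export
channel_design <- function(channels = c("113", "114", "115", "116"),
                           groups = c("patient", "control",
                                      "patient", "control"),
                           reference = "113") {
  channels <- as.character(channels)
  reference <- as.character(reference)
  if (length(channels) < 2L) {
    stop("a channel design needs at least two channels", call. = FALSE)
  }
  if (anyDuplicated(channels)) {
    stop("duplicated channel tags in design", call. = FALSE)
  }
  if (length(groups) != length(channels)) {
    stop("`groups` must have one entry per channel", call. = FALSE)
  }
  if (!all(groups %in% c("patient", "control"))) {
    stop("group labels must be 'patient' or 'control'", call. = FALSE)
  }
  if (!reference %in% channels) {
    stop("reference channel '", reference, "' is not among the channels",
         call. = FALSE)
  }
  if (!all(c("patient", "control") %in% groups)) {
    stop("each group needs at least one channel", call. = FALSE)
  }
  structure(
    list(channels = channels,
         group_of = setNames(groups, channels),
         reference = reference),
    class = "channel_design"
  )
}

#' @rdname channel_design
#' @param design A `channel_design`.
#' @export
control_channels <- function(design) {
  stopifnot(inherits(design, "channel_design"))
  names(design$group_of)[design$group_of == "control"]
}

#' @rdname channel_design
#' @param include_reference Keep the reference channel in the returned set?
#' @export
patient_channels <- function(design, include_reference = TRUE) {
  stopifnot(inherits(design, "channel_design"))
  out <- names(design$group_of)[design$group_of == "patient"]
  if (!include_reference) out <- setdiff(out, design$reference)
  out
}

#' @export
print.channel_design <- function(x, ...) {
  cat(length(x$channels), "-plex channel design\n", sep = "")
  for (ch in x$channels) {
    cat(sprintf("  %s  %s%s\n", ch, x$group_of[[ch]],
                if (ch == x$reference) "  (reference)" else ""))
  }
  invisible(x)
}

# Column names carrying per-channel ratios in peptide/protein tables.
channel_cols <- function(design) paste0("ch_", design$channels)
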