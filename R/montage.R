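#' The 4-lead epidural somatosensory montage
#'
#' Canonical channel labels and 2-D positions for the bilateral
#' anterior/posterior somatosensory epidural array, mapped onto the
#' human 10-20 naming scheme (C3/C4 centro-parietal leads). Positions are
#' schematic head coordinates in the range [-1, 1] (x: left negative,
#' y: anterior positive).
#'
#' @return Named list of length-2 numeric positions, one per canonical label.
#' @export
default_montage <- function() {
  list(
    "LA-SSC" = c(-0.4,  0.3),   # left anterior somatosensory
    "LP-SSC" = c(-0.4, -0.3),   # left posterior somatosensory
    "RA-SSC" = c( 0.4,  0.3),   # right anterior somatosensory
    "RP-SSC" = c( 0.4, -0.3)    # right posterior somatosensory
  )
}

# alias table: lower-cased, punctuation-stripped label -> canonical label
.montage_aliases <- function() {
  c("lassc"  = "LA-SSC", "lantssc" = "LA-SSC", "lantsc" = "LA-SSC",
    "leftanteriorssc" = "LA-SSC", "lantsomatosensory" = "LA-SSC",
    "lantss" = "LA-SSC", "c3a" = "LA-SSC",
    "lpssc"  = "LP-SSC", "lpostssc" = "LP-SSC", "lpostsc" = "LP-SSC",
    "leftposteriorssc" = "LP-SSC", "lpostsomatosensory" = "LP-SSC",
    "c3p" = "LP-SSC",
    "rassc"  = "RA-SSC", "rantssc" = "RA-SSC", "rantsc" = "RA-SSC",
    "rightanteriorssc" = "RA-SSC", "rantsomatosensory" = "RA-SSC",
    "c4a" = "RA-SSC",
    "rpssc"  = "RP-SSC", "rpostssc" = "RP-SSC", "rpostsc" = "RP-SSC",
    "rightposteriorssc" = "RP-SSC", "rpostsomatosensory" = "RP-SSC",
    "c4p" = "RP-SSC")
}

#' Standardize channel labels to the canonical montage
#'
#' Maps recorded channel names (which vary with the acquisition software)
#' onto the canonical 4-lead labels and their 2-D positions. Matching is
#' case- and punctuation-insensitive against a built-in alias table. Unknown
#' labels are passed through unchanged, flagged `unmapped`, and reported with
#' a warning rather than silently dropped.
#'
#' @param labels character vector of raw channel labels.
#' @return data.frame with columns `input`, `canonical`, `mapped` (logical),
#'   `x`, `y` (position; NA when unmapped).
#' @export
standardize_montage <- function(labels) {
  if (!is.character(labels) || length(labels) == 0L)
    stop("`labels` must be a non-empty character vector")
  key <- gsub("[^a-z0-9]", "", tolower(labels))
  aliases <- .montage_aliases()
  # canonical labels map to themselves
  canon <- default_montage()
  self_key <- gsub("[^a-z0-9]", "", tolower(names(canon)))
  aliases <- c(aliases, stats::setNames(names(canon), self_key))
  canonical <- unname(aliases[key])
  mapped <- !is.na(canonical)
  canonical[!mapped] <- labels[!mapped]
  if (any(!mapped))
    warning("unmapped channel label(s): ",
            paste(labels[!mapped], collapse = ", "))
  dup <- duplicated(canonical[mapped])
  if (any(dup))
    stop("duplicate canonical assignment: ",
         paste(unique(canonical[mapped][dup]), collapse = ", "))
  pos <- t(vapply(canonical, function(l) {
    if (l %in% names(canon)) canon[[l]] else c(NA_real_, NA_real_)
  }, numeric(2)))
  data.frame(input = labels, canonical = canonical, mapped = mapped,
             x = pos[, 1], y = pos[, 2], row.names = NULL,
             stringsAsFactors = FALSE)
}
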