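#' @include AllGenerics.R
NULL

#' Create a scan protocol from explicit frame durations
#'
#' @param frameDurations numeric vector of frame durations in seconds.
#' @return a [ScanProtocol-class].
#' @examples
#' p <- scanProtocol(c(30, 30, 60))
#' nFrames(p)
#' @export
scanProtocol <- function(frameDurations) {
  new("ScanProtocol", frameDurations = as.numeric(frameDurations))
}

#' Parse a scanning-protocol string
#'
#' Protocol strings are '+'-joined terms of the form
#' \code{"<seconds>s×<count>"} (a plain \code{"x"} is accepted in place of
#' the multiplication sign), e.g. \code{"30s×4+110s×12+180s×2"} for four
#' 30-s frames, twelve 110-s frames and two 180-s frames (18 frames,
#' 1800 s total).
#'
#' @param spec protocol string.
#' @return a [ScanProtocol-class].
#' @examples
#' p <- parseProtocol("30s×4+110s×12+180s×2")
#' nFrames(p)        # 18
#' totalDuration(p)  # 1800
#' @export
parseProtocol <- function(spec) {
  if (!is.character(spec) || length(spec) != 1L)
    stop("'spec' must be a single character string")
  terms <- strsplit(gsub("\\s", "", spec), "+", fixed = TRUE)[[1]]
  if (length(terms) == 0L) stop("empty protocol string")
  durs <- lapply(terms, function(term) {
    m <- regmatches(term,
                    regexec("^([0-9]*\\.?[0-9]+)s(x|×|\\*)([0-9]+)$",
                            term))[[1]]
    if (length(m) != 4L)
      stop(sprintf(
        "malformed protocol term '%s' (expected '<seconds>s×<count>')",
        term))
    rep(as.numeric(m[2]), as.integer(m[4]))
  })
  scanProtocol(unlist(durs))
}

#' @rdname nFrames
#' @export
setMethod("nFrames", "ScanProtocol",
          function(x) length(x@frameDurations))

#' @rdname frameDurations
#' @export
setMethod("frameDurations", "ScanProtocol", function(x) x@frameDurations)

#' @rdname frameEdges
#' @export
setMethod("frameEdges", "ScanProtocol", function(x) {
  e <- cumsum(x@frameDurations)
  cbind(start = c(0, e[-length(e)]), end = e)
})

#' @rdname midFrameTimes
#' @export
setMethod("midFrameTimes", "ScanProtocol", function(x) {
  fe <- frameEdges(x)
  unname(fe[, 1] + x@frameDurations / 2)
})

#' @rdname totalDuration
#' @export
setMethod("totalDuration", "ScanProtocol",
          function(x) sum(x@frameDurations))

setMethod("show", "ScanProtocol", function(object) {
  d <- object@frameDurations
  r <- rle(d)
  cat(sprintf("ScanProtocol: %d frames, %g s total\n  %s\n",
              length(d), sum(d),
              paste(sprintf("%gs×%d", r$values, r$lengths),
                    collapse = " + ")))
})
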