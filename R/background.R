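#' Background-correct field channels
#'
#' Estimates each channel's smooth background by grayscale morphological
#' opening with a large disc (the rolling-ball equivalent) and subtracts
#' it, clipping at zero. Channels are corrected independently.
#'
#' @param image a field object (list with a `channels` list of matrices),
#'   or a single numeric matrix.
#' @param method background estimator; currently `"opening"`.
#' @param radius structuring-element radius in px; must exceed the largest
#'   span covered by foreground structure. In a confluent monolayer the
#'   cell carpet itself is quasi-continuous, so the radius has to be much
#'   larger than a single cell (default ~3 cell diameters) for the
#'   estimate to track the true inter-cellular background level.
#' @return Object of the same shape as `image` with corrected intensities.
#' @export
correct_background <- function(image, method = "opening", radius = 96) {
  if (!identical(method, "opening"))
    stop("unknown background correction method: ", method)
  corr <- function(ch) {
    scale <- max(ch)
    if (scale <= 0) return(ch * 0)
    nr <- nrow(ch); nc <- ncol(ch)
    ## estimate the smooth background on a downsampled copy (the opening
    ## cost grows with brush area), with edge-replication padding so the
    ## estimate has no border bias; EBImage grayscale morphology operates
    ## on [0,1]
    ds <- max(1L, as.integer(radius %/% 20))
    rs <- as.integer(ceiling(radius / ds))
    small <- if (ds > 1)
      matrix(EBImage::imageData(EBImage::resize(
        EBImage::Image(ch / scale),
        w = ceiling(nr / ds), h = ceiling(nc / ds))),
        ceiling(nr / ds), ceiling(nc / ds))
    else ch / scale
    sr <- nrow(small); sc <- ncol(small)
    ri <- pmin(pmax(seq(1 - rs, sr + rs), 1), sr)
    ci <- pmin(pmax(seq(1 - rs, sc + rs), 1), sc)
    bg <- matrix(EBImage::imageData(EBImage::opening(
      EBImage::Image(small[ri, ci]),
      EBImage::makeBrush(2 * rs + 1, "disc"))),
      length(ri), length(ci))[rs + seq_len(sr), rs + seq_len(sc)]
    if (ds > 1)
      bg <- matrix(EBImage::imageData(EBImage::resize(
        EBImage::Image(bg), w = nr, h = nc)), nr, nc)
    pmax(ch - bg * scale, 0)
  }
  if (is.matrix(image)) return(corr(image))
  stopifnot(is.list(image), !is.null(image$channels))
  image$channels <- lapply(image$channels, corr)
  image
}
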