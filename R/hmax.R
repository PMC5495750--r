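## HMAX front end: S1 Gabor filter bank (simple cells) and C1 local max
## pooling (complex cells), used to build the stimulus-similarity model RDM
## over the nine cue images.

#' Build an S1 Gabor filter bank
#'
#' Odd-sized, zero-mean, unit-norm Gabor kernels at several orientations and
#' scales, following the conventional HMAX parameterization (kernel sigma
#' and wavelength grow linearly with size, aspect ratio 0.3).  Scales are
#' grouped into bands of two adjacent sizes; each band has a C1 spatial
#' pooling window and stride.
#'
#' @param orientations filter orientations in degrees (>= 4).
#' @param sizes odd kernel sizes in pixels (>= 2 scales).
#' @param band_size number of adjacent scales pooled per C1 band.
#' @param pool_sizes C1 spatial pooling window per band (defaults to
#'   `8, 10, 12, ...`).
#' @return An object of class `s1_bank`.
#' @export
build_s1_bank <- function(orientations = c(0, 45, 90, 135),
                          sizes = seq(7, 21, by = 2),
                          band_size = 2,
                          pool_sizes = NULL) {
  if (length(orientations) < 4) stop_invalid("need at least 4 orientations")
  if (length(sizes) < 2) stop_invalid("need at least 2 scales")
  if (any(sizes %% 2 == 0))
    stop_invalid("kernel sizes must be odd (a center pixel must exist)")
  n_bands <- length(sizes) %/% band_size
  bands <- lapply(seq_len(n_bands), function(b)
    ((b - 1) * band_size + 1):(b * band_size))
  if (is.null(pool_sizes)) pool_sizes <- 8 + 2 * (seq_len(n_bands) - 1)
  if (length(pool_sizes) != n_bands)
    stop_invalid("need one pool size per band (%d)", n_bands)
  filters <- lapply(sizes, function(s)
    lapply(orientations, function(th) gabor_kernel(s, th)))
  structure(list(orientations = orientations, sizes = sizes,
                 filters = filters, bands = bands, pool_sizes = pool_sizes,
                 strides = pmax(1L, ceiling(pool_sizes / 2)),
                 cache = new.env(parent = emptyenv())),
            class = "s1_bank")
}

## one zero-mean, unit-norm Gabor kernel of odd size s
gabor_kernel <- function(s, theta_deg, gamma = 0.3) {
  sigma <- 0.0036 * s^2 + 0.35 * s + 0.18
  lambda <- sigma / 0.8
  h <- (s - 1) / 2
  ax <- -h:h
  x <- matrix(ax, s, s, byrow = TRUE)
  y <- matrix(ax, s, s)
  th <- theta_deg * pi / 180
  x0 <- x * cos(th) + y * sin(th)
  y0 <- -x * sin(th) + y * cos(th)
  k <- exp(-(x0^2 + gamma^2 * y0^2) / (2 * sigma^2)) * cos(2 * pi * x0 / lambda)
  k[x^2 + y^2 > h^2] <- 0          # circular aperture
  k <- k - mean(k[x^2 + y^2 <= h^2]) # zero mean over the support
  k[x^2 + y^2 > h^2] <- 0
  k / sqrt(sum(k^2))
}

## FFT-based valid 2D cross-correlation of `img` with kernel `k`
## (kernels cached per padded size in bank$cache by the callers)
fft_pad <- function(m, P) {
  out <- matrix(0, P[1], P[2])
  out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  stats::fft(out)
}

#' S1 simple-cell responses
#'
#' Absolute normalized cross-correlation of every bank kernel with every
#' image neighborhood (valid positions only): the kernel inner product
#' divided by the L2 norm of the underlying image patch, so all responses
#' lie in `[0, 1]` and a uniform image yields zero response.
#'
#' @param image a `stimulus_image` or numeric matrix.
#' @param bank an [build_s1_bank()] filter bank.
#' @return Object of class `s1_response`: `maps[[scale]][[orientation]]`
#'   response matrices.
#' @export
s1_response <- function(image, bank = build_s1_bank()) {
  px <- if (inherits(image, "stimulus_image")) image$pixels else as.matrix(image)
  if (any(!is.finite(px))) stop_invalid("image contains non-finite values")
  n1 <- nrow(px); n2 <- ncol(px)
  smax <- max(bank$sizes)
  if (n1 < smax || n2 < smax)
    stop_invalid("image (%d x %d) smaller than largest kernel (%d)", n1, n2, smax)
  P <- c(stats::nextn(n1 + smax - 1, c(2, 3, 5)),
         stats::nextn(n2 + smax - 1, c(2, 3, 5)))
  key <- paste(P, collapse = "x")
  kc <- bank$cache[[key]]
  if (is.null(kc)) {
    ## cache FFTs of (flipped) kernels and of the box kernels used for norms
    kc <- list(
      kern = lapply(bank$filters, function(fs) lapply(fs, function(k)
        fft_pad(k[nrow(k):1, ncol(k):1, drop = FALSE], P))),
      box = lapply(bank$sizes, function(s) fft_pad(matrix(1, s, s), P))
    )
    bank$cache[[key]] <- kc
  }
  Fimg <- stats::fft(`[<-`(matrix(0, P[1], P[2]), seq_len(n1), seq_len(n2), px))
  Fsq <- stats::fft(`[<-`(matrix(0, P[1], P[2]), seq_len(n1), seq_len(n2), px^2))
  maps <- vector("list", length(bank$sizes))
  for (si in seq_along(bank$sizes)) {
    s <- bank$sizes[si]
    rows <- s:n1; cols <- s:n2
    en <- Re(stats::fft(Fsq * kc$box[[si]], inverse = TRUE)) / prod(P)
    patch_norm <- sqrt(pmax(en[rows, cols, drop = FALSE], 0))
    maps[[si]] <- lapply(seq_along(bank$orientations), function(oi) {
      num <- Re(stats::fft(Fimg * kc$kern[[si]][[oi]], inverse = TRUE)) / prod(P)
      r <- abs(num[rows, cols, drop = FALSE])
      r <- ifelse(patch_norm > 1e-12, r / patch_norm, 0)
      pmin(r, 1)
    })
  }
  structure(list(maps = maps, sizes = bank$sizes,
                 orientations = bank$orientations),
            class = "s1_response")
}

#' C1 complex-cell pooling
#'
#' Local max pooling of S1 responses over space (square windows of the
#' band's pool size, stride half the window) and over the adjacent scales
#' within each band, per orientation.  Max pooling confers tolerance to
#' small translations: pooled outputs change less than the underlying S1
#' maps when the input shifts by less than a pooling window.
#'
#' @param s1 an [s1_response()].
#' @param bank the bank that produced it.
#' @return Object of class `c1_response`: `maps[[band]][[orientation]]`
#'   pooled matrices.
#' @export
c1_pool <- function(s1, bank = build_s1_bank()) {
  if (length(s1$maps) < 2) stop_invalid("C1 pooling needs S1 maps from >= 2 scales")
  maps <- lapply(seq_along(bank$bands), function(b) {
    scales <- bank$bands[[b]]
    p <- bank$pool_sizes[b]
    st <- bank$strides[b]
    lapply(seq_along(bank$orientations), function(oi) {
      ms <- lapply(scales, function(si) s1$maps[[si]][[oi]])
      nr <- min(vapply(ms, nrow, 1L)); nc <- min(vapply(ms, ncol, 1L))
      m <- Reduce(pmax, lapply(ms, function(x) x[seq_len(nr), seq_len(nc), drop = FALSE]))
      max_pool(m, p, st)
    })
  })
  structure(list(maps = maps, pool_sizes = bank$pool_sizes,
                 orientations = bank$orientations),
            class = "c1_response")
}

max_pool <- function(m, p, stride) {
  if (p <= 1) return(m)
  nr <- nrow(m); nc <- ncol(m)
  if (nr < p || nc < p)
    stop_invalid("map (%d x %d) smaller than pooling window %d", nr, nc, p)
  ri <- seq(1, nr - p + 1, by = stride)
  ci <- seq(1, nc - p + 1, by = stride)
  out <- matrix(0, length(ri), length(ci))
  for (a in seq_along(ri))
    for (b in seq_along(ci))
      out[a, b] <- max(m[ri[a]:(ri[a] + p - 1), ci[b]:(ci[b] + p - 1)])
  out
}

flatten_c1 <- function(c1) unlist(lapply(c1$maps, function(bm) lapply(bm, as.vector)),
                                  use.names = FALSE)

#' HMAX C1 stimulus-similarity RDM
#'
#' Runs each image through the S1/C1 front end and computes the 9 x 9 (or
#' n x n) correlation-distance matrix between flattened C1 response
#' vectors: entry (i, j) is `1 - Pearson r` between the simulated
#' complex-cell responses to images i and j.
#'
#' @param images list of `stimulus_image` objects or matrices, all at the
#'   same resolution (default: the nine rendered cue images).
#' @param bank S1 filter bank.
#' @param pixels_per_degree rendering resolution used when `images` are
#'   [gabor_spec()]s.
#' @return An `rdm` with one row per image.
#' @export
hmax_c1_rdm <- function(images = cue_set(), bank = build_s1_bank(),
                        pixels_per_degree = 32) {
  images <- lapply(images, function(im)
    if (inherits(im, "gabor_spec")) render_gabor(im, pixels_per_degree) else im)
  dims <- vapply(images, function(im)
    dim(if (inherits(im, "stimulus_image")) im$pixels else im), integer(2))
  if (any(dims != dims[, 1])) stop_invalid("all images must share one resolution")
  feats <- lapply(images, function(im) flatten_c1(c1_pool(s1_response(im, bank), bank)))
  F <- do.call(cbind, feats)
  if (any(apply(F, 2, sd) < 1e-10))
    stop_invalid("degenerate image: constant C1 output, correlation undefined")
  m <- 1 - cor(F)
  m <- pmin(pmax(m, 0), 2)
  diag(m) <- 0
  m <- (m + t(m)) / 2
  labels <- names(images) %||% paste0("cue", seq_along(images))
  rdm(m, labels = labels, type = "model")
}
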