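#' Lexicon: decoded pre-image sequences at latent density peaks
#'
#' @slot entries List of entries, each a list with `id`, `phiStar` (latent
#'   centroid of the peak's members), `preImage` (`M x C` decoded sequence),
#'   `density`, `peakXY` (2-D embedding coordinates of the peak),
#'   `memberCount`, `reconGap` (`||encode(preImage) - phiStar||`) and a
#'   free-text `interpretation` slot.
#' @slot bandwidth KDE bandwidths used.
#' @export
setClass("Lexicon", representation(entries = "list", bandwidth = "numeric"))

setMethod("show", "Lexicon", function(object) {
  cat(sprintf("Lexicon with %d entries:\n", length(object@entries)))
  for (e in object@entries)
    cat(sprintf("  %s: density %.4g, %d members, recon gap %.3g\n",
                e$id, e$density, e$memberCount, e$reconGap))
})

#' @describeIn Lexicon-class Entry accessor.
#' @param lexicon A [Lexicon-class].
#' @export
lexiconEntries <- function(lexicon) lexicon@entries

# Local maxima of a kde2d grid: cells >= all 8 neighbours.
kdeLocalMaxima <- function(kde) {
  z <- kde$z; nx <- nrow(z); ny <- ncol(z)
  peaks <- NULL
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    ii <- max(1, i - 1):min(nx, i + 1)
    jj <- max(1, j - 1):min(ny, j + 1)
    if (z[i, j] >= max(z[ii, jj]) && z[i, j] > 0)
      peaks <- rbind(peaks, c(kde$x[i], kde$y[j], z[i, j]))
  }
  peaks[order(-peaks[, 3]), , drop = FALSE]
}

#' Build a behaviour lexicon from latent density peaks
#'
#' Estimates a kernel density on the 2-D embedding of the latent points,
#' selects up to `nPeaks` local density maxima greedily with a minimum
#' separation, collects each peak's member points (embedded points within the
#' basin radius, half the minimum inter-peak distance), takes the member
#' centroid in the original latent space as the peak representative
#' `phiStar`, and decodes it through the autoencoder to the pre-image
#' sequence. Entries are sorted by density.
#'
#' @param ae A [ConvAutoencoder-class].
#' @param latents `n x N` latent matrix (from [encodeSamples()]).
#' @param embedding `n x 2` embedding aligned with `latents` (from
#'   [embedLatents()]).
#' @param nPeaks Number of peaks requested; fewer are returned with a
#'   warning when the density surface has fewer maxima.
#' @param bandwidth Optional KDE bandwidth vector `c(hx, hy)`; default is a
#'   Scott-type normal reference rule per axis.
#' @param gridN KDE grid resolution (default 60).
#' @param minSepFrac Minimum peak separation as a fraction of the embedding
#'   diagonal (default 0.1).
#' @return A [Lexicon-class].
#' @export
buildLexicon <- function(ae, latents, embedding, nPeaks, bandwidth = NULL,
                         gridN = 60, minSepFrac = 0.1) {
  latents <- as.matrix(latents)
  embedding <- as.matrix(embedding)
  stopIfNot(nrow(latents) == nrow(embedding),
            "embedding must be aligned with latents")
  stopIfNot(nPeaks >= 1, "nPeaks must be >= 1")

  makeEntry <- function(id, phiStar, density, peakXY, memberCount) {
    pre <- decodeLatent(ae, phiStar)
    gap <- sqrt(sum((as.numeric(encodeSamples(
      ae, array(pre, c(1, nrow(pre), ncol(pre))))) - phiStar)^2))
    list(id = id, phiStar = phiStar, preImage = pre, density = density,
         peakXY = peakXY, memberCount = memberCount, reconGap = gap,
         interpretation = NA_character_)
  }

  spread <- apply(embedding, 2, function(v) diff(range(v)))
  if (any(spread < 1e-12)) {
    # degenerate cloud (e.g. all latents identical): a single peak
    phiStar <- colMeans(latents)
    return(new("Lexicon",
               entries = list(makeEntry("lex1", phiStar, Inf,
                                        colMeans(embedding), nrow(latents))),
               bandwidth = c(NA_real_, NA_real_)))
  }
  if (is.null(bandwidth))
    bandwidth <- c(MASS::bandwidth.nrd(embedding[, 1]),
                   MASS::bandwidth.nrd(embedding[, 2]))
  kde <- MASS::kde2d(embedding[, 1], embedding[, 2], h = bandwidth, n = gridN)
  cand <- kdeLocalMaxima(kde)
  minSep <- minSepFrac * sqrt(sum(spread^2))
  sel <- NULL
  for (r in seq_len(nrow(cand))) {
    p <- cand[r, 1:2]
    if (is.null(sel) ||
        all(sqrt(rowSums(sweep(sel[, 1:2, drop = FALSE], 2, p)^2)) >= minSep))
      sel <- rbind(sel, cand[r, ])
    if (nrow(sel) == nPeaks) break
  }
  if (nrow(sel) < nPeaks)
    warning(sprintf("only %d density peaks found (requested %d)",
                    nrow(sel), nPeaks), call. = FALSE)
  radius <- if (nrow(sel) > 1L)
    min(dist(sel[, 1:2, drop = FALSE])) / 2 else Inf
  entries <- lapply(seq_len(nrow(sel)), function(r) {
    p <- sel[r, 1:2]
    d2 <- rowSums(sweep(embedding, 2, p)^2)
    members <- which(sqrt(d2) <= radius)
    if (length(members) == 0L) members <- which.min(d2)
    phiStar <- colMeans(latents[members, , drop = FALSE])
    makeEntry(paste0("lex", r), phiStar, sel[r, 3], p, length(members))
  })
  new("Lexicon", entries = entries, bandwidth = bandwidth)
}

#' Doubly integrate acceleration to position
#'
#' Cumulative trapezoidal integration applied twice with zero initial
#' velocity and position, to turn a (unit-free) acceleration pattern into an
#' estimated position trajectory.
#'
#' @param acceleration Numeric vector or `T x C` matrix (one column per
#'   axis).
#' @param dt Uniform sampling interval, > 0.
#' @return Position sequence with the same shape as the input.
#' @examples
#' doubleIntegrate(rep(2, 101), dt = 0.01)[101]   # ~ a*T^2/2 = 1
#' @export
doubleIntegrate <- function(acceleration, dt) {
  stopIfNot(is.numeric(dt) && length(dt) == 1L && dt > 0, "dt must be > 0")
  vec <- is.null(dim(acceleration))
  A <- if (vec) matrix(acceleration, ncol = 1) else as.matrix(acceleration)
  tt <- dt * (seq_len(nrow(A)) - 1)
  v <- pracma::cumtrapz(tt, A)
  p <- pracma::cumtrapz(tt, v)
  if (vec) as.numeric(p) else p
}

#' Planar trajectory of two inertial axes
#'
#' Ordered `(a1, a2)` points preserving time order, for visualising motion
#' manifolds (distinct gaits trace distinct closed shapes; flipping one
#' axis's sign mirrors the trajectory across the other axis).
#'
#' @param imu `T x C` matrix with named columns (e.g. `x`, `y`, `z` or
#'   `imu.x`, ...), or an [AlignedSequence-class].
#' @param axes Two axis names to plot against each other.
#' @return `data.frame` with the two named columns, one row per time step.
#' @export
axisPlaneTrajectory <- function(imu, axes = c("x", "y")) {
  if (is(imu, "AlignedSequence")) imu <- imu@values
  stopIfNot(is.matrix(imu) && !is.null(colnames(imu)),
            "imu must be a matrix with named columns")
  stopIfNot(length(axes) == 2L, "axes must name exactly two columns")
  cols <- match(axes, colnames(imu))
  # tolerate the fused naming ("imu.x") for bare axis names
  if (anyNA(cols)) cols <- ifelse(is.na(cols),
                                  match(paste0("imu.", axes), colnames(imu)),
                                  cols)
  if (anyNA(cols))
    stop("unknown axis name(s): ",
         paste(axes[is.na(cols)], collapse = ", "), call. = FALSE)
  out <- data.frame(imu[, cols[1]], imu[, cols[2]])
  names(out) <- axes
  out
}
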