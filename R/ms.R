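# MS glycomics: raw spectrum ingestion (.msd two-column dialect), the
# four-step peak processing method (background adjustment, normalization,
# noise removal, peak finding), composition annotation of centroids by
# permethylated/native monoisotopic mass, and a seeded synthetic-spectrum
# generator with ground truth for pipeline validation.

#' Read a raw spectrum from a two-column text file
#'
#' The `.msd` dialect: one `m/z intensity` pair per line, whitespace- or
#' comma-delimited; blank lines and lines starting with `#` or `;` are
#' ignored. Rows are sorted by m/z.
#'
#' @param path input file.
#' @return an `ms_spectrum`: list with ascending `mz` and co-indexed
#'   non-negative `intensity`.
#' @export
read_ms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) &
                  !grepl("^\\s*[#;]", lines))
  if (!length(keep)) stop("MS format error: '", path, "' contains no data rows",
                          call. = FALSE)
  mz <- numeric(length(keep)); intensity <- numeric(length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    fields <- strsplit(trimws(lines[ln]), "[,;[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2L || anyNA(vals[1:2])) {
      stop("MS parse error at line ", ln, ": non-numeric row '", lines[ln], "'",
           call. = FALSE)
    }
    mz[i] <- vals[1]; intensity[i] <- vals[2]
  }
  ord <- order(mz)
  new_spectrum(mz[ord], intensity[ord])
}

new_spectrum <- function(mz, intensity) {
  stopifnot(length(mz) == length(intensity), !is.unsorted(mz),
            all(intensity >= 0))
  structure(list(mz = mz, intensity = intensity), class = "ms_spectrum")
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat("<spectrum: ", length(x$mz), " points, m/z ",
      round(min(x$mz), 2), "-", round(max(x$mz), 2), ">\n", sep = "")
  invisible(x)
}

#' Write a spectrum to a two-column text file
#'
#' @param s an `ms_spectrum`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ms <- function(s, path) {
  stopifnot(inherits(s, "ms_spectrum"))
  writeLines(sprintf("%.6f %.6f", s$mz, s$intensity), path)
  invisible(path)
}

# O(n) sliding-window minimum (monotonic deque), centered window of half
# width w points.
roll_min <- function(x, w) {
  n <- length(x)
  out <- numeric(n)
  dq_idx <- integer(0)
  j <- 0L # points pushed so far
  for (i in seq_len(n)) {
    hi <- min(n, i + w)
    while (j < hi) {
      j <- j + 1L
      while (length(dq_idx) && x[dq_idx[length(dq_idx)]] >= x[j]) {
        dq_idx <- dq_idx[-length(dq_idx)]
      }
      dq_idx <- c(dq_idx, j)
    }
    lo <- max(1L, i - w)
    while (dq_idx[1L] < lo) dq_idx <- dq_idx[-1L]
    out[i] <- x[dq_idx[1L]]
  }
  out
}

# centered moving average with shrinking edges
roll_mean <- function(x, w) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - w, 1L)
  hi <- pmin(seq_len(n) + w, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Peak-processing parameters
#'
#' @param baseline_window_th width (in Th, half-window) of the moving
#'   minimum/average used for background adjustment; must be much wider
#'   than a peak.
#' @param smooth_window_th half-width (Th) of the smoothing average used
#'   before noise thresholding and peak picking.
#' @param snr_threshold signal points below `snr_threshold` times the
#'   robust noise estimate (median absolute deviation) are zeroed.
#' @param min_height minimum peak height after normalization to 100.
#' @return a list of parameters for [ms_process()].
#' @export
ms_params <- function(baseline_window_th = 10, smooth_window_th = 0.15,
                      snr_threshold = 3, min_height = 1) {
  list(baseline_window_th = baseline_window_th,
       smooth_window_th = smooth_window_th,
       snr_threshold = snr_threshold, min_height = min_height)
}

#' Convert a raw spectrum into a peak list
#'
#' The four-step method: (1) background adjustment - a moving-minimum
#' followed by a moving-average estimates the baseline, which is subtracted
#' and floored at zero; (2) normalization of intensities to a maximum of
#' 100; (3) noise removal - smoothing plus zeroing of points below
#' `snr_threshold` x the median-absolute-deviation noise estimate;
#' (4) peak finding - local maxima above `min_height`, with the centroid
#' taken as the intensity-weighted mean over the half-height region and the
#' FWHM measured on the smoothed trace.
#'
#' @param s an `ms_spectrum`.
#' @param params see [ms_params()].
#' @return an `ms_peaklist`: data.frame with columns `centroid` (Th),
#'   `height` (relative, max 100) and `fwhm` (Th), ascending in centroid.
#'   An all-zero spectrum yields an empty peak list.
#' @export
ms_process <- function(s, params = ms_params()) {
  stopifnot(inherits(s, "ms_spectrum"))
  n <- length(s$mz)
  step <- stats::median(diff(s$mz))
  wb <- max(1L, round(params$baseline_window_th / step))
  ws <- max(1L, round(params$smooth_window_th / step))
  if (n < 2L * ws + 1L) stop("spectrum shorter than the smoothing window", call. = FALSE)

  # 1. background adjustment
  baseline <- roll_mean(roll_min(s$intensity, wb), wb)
  y <- pmax(s$intensity - baseline, 0)

  # 2. normalization
  top <- max(y)
  if (top <= 0) return(empty_peaklist())
  y <- y * (100 / top)

  # 3. noise removal. The moving-minimum baseline sits below the noise
  # floor, so the smoothed trace retains a small positive offset: re-center
  # on its median (peaks are sparse) before thresholding.
  ys0 <- roll_mean(y, ws)
  lvl <- stats::median(ys0)
  dev <- ys0 - lvl
  sigma_s <- stats::mad(dev[dev <= stats::quantile(dev, 0.95)]) # smoothed-noise scale
  sigma_raw <- stats::mad(y[y <= stats::quantile(y, 0.95)])     # point-noise scale
  if (is.na(sigma_s)) sigma_s <- 0
  if (is.na(sigma_raw)) sigma_raw <- 0
  ys <- pmax(dev, 0)
  ys[ys < params$snr_threshold * sigma_s] <- 0
  apex_min <- max(params$min_height, params$snr_threshold * sigma_raw)

  # 4. peak finding on the smoothed trace
  peaks <- list()
  i <- 2L
  while (i < n) {
    if (ys[i] >= apex_min && ys[i] > ys[i - 1L] && ys[i] >= ys[i + 1L]) {
      # walk a plateau to its end
      j <- i
      while (j < n && ys[j + 1L] == ys[i]) j <- j + 1L
      apex <- (i + j) %/% 2L
      half <- ys[apex] / 2
      l <- apex; while (l > 1L && ys[l - 1L] > half) l <- l - 1L
      r <- apex; while (r < n && ys[r + 1L] > half) r <- r + 1L
      # linear interpolation of the half-height crossings
      xl <- if (l > 1L && ys[l - 1L] <= half && ys[l] > half) {
        s$mz[l - 1L] + (half - ys[l - 1L]) / (ys[l] - ys[l - 1L]) * (s$mz[l] - s$mz[l - 1L])
      } else s$mz[l]
      xr <- if (r < n && ys[r + 1L] <= half && ys[r] > half) {
        s$mz[r] + (ys[r] - half) / (ys[r] - ys[r + 1L]) * (s$mz[r + 1L] - s$mz[r])
      } else s$mz[r]
      sel <- l:r
      centroid <- sum(s$mz[sel] * ys[sel]) / sum(ys[sel])
      peaks[[length(peaks) + 1L]] <- c(centroid = centroid,
                                       height = ys[apex], fwhm = xr - xl)
      i <- r + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(peaks)) return(empty_peaklist())
  out <- as.data.frame(do.call(rbind, peaks))
  out <- out[order(out$centroid), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ms_peaklist", "data.frame")
  out
}

empty_peaklist <- function() {
  out <- data.frame(centroid = numeric(0), height = numeric(0), fwhm = numeric(0))
  class(out) <- c("ms_peaklist", "data.frame")
  out
}

# ---- composition masses -----------------------------------------------------

# Monoisotopic in-chain residue masses (Da), native and permethylated, from
# standard atomic masses (C 12, H 1.00782503, N 14.00307401, O 15.99491462;
# CH2 = 14.01565).
.CH2 <- 14.0156500
.H2O <- 18.0105646
.NA_ADDUCT <- 22.9892213  # Na+ (sodium minus one electron)
.H_ADDUCT <- 1.0072765    # proton
.RES_MASS_NATIVE <- c(Hex = 162.0528234, HexNAc = 203.0793725,
                      dHex = 146.0579088, NeuAc = 291.0954165,
                      Pen = 132.0422588)
# extra methyl groups per residue class upon permethylation
.PERM_CH2 <- c(Hex = 3, HexNAc = 3, dHex = 2, NeuAc = 5, Pen = 2)

#' Theoretical m/z of a glycan composition
#'
#' Singly charged ion of a released glycan: the sum of residue monoisotopic
#' masses (permethylated masses when requested), plus water, plus the two
#' extra methyls of a permethylated free reducing end, plus the adduct.
#'
#' @param counts named numeric vector of class counts, e.g.
#'   `c(Hex = 5, HexNAc = 2)`; a `glycan_composition` works.
#' @param derivatization `"permethylated"` or `"native"`.
#' @param adduct `"[M+Na]+"` or `"[M+H]+"`.
#' @return theoretical m/z (Th).
#' @examples
#' composition_mz(c(Hex = 5, HexNAc = 2)) # permethylated Man5GlcNAc2, sodiated
#' @export
composition_mz <- function(counts, derivatization = c("permethylated", "native"),
                           adduct = c("[M+Na]+", "[M+H]+")) {
  derivatization <- match.arg(derivatization)
  adduct <- match.arg(adduct)
  counts <- unclass(counts)
  bad <- setdiff(names(counts), names(.RES_MASS_NATIVE))
  if (length(bad)) stop("unknown composition class(es): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  res <- .RES_MASS_NATIVE[names(counts)]
  if (derivatization == "permethylated") {
    res <- res + .PERM_CH2[names(counts)] * .CH2
  }
  m <- sum(res * counts) + .H2O
  if (derivatization == "permethylated") m <- m + 2 * .CH2
  m + if (adduct == "[M+Na]+") .NA_ADDUCT else .H_ADDUCT
}

#' Annotate peak centroids with candidate glycan compositions
#'
#' Enumerates every composition within the per-class `bounds` whose
#' theoretical m/z falls within `tol_ppm` of a centroid.
#'
#' @param pl an `ms_peaklist` (or numeric vector of centroids).
#' @param tol_ppm mass tolerance in parts per million.
#' @inheritParams composition_mz
#' @param bounds named integer vector of per-class maxima.
#' @return list of annotated peaks: each has `centroid`, `height`, and a
#'   data.frame `candidates` (columns Hex, HexNAc, dHex, NeuAc, mz, ppm).
#' @export
annotate_compositions <- function(pl, tol_ppm = 20,
                                  derivatization = c("permethylated", "native"),
                                  adduct = c("[M+Na]+", "[M+H]+"),
                                  bounds = c(Hex = 12, HexNAc = 8, dHex = 3, NeuAc = 4)) {
  derivatization <- match.arg(derivatization)
  adduct <- match.arg(adduct)
  centroids <- if (is.numeric(pl)) pl else pl$centroid
  heights <- if (is.numeric(pl)) rep(NA_real_, length(pl)) else pl$height
  grid <- expand.grid(lapply(bounds, function(b) 0:b), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[rowSums(grid) >= 1L, , drop = FALSE]
  mzs <- apply(grid, 1L, function(row) {
    composition_mz(stats::setNames(as.numeric(row), names(bounds)),
                   derivatization, adduct)
  })
  lapply(seq_along(centroids), function(i) {
    ppm <- abs(mzs - centroids[i]) / centroids[i] * 1e6
    hit <- which(ppm <= tol_ppm)
    cand <- cbind(grid[hit, , drop = FALSE],
                  mz = mzs[hit], ppm = ppm[hit])
    cand <- cand[order(cand$ppm), , drop = FALSE]
    rownames(cand) <- NULL
    list(centroid = centroids[i], height = heights[i], candidates = cand)
  })
}

#' Generate a synthetic spectrum with known ground truth
#'
#' Gaussian peaks at the theoretical m/z of the supplied compositions, on a
#' smooth baseline with seeded Gaussian noise; stands in for raw MALDI-TOF
#' glycomics profiles when validating the processing pipeline.
#'
#' @param compositions list of named count vectors (see [composition_mz()]).
#' @param heights peak heights (recycled).
#' @param mz_range numeric length-2 m/z window.
#' @param step grid spacing (Th).
#' @param peak_sigma Gaussian peak width (Th).
#' @param baseline length-2 `c(intercept, slope)` of a linear baseline.
#' @param noise_sigma standard deviation of additive noise (same units as
#'   `heights`).
#' @param seed integer seed fixing the noise realization.
#' @inheritParams composition_mz
#' @return list with `spectrum` (an `ms_spectrum`) and `truth` (data.frame
#'   of composition, true m/z and height).
#' @export
synth_spectrum <- function(compositions, heights = 50,
                           mz_range = c(1500, 3250), step = 0.05,
                           peak_sigma = 0.15, baseline = c(5, -0.001),
                           noise_sigma = 1, seed = 1,
                           derivatization = c("permethylated", "native"),
                           adduct = c("[M+Na]+", "[M+H]+")) {
  derivatization <- match.arg(derivatization)
  adduct <- match.arg(adduct)
  heights <- rep_len(heights, length(compositions))
  mz_true <- vapply(compositions, composition_mz, 0, derivatization, adduct)
  if (any(diff(sort(mz_true)) < 4 * peak_sigma)) {
    warning("some compositions are closer than the peak resolution; ",
            "their peaks will overlap")
  }
  mz <- seq(mz_range[1], mz_range[2], by = step)
  signal <- baseline[1] + baseline[2] * (mz - mz_range[1])
  for (i in seq_along(mz_true)) {
    if (mz_true[i] < mz_range[1] || mz_true[i] > mz_range[2]) next
    signal <- signal + heights[i] * exp(-0.5 * ((mz - mz_true[i]) / peak_sigma)^2)
  }
  if (noise_sigma > 0) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
    set.seed(seed)
    signal <- signal + stats::rnorm(length(mz), 0, noise_sigma)
  }
  truth <- data.frame(
    composition = vapply(compositions, function(cc) {
      cc <- unclass(cc); cc <- cc[cc > 0]
      paste0(names(cc), cc, collapse = "")
    }, ""),
    mz = mz_true, height = heights)
  list(spectrum = new_spectrum(mz, pmax(signal, 0)), truth = truth)
}
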