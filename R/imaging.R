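# Synthetic two-channel well images (nuclear stain + Pax7) and a simple
# threshold/connected-component nucleus counter. Stands in for the
# commercial high-content imager so the ratio read-out can be exercised
# end to end.

#' Render a synthetic two-channel well image
#'
#' Places `n_nuclei` non-overlapping Gaussian blobs (unit peak amplitude,
#' spread `blob_sigma` pixels) on a square raster as the nuclear channel; a
#' random subset of `round(n_nuclei * pax7_fraction)` centers is also
#' rendered in the Pax7 channel. Gaussian read noise of sd `noise_sd` is
#' added to both channels. Centers are kept at least `6 * blob_sigma`
#' apart, guaranteeing separable components for the counter; densities too
#' high to place are an error.
#'
#' @param n_nuclei number of nuclei (>= 0).
#' @param pax7_fraction fraction of nuclei that are Pax7+ in `[0, 1]`.
#' @param blob_sigma Gaussian spread in pixels (default 2).
#' @param noise_sd additive noise sd relative to unit amplitude
#'   (default 0.02).
#' @param seed mandatory integer seed.
#' @param dim raster side length in pixels (default 192; about 100 nuclei
#'   fit at the default spread).
#' @return Object of class `well_image`: list with matrices `nuclear` and
#'   `pax7` and a `centers` data.frame (`x`, `y`, `pax7_pos`).
#' @export
render_well <- function(n_nuclei, pax7_fraction, blob_sigma = 2,
                        noise_sd = 0.02, seed, dim = 192L) {
  if (!is_count(n_nuclei, 0)) param_error("`n_nuclei` must be >= 0")
  if (pax7_fraction < 0 || pax7_fraction > 1)
    param_error("`pax7_fraction` must be in [0, 1]")
  if (missing(seed) || is.null(seed))
    param_error("`seed` is mandatory for the image generator")
  min_sep <- 6 * blob_sigma
  margin <- ceiling(3 * blob_sigma)
  with_seed(seed, {
    centers <- matrix(numeric(0), ncol = 2)
    tries <- 0L
    while (nrow(centers) < n_nuclei) {
      cand <- stats::runif(2, margin + 1, dim - margin)
      if (!nrow(centers) ||
          min(sqrt(colSums((t(centers) - cand)^2))) >= min_sep) {
        centers <- rbind(centers, cand)
      }
      tries <- tries + 1L
      if (tries > 200L * max(1L, n_nuclei))
        param_error(sprintf(
          "cannot place %d non-overlapping nuclei on a %dx%d raster",
          n_nuclei, dim, dim))
    }
    n_pax7 <- round(n_nuclei * pax7_fraction)
    pax7_pos <- rep(FALSE, n_nuclei)
    if (n_pax7 > 0) pax7_pos[sample(n_nuclei, n_pax7)] <- TRUE

    render <- function(which_centers) {
      img <- matrix(0, dim, dim)
      xs <- matrix(rep(seq_len(dim), dim), dim, dim)        # row index
      ys <- t(xs)                                           # column index
      if (length(which_centers)) for (i in which_centers) {
        img <- img + exp(-((xs - centers[i, 1])^2 +
                           (ys - centers[i, 2])^2) / (2 * blob_sigma^2))
      }
      img + matrix(rnorm(dim * dim, 0, noise_sd), dim, dim)
    }
    structure(list(
      nuclear = render(seq_len(n_nuclei)),
      pax7 = render(which(pax7_pos)),
      centers = if (n_nuclei) data.frame(x = centers[, 1], y = centers[, 2],
                                         pax7_pos = pax7_pos)
                else data.frame(x = numeric(), y = numeric(),
                                pax7_pos = logical())),
      class = "well_image")
  })
}

#' Otsu's automatic global threshold
#'
#' Maximizes between-class variance on a 256-bin histogram of the image.
#'
#' @param img numeric matrix.
#' @param n_bins histogram resolution (default 256).
#' @return Threshold on the intensity scale of `img`.
#' @export
otsu_threshold <- function(img, n_bins = 256L) {
  v <- as.numeric(img)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  sigma_b <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# 4-connected component labelling by iterative label propagation on the
# row/column-shifted mask; images are small (<= a few hundred px square).
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  repeat {
    nb <- lab
    n <- nrow(lab); m <- ncol(lab)
    nb[-1, ] <- pmax(nb[-1, ], lab[-n, ])
    nb[-n, ] <- pmax(nb[-n, ], lab[-1, ])
    nb[, -1] <- pmax(nb[, -1], lab[, -m])
    nb[, -m] <- pmax(nb[, -m], lab[, -1])
    nb[!mask] <- 0L
    if (identical(nb, lab)) break
    lab <- nb
  }
  ids <- sort(unique(lab[lab > 0]))
  lab[] <- match(lab, c(0L, ids)) - 1L
  lab
}

#' Count nuclei in a two-channel well image
#'
#' Thresholds the nuclear channel (Otsu by default), labels 4-connected
#' components, and counts components of at least `min_area` pixels as
#' nuclei. A component is Pax7+ when its mean Pax7-channel intensity
#' exceeds the Pax7 channel threshold. Both automatic thresholds are
#' floored at `median + 5 * mad` of their channel, so a signal-free
#' channel (pure read noise) yields zero detections instead of spurious
#' noise components; counting error is zero for non-overlapping blobs
#' whenever the noise sd stays below about a fifth of the blob amplitude.
#' A constant or near-saturated raster is flagged unmeasurable.
#'
#' @param image a `well_image` (or list with `nuclear` and `pax7`
#'   matrices).
#' @param threshold_policy `"otsu"` or a fixed numeric threshold applied
#'   to both channels.
#' @param min_area minimum component area in pixels (default 4).
#' @return list with `dapi_count`, `pax7_count`, and `measurable`
#'   (FALSE for blank/saturated rasters, with counts `NA`).
#' @export
count_nuclei <- function(image, threshold_policy = "otsu", min_area = 4L) {
  nuc <- image$nuclear
  pax <- image$pax7
  if (is.null(nuc) || is.null(pax))
    param_error("`image` must carry `nuclear` and `pax7` matrices")
  if (diff(range(nuc)) == 0 || mean(nuc >= max(nuc)) > 0.99)
    return(list(dapi_count = NA_integer_, pax7_count = NA_integer_,
                measurable = FALSE))
  auto_threshold <- function(img) max(otsu_threshold(img),
                                      stats::median(img) + 5 * stats::mad(img))
  thr_nuc <- if (identical(threshold_policy, "otsu")) auto_threshold(nuc)
             else as.numeric(threshold_policy)
  thr_pax <- if (identical(threshold_policy, "otsu")) auto_threshold(pax)
             else as.numeric(threshold_policy)
  lab <- label_components(nuc > thr_nuc)
  if (!any(lab > 0))
    return(list(dapi_count = 0L, pax7_count = 0L, measurable = TRUE))
  area <- tabulate(lab[lab > 0])
  keep <- which(area >= min_area)
  pax_mean <- vapply(keep, function(k) mean(pax[lab == k]), numeric(1))
  list(dapi_count = length(keep),
       pax7_count = sum(pax_mean > thr_pax),
       measurable = TRUE)
}

#' Write / read a well image as plain-text PGM
#'
#' Images are serialized as ASCII PGM (P2) rasters, one file per channel,
#' quantized to 16 bits over a fixed intensity window `[lo, hi]`. PGM is
#' used as the interchange raster format because it is plain text and
#' universally readable; intensities are restored on read as
#' `lo + v/65535 * (hi - lo)`.
#'
#' @param img numeric matrix.
#' @param path output file.
#' @param lo,hi intensity window mapped onto 0..65535 (defaults -0.5, 2).
#' @return `write_pgm` returns `path` invisibly; `read_pgm` returns the
#'   matrix.
#' @export
write_pgm <- function(img, path, lo = -0.5, hi = 2) {
  v <- pmin(pmax(as.numeric(t(img)), lo), hi)
  q <- as.integer(round((v - lo) / (hi - lo) * 65535))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2",
               sprintf("# muscscreen well image lo=%g hi=%g", lo, hi),
               sprintf("%d %d", ncol(img), nrow(img)), "65535"), con)
  writeLines(paste(q, collapse = " "), con)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  lines <- readLines(path)
  stopifnot(lines[1] == "P2")
  meta <- lines[2]
  lo <- -0.5; hi <- 2
  if (grepl("lo=", meta)) {
    lo <- as.numeric(sub(".*lo=([-0-9.eE+]+).*", "\\1", meta))
    hi <- as.numeric(sub(".*hi=([-0-9.eE+]+).*", "\\1", meta))
  }
  body <- lines[!startsWith(lines, "#")][-1]
  dims <- as.integer(strsplit(trimws(body[1]), "\\s+")[[1]])
  maxval <- as.numeric(body[2])
  vals <- as.numeric(unlist(strsplit(trimws(paste(body[-(1:2)],
                                                  collapse = " ")), "\\s+")))
  stopifnot(length(vals) == prod(dims))
  matrix(lo + vals / maxval * (hi - lo), nrow = dims[2], ncol = dims[1],
         byrow = TRUE)
}
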