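#' Similarity dimension of an exactly self-similar construction
#'
#' `D_S = -ln(N) / ln(r)` for an object made of `N` non-overlapping copies
#' of itself scaled by `r < 1`.
#'
#' @param N number of copies, integer `>= 1`.
#' @param r scaling ratio in `(0, 1)`.
#' @return The similarity dimension.
#' @examples
#' similarity_dimension(4, 1 / 3)  # Koch curve, ~1.2619
#' similarity_dimension(3, 1 / 2)  # Sierpinski triangle, ~1.5850
#' @export
similarity_dimension <- function(N, r) {
  if (N < 1 || N != round(N)) stop("N must be a positive integer")
  if (r <= 0 || r >= 1) stop("scaling ratio r must lie strictly between 0 and 1")
  -log(N) / log(r)
}

#' Box-counting dimension of a binary image
#'
#' Counts the non-empty boxes of an origin-anchored grid at each box size
#' and fits the dimension as the least-squares slope of `ln N(eps)` against
#' `ln(1/eps)`.  Box sizes larger than a quarter of the image side are
#' excluded from the fit (boundary saturation); the excluded sizes are still
#' reported in the counts.
#'
#' @param image logical or 0/1 matrix; must contain at least one foreground
#'   pixel.
#' @param box_sizes integer box edge lengths in pixels; at least 3 distinct
#'   fitted sizes are required.  Default: dyadic sizes up to a quarter of
#'   the shorter side.
#' @return List with `counts` (data.frame eps, N), `dimension`, `r_squared`,
#'   and `fitted_sizes`.
#' @examples
#' sq <- matrix(1L, 64, 64)
#' box_count(sq)$dimension  # 2 for a filled square
#' @export
box_count <- function(image, box_sizes = NULL) {
  img <- (as.matrix(image) != 0)
  fg <- which(img, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("box counting needs at least one foreground pixel")
  side <- max(dim(img))
  if (is.null(box_sizes)) {
    box_sizes <- 2^(0:floor(log2(side / 4)))
  }
  box_sizes <- sort(unique(as.integer(box_sizes)))
  if (any(box_sizes < 1)) stop("box sizes must be at least 1 pixel")
  counts <- vapply(box_sizes, function(e) {
    bi <- (fg[, 1] - 1L) %/% e
    bj <- (fg[, 2] - 1L) %/% e
    length(unique(bi * (max(bj) + 1) + bj))
  }, numeric(1))
  fit_mask <- box_sizes <= side / 4
  if (sum(fit_mask) < 3)
    stop("at least 3 distinct box sizes within a quarter of the image side are required")
  lx <- log(1 / box_sizes[fit_mask])
  ly <- log(counts[fit_mask])
  fit <- lsfit(lx, ly)
  slope <- unname(fit$coefficients[2])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ly - mean(ly))^2)
  list(counts = data.frame(eps = box_sizes, N = counts),
       dimension = slope,
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
       fitted_sizes = box_sizes[fit_mask])
}

# shifted copies of a matrix over a (2k+1) window with replicate padding
.window_offsets <- function(k) {
  expand.grid(di = -k:k, dj = -k:k)
}

.shift_pad <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + di, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dj, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# window aggregate over all offsets of an eps x eps window (eps = 2k+1)
.window_measure <- function(img, k, measure, quantum) {
  off <- .window_offsets(k)
  acc <- NULL
  for (w in seq_len(nrow(off))) {
    s <- .shift_pad(img, off$di[w], off$dj[w])
    acc <- switch(measure,
      sum = if (is.null(acc)) s else acc + s,
      max = if (is.null(acc)) s else pmax(acc, s),
      min = if (is.null(acc)) s else pmin(acc, s),
      iso = {
        hit <- (abs(s - img) <= quantum) * 1
        if (is.null(acc)) hit else acc + hit
      })
  }
  acc
}

#' Holder exponent (alpha) image of a grayscale image
#'
#' Estimates the local singularity strength at every pixel as the
#' least-squares slope of `ln mu_eps` against `ln eps` over a set of square
#' windows, where `mu_eps` is the chosen capacity measure of the
#' `eps x eps` window centered on the pixel: `sum`, `max` or `min` of the
#' intensities, or `iso` (count of pixels within one intensity quantum of
#' the center value).  Windows use replicate padding at the image border.
#' Zero measures are floored at one intensity quantum before taking logs so
#' that alpha stays finite on digital images.
#'
#' @param image numeric matrix of nonnegative intensities.
#' @param measure one of `"sum"`, `"max"`, `"min"`, `"iso"`.
#' @param radii odd window edge lengths (`eps`), at least two.
#' @param quantum intensity quantum used for flooring and for the `iso`
#'   tolerance; default: the smallest positive intensity in the image.
#' @return An object of class `alpha_image`: list with `alpha` (matrix),
#'   `measure`, `radii`, `alpha_min`, `alpha_max`.
#' @examples
#' a <- holder_alpha(matrix(1, 32, 32), measure = "sum")
#' range(a$alpha)  # exactly 2 for a constant image
#' @export
holder_alpha <- function(image, measure = c("sum", "max", "min", "iso"),
                         radii = c(1, 3, 5, 7), quantum = NULL) {
  measure <- match.arg(measure)
  img <- as.matrix(image)
  if (any(img < 0)) stop("image intensities must be nonnegative")
  radii <- sort(unique(as.integer(radii)))
  if (length(radii) < 2) stop("at least 2 window sizes are required")
  if (any(radii %% 2 != 1)) stop("window sizes must be odd (centered windows)")
  if (is.null(quantum)) {
    pos <- img[img > 0]
    quantum <- if (length(pos)) min(pos) else 1
  }
  lmu <- lapply(radii, function(eps) {
    k <- (eps - 1L) %/% 2L
    mu <- if (k == 0L) {
      switch(measure, sum = img, max = img, min = img,
             iso = matrix(1, nrow(img), ncol(img)))
    } else .window_measure(img, k, measure, quantum)
    log(pmax(mu, quantum))
  })
  le <- log(radii)
  lec <- le - mean(le)
  denom <- sum(lec^2)
  alpha <- Reduce(`+`, Map(function(lm_, w) lm_ * w, lmu, lec / denom))
  support <- img > 0
  asup <- if (any(support)) alpha[support] else alpha
  structure(list(alpha = alpha, support = support, measure = measure,
                 radii = radii, alpha_min = min(asup), alpha_max = max(asup)),
            class = "alpha_image")
}

#' @export
print.alpha_image <- function(x, ...) {
  cat("<alpha_image> ", paste(dim(x$alpha), collapse = " x "),
      ", measure ", x$measure, ", alpha in [",
      format(x$alpha_min), ", ", format(x$alpha_max), "]\n", sep = "")
  invisible(x)
}

#' Multifractal f(alpha) spectrum
#'
#' Partitions the alpha range of an alpha-image into bins and computes the
#' box-counting dimension of each alpha-level pixel set; bins holding fewer
#' pixels than the noise threshold are dropped (noise adjustment for digital
#' images).  Only pixels in the support of the intensity measure (positive
#' intensity) enter the level sets, so the spectrum characterizes the
#' measure rather than the zero-intensity background.
#'
#' @param alpha_img an [holder_alpha()] result.
#' @param n_bins number of alpha bins, `>= 2` (a degenerate constant image
#'   collapses to a single bin).
#' @param noise_threshold minimum fraction of pixels a bin must hold to be
#'   evaluated (default 0.1%).
#' @return A data.frame of class `multifractal_spectrum` with columns
#'   `alpha` (bin center), `f_alpha`, `n_pixels`.
#' @export
multifractal_spectrum <- function(alpha_img, n_bins = 20, noise_threshold = 0.001) {
  stopifnot(inherits(alpha_img, "alpha_image"))
  if (n_bins < 2) stop("n_bins must be at least 2")
  a <- alpha_img$alpha
  sup <- alpha_img$support
  if (!any(sup)) stop("the alpha image has an empty support")
  lo <- alpha_img$alpha_min; hi <- alpha_img$alpha_max
  npx <- sum(sup)
  if (hi - lo < .Machine$double.eps * max(1, abs(hi))) {
    bc <- box_count(sup)
    out <- data.frame(alpha = lo, f_alpha = bc$dimension, n_pixels = npx)
    class(out) <- c("multifractal_spectrum", "data.frame")
    return(out)
  }
  edges <- seq(lo, hi, length.out = n_bins + 1)
  bin <- findInterval(a, edges, rightmost.closed = TRUE, all.inside = TRUE)
  bin[!sup] <- NA_integer_
  keep <- which(tabulate(bin[sup], n_bins) >= max(1, noise_threshold * npx))
  if (length(keep) == 0) stop("all alpha bins fall below the noise threshold")
  rows <- lapply(keep, function(b) {
    mask <- matrix(!is.na(bin) & bin == b, nrow(a), ncol(a))
    dim_b <- tryCatch(box_count(mask)$dimension, error = function(e) NA_real_)
    data.frame(alpha = (edges[b] + edges[b + 1]) / 2, f_alpha = dim_b,
               n_pixels = sum(mask))
  })
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$f_alpha), , drop = FALSE]
  class(out) <- c("multifractal_spectrum", "data.frame")
  out
}

# ---- fixture generators -----------------------------------------------------

# rasterize segments (x0,y0,x1,y1 in pixel units) onto a nr x nc canvas
.rasterize_segments <- function(seg, nr, nc) {
  img <- matrix(0L, nr, nc)
  for (s in seq_len(nrow(seg))) {
    len <- sqrt((seg$x1[s] - seg$x0[s])^2 + (seg$y1[s] - seg$y0[s])^2)
    npt <- max(2L, ceiling(len * 2))
    tt <- seq(0, 1, length.out = npt)
    xs <- round(seg$x0[s] + tt * (seg$x1[s] - seg$x0[s]))
    ys <- round(seg$y0[s] + tt * (seg$y1[s] - seg$y0[s]))
    xs <- pmin(pmax(xs, 1), nc)
    ys <- pmin(pmax(ys, 1), nr)
    img[cbind(ys, xs)] <- 1L
  }
  img
}

.koch_segments <- function(depth) {
  seg <- data.frame(x0 = 0, y0 = 0, x1 = 1, y1 = 0)
  for (d in seq_len(depth)) {
    out <- vector("list", nrow(seg))
    for (s in seq_len(nrow(seg))) {
      p0 <- c(seg$x0[s], seg$y0[s]); p1 <- c(seg$x1[s], seg$y1[s])
      v <- (p1 - p0) / 3
      a <- p0 + v; b <- p0 + 2 * v
      # peak of the equilateral bump (rotate v by -60 degrees: y grows downward)
      rot <- c(v[1] * 0.5 + v[2] * sqrt(3) / 2, -v[1] * sqrt(3) / 2 + v[2] * 0.5)
      peak <- a + rot
      out[[s]] <- data.frame(
        x0 = c(p0[1], a[1], peak[1], b[1]),
        y0 = c(p0[2], a[2], peak[2], b[2]),
        x1 = c(a[1], peak[1], b[1], p1[1]),
        y1 = c(a[2], peak[2], b[2], p1[2]))
    }
    seg <- do.call(rbind, out)
  }
  seg
}

.fractal_tree_segments <- function(depth, ratio = 0.7, angle = 25) {
  ang <- angle * pi / 180
  segs <- list()
  grow <- function(x, y, len, theta, d) {
    x1 <- x + len * sin(theta); y1 <- y - len * cos(theta)
    segs[[length(segs) + 1L]] <<- c(x, y, x1, y1)
    if (d > 0) {
      grow(x1, y1, len * ratio, theta - ang, d - 1)
      grow(x1, y1, len * ratio, theta + ang, d - 1)
    }
  }
  grow(0, 0, 1, 0, depth)
  m <- do.call(rbind, segs)
  data.frame(x0 = m[, 1], y0 = m[, 2], x1 = m[, 3], y1 = m[, 4])
}

#' Generate fractal and synthetic test images
#'
#' Deterministic rasterizers for classic fractal constructions plus a seeded
#' smooth random texture:
#' * `koch`: the Koch curve at `depth` refinements, rasterized at
#'   `3^depth + 1` pixels base width (one pixel per elementary segment);
#' * `sierpinski`: the Sierpinski (right-triangle) gasket on a
#'   `2^depth` grid, exactly self-similar under dyadic boxes;
#' * `filled_square`, `line`: Euclidean controls;
#' * `fractal_tree`: recursive two-branch tree (`2^(depth+1) - 1` segments)
#'   with configurable branch `ratio` and `angle`;
#' * `blob_texture`: grayscale sum of seeded Gaussian blobs.
#'
#' @param kind one of `"koch"`, `"sierpinski"`, `"filled_square"`, `"line"`,
#'   `"fractal_tree"`, `"blob_texture"`.
#' @param depth recursion depth (`>= 0`) for the fractal kinds.
#' @param size image side for the non-recursive kinds.
#' @param seed RNG seed for `blob_texture`.
#' @param ratio,angle fractal-tree branch length ratio and half-angle
#'   (degrees).
#' @return A 0/1 integer matrix (binary kinds) or numeric matrix
#'   (`blob_texture`); attribute `n_segments` is set for rasterized curve
#'   kinds.
#' @examples
#' k <- generate_fixture("koch", depth = 3)
#' attr(k, "n_segments")  # 4^3
#' @export
generate_fixture <- function(kind, depth = 5, size = 256, seed = 1,
                             ratio = 0.7, angle = 25) {
  if (depth < 0) stop("depth must be nonnegative")
  switch(kind,
    koch = {
      seg <- .koch_segments(depth)
      w <- 3^depth
      nc <- w + 1L
      nr <- max(2L, ceiling(w * sqrt(3) / 6) + 2L)
      seg2 <- data.frame(x0 = seg$x0 * w + 1, y0 = nr - 1 + seg$y0 * w,
                         x1 = seg$x1 * w + 1, y1 = nr - 1 + seg$y1 * w)
      img <- .rasterize_segments(seg2, nr, nc)
      attr(img, "n_segments") <- nrow(seg)
      img
    },
    sierpinski = {
      n <- 2^depth
      img <- outer(0:(n - 1), 0:(n - 1),
                   function(i, j) as.integer(bitwAnd(i, j) == 0L))
      img
    },
    filled_square = matrix(1L, size, size),
    line = {
      img <- matrix(0L, size, size)
      img[size %/% 2, ] <- 1L
      img
    },
    fractal_tree = {
      seg <- .fractal_tree_segments(depth, ratio, angle)
      # total vertical extent <= 1/(1-ratio); scale into a square canvas
      ext <- 1 / (1 - min(ratio, 0.95))
      scale <- (size - 2) / (2 * ext)
      seg2 <- data.frame(x0 = size / 2 + seg$x0 * scale,
                         y0 = size - 1 + seg$y0 * scale,
                         x1 = size / 2 + seg$x1 * scale,
                         y1 = size - 1 + seg$y1 * scale)
      img <- .rasterize_segments(seg2, size, size)
      attr(img, "n_segments") <- nrow(seg)
      img
    },
    blob_texture = {
      set.seed(seed)
      img <- matrix(0, size, size)
      xs <- row(img); ys <- col(img)
      for (b in seq_len(25)) {
        cx <- runif(1, 1, size); cy <- runif(1, 1, size)
        s <- runif(1, size / 40, size / 8); amp <- runif(1, 0.2, 1)
        img <- img + amp * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * s^2))
      }
      img / max(img)
    },
    stop(sprintf("unknown fixture kind '%s'", kind)))
}

#' Read and write images for fractal analysis
#'
#' Grayscale PNG/TIFF round-trip helpers; multi-channel images are averaged
#' to one channel on read.
#'
#' @param path file path ending in `.png` or `.tif`/`.tiff`.
#' @param image numeric matrix in `[0, 1]` (values are clipped).
#' @return `read_image()`: a numeric matrix; `write_image()`: `path`,
#'   invisibly.
#' @export
read_image <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
         else tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- apply(img[, , seq_len(min(3, dim(img)[3])), drop = FALSE], c(1, 2), mean)
  img
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  img <- pmin(pmax(image, 0), 1)
  if (grepl("\\.png$", path, ignore.case = TRUE)) png::writePNG(img, path)
  else tiff::writeTIFF(img, path)
  invisible(path)
}
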