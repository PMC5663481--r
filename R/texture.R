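#' Haralick texture features of a masked image
#'
#' Gray-level co-occurrence statistics at distance 1 over the 4 standard
#' directions (0, 45, 90, 135 degrees). Intensities inside the mask are
#' quantized to `levels` gray levels between the object's min and max
#' (a fixed convention making the features invariant to affine intensity
#' changes); only pixel pairs with both members inside the mask are
#' counted, symmetrically. Thirteen classic statistics are computed per
#' direction and reported as the direction mean and direction range
#' (max - min) of each, 26 values. Degenerate masks with no valid pair
#' return all zeros.
#'
#' @param img numeric matrix.
#' @param mask logical matrix, same shape.
#' @param levels number of gray levels (default 64).
#' @return named numeric vector of 26 values
#'   (`h_<stat>_mean`, `h_<stat>_range`).
#' @export
haralick_features <- function(img, mask, levels = 64L) {
  stat_names <- c("asm", "contrast", "correlation", "variance",
                  "homogeneity", "sum_average", "sum_variance",
                  "sum_entropy", "entropy", "diff_variance", "diff_entropy",
                  "imc1", "imc2")
  out0 <- stats::setNames(numeric(26),
                          c(paste0("h_", stat_names, "_mean"),
                            paste0("h_", stat_names, "_range")))
  v <- img[mask]
  if (length(v) < 2) return(out0)
  lo <- min(v); hi <- max(v)
  q <- matrix(0L, nrow(img), ncol(img))
  if (hi > lo) {
    q[mask] <- pmin(as.integer(floor((img[mask] - lo) / (hi - lo) * levels)) + 1L,
                    as.integer(levels))
  } else {
    q[mask] <- 1L
  }
  dirs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  per_dir <- matrix(NA_real_, 4, 13)
  for (d in seq_along(dirs)) {
    g <- glcm_symmetric(q, dirs[[d]][1], dirs[[d]][2], levels)
    if (!is.null(g)) per_dir[d, ] <- haralick_stats(g)
  }
  ok <- stats::complete.cases(per_dir)
  if (!any(ok)) return(out0)
  per_dir <- per_dir[ok, , drop = FALSE]
  out0[1:13] <- colMeans(per_dir)
  out0[14:26] <- apply(per_dir, 2, max) - apply(per_dir, 2, min)
  out0
}

# symmetric co-occurrence matrix for offset (dx, dy) on quantized labels
# (0 = outside mask); NULL when no valid pair exists
glcm_symmetric <- function(q, dx, dy, levels) {
  nr <- nrow(q); nc <- ncol(q)
  if (dx > 0) { xa <- seq_len(nr - dx); xb <- xa + dx }
  else if (dx < 0) { xa <- seq(1 - dx, nr); xb <- xa + dx }
  else { xa <- xb <- seq_len(nr) }
  if (dy > 0) { ya <- seq_len(nc - dy); yb <- ya + dy }
  else if (dy < 0) { ya <- seq(1 - dy, nc); yb <- ya + dy }
  else { ya <- yb <- seq_len(nc) }
  a <- q[xa, ya]; b <- q[xb, yb]
  sel <- a > 0L & b > 0L
  if (!any(sel)) return(NULL)
  a <- a[sel]; b <- b[sel]
  g <- matrix(0, levels, levels)
  tab <- table(factor(a, levels = seq_len(levels)),
               factor(b, levels = seq_len(levels)))
  g <- unclass(tab) + t(unclass(tab))
  g / sum(g)
}

haralick_stats <- function(p) {
  L <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(L) * px); muy <- sum(seq_len(L) * py)
  sx <- sqrt(sum((seq_len(L) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(L) - muy)^2 * py))
  asm <- sum(p^2)
  contrast <- sum((i - j)^2 * p)
  correlation <- if (sx > 0 && sy > 0) (sum(i * j * p) - mux * muy) / (sx * sy) else 0
  variance <- sum((i - mux)^2 * p)
  homogeneity <- sum(p / (1 + (i - j)^2))
  # p_{x+y}(k), k = 2..2L ; p_{x-y}(k), k = 0..L-1
  k_sum <- as.numeric(tapply(p, i + j, sum))
  ks <- sort(unique(as.numeric(i + j)))
  sum_average <- sum(ks * k_sum)
  sum_variance <- sum((ks - sum_average)^2 * k_sum)
  sum_entropy <- -sum(ifelse(k_sum > 0, k_sum * log2(k_sum), 0))
  entropy <- -sum(ifelse(p > 0, p * log2(p), 0))
  k_diff <- as.numeric(tapply(p, abs(i - j), sum))
  kd <- sort(unique(as.numeric(abs(i - j))))
  mu_d <- sum(kd * k_diff)
  diff_variance <- sum((kd - mu_d)^2 * k_diff)
  diff_entropy <- -sum(ifelse(k_diff > 0, k_diff * log2(k_diff), 0))
  hx <- -sum(ifelse(px > 0, px * log2(px), 0))
  hy <- -sum(ifelse(py > 0, py * log2(py), 0))
  pxy <- outer(px, py)
  hxy1 <- -sum(p[pxy > 0] * log2(pxy[pxy > 0]))
  hxy2 <- -sum(ifelse(pxy > 0, pxy * log2(pxy), 0))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - entropy)), 0))
  c(asm, contrast, correlation, variance, homogeneity, sum_average,
    sum_variance, sum_entropy, entropy, diff_variance, diff_entropy,
    imc1, imc2)
}

#' Rotation-invariant uniform local binary pattern histogram
#'
#' For each masked pixel whose circular neighborhood lies inside the
#' image, `points` samples on a circle of `radius` pixels are bilinearly
#' interpolated and compared (>=) to the center. Patterns with at most
#' two 0/1 transitions are "uniform" and binned by their number of set
#' bits (0..points); all others share one extra bin, giving `points + 2`
#' bins. The histogram is normalized to sum 1 (all zeros if no pixel
#' qualifies). Comparing signs only makes the histogram invariant to
#' positive intensity scaling.
#'
#' @param img numeric matrix.
#' @param mask logical matrix.
#' @param radius circle radius in pixels.
#' @param points number of samples on the circle.
#' @return numeric vector of `points + 2` bin frequencies.
#' @export
lbp_histogram <- function(img, mask, radius = 1, points = 8L) {
  nb <- points + 2L
  out <- stats::setNames(numeric(nb),
                         c(paste0("u", 0:points), "nonuniform"))
  nr <- nrow(img); nc <- ncol(img)
  m <- ceiling(radius)
  if (nr < 2 * m + 1 || nc < 2 * m + 1) return(out)
  xs <- (m + 1):(nr - m); ys <- (m + 1):(nc - m)
  sel <- which(mask[xs, ys, drop = FALSE], arr.ind = TRUE)
  if (nrow(sel) == 0) return(out)
  cx <- xs[sel[, 1]]; cy <- ys[sel[, 2]]
  center <- img[cbind(cx, cy)]
  ang <- 2 * pi * (0:(points - 1)) / points
  bits <- matrix(FALSE, length(cx), points)
  for (k in seq_len(points)) {
    px <- cx + radius * cos(ang[k])
    py <- cy + radius * sin(ang[k])
    x0 <- floor(px); y0 <- floor(py)
    fx <- px - x0; fy <- py - y0
    v <- img[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
      img[cbind(pmin(x0 + 1, nr), y0)] * fx * (1 - fy) +
      img[cbind(x0, pmin(y0 + 1, nc))] * (1 - fx) * fy +
      img[cbind(pmin(x0 + 1, nr), pmin(y0 + 1, nc))] * fx * fy
    # tolerant >=: bilinear weights may sum to 1 only up to rounding
    bits[, k] <- v - center >= -1e-9 * (1 + abs(center))
  }
  trans <- rowSums(bits != bits[, c(2:points, 1), drop = FALSE])
  bin <- ifelse(trans <= 2, rowSums(bits), points + 1L)
  h <- tabulate(bin + 1L, nbins = nb)
  out[] <- h / sum(h)
  out
}

# (n, m) index pairs for Zernike magnitudes up to a given degree
zernike_orders <- function(degree = 8L) {
  do.call(rbind, lapply(0:degree, function(n) {
    m <- seq(n %% 2, n, by = 2)
    cbind(n = n, m = m)
  }))
}

#' Zernike moment magnitudes of a masked intensity image
#'
#' Magnitudes of the complex Zernike moments up to `degree` (25 values
#' for degree 8), computed on the intensity distribution inside the mask
#' after normalizing it to unit total, over the disk circumscribing the
#' mask (center = mask centroid, radius = half the larger bounding-box
#' side). Magnitudes are invariant to rotation and, through the
#' normalization, to positive intensity scaling. A mask with zero total
#' intensity returns all zeros.
#'
#' @param img numeric matrix.
#' @param mask logical matrix.
#' @param degree maximal polynomial degree (default 8).
#' @return named numeric vector (`z_<n>_<m>`).
#' @export
zernike_magnitudes <- function(img, mask, degree = 8L) {
  ord <- zernike_orders(degree)
  out <- stats::setNames(numeric(nrow(ord)),
                         sprintf("z_%d_%d", ord[, "n"], ord[, "m"]))
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(out)
  w <- pmax(img[idx], 0)
  tot <- sum(w)
  if (tot <= 0) return(out)
  w <- w / tot
  cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
  bw <- diff(range(idx[, 1])) + 1
  bh <- diff(range(idx[, 2])) + 1
  r0 <- max(bw, bh) / 2
  x <- (idx[, 1] - cx) / r0
  y <- (idx[, 2] - cy) / r0
  rho <- sqrt(x^2 + y^2)
  inside <- rho <= 1
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]; rho <- rho[inside]; w <- w[inside]
  theta <- atan2(y, x)
  for (k in seq_len(nrow(ord))) {
    n <- ord[k, "n"]; m <- ord[k, "m"]
    rad <- zernike_radial(rho, n, m)
    re <- sum(w * rad * cos(m * theta))
    im <- sum(w * rad * sin(m * theta))
    out[k] <- (n + 1) / pi * sqrt(re^2 + im^2)
  }
  out
}

zernike_radial <- function(rho, n, m) {
  s <- 0:((n - m) / 2)
  coef <- (-1)^s * factorial(n - s) /
    (factorial(s) * factorial((n + m) / 2 - s) * factorial((n - m) / 2 - s))
  out <- numeric(length(rho))
  for (i in seq_along(s)) out <- out + coef[i] * rho^(n - 2 * s[i])
  out
}
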