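# Shared numerical helpers: quaternion algebra, rotation construction,
# uniform resampling, and a small fully-connected network used by the
# time-series regression family.

#' Standard gravitational acceleration (m/s^2)
#'
#' Conversion constant between accelerometer g units and m/s^2.
#' @export
GRAVITY <- 9.80665

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quaternion product
#'
#' Hamilton product of two unit quaternions stored as `c(w, x, y, z)`.
#' @param p,q numeric length-4 quaternions.
#' @return numeric length-4 quaternion `p %q% q`.
#' @keywords internal
quat_multiply <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n < .Machine$double.eps) stop("cannot normalize a zero quaternion")
  q / n
}

quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' Rotation matrix from a unit quaternion
#'
#' Returns the 3x3 matrix mapping sensor-frame vectors to world-frame
#' vectors for a sensor-to-world quaternion `c(w, x, y, z)`.
#' @param q unit quaternion.
#' @return 3x3 orthonormal matrix with determinant +1.
#' @keywords internal
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Minimal rotation between two unit vectors, as a quaternion
#'
#' @param u,v unit 3-vectors; returns q with R(q) u = v and zero rotation
#'   about the u-v plane normal (shortest arc).
#' @keywords internal
quat_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  d <- sum(u * v)
  if (d > 1 - 1e-12) return(c(1, 0, 0, 0))
  if (d < -1 + 1e-12) {
    # antipodal: rotate pi about any axis orthogonal to u
    ax <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- ax - sum(ax * u) * u
    ax <- ax / sqrt(sum(ax^2))
    return(c(0, ax))
  }
  axis <- c(u[2] * v[3] - u[3] * v[2],
            u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
  w <- sqrt((1 + d) / 2)
  quat_normalize(c(w, axis / (2 * w)))
}

#' Rotation matrix about a coordinate axis
#' @param axis one of "x", "y", "z".
#' @param angle rotation angle in radians (right-handed).
#' @keywords internal
rotation_about <- function(axis = c("x", "y", "z"), angle) {
  axis <- match.arg(axis)
  ca <- cos(angle); sa <- sin(angle)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, ca, -sa, 0, sa, ca), 3, byrow = TRUE),
    y = matrix(c(ca, 0, sa, 0, 1, 0, -sa, 0, ca), 3, byrow = TRUE),
    z = matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, byrow = TRUE))
}

is_rotation_matrix <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol &&
    abs(det(R) - 1) < tol
}

#' Resample a series to a fixed number of points
#'
#' Linear interpolation onto a uniform grid spanning the full series,
#' endpoints included. Used to place stance signals on a normalized
#' 0--100% stance time base and back.
#' @param x numeric vector (length >= 2).
#' @param n_out number of output samples.
#' @return numeric vector of length `n_out`.
#' @export
resample_series <- function(x, n_out) {
  if (length(x) < 2) stop("need at least 2 samples to resample")
  if (n_out < 2) stop("n_out must be >= 2")
  stats::approx(seq(0, 1, length.out = length(x)), x,
                xout = seq(0, 1, length.out = n_out))$y
}

# ---- minimal multilayer perceptron (tanh hidden layers, linear output) ----
# Trained full-batch with Adam on mean squared error. Deliberately small and
# dependency-free; deterministic for a fixed seed.

mlp_init <- function(n_in, hidden, n_out, seed) {
  set.seed(seed)
  sizes <- c(n_in, hidden, n_out)
  lapply(seq_len(length(sizes) - 1), function(i) {
    sd <- sqrt(1 / sizes[i])
    list(W = matrix(stats::rnorm(sizes[i] * sizes[i + 1], sd = sd),
                    sizes[i], sizes[i + 1]),
         b = rep(0, sizes[i + 1]))
  })
}

mlp_forward <- function(layers, X) {
  acts <- vector("list", length(layers) + 1)
  acts[[1]] <- X
  n_layers <- length(layers)
  for (i in seq_len(n_layers)) {
    Z <- sweep(acts[[i]] %*% layers[[i]]$W, 2, layers[[i]]$b, "+")
    acts[[i + 1]] <- if (i < n_layers) tanh(Z) else Z
  }
  acts
}

#' Fit a small fully connected network by full-batch Adam
#'
#' @param X numeric matrix of inputs (rows = cases).
#' @param Y numeric matrix of targets.
#' @param hidden integer vector of hidden-layer widths.
#' @param epochs number of full-batch updates.
#' @param lr Adam step size.
#' @param seed integer seed controlling weight initialization.
#' @return list of layers with trained weights plus training diagnostics.
#' @keywords internal
mlp_fit <- function(X, Y, hidden = c(32, 32), epochs = 300, lr = 0.01,
                    seed = 1L) {
  stopifnot(nrow(X) == nrow(Y))
  layers <- mlp_init(ncol(X), hidden, ncol(Y), seed)
  mom <- lapply(layers, function(l) list(mW = 0 * l$W, vW = 0 * l$W,
                                         mb = 0 * l$b, vb = 0 * l$b))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  n <- nrow(X)
  loss <- NA_real_
  for (epoch in seq_len(epochs)) {
    acts <- mlp_forward(layers, X)
    pred <- acts[[length(acts)]]
    delta <- 2 * (pred - Y) / (n * ncol(Y))    # d MSE / d output
    loss <- mean((pred - Y)^2)
    for (i in rev(seq_along(layers))) {
      gW <- crossprod(acts[[i]], delta)
      gb <- colSums(delta)
      if (i > 1) {
        delta <- (delta %*% t(layers[[i]]$W)) * (1 - acts[[i]]^2)
      }
      m <- mom[[i]]
      m$mW <- b1 * m$mW + (1 - b1) * gW
      m$vW <- b2 * m$vW + (1 - b2) * gW^2
      m$mb <- b1 * m$mb + (1 - b1) * gb
      m$vb <- b2 * m$vb + (1 - b2) * gb^2
      mom[[i]] <- m
      corr1 <- 1 - b1^epoch; corr2 <- 1 - b2^epoch
      layers[[i]]$W <- layers[[i]]$W -
        lr * (m$mW / corr1) / (sqrt(m$vW / corr2) + eps)
      layers[[i]]$b <- layers[[i]]$b -
        lr * (m$mb / corr1) / (sqrt(m$vb / corr2) + eps)
    }
  }
  list(layers = layers, final_loss = loss, epochs = epochs, seed = seed)
}

mlp_predict <- function(fit, X) {
  acts <- mlp_forward(fit$layers, X)
  acts[[length(acts)]]
}

# run-length aware local maxima: strictly greater than both neighbouring
# *distinct* values; a plateau is represented by its first sample.
local_maxima <- function(x) {
  r <- rle(x)
  v <- r$values
  k <- length(v)
  if (k == 0) return(integer(0))
  starts <- cumsum(c(1, r$lengths[-k]))
  is_max <- logical(k)
  if (k >= 3) {
    mid <- 2:(k - 1)
    is_max[mid] <- v[mid] > v[mid - 1] & v[mid] > v[mid + 1]
  }
  starts[is_max]
}
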