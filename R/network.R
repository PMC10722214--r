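# Network model of inter-cellular coupling: orientation-weighted bonds in
# four undirected directions per node (+x, +y, +x+y, +x-y), with
# fibrosis-specific random connection removal.
#
# Bond weights are stored at the lower endpoint of each bond in an n x 4
# matrix (node id = x + nx * (y - 1), column-major like an R matrix), with
# zeros for absent (boundary or removed) bonds.  Boundaries are no-flux.

.bond_dirs <- list(
  c(1, 0),   # +x
  c(0, 1),   # +y
  c(1, 1),   # +x +y (diagonal)
  c(1, -1)   # +x -y (diagonal)
)
.bond_angles <- c(0, pi / 2, pi / 4, -pi / 4)

#' Build an orientation-weighted connection map
#'
#' For each node and each of the four bond directions (angle `phi`), the
#' nodal weight is `(g_a cos^2(delta) + g_t sin^2(delta)) * cos^2(2 delta)`
#' where `delta = theta - phi` is the angle between the local fibre
#' orientation and the bond.  The `cos^2(2 delta)` selection factor makes
#' exactly two of the four directions non-zero when the fibre points along
#' an axis or diagonal (the aligned direction carries `g_a`, the
#' perpendicular one `g_t`), while intermediate orientations engage all four
#' directions.  Diagonal bonds carry an additional `1/sqrt(2)` geometric
#' correction for their longer internodal distance.  The stored bond weight
#' is the mean of the two endpoint evaluations, which makes the map
#' symmetric by construction.
#'
#' @param orient an [make_orientation()] field.
#' @param g_a axial coupling strength (nS/pF).
#' @param anisotropy_ratio axial-to-transverse coupling ratio; the
#'   transverse strength is `g_t = g_a / anisotropy_ratio`.
#' @param dx inter-nodal spacing (mm), carried as metadata.
#' @return a `connection_map`: list with the n x 4 weight matrix `w`,
#'   geometry, `g_a`, `g_t` and the orientation field.
#' @export
build_connection_map <- function(orient, g_a = 1.28, anisotropy_ratio = 7,
                                 dx = 0.3125) {
  stopifnot(inherits(orient, "orientation_field"), g_a >= 0,
            anisotropy_ratio > 0)
  nx <- orient$nx
  ny <- orient$ny
  g_t <- g_a / anisotropy_ratio
  theta <- orient$theta
  n <- nx * ny
  w <- matrix(0, n, 4)
  for (k in 1:4) {
    delta <- theta - .bond_angles[k]
    node_w <- (g_a * cos(delta)^2 + g_t * sin(delta)^2) * cos(2 * delta)^2
    if (k >= 3) node_w <- node_w / sqrt(2)
    # clean up floating noise so exactly-aligned fields give exact zeros
    node_w[abs(node_w) < 1e-12] <- 0
    bond <- matrix(0, nx, ny)
    ox <- .bond_dirs[[k]][1]
    oy <- .bond_dirs[[k]][2]
    xs <- 1:(nx - ox)
    ys <- if (oy >= 0) 1:(ny - oy) else (1 - oy):ny
    bond[xs, ys] <- (node_w[xs, ys] + node_w[xs + ox, ys + oy]) / 2
    w[, k] <- as.vector(bond)
  }
  structure(list(w = w, nx = nx, ny = ny, dx = dx, g_a = g_a, g_t = g_t,
                 anisotropy_ratio = anisotropy_ratio, orient = orient),
            class = "connection_map")
}

# endpoint node ids (1-based) of every bond in direction k; returns list(i, j)
.bond_endpoints <- function(nx, ny, k) {
  ox <- .bond_dirs[[k]][1]
  oy <- .bond_dirs[[k]][2]
  xs <- 1:(nx - ox)
  ys <- if (oy >= 0) 1:(ny - oy) else (1 - oy):ny
  i <- outer(xs, (ys - 1) * nx, "+")
  j <- outer(xs + ox, (ys + oy - 1) * nx, "+")
  list(i = as.vector(i), j = as.vector(j))
}

#' Remove connections inside fibrotic patches
#'
#' Classifies every present bond with at least one fibrotic endpoint as
#' longitudinal or transverse -- longitudinal when the magnitude of the dot
#' product between the (normalised) mean endpoint fibre vector and the bond
#' direction exceeds `1/sqrt(2)` -- and removes an exact count
#' `round(p * N)` of each class, selected uniformly without replacement
#' using R's RNG.  Bonds outside patches, and non-removed weights, are
#' untouched.
#'
#' @param cmap a [build_connection_map()] result.
#' @param fib a `fibrosis_map`.
#' @param p_transverse,p_longitudinal removal fractions in `[0, 1]`
#'   (defaults 0.8 and 0.2: collagen preferentially separates fibre bundles
#'   laterally).
#' @return the modified `connection_map`, with an attribute `removed`
#'   giving per-class counts.
#' @export
apply_fibrosis_removal <- function(cmap, fib, p_transverse = 0.8,
                                   p_longitudinal = 0.2) {
  stopifnot(inherits(cmap, "connection_map"), inherits(fib, "fibrosis_map"))
  if (p_transverse < 0 || p_transverse > 1 ||
      p_longitudinal < 0 || p_longitudinal > 1)
    stop("removal fractions must lie in [0, 1]")
  if (fib$nx != cmap$nx || fib$ny != cmap$ny)
    stop("fibrosis map and connection map dimensions differ")
  mask <- as.vector(fib$mask)
  fx <- as.vector(cmap$orient$fx)
  fy <- as.vector(cmap$orient$fy)
  long_idx <- list()
  trans_idx <- list()
  for (k in 1:4) {
    ep <- .bond_endpoints(cmap$nx, cmap$ny, k)
    present <- cmap$w[ep$i, k] != 0
    infib <- mask[ep$i] | mask[ep$j]
    cand <- which(present & infib)
    if (!length(cand)) next
    mx <- fx[ep$i[cand]] + fx[ep$j[cand]]
    my <- fy[ep$i[cand]] + fy[ep$j[cand]]
    nrm <- sqrt(mx^2 + my^2)
    nrm[nrm == 0] <- 1
    d <- .bond_dirs[[k]] / sqrt(sum(.bond_dirs[[k]]^2))
    dot <- abs(mx * d[1] + my * d[2]) / nrm
    is_long <- dot > 1 / sqrt(2)
    if (any(is_long)) long_idx[[k]] <- cbind(ep$i[cand[is_long]], k)
    if (any(!is_long)) trans_idx[[k]] <- cbind(ep$i[cand[!is_long]], k)
  }
  long_all <- do.call(rbind, long_idx)
  trans_all <- do.call(rbind, trans_idx)
  n_rm <- c(longitudinal = 0L, transverse = 0L)
  for (cls in list(list(long_all, p_longitudinal, "longitudinal"),
                   list(trans_all, p_transverse, "transverse"))) {
    b <- cls[[1]]
    if (is.null(b) || nrow(b) == 0) next
    k_rm <- round(cls[[2]] * nrow(b))
    if (k_rm > 0) {
      pick <- sample.int(nrow(b), k_rm)
      cmap$w[b[pick, , drop = FALSE]] <- 0
      n_rm[cls[[3]]] <- as.integer(k_rm)
    }
  }
  attr(cmap, "removed") <- c(n_rm,
                             n_longitudinal = if (is.null(long_all)) 0L else nrow(long_all),
                             n_transverse = if (is.null(trans_all)) 0L else nrow(trans_all))
  cmap
}

#' Inter-nodal coupling current
#'
#' Computes the per-node network coupling current
#' `I_i = sum_j w_ij (V_j - V_i)` (pA/pF) over the present bonds.  The
#' accumulation is pairwise antisymmetric, so the currents sum to zero to
#' machine precision.
#'
#' @param V voltage matrix (nx by ny, mV).
#' @param cmap a `connection_map`.
#' @return an nx by ny matrix of coupling currents.
#' @export
coupling_current <- function(V, cmap) {
  stopifnot(inherits(cmap, "connection_map"), is.matrix(V))
  if (any(!is.finite(V))) stop("V must be finite")
  nx <- cmap$nx
  ny <- cmap$ny
  stopifnot(nrow(V) == nx, ncol(V) == ny)
  v <- as.vector(V)
  out <- numeric(nx * ny)
  for (k in 1:4) {
    ep <- .bond_endpoints(nx, ny, k)
    wk <- cmap$w[ep$i, k]
    flux <- wk * (v[ep$j] - v[ep$i])
    # two-pass accumulate (indices are unique within i and within j per dir)
    acc_i <- numeric(nx * ny)
    acc_i[ep$i] <- flux
    acc_j <- numeric(nx * ny)
    acc_j[ep$j] <- flux
    out <- out + acc_i - acc_j
  }
  matrix(out, nx, ny)
}

#' View one bond direction of a connection map as a grid
#'
#' @param cmap a `connection_map`.
#' @param direction one of `"x"`, `"y"`, `"xy"`, `"xmy"`.
#' @return an nx by ny matrix of bond weights (stored at the lower
#'   endpoint).
#' @export
connection_grid <- function(cmap, direction = c("x", "y", "xy", "xmy")) {
  direction <- match.arg(direction)
  k <- match(direction, c("x", "y", "xy", "xmy"))
  matrix(cmap$w[, k], cmap$nx, cmap$ny)
}

#' @export
print.connection_map <- function(x, ...) {
  cat("<connection_map>", x$nx, "x", x$ny, "nodes, g_a =", x$g_a,
      "nS/pF, g_t =", signif(x$g_t, 3), "nS/pF (ratio",
      paste0(x$anisotropy_ratio, ":1)"), "\n")
  rm <- attr(x, "removed")
  if (!is.null(rm))
    cat("  removed bonds:", rm[["transverse"]], "transverse,",
        rm[["longitudinal"]], "longitudinal\n")
  invisible(x)
}
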