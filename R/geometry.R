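#' Arc length of a polyline
#' @param p two-column coordinate matrix.
#' @return total chord length.
#' @export
polyline_length <- function(p) {
  p <- as_xy(p)
  sum(sqrt(rowSums(diff(p)^2)))
}

as_xy <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p[, c(1, 2)])
  if (!is.matrix(p) || ncol(p) < 2) stop("expected a two-column coordinate matrix")
  storage.mode(p) <- "double"
  p[, 1:2, drop = FALSE]
}

#' Resample a polyline to equally spaced arc-length positions
#'
#' Linear interpolation along the chords of `p` at `n` equally spaced
#' cumulative-arc-length positions (endpoints preserved).
#'
#' @param p two-column coordinate matrix with at least 2 rows.
#' @param n number of output points (>= 2).
#' @return `n` x 2 matrix.
#' @export
resample_polyline <- function(p, n) {
  p <- as_xy(p)
  if (nrow(p) < 2) stop("polyline needs at least 2 points")
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  if (s[length(s)] == 0) {
    return(matrix(rep(p[1, ], each = n), n, 2,
                  dimnames = list(NULL, colnames(p))))
  }
  keep <- c(TRUE, seg > 0)  # drop duplicate consecutive points for approx()
  s2 <- s[keep]; p2 <- p[keep, , drop = FALSE]
  at <- seq(0, s2[length(s2)], length.out = n)
  cbind(x = stats::approx(s2, p2[, 1], xout = at)$y,
        y = stats::approx(s2, p2[, 2], xout = at)$y)
}

# all proper (transversal) crossings between edges of a closed polygon
# given as vertex matrix V (edges i: V[i] -> V[i+1], wrapping).
# Returns data.frame(e1, e2, t1, t2, x, y) with t in (0,1) along each edge.
polygon_self_intersections <- function(V) {
  nE <- nrow(V)
  x1 <- V[, 1]; y1 <- V[, 2]
  nxt <- c(2:nE, 1L)
  x2 <- V[nxt, 1]; y2 <- V[nxt, 2]
  lox <- pmin(x1, x2); hix <- pmax(x1, x2)
  loy <- pmin(y1, y2); hiy <- pmax(y1, y2)
  # bounding-box prefilter over all unordered pairs
  cand_i <- integer(0); cand_j <- integer(0)
  step <- max(1L, 4000000L %/% nE)
  for (i0 in seq(1L, nE - 1L, by = step)) {
    i1 <- min(i0 + step - 1L, nE - 1L)
    ii <- i0:i1
    M <- outer(lox[ii], hix, "<=") & outer(hix[ii], lox, ">=") &
      outer(loy[ii], hiy, "<=") & outer(hiy[ii], loy, ">=")
    w <- which(M, arr.ind = TRUE)
    keep <- (ii[w[, 1]] + 1L) < w[, 2]  # j > i + 1: skip self and neighbors
    cand_i <- c(cand_i, ii[w[keep, 1]])
    cand_j <- c(cand_j, w[keep, 2])
  }
  # wrap adjacency: edge nE and edge 1 share a vertex
  drop <- cand_i == 1L & cand_j == nE
  cand_i <- cand_i[!drop]; cand_j <- cand_j[!drop]
  if (!length(cand_i))
    return(data.frame(e1 = integer(0), e2 = integer(0), t1 = numeric(0),
                      t2 = numeric(0), x = numeric(0), y = numeric(0)))
  ax <- x1[cand_i]; ay <- y1[cand_i]
  bx <- x2[cand_i]; by <- y2[cand_i]
  cx <- x1[cand_j]; cy <- y1[cand_j]
  dx <- x2[cand_j]; dy <- y2[cand_j]
  rxs <- (bx - ax) * (dy - cy) - (by - ay) * (dx - cx)
  t1 <- ((cx - ax) * (dy - cy) - (cy - ay) * (dx - cx)) / rxs
  t2 <- ((cx - ax) * (by - ay) - (cy - ay) * (bx - ax)) / rxs
  ok <- is.finite(t1) & is.finite(t2) &
    t1 > 0 & t1 < 1 & t2 > 0 & t2 < 1
  if (!any(ok))
    return(data.frame(e1 = integer(0), e2 = integer(0), t1 = numeric(0),
                      t2 = numeric(0), x = numeric(0), y = numeric(0)))
  data.frame(e1 = cand_i[ok], e2 = cand_j[ok], t1 = t1[ok], t2 = t2[ok],
             x = ax[ok] + t1[ok] * (bx[ok] - ax[ok]),
             y = ay[ok] + t1[ok] * (by[ok] - ay[ok]))
}

shoelace_abs <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# total area of a (possibly self-intersecting) closed polygon as the sum
# of absolute areas of its simple sub-loops, split at proper crossings.
polygon_loop_area <- function(V) {
  inter <- polygon_self_intersections(V)
  nE <- nrow(V)
  if (!nrow(inter)) return(shoelace_abs(V[, 1], V[, 2]))
  # augmented vertex walk: each edge start vertex, then its crossing
  # points ordered along the edge; crossings carry a shared id
  per_edge <- vector("list", nE)
  for (r in seq_len(nrow(inter))) {
    per_edge[[inter$e1[r]]] <- rbind(per_edge[[inter$e1[r]]],
                                     c(inter$t1[r], r, inter$x[r], inter$y[r]))
    per_edge[[inter$e2[r]]] <- rbind(per_edge[[inter$e2[r]]],
                                     c(inter$t2[r], r, inter$x[r], inter$y[r]))
  }
  xs <- numeric(0); ys <- numeric(0); ids <- integer(0)
  for (e in seq_len(nE)) {
    xs <- c(xs, V[e, 1]); ys <- c(ys, V[e, 2]); ids <- c(ids, 0L)
    pe <- per_edge[[e]]
    if (!is.null(pe)) {
      pe <- pe[order(pe[, 1]), , drop = FALSE]
      xs <- c(xs, pe[, 3]); ys <- c(ys, pe[, 4]); ids <- c(ids, as.integer(pe[, 2]))
    }
  }
  # stack walk: when a crossing id reappears, the vertices since its
  # first appearance close one simple loop
  total <- 0
  sx <- numeric(0); sy <- numeric(0); sid <- integer(0)
  open_pos <- integer(nrow(inter))  # id -> stack position (0 = closed)
  for (v in seq_along(xs)) {
    id <- ids[v]
    if (id > 0L && open_pos[id] > 0L) {
      pos <- open_pos[id]
      loop_ix <- pos:length(sx)
      total <- total + shoelace_abs(sx[loop_ix], sy[loop_ix])
      closed_ids <- sid[loop_ix]
      open_pos[closed_ids[closed_ids > 0L]] <- 0L
      sx <- sx[seq_len(pos - 1L)]; sy <- sy[seq_len(pos - 1L)]
      sid <- sid[seq_len(pos - 1L)]
      # the crossing point itself remains a vertex of the outer loop
      sx <- c(sx, xs[v]); sy <- c(sy, ys[v]); sid <- c(sid, 0L)
    } else {
      sx <- c(sx, xs[v]); sy <- c(sy, ys[v]); sid <- c(sid, id)
      if (id > 0L) open_pos[id] <- length(sx)
    }
  }
  total + shoelace_abs(sx, sy)
}

#' Area enclosed between two open polylines
#'
#' The position-error primitive of the tracing task: the unsigned area
#' between a traced trajectory and the intended track path, after
#' joining corresponding endpoints. Both polylines are resampled to a
#' common dense arc-length parameterization and concatenated (trace
#' forward, track backward) into one closed polygon; the polygon is
#' split into simple sub-loops at every proper self-crossing and the
#' absolute areas of the sub-loops are summed, so regions on opposite
#' sides of a crossing never cancel.
#'
#' The result is symmetric in its arguments, invariant under translation
#' and rotation, and scales with the square of any uniform coordinate
#' scaling.
#'
#' @param trace,track two-column coordinate matrices (>= 2 points each).
#' @param n_samples resampling density per curve; default scales with
#'   the input vertex count (4x the larger, clamped to 256..1500).
#' @return area in squared input units (pixels^2 for pixel input).
#' @export
position_error <- function(trace, track, n_samples = NULL) {
  trace <- as_xy(trace); track <- as_xy(track)
  if (nrow(trace) < 2 || nrow(track) < 2)
    stop("trace and track must each have at least 2 points")
  if (is.null(n_samples))
    n_samples <- min(1500L, max(256L, 4L * max(nrow(trace), nrow(track))))
  A <- resample_polyline(trace, n_samples)
  C <- resample_polyline(track, n_samples)
  V <- rbind(A, C[n_samples:1, ])
  # drop exactly duplicated consecutive vertices (degenerate edges)
  d <- rowSums((V - V[c(2:nrow(V), 1L), ])^2)
  V <- V[d > 0, , drop = FALSE]
  if (nrow(V) < 3) return(0)
  polygon_loop_area(V)
}
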