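# Shared spline-centerline machinery used by both the phantom generator
# and the quantification module.

# Natural cubic spline through ordered 3D markers, reparameterized to arc
# length. Returns points/tangents at either a fixed arc step (step, mm) or
# a fixed count (n) of equally spaced samples.
resample_curve <- function(markers, step = NULL, n = NULL) {
  markers <- rbind(markers)
  if (nrow(markers) < 2L) stop("need at least 2 markers")
  seg <- sqrt(rowSums((markers[-1, , drop = FALSE] -
                       markers[-nrow(markers), , drop = FALSE])^2))
  if (any(seg == 0)) stop("duplicate consecutive markers")
  tpar <- c(0, cumsum(seg))
  fx <- stats::splinefun(tpar, markers[, 1], method = "natural")
  fy <- stats::splinefun(tpar, markers[, 2], method = "natural")
  fz <- stats::splinefun(tpar, markers[, 3], method = "natural")
  # dense evaluation to get the chord-parameter -> arc-length map
  tt <- seq(0, tpar[length(tpar)], length.out = max(200L, 20L * nrow(markers)))
  dp <- cbind(fx(tt), fy(tt), fz(tt))
  darc <- c(0, cumsum(sqrt(rowSums(diff(dp)^2))))
  total <- darc[length(darc)]
  s <- if (!is.null(n)) seq(0, total, length.out = n)
       else seq(0, total, by = step)
  tq <- stats::approx(darc, tt, xout = s, rule = 2)$y
  pts <- cbind(fx(tq), fy(tq), fz(tq))
  tans <- cbind(fx(tq, deriv = 1), fy(tq, deriv = 1), fz(tq, deriv = 1))
  tans <- tans / sqrt(rowSums(tans^2))
  list(points = pts, tangents = tans, arc = s, total = total)
}

# Two unit vectors spanning the plane perpendicular to a unit tangent.
plane_basis <- function(tangent) {
  a <- if (abs(tangent[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * tangent) * tangent
  u <- u / sqrt(sum(u^2))
  v <- c(tangent[2] * u[3] - tangent[3] * u[2],
         tangent[3] * u[1] - tangent[1] * u[3],
         tangent[1] * u[2] - tangent[2] * u[1])
  list(u = u, v = v)
}

# Minimum distance (and index of nearest polyline sample) from each query
# point to a dense polyline; chunked to bound memory.
nearest_on_polyline <- function(query, poly, chunk = 64L) {
  nq <- nrow(query)
  best_d2 <- rep(Inf, nq)
  best_i <- rep(1L, nq)
  q2 <- rowSums(query^2)
  i0 <- 1L
  while (i0 <= nrow(poly)) {
    i1 <- min(i0 + chunk - 1L, nrow(poly))
    pb <- poly[i0:i1, , drop = FALSE]
    d2 <- outer(q2, rowSums(pb^2), `+`) - 2 * query %*% t(pb)
    j <- max.col(-d2, ties.method = "first")
    dmin <- d2[cbind(seq_len(nq), j)]
    upd <- dmin < best_d2
    best_d2[upd] <- dmin[upd]
    best_i[upd] <- i0 + j[upd] - 1L
    i0 <- i1 + 1L
  }
  list(dist = sqrt(pmax(best_d2, 0)), index = best_i)
}
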