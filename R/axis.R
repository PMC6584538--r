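# Medial-axis machinery shared by the 2D and 3D morphometry modules.
#
# The cell axis is obtained from a 2D binary silhouette: Zhang-Suen
# thinning, longest path through the skeleton graph (robust to short
# spurs), sub-pixel smoothing spline through the ordered skeleton points,
# and linear extension of both spline ends to the silhouette boundary so
# arclengths span tip to tip. Widths are perpendicular extents of the
# silhouette pixels assigned to each axis sample. Compartment boundaries
# use a width-profile rule (head/midpiece) or a profile change point
# (midpiece/tail), shared across modules for consistency.

# longest path between skeleton endpoints via double BFS on the 8-connected
# skeleton graph; returns ordered pixel indices (rows of `px`)
skeleton_path <- function(skel) {
  px <- which(skel, arr.ind = TRUE)
  n <- nrow(px)
  if (n == 0) stop("empty skeleton")
  if (n <= 2) return(px)
  id <- matrix(0L, nrow(skel), ncol(skel))
  id[px] <- seq_len(n)
  nbrs <- vector("list", n)
  # radius-2 adjacency so one-pixel breaks in the skeleton (hair-thin
  # necks of the silhouette) do not sever the path
  offs <- expand.grid(dy = -2:2, dx = -2:2)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0), ]
  for (k in seq_len(n)) {
    iy <- px[k, 1]; ix <- px[k, 2]
    jj <- integer(0)
    for (o in seq_len(nrow(offs))) {
      y <- iy + offs$dy[o]; x <- ix + offs$dx[o]
      if (y >= 1 && y <= nrow(skel) && x >= 1 && x <= ncol(skel) &&
          id[y, x] > 0L) jj <- c(jj, id[y, x])
    }
    nbrs[[k]] <- jj
  }
  bfs <- function(start) {
    prev <- integer(n); dist <- rep(NA_integer_, n)
    dist[start] <- 0L; queue <- start; qi <- 1L
    while (qi <= length(queue)) {
      u <- queue[qi]; qi <- qi + 1L
      for (v in nbrs[[u]]) if (is.na(dist[v])) {
        dist[v] <- dist[u] + 1L; prev[v] <- u
        queue <- c(queue, v)
      }
    }
    list(far = which.max(dist), prev = prev)
  }
  e1 <- bfs(1L)$far
  b2 <- bfs(e1)
  path <- b2$far; cur <- b2$far
  while (cur != e1) {
    cur <- b2$prev[cur]
    path <- c(cur, path)
  }
  px[path, , drop = FALSE]
}

# Extract a smoothed, tip-extended medial axis from a 2D silhouette.
# mask: logical matrix; pixel_size: (dy, dx) um. Returns axis samples,
# arclengths, per-sample silhouette widths and per-pixel assignments,
# oriented so the thick (head) end comes first.
extract_axis_2d <- function(mask, pixel_size) {
  if (length(pixel_size) == 1L) pixel_size <- rep(pixel_size, 2L)
  dy <- pixel_size[1]; dx <- pixel_size[2]
  pady <- matrix(FALSE, 1, ncol(mask))
  m <- rbind(pady, mask, pady)
  m <- cbind(FALSE, m, FALSE)
  skel <- cpp_thin2d(m)[2:(nrow(mask) + 1), 2:(ncol(mask) + 1), drop = FALSE]
  path <- skeleton_path(skel)
  py <- (path[, 1] - 1) * dy
  px_ <- (path[, 2] - 1) * dx
  n <- nrow(path)

  if (n >= 8) {
    tchord <- c(0, cumsum(sqrt(diff(py)^2 + diff(px_)^2)))
    df <- max(4, min(n - 1, round(tchord[n] / 3)))
    sy <- smooth.spline(tchord, py, df = df)
    sx <- smooth.spline(tchord, px_, df = df)
    tt <- seq(0, tchord[n], by = min(dy, dx) / 2)
    ay <- predict(sy, tt)$y
    axp <- predict(sx, tt)$y
  } else {
    # degenerate blob (e.g. near-circular silhouette): thinning collapses
    # to a point; seed the axis with the principal direction of the mask
    pix0 <- which(mask, arr.ind = TRUE)
    cy <- mean((pix0[, 1] - 1) * dy); cx <- mean((pix0[, 2] - 1) * dx)
    pc <- cbind((pix0[, 1] - 1) * dy - cy, (pix0[, 2] - 1) * dx - cx)
    v <- svd(pc, nu = 0, nv = 1)$v[, 1]
    h <- min(dy, dx)
    ay <- cy + c(-1, 0, 1) * h * v[1]
    axp <- cx + c(-1, 0, 1) * h * v[2]
  }

  inside <- function(y, x) {
    iy <- round(y / dy) + 1; ix <- round(x / dx) + 1
    ok <- iy >= 1 & iy <= nrow(mask) & ix >= 1 & ix <= ncol(mask)
    ok[ok] <- mask[cbind(iy[ok], ix[ok])]
    ok
  }
  step <- min(dy, dx) / 2
  extend_end <- function(ay, axp, head_end = TRUE) {
    m <- length(ay)
    if (m < 2) return(cbind(ay, axp))
    if (head_end) {
      ty <- ay[1] - ay[min(5, m)]; tx <- axp[1] - axp[min(5, m)]
    } else {
      ty <- ay[m] - ay[max(1, m - 4)]; tx <- axp[m] - axp[max(1, m - 4)]
    }
    nrm <- sqrt(ty^2 + tx^2)
    if (nrm == 0) return(cbind(ay, axp))
    ty <- ty / nrm; tx <- tx / nrm
    y0 <- if (head_end) ay[1] else ay[m]
    x0 <- if (head_end) axp[1] else axp[m]
    add_y <- add_x <- numeric(0)
    for (k in seq_len(2000)) {
      yy <- y0 + k * step * ty; xx <- x0 + k * step * tx
      if (!inside(yy, xx)) {
        # boundary sits about midway between last inside and first outside
        add_y <- c(add_y, y0 + (k - 0.5) * step * ty)
        add_x <- c(add_x, x0 + (k - 0.5) * step * tx)
        break
      }
      add_y <- c(add_y, yy); add_x <- c(add_x, xx)
    }
    if (head_end) cbind(c(rev(add_y), ay), c(rev(add_x), axp))
    else cbind(c(ay, add_y), c(axp, add_x))
  }
  ext <- extend_end(ay, axp, TRUE)
  ext <- extend_end(ext[, 1], ext[, 2], FALSE)
  ay <- ext[, 1]; axp <- ext[, 2]
  s <- c(0, cumsum(sqrt(diff(ay)^2 + diff(axp)^2)))

  # assign every silhouette pixel to its nearest axis sample
  pix <- which(mask, arr.ind = TRUE)
  pyy <- (pix[, 1] - 1) * dy; pxx <- (pix[, 2] - 1) * dx
  nax <- length(ay)
  assign_idx <- integer(length(pyy))
  chunk <- 2000L
  for (st in seq(1L, length(pyy), by = chunk)) {
    en <- min(st + chunk - 1L, length(pyy))
    d2 <- outer(pyy[st:en], ay, "-")^2 + outer(pxx[st:en], axp, "-")^2
    assign_idx[st:en] <- max.col(-d2, ties.method = "first")
  }

  # tangents and perpendicular offsets -> width profile
  tgy <- c(diff(ay), ay[nax] - ay[nax - 1])
  tgx <- c(diff(axp), axp[nax] - axp[nax - 1])
  tn <- sqrt(tgy^2 + tgx^2); tn[tn == 0] <- 1
  tgy <- tgy / tn; tgx <- tgx / tn
  off <- (pyy - ay[assign_idx]) * tgx[assign_idx] -
    (pxx - axp[assign_idx]) * tgy[assign_idx]
  bmax <- tapply(off, assign_idx, max)
  bmin <- tapply(off, assign_idx, min)
  wmax <- rep(NA_real_, nax); wmin <- rep(NA_real_, nax)
  wmax[as.integer(names(bmax))] <- bmax
  wmin[as.integer(names(bmin))] <- bmin
  # cross-sections split across neighbouring samples (sub-pixel axis
  # sampling); take the offset range over a window of +- one pixel width
  halfw <- max(1L, ceiling(mean(pixel_size) / max(mean(diff(s)), 1e-9)))
  roll <- function(v, f) {
    m <- sapply(-halfw:halfw, function(k) {
      if (k < 0) c(rep(NA, -k), v[seq_len(nax + k)])
      else c(v[(k + 1):nax], rep(NA, k))
    })
    apply(m, 1, function(r) if (all(is.na(r))) NA_real_ else f(r, na.rm = TRUE))
  }
  width <- roll(wmax, max) - roll(wmin, min) + mean(pixel_size)
  if (anyNA(width)) {
    ok <- which(!is.na(width))
    width <- approx(s[ok], width[ok], xout = s, rule = 2)$y
  }
  width <- as.numeric(stats::filter(width, rep(1 / 3, 3), sides = 2))
  if (anyNA(width)) {
    ok <- which(!is.na(width))
    width <- approx(s[ok], width[ok], xout = s, rule = 2)$y
  }

  # orient: thick (head) end first
  q <- max(5L, round(nax / 5))
  if (mean(width[seq_len(q)]) < mean(width[(nax - q + 1):nax])) {
    ay <- rev(ay); axp <- rev(axp); width <- rev(width)
    s <- max(s) - rev(s)
    assign_idx <- nax + 1L - assign_idx
    ord <- TRUE
  } else ord <- FALSE

  list(y = ay, x = axp, s = s, width = width,
       pixels = pix, pixel_s = s[assign_idx], assign = assign_idx,
       reversed = ord)
}

# Head/midpiece boundary: first arclength past the widest point where the
# silhouette width falls below `frac` of its maximum, then advanced along
# the falling shoulder until the profile flattens (so the boundary lands
# at the anatomical neck rather than on the ellipsoidal shoulder).
boundary_from_width <- function(s, width, frac = 0.25) {
  imax <- which.max(width)
  wmax <- width[imax]
  thr <- frac * wmax
  n <- length(s)
  below <- which(width < thr & seq_along(width) > imax)
  if (length(below) == 0) return(s[n])
  i <- below[1]
  while (i + 1 <= n && width[i + 1] < width[i] - 0.005 * wmax) i <- i + 1
  s[i]
}

# Midpiece/tail boundary: largest downward step of a per-sample intensity
# profile (projected phase in 2D, RI-core occupancy in 3D), searched past
# `from`. Window half-width ~0.5 um.
boundary_from_profile <- function(s, profile, from) {
  n <- length(s)
  ds <- mean(diff(s))
  k <- max(2L, round(0.5 / ds))
  cand <- which(s > from & seq_len(n) > k & seq_len(n) <= n - k)
  if (length(cand) == 0) return(max(s))
  cs <- cumsum(c(0, profile))
  left <- (cs[cand + 1] - cs[cand + 1 - k]) / k
  right <- (cs[pmin(cand + k, n) + 1] - cs[cand + 1]) /
    (pmin(cand + k, n) - cand)
  jump <- left - right
  s[cand[which.max(jump)]]
}
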