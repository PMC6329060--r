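# Independent oracles used by the tests. These deliberately avoid the code
# paths they check: plain-R connected components, from-definition ANOVA
# mean squares, general-purpose optimisation, direct polynomial regression.

# 26-connected component labelling by iterative dilation (tiny grids only)
label_components_oracle <- function(arr) {
  d <- dim(arr)
  labels <- array(0L, dim = d)
  nextlab <- 0L
  idx_all <- which(arr)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    nextlab <- nextlab + 1L
    comp <- array(FALSE, dim = d)
    comp[start] <- TRUE
    repeat {
      grown <- comp
      ids <- which(comp)
      k <- (ids - 1L) %/% (d[1] * d[2])
      r <- (ids - 1L) %% (d[1] * d[2])
      j <- r %/% d[1]
      i <- r %% d[1]
      for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
        ii <- i + di; jj <- j + dj; kk <- k + dk
        ok <- ii >= 0 & ii < d[1] & jj >= 0 & jj < d[2] & kk >= 0 & kk < d[3]
        lin <- 1L + ii[ok] + d[1] * (jj[ok] + d[2] * kk[ok])
        grown[lin] <- TRUE
      }
      grown <- grown & arr
      if (identical(grown, comp)) break
      comp <- grown
    }
    labels[comp] <- nextlab
  }
  labels
}

# from-definition two-way ANOVA mean squares (independent of the package)
oracle_mean_squares <- function(M) {
  n <- nrow(M); k <- ncol(M)
  grand <- mean(M)
  rm_ <- rowMeans(M); cm_ <- colMeans(M)
  msr <- k * sum((rm_ - grand)^2) / (n - 1)
  msc <- n * sum((cm_ - grand)^2) / (k - 1)
  mse <- sum((sweep(sweep(M, 1, rm_), 2, cm_) + grand)^2) / ((n - 1) * (k - 1))
  list(msr = msr, msc = msc, mse = mse)
}

oracle_icc21 <- function(M) {
  ms <- oracle_mean_squares(M)
  n <- nrow(M); k <- ncol(M)
  (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)
}

oracle_icc31 <- function(M) {
  ms <- oracle_mean_squares(M)
  k <- ncol(M)
  (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
}

# nonlinear least-squares sphere oracle via general-purpose optimiser
oracle_sphere_nls <- function(pts, start = c(colMeans(pts), 10)) {
  obj <- function(p) sum((sqrt(rowSums(sweep(pts, 2, p[1:3])^2)) - p[4])^2)
  op <- stats::optim(start, obj, method = "BFGS",
                     control = list(maxit = 5000, reltol = 1e-15))
  list(center = op$par[1:3], radius = op$par[4])
}

# triangulated height-field mesh z = f(x, y) over a regular grid
heightfield_mesh <- function(xs, ys, f) {
  g <- expand.grid(x = xs, y = ys)
  V <- cbind(g$x, g$y, f(g$x, g$y))
  nx <- length(xs); ny <- length(ys)
  id <- function(i, j) (j - 1L) * nx + i
  faces <- NULL
  for (j in seq_len(ny - 1)) for (i in seq_len(nx - 1)) {
    faces <- rbind(faces,
                   c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
                   c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
  }
  surface_mesh(V, faces)
}

# membership test for phantom primitives, re-derived from the parameter
# table (used by the Monte-Carlo union-volume oracle)
oracle_inside_any <- function(prims, pts) {
  inside <- rep(FALSE, nrow(pts))
  for (p in prims) {
    hit <- switch(p$type,
      shell = {
        d2 <- rowSums(sweep(pts, 2, p$center)^2)
        d2 >= p$r_inner^2 & d2 <= p$r_outer^2
      },
      ball = rowSums(sweep(pts, 2, p$center)^2) <= p$r^2,
      capsule = {
        dd <- p$p2 - p$p1
        tt <- pmin(pmax(as.numeric(sweep(pts, 2, p$p1) %*% dd) / sum(dd^2), 0), 1)
        rowSums((sweep(pts, 2, p$p1) - outer(tt, dd))^2) <= p$r^2
      },
      endplate = {
        rel <- sweep(pts, 2, p$midpoint)
        s <- as.numeric(rel %*% p$e)
        u <- as.numeric(rel %*% p$u)
        w <- as.numeric(rel %*% p$n)
        cmag <- abs(p$concavity)
        top <- if (cmag < 1e-12) rep(0, length(s)) else {
          rho <- ((p$depth / 2)^2 + cmag^2) / (2 * cmag)
          arc <- sqrt(pmax(rho^2 - s^2, 0))
          if (p$concavity > 0) (rho - cmag) - arc else arc - (rho - cmag)
        }
        abs(s) <= p$depth / 2 & abs(u) <= p$width / 2 &
          w <= top & w >= top - p$thickness
      })
    inside <- inside | hit
  }
  inside
}
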