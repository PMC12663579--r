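# Literal, slow reimplementation of the reconstruction pipeline used as an
# independent oracle: explicit DFT matrices instead of FFTs, explicit small
# matrix inversions, per-band loops. Only the mathematical definitions are
# shared with the package; none of its internals are called.

oDftMat <- function(n) {
  jk <- outer(0:(n - 1), 0:(n - 1))
  exp(-2i * pi * jk / n)
}

oDft2 <- function(x) {
  Fy <- oDftMat(nrow(x)); Fx <- oDftMat(ncol(x))
  Fy %*% x %*% Fx
}

oIdft2 <- function(X) {
  Fy <- Conj(oDftMat(nrow(X))); Fx <- Conj(oDftMat(ncol(X)))
  (Fy %*% X %*% Fx) / length(X)
}

oFreq <- function(n) {
  k <- 0:(n - 1)
  ifelse(k < ceiling(n / 2), k, k - n) / n
}

oOtfRadial <- function(rho) ifelse(rho < 1, (2 / pi) * (acos(pmin(rho, 1)) -
  pmin(rho, 1) * sqrt(pmax(1 - pmin(rho, 1)^2, 0))), 0)

oOtfAt <- function(ky, kx, kcut) oOtfRadial(sqrt(ky^2 + kx^2) / kcut)

# Full oracle reconstruction of one 3x3-frame plane.
# framesByAngle: list over 3 angles of lists of 3 matrices.
oracleReconstruct <- function(framesByAngle, k0, phases, m, kcut,
                              wienerW = 0.15, upsample = 2L,
                              apodization = "triangular",
                              lockin = FALSE, dcSigma = NULL) {
  ny <- nrow(framesByAngle[[1]][[1]]); nx <- ncol(framesByAngle[[1]][[1]])
  if (lockin) {
    KYs <- matrix(oFreq(ny), ny, nx); KXs <- matrix(oFreq(nx), ny, nx, byrow = TRUE)
    # literal per-pixel disk rank filters with clamped borders
    oRank <- function(m, r, fun) {
      out <- m
      for (iy in 1:ny) for (ix in 1:nx) {
        vals <- c()
        for (dy in -r:r) for (dx in -r:r) if (dy^2 + dx^2 <= r^2) {
          sy <- min(max(iy + dy, 1), ny); sx <- min(max(ix + dx, 1), nx)
          vals <- c(vals, m[sy, sx])
        }
        out[iy, ix] <- fun(vals)
      }
      out
    }
    for (d in 1:3) {
      fr <- framesByAngle[[d]]
      X <- cbind(1, cos(phases[d, ]), sin(phases[d, ]))
      Xi <- solve(X)
      C <- matrix(0, ny, nx); A <- matrix(0, ny, nx)
      for (iy in 1:ny) for (ix in 1:nx) {
        v <- Xi %*% c(fr[[1]][iy, ix], fr[[2]][iy, ix], fr[[3]][iy, ix])
        C[iy, ix] <- v[1]; A[iy, ix] <- sqrt(v[2]^2 + v[3]^2)
      }
      dc <- pmax(C - A, 0)
      k0len <- sqrt(sum(k0[d, ]^2))
      r <- ceiling(1.5 / k0len)
      opened <- oRank(oRank(dc, r, min), r, max)   # grayscale opening
      s <- if (is.null(dcSigma)) 1 / k0len else dcSigma
      G <- exp(-2 * pi^2 * s^2 * (KYs^2 + KXs^2))
      openedSm <- pmax(Re(oIdft2(oDft2(opened) * G)), 0)
      Gb <- exp(-2 * pi^2 * 2^2 * (KYs^2 + KXs^2))
      S <- Re(oIdft2(oDft2(A) * Gb))
      Cb <- Re(oIdft2(oDft2(C) * Gb))
      W <- S^2 / (S^2 + (0.02 * Cb)^2 + 1e-24)
      dc <- W * openedSm + (1 - W) * dc
      framesByAngle[[d]] <- lapply(fr, function(f) pmax(f - dc, 0))
    }
  }
  uy <- upsample * ny; ux <- upsample * nx
  ry <- matrix(seq(0, by = 1 / upsample, length.out = uy), uy, ux)
  rx <- matrix(seq(0, by = 1 / upsample, length.out = ux), uy, ux, byrow = TRUE)
  KY <- matrix(oFreq(uy) * upsample, uy, ux)
  KX <- matrix(oFreq(ux) * upsample, uy, ux, byrow = TRUE)
  num <- matrix(0i, uy, ux)
  den <- matrix(wienerW^2, uy, ux)
  embed <- function(spec) {
    big <- matrix(0i, uy, ux)
    for (iy in 1:ny) for (ix in 1:nx) {
      ty <- if (iy - 1 < ceiling(ny / 2)) iy else uy - (ny - iy)
      tx <- if (ix - 1 < ceiling(nx / 2)) ix else ux - (nx - ix)
      big[ty, tx] <- spec[iy, ix]
    }
    big * upsample^2
  }
  for (d in 1:3) {
    M <- outer(phases[d, ], c(-1, 0, 1), function(p, n) exp(1i * n * p))
    Mi <- solve(M)
    fts <- lapply(framesByAngle[[d]], oDft2)
    for (ni in 1:3) {
      n <- ni - 2L
      band <- Mi[ni, 1] * fts[[1]] + Mi[ni, 2] * fts[[2]] + Mi[ni, 3] * fts[[3]]
      bembed <- embed(band)
      shift <- -n * k0[d, ]
      breal <- oIdft2(bembed)
      bshift <- oDft2(breal * exp(2i * pi * (shift[1] * ry + shift[2] * rx)))
      w <- if (n == 0L) 1 else m[d] / 2
      H <- oOtfAt(KY + n * k0[d, 1], KX + n * k0[d, 2], kcut)
      num <- num + w * H * bshift
      den <- den + (w * H)^2
    }
  }
  sr <- num / den
  kr <- sqrt(KY^2 + KX^2)
  kmax <- kcut + max(sqrt(rowSums(k0^2)))
  if (apodization == "triangular") sr <- sr * pmax(0, 1 - kr / kmax)
  out <- Re(oIdft2(sr))
  out[out < 0] <- 0
  out
}
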