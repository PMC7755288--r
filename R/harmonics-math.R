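# Internal spherical-harmonic workhorse.
#
# Complex spherical harmonics, orthonormal on the sphere, with Condon-Shortley
# phase: Y_l^m(theta, phi) = Pbar_l^m(cos theta) * exp(i m phi), where Pbar
# carries the full normalization sqrt((2l+1)/(4pi) * (l-m)!/(l+m)!) * (-1)^m *
# P_l^m.  Negative orders follow Y_l^{-m} = (-1)^m Conj(Y_l^m).
#
# The degree-l blocks are produced by a rolling three-term recursion in l so
# that memory stays O(npts * lmax) even for large band limits.

# visit degree blocks: calls fun(l, Y) with Y complex [npts x (2l+1)],
# columns ordered m = -l ... l.
ylm_visit <- function(dirs, lmax, fun) {
  npts <- nrow(dirs)
  ct <- dirs[, 3]
  st <- sqrt(pmax(0, dirs[, 1]^2 + dirs[, 2]^2))
  phi <- atan2(dirs[, 2], dirs[, 1])
  # e^{i m phi} columns built incrementally
  e1 <- complex(real = cos(phi), imaginary = sin(phi))

  # Pprev holds Pbar_{l-1, m} for m = 0..l-1 (matrix npts x l),
  # Pprev2 holds Pbar_{l-2, m}.
  p00 <- rep(sqrt(1 / (4 * pi)), npts)
  Pprev2 <- NULL
  Pprev <- matrix(p00, npts, 1L)
  Em <- matrix(complex(real = 1, imaginary = 0), npts, 1L)  # e^{i m phi}, m=0

  emit <- function(l, P) {
    # P: npts x (l+1), columns m = 0..l
    Ypos <- P * Em  # recycling by column works since dims match
    if (l == 0L) {
      fun(0L, Ypos)
      return(invisible())
    }
    Yneg <- Ypos[, (l + 1L):2L, drop = FALSE]
    signs <- rep_len(c(-1, 1), l)  # (-1)^m for m = l..1 -> start with (-1)^l
    if (l %% 2 == 0) signs <- rep_len(c(1, -1), l)
    Yneg <- Conj(Yneg) * matrix(signs, npts, l, byrow = TRUE)
    fun(l, cbind(Yneg, Ypos))
  }

  emit(0L, Pprev)
  if (lmax == 0L) return(invisible())

  for (l in 1:lmax) {
    P <- matrix(0, npts, l + 1L)
    if (l >= 2L) {
      for (m in 0:(l - 2L)) {
        a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
        b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
        P[, m + 1L] <- a * (ct * Pprev[, m + 1L] - b * Pprev2[, m + 1L])
      }
    }
    # m = l - 1
    P[, l] <- sqrt(2 * l + 1) * ct * Pprev[, l]
    # m = l (diagonal, includes Condon-Shortley sign)
    P[, l + 1L] <- -sqrt((2 * l + 1) / (2 * l)) * st * Pprev[, l]
    Em <- cbind(Em, Em[, l] * e1)
    emit(l, P)
    Pprev2 <- Pprev
    Pprev <- P
  }
  invisible()
}

# flat index of coefficient (l, m): l^2 + l + m + 1
lm_index <- function(l, m) l * (l + 1L) + m + 1L

lm_table <- function(lmax) {
  l <- rep.int(0:lmax, times = 2L * (0:lmax) + 1L)
  m <- unlist(lapply(0:lmax, function(li) -li:li), use.names = FALSE)
  tibble::tibble(l = l, m = m)
}
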