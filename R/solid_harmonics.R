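# Real solid harmonics as Cartesian polynomials.
#
# Polynomials are stored as matrices with columns (i, j, k, c) meaning
# c * x^i * y^j * z^k.  The Racah-normalized real solid harmonics R_lm
# (R_l0(0,0,r) = r^l) are built from the standard recursions
#   R_{l+1,l+1}   = sqrt((2l+1)/(2l+2)) (x R_{l,l} - y R_{l,-l})
#   R_{l+1,-l-1}  = sqrt((2l+1)/(2l+2)) (y R_{l,l} + x R_{l,-l})
#   R_{l+1,m}     = ((2l+1) z R_{l,m} - sqrt((l+m)(l-m)) r^2 R_{l-1,m})
#                   / sqrt((l+1+m)(l+1-m))
# and cached.  Spherically normalized versions carry the extra factor
# sqrt((2l+1)/(4 pi)) so that the angular parts are orthonormal on the
# unit sphere.

.poly_collapse <- function(P) {
  key <- paste(P[, 1], P[, 2], P[, 3])
  c2 <- tapply(P[, 4], key, sum)
  ijk <- matrix(as.numeric(unlist(strsplit(names(c2), " ", fixed = TRUE))),
                ncol = 3, byrow = TRUE)
  out <- cbind(ijk, as.numeric(c2))
  out <- out[abs(out[, 4]) > 1e-300, , drop = FALSE]
  if (nrow(out) == 0L) out <- matrix(c(0, 0, 0, 0), 1)
  colnames(out) <- c("i", "j", "k", "c")
  out
}

.poly_add <- function(A, B) .poly_collapse(rbind(A, B))
.poly_scale <- function(P, s) { P[, 4] <- P[, 4] * s; P }
.poly_shift <- function(P, di = 0, dj = 0, dk = 0) {
  P[, 1] <- P[, 1] + di; P[, 2] <- P[, 2] + dj; P[, 3] <- P[, 3] + dk; P
}
# multiply by r^2 = x^2 + y^2 + z^2
.poly_r2 <- function(P) {
  .poly_collapse(rbind(.poly_shift(P, di = 2), .poly_shift(P, dj = 2),
                       .poly_shift(P, dk = 2)))
}

.sh_cache <- new.env(parent = emptyenv())

# list of Racah-normalized real solid harmonic polynomials for one l,
# ordered m = -l .. l
.solid_harmonics_l <- function(l) {
  key <- as.character(l)
  if (!is.null(.sh_cache[[key]])) return(.sh_cache[[key]])
  one <- matrix(c(0, 0, 0, 1), 1, dimnames = list(NULL, c("i", "j", "k", "c")))
  tabs <- list(`0` = list(`0` = one))
  if (l >= 1) {
    tabs[["1"]] <- list(
      `-1` = .poly_shift(one, dj = 1),   # y
      `0`  = .poly_shift(one, dk = 1),   # z
      `1`  = .poly_shift(one, di = 1))   # x
  }
  if (l >= 2) {
    for (ll in 1:(l - 1)) {
      prev <- tabs[[as.character(ll)]]
      prev2 <- tabs[[as.character(ll - 1)]]
      nxt <- list()
      f <- sqrt((2 * ll + 1) / (2 * ll + 2))
      Rll <- prev[[as.character(ll)]]
      Rlm <- prev[[as.character(-ll)]]
      nxt[[as.character(ll + 1)]] <- .poly_scale(
        .poly_add(.poly_shift(Rll, di = 1), .poly_scale(.poly_shift(Rlm, dj = 1), -1)), f)
      nxt[[as.character(-(ll + 1))]] <- .poly_scale(
        .poly_add(.poly_shift(Rll, dj = 1), .poly_shift(Rlm, di = 1)), f)
      for (m in (-ll):ll) {
        num <- .poly_scale(.poly_shift(prev[[as.character(m)]], dk = 1), 2 * ll + 1)
        cf <- sqrt((ll + m) * (ll - m))
        if (cf > 0 && abs(m) <= ll - 1) {
          num <- .poly_add(num, .poly_scale(.poly_r2(prev2[[as.character(m)]]), -cf))
        }
        nxt[[as.character(m)]] <- .poly_scale(
          num, 1 / sqrt((ll + 1 + m) * (ll + 1 - m)))
      }
      # order m = -(ll+1) .. (ll+1)
      tabs[[as.character(ll + 1)]] <- nxt[as.character((-(ll + 1)):(ll + 1))]
    }
  }
  for (ll in 0:l) .sh_cache[[as.character(ll)]] <- tabs[[as.character(ll)]]
  tabs[[key]]
}

#' Real solid harmonic polynomials
#'
#' Returns the real solid harmonics of angular momentum `l` in the solid
#' harmonic ordering m = -l..l, either Racah-normalized (`R_l0` along z equals
#' `r^l`) or spherically normalized (angular parts orthonormal on the unit
#' sphere; this is the normalization used for basis functions).
#'
#' @param l Angular momentum (0 to 6 supported).
#' @param normalization `"racah"` or `"sphere"`.
#' @return A list of 2l+1 polynomial matrices with columns (i, j, k, c).
#' @export
solid_harmonics <- function(l, normalization = c("sphere", "racah")) {
  normalization <- match.arg(normalization)
  if (!is.numeric(l) || l < 0 || l != round(l)) stop("l must be a non-negative integer")
  if (l > 6) {
    stop("unsupported angular momentum l = ", l, " (supported: 0..6)")
  }
  polys <- .solid_harmonics_l(l)
  if (normalization == "sphere") {
    polys <- lapply(polys, .poly_scale, s = sqrt((2 * l + 1) / (4 * pi)))
  }
  polys
}

# evaluate polynomial at vectors x, y, z
.poly_eval <- function(P, x, y, z) {
  v <- numeric(length(x))
  for (r in seq_len(nrow(P))) {
    t <- rep(P[r, 4], length(x))
    if (P[r, 1] > 0) t <- t * x^P[r, 1]
    if (P[r, 2] > 0) t <- t * y^P[r, 2]
    if (P[r, 3] > 0) t <- t * z^P[r, 3]
    v <- v + t
  }
  v
}

# partial derivative of polynomial along dim (1, 2, 3)
.poly_deriv <- function(P, dim) {
  Q <- P[P[, dim] > 0, , drop = FALSE]
  if (nrow(Q) == 0L) return(matrix(c(0, 0, 0, 0), 1,
                                   dimnames = list(NULL, c("i", "j", "k", "c"))))
  Q[, 4] <- Q[, 4] * Q[, dim]
  Q[, dim] <- Q[, dim] - 1
  Q
}
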