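# Variable-projection solver for octahedral quadrature parameters:
# weights are linear for fixed orbit parameters, so LM searches only the
# nonlinear orbit parameters.
suppressMessages(library(minpack.lm))

perms3 <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
signs_all <- as.matrix(expand.grid(c(1,-1), c(1,-1), c(1,-1)))
images48 <- function(v) {
  M <- matrix(0, 48, 3); r <- 1
  for (p in seq_len(6)) {
    M[r:(r + 7), ] <- signs_all * matrix(v[perms3[p, ]], 8, 3, byrow = TRUE)
    r <- r + 8
  }
  M
}
dfact <- function(n) if (n <= 0) 1 else prod(seq(n, 1, by = -2))
mono_exact <- function(i, j, k) dfact(2*i-1)*dfact(2*j-1)*dfact(2*k-1)/dfact(2*(i+j+k)+1)
mono_list <- function(maxdeg) {
  out <- NULL
  for (d in 0:(maxdeg %/% 2))
    for (i in d:0) for (j in (d - i):0) { k <- d - i - j
      if (i >= j && j >= k) out <- rbind(out, c(i, j, k)) }
  out
}

orbit_pts <- function(type, par) {
  switch(type,
    a1 = images48(c(1, 0, 0)),
    a2 = images48(c(1/sqrt(2), 1/sqrt(2), 0)),
    a3 = images48(rep(1/sqrt(3), 3)),
    b  = images48(c(par[1], par[1], sqrt(max(0, 1 - 2*par[1]^2)))),
    c  = images48(c(par[1], sqrt(max(0, 1 - par[1]^2)), 0)),
    d  = images48(c(par[1], par[2], sqrt(max(0, 1 - par[1]^2 - par[2]^2)))))
}
orbit_mult <- c(a1 = 6, a2 = 12, a3 = 8, b = 24, c = 24, d = 48)
n_par <- c(a1 = 0, a2 = 0, a3 = 0, b = 1, c = 1, d = 2)

# moment column for one orbit: sum over its 48 images (with mult/48 factor)
# of x^2i y^2j z^2k, per monomial row
orbit_col <- function(type, par, monos) {
  P <- orbit_pts(type, par)
  x2 <- P[, 1]^2; y2 <- P[, 2]^2; z2 <- P[, 3]^2
  f <- orbit_mult[[type]] / 48
  vapply(seq_len(nrow(monos)), function(r)
    f * sum(x2^monos[r, 1] * y2^monos[r, 2] * z2^monos[r, 3]), numeric(1))
}

solve_varpro <- function(comp, degree, ntry = 5000, seed = 1) {
  set.seed(seed)
  monos <- mono_list(degree)
  tgt <- vapply(seq_len(nrow(monos)), function(r)
    mono_exact(monos[r, 1], monos[r, 2], monos[r, 3]), numeric(1))
  npars <- sum(n_par[comp])
  fixed_cols <- lapply(comp[n_par[comp] == 0], orbit_col, par = NULL, monos = monos)
  par_types <- comp[n_par[comp] > 0]
  Afun <- function(theta) {
    cols <- fixed_cols
    ei <- 1
    for (t in par_types) {
      np <- n_par[[t]]
      cols <- c(cols, list(orbit_col(t, theta[ei:(ei + np - 1)], monos)))
      ei <- ei + np
    }
    do.call(cbind, cols)
  }
  resid <- function(theta) {
    A <- Afun(theta)
    w <- tryCatch(qr.solve(qr(A, LAPACK = TRUE), tgt), error = function(e) NULL)
    if (is.null(w)) return(rep(1e3, length(tgt)))
    A %*% w - tgt
  }
  weights_of <- function(theta) {
    A <- Afun(theta)
    qr.solve(qr(A, LAPACK = TRUE), tgt)
  }
  for (t in seq_len(ntry)) {
    theta <- numeric(0)
    for (ty in par_types) {
      if (ty == "b") theta <- c(theta, runif(1, 0.02, 0.70))
      if (ty == "c") theta <- c(theta, runif(1, 0.02, 0.68))
      if (ty == "d") { r <- runif(1, 0.05, 0.9)
        theta <- c(theta, r, runif(1, 0.02, sqrt(max(0.01, 1 - r^2)))) }
    }
    fit <- tryCatch(nls.lm(theta, fn = resid,
                           control = nls.lm.control(maxiter = 200, ftol = 1e-16, ptol = 1e-16)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    r2 <- resid(fit$par)
    if (max(abs(r2)) < 1e-13) {
      w <- weights_of(fit$par)
      # validity: positive weights, params in open valid range
      ok <- all(w > 1e-7)
      ei <- 1
      for (ty in par_types) {
        if (ty == "b") { l <- fit$par[ei]; ei <- ei + 1
          if (!(l > 1e-3 && 2*l^2 < 1 - 1e-7)) ok <- FALSE }
        if (ty == "c") { p <- fit$par[ei]; ei <- ei + 1
          if (!(p > 1e-3 && p < 1 - 1e-3)) ok <- FALSE }
        if (ty == "d") { rr <- fit$par[ei]; ss <- fit$par[ei+1]; ei <- ei + 2
          tt2 <- 1 - rr^2 - ss^2
          if (!(rr > 1e-3 && ss > 1e-3 && tt2 > 1e-7)) ok <- FALSE }
      }
      if (ok) {
        return(list(theta = fit$par, w = as.numeric(w), comp = comp,
                    degree = degree, tries = t))
      }
    }
  }
  NULL
}

ladder <- list(
  list(deg = 3,  comp = c("a1")),
  list(deg = 5,  comp = c("a1", "a3")),
  list(deg = 7,  comp = c("a1", "a2", "a3")),
  list(deg = 9,  comp = c("a1", "a3", "c")),
  list(deg = 11, comp = c("a1", "a2", "a3", "b")),
  list(deg = 15, comp = c("a1", "a3", "b", "b", "c")),
  list(deg = 17, comp = c("a1", "a3", "b", "b", "b", "c")),
  list(deg = 19, comp = c("a1", "a2", "a3", "b", "b", "b", "d")),
  list(deg = 21, comp = c("a1", "a2", "a3", "b", "b", "b", "c", "d")),
  list(deg = 23, comp = c("a1", "a2", "a3", "b", "b", "b", "b", "c", "d")),
  list(deg = 29, comp = c("a1", "a3", "b", "b", "b", "b", "b", "b", "c", "c", "d", "d"))
)

args <- commandArgs(trailingOnly = TRUE)
sel <- if (length(args)) as.integer(args) else seq_along(ladder)
res <- list()
out <- if (Sys.getenv("LEB_OUT") != "") Sys.getenv("LEB_OUT") else "/root/pkg/scratch/lebedev_varpro.rds"
for (i in sel) {
  L <- ladder[[i]]
  cat(sprintf("deg %d: ", L$deg)); flush.console()
  t0 <- Sys.time()
  s <- solve_varpro(L$comp, L$deg, ntry = 5000, seed = 42 + i)
  dt <- as.numeric(Sys.time() - t0, units = "secs")
  if (is.null(s)) cat(sprintf("FAILED (%.0fs)\n", dt)) else {
    cat(sprintf("ok, %d tries (%.0fs)\n", s$tries, dt))
    res[[as.character(L$deg)]] <- s
    saveRDS(res, out)
  }
}
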