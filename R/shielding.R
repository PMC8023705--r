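# Biot-Savart shielding densities, global and per-domain integration.
#
# The shielding density for nucleus I and tensor component (alpha, beta) is
#   s_ab(r) = alpha^2 [ J^(beta)(r) x u ]_alpha / |u|^3,   u = r - R_I,
# where J^(beta) = dJ/dB_beta is the provider field and alpha^2 is the
# Biot-Savart prefactor in atomic units (mu0/4pi in SI). Its volume
# integral is the (alpha, beta) element of the nuclear magnetic shielding
# tensor; positive regions shield the nucleus, negative regions deshield it.
# A current circulating so that its induced field at the nucleus opposes the
# external field gives positive values.

.component_pairs <- function(component) {
  comp_map <- list(xx = c(1, 1), xy = c(1, 2), xz = c(1, 3),
                   yx = c(2, 1), yy = c(2, 2), yz = c(2, 3),
                   zx = c(3, 1), zy = c(3, 2), zz = c(3, 3))
  if (identical(component, "isotropic")) {
    list(comp_map$xx, comp_map$yy, comp_map$zz)
  } else if (component %in% names(comp_map)) {
    comp_map[component]
  } else {
    stop("unknown shielding component: ", component,
         " (use two Cartesian letters, e.g. \"zz\", or \"isotropic\")")
  }
}

#' Biot-Savart kernel at a point
#'
#' The 3 x 3 linear map `K` from the current-density derivative vector
#' `J(r)` to the shielding-density contribution:
#' `K[alpha, gamma] = alpha^2 eps_{alpha gamma delta} u_delta / |u|^3` with
#' `u = r - R_I`, so that `K %*% J^(beta)` gives the (alpha, beta) density
#' column. The kernel norm scales as `|u|^-2`.
#'
#' @param point Length-3 position (bohr).
#' @param nucleus_pos Length-3 position of nucleus I (bohr).
#' @param exclusion Exclusion radius (bohr); inside it the kernel is the
#'   zero sentinel (attribute `excluded = TRUE`) and the integrand is 0.
#' @return 3 x 3 matrix (a.u.), with attribute `excluded`.
#' @export
biot_savart_kernel <- function(point, nucleus_pos, exclusion = 1e-10) {
  u <- as.numeric(point) - as.numeric(nucleus_pos)
  d <- sqrt(sum(u^2))
  if (d <= exclusion) {
    return(structure(matrix(0, 3, 3), excluded = TRUE))
  }
  K <- matrix(0, 3, 3)
  for (a in 1:3) for (g in 1:3) {
    K[a, g] <- sum(.eps3[a, g, ] * u) / d^3
  }
  structure(shieldens_constants$alpha2 * K, excluded = FALSE)
}

# vectorized density values for one (a, b) pair; J is n x 3
.bs_density_ab <- function(J, points, nucleus_pos, a, b, exclusion = 1e-10) {
  u1 <- points[, 1] - nucleus_pos[1]
  u2 <- points[, 2] - nucleus_pos[2]
  u3 <- points[, 3] - nucleus_pos[3]
  d2 <- u1^2 + u2^2 + u3^2
  # (J x u)_a
  cx <- switch(a,
               J[, 2] * u3 - J[, 3] * u2,
               J[, 3] * u1 - J[, 1] * u3,
               J[, 1] * u2 - J[, 2] * u1)
  v <- shieldens_constants$alpha2 * cx / d2^1.5
  v[d2 <= exclusion^2] <- 0
  v
}

#' Shielding density field at points
#'
#' Evaluates the Biot-Savart shielding-density integrand for one nucleus
#' and one tensor component (or the isotropic mean of xx, yy, zz) at a set
#' of points.
#'
#' @param provider A [current_provider()] (e.g. [bundle_provider()],
#'   [make_loop_provider()], [make_vortex_provider()]).
#' @param mol A [molecule()] supplying the nucleus position.
#' @param nucleus Atom index of the studied nucleus.
#' @param component `"zz"`, any other Cartesian pair, or `"isotropic"`.
#' @param points n x 3 matrix (bohr).
#' @param exclusion Exclusion radius around the nucleus (bohr).
#' @return A `shielding_density_field`: list with `nucleus`, `component`,
#'   `points`, `values` (a.u.; multiply by 1e6 for ppm / bohr^3).
#' @export
shielding_density <- function(provider, mol, nucleus, component, points,
                              exclusion = 1e-10) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (nucleus < 1 || nucleus > n_atoms(mol)) {
    stop("nucleus index out of range: ", nucleus)
  }
  R_I <- mol$coords[nucleus, ]
  pairs <- .component_pairs(component)
  vals <- numeric(nrow(points))
  Tn <- .provider_tensor(provider, points)
  for (p in pairs) {
    J <- Tn[, , p[2], drop = TRUE]
    if (is.null(dim(J))) J <- matrix(J, ncol = 3)
    vals <- vals + .bs_density_ab(J, points, R_I, p[1], p[2], exclusion)
  }
  vals <- vals / length(pairs)
  if (!all(is.finite(vals))) stop("non-finite shielding density values")
  structure(list(nucleus = nucleus, component = component, points = points,
                 values = vals), class = "shielding_density_field")
}

#' Integrate a shielding component over molecular grids
#'
#' Integrates the shielding density over the union of the atomic grids and
#' splits the quadrature sum pointwise into its positive (shielding) and
#' negative (deshielding) parts. `total = positive + negative` holds
#' exactly.
#'
#' @inheritParams shielding_density
#' @param grids List of `atomic_grid` objects from [build_grids()].
#' @return List with `total`, `positive`, `negative` (ppm).
#' @export
integrate_component <- function(provider, mol, nucleus, component, grids,
                                exclusion = 1e-10) {
  pos <- 0; neg <- 0
  for (g in grids) {
    f <- shielding_density(provider, mol, nucleus, component, g$points,
                           exclusion)
    contrib <- g$weights * f$values
    pos <- pos + sum(contrib[contrib > 0])
    neg <- neg + sum(contrib[contrib < 0])
  }
  ppm <- shieldens_constants$ppm
  list(total = (pos + neg) * ppm, positive = pos * ppm, negative = neg * ppm)
}

#' Isotropic average of diagonal shielding components
#'
#' @param sxx,syy,szz Diagonal tensor components.
#' @return Their arithmetic mean.
#' @export
isotropic <- function(sxx, syy, szz) (sxx + syy + szz) / 3

#' Atomic decomposition of a shielding component
#'
#' Integrates the shielding density separately over every Becke atomic
#' domain, giving per-atom contributions with pointwise positive/negative
#' splits and percentages of the grand total. Row labels default to
#' `element + index`; a labeling map (named by label, each entry a vector of
#' atom indices) merges symmetry-equivalent atoms into one row, e.g.
#' ipso/ortho/meta/para.
#'
#' @inheritParams integrate_component
#' @param component Tensor component, default `"isotropic"`.
#' @param labeling Optional named list mapping row labels to atom index
#'   vectors; indices must exist and appear exactly once.
#' @return A `decomposition_table`: data frame with columns `domain`,
#'   `total`, `positive`, `negative` (ppm), `percentage`, plus a grand-total
#'   row; attribute `degenerate` flags an all-zero grand total (percentages
#'   then reported as 0).
#' @export
decompose_atomic <- function(provider, mol, nucleus, grids,
                             component = "isotropic", labeling = NULL,
                             exclusion = 1e-10) {
  nat <- n_atoms(mol)
  tot <- pos <- neg <- numeric(nat)
  for (i in seq_along(grids)) {
    g <- grids[[i]]
    f <- shielding_density(provider, mol, nucleus, component, g$points,
                           exclusion)
    contrib <- g$weights * f$values
    pos[g$owner] <- pos[g$owner] + sum(contrib[contrib > 0])
    neg[g$owner] <- neg[g$owner] + sum(contrib[contrib < 0])
  }
  tot <- pos + neg
  if (is.null(labeling)) {
    labeling <- as.list(stats::setNames(seq_len(nat),
                                        paste0(mol$element, seq_len(nat))))
  } else {
    idx <- unlist(labeling)
    if (any(idx < 1 | idx > nat)) {
      stop("labeling map references absent atom index: ",
           paste(idx[idx < 1 | idx > nat], collapse = ", "))
    }
    if (length(idx) != nat || anyDuplicated(idx)) {
      stop("labeling map must cover every atom exactly once")
    }
  }
  ppm <- shieldens_constants$ppm
  rows <- data.frame(
    domain = names(labeling),
    total = vapply(labeling, function(i) sum(tot[i]), numeric(1)) * ppm,
    positive = vapply(labeling, function(i) sum(pos[i]), numeric(1)) * ppm,
    negative = vapply(labeling, function(i) sum(neg[i]), numeric(1)) * ppm,
    row.names = NULL)
  grand <- sum(rows$total)
  degenerate <- abs(grand) < .Machine$double.eps * 100
  rows$percentage <- if (degenerate) 0 else rows$total / grand * 100
  out <- rbind(rows,
               data.frame(domain = "total", total = grand,
                          positive = sum(rows$positive),
                          negative = sum(rows$negative),
                          percentage = if (degenerate) 0 else 100))
  structure(out, class = c("decomposition_table", "data.frame"),
            nucleus = nucleus, component = component, degenerate = degenerate)
}

#' @export
print.decomposition_table <- function(x, digits = 2, ...) {
  cat(sprintf("Atomic contributions (nucleus %d, component %s)\n",
              attr(x, "nucleus"), attr(x, "component")))
  fmt <- sprintf("%%-10s %%10.%df %%10.%df %%10.%df %%9.%df%%%%\n",
                 digits, digits, digits, digits)
  cat(sprintf("%-10s %10s %10s %10s %10s\n", "domain", "total", "positive",
              "negative", "percentage"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf(fmt, x$domain[i], x$total[i], x$positive[i], x$negative[i],
                x$percentage[i]))
  }
  if (isTRUE(attr(x, "degenerate"))) {
    cat("(grand total is zero; percentages reported as 0)\n")
  }
  invisible(x)
}

#' Write a decomposition table as CSV
#'
#' Column order mirrors the printed table: domain, total, positive,
#' negative, percentage (ppm and percent, unrounded values).
#'
#' @param x A `decomposition_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_decomposition_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
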