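# Response bundle: density matrices and basis from a GIAO NMR calculation.

.bundle_schema <- "shieldens-bundle-1"

#' Create and validate a response bundle
#'
#' A response bundle carries everything the current-density susceptibility
#' tensor evaluation needs: the molecule, the solid-harmonic Gaussian basis,
#' the AO overlap matrix, the unperturbed one-electron density matrix `D`,
#' and the three magnetically perturbed density matrices.
#'
#' Conventions (the adapter contract): AO ordering is shells in input order,
#' within a shell m = -l..l. The electron density is
#' `rho(r) = sum_{mu nu} D[mu, nu] chi_mu(r) chi_nu(r)`; `D` is symmetric.
#' The stored perturbed matrices are the imaginary parts of the complex GIAO
#' perturbed density matrices, `P^beta = Im(dD/dB_beta)`, for a magnetic field
#' differentiated along +x, +y, +z in atomic units; they are real and
#' antisymmetric. Engines that differentiate with respect to -B, use a
#' different AO ordering, or store `-Im(dD/dB)` must be converted with
#' [adapt_engine()].
#'
#' @param mol A [molecule()].
#' @param shells List of [gaussian_shell()] objects over `mol`.
#' @param overlap AO overlap matrix.
#' @param density Unperturbed density matrix `D` (symmetric).
#' @param perturbed_density List of three real antisymmetric matrices
#'   (`Im(dD/dB_x)`, `Im(dD/dB_y)`, `Im(dD/dB_z)`).
#' @param n_electrons Electron count; must equal `tr(D S)`.
#' @param metadata Optional named list (method label, engine label, engine
#'   analytic isotropic shieldings under `analytic_shielding`, ...).
#' @return An object of class `response_bundle`.
#' @export
response_bundle <- function(mol, shells, overlap, density, perturbed_density,
                            n_electrons, metadata = list()) {
  b <- structure(
    list(molecule = mol, shells = shells, overlap = unname(as.matrix(overlap)),
         density = unname(as.matrix(density)),
         perturbed_density = lapply(perturbed_density,
                                    function(m) unname(as.matrix(m))),
         n_electrons = as.numeric(n_electrons), metadata = metadata),
    class = "response_bundle")
  validate_bundle(b)
  b
}

#' Validate a response bundle
#'
#' Checks the structural invariants of the bundle: matching AO dimensions,
#' symmetry of the density (tolerance 1e-10), antisymmetry of the perturbed
#' densities (tolerance 1e-8), and `tr(D S) = n_electrons` (tolerance 1e-8).
#'
#' @param b A `response_bundle`.
#' @return `b` invisibly; stops with a validation error naming the failed
#'   check otherwise.
#' @export
validate_bundle <- function(b) {
  nao <- n_ao(b$shells)
  mats <- c(list(overlap = b$overlap, density = b$density),
            stats::setNames(b$perturbed_density,
                            paste0("perturbed_density_", c("x", "y", "z"))))
  if (length(b$perturbed_density) != 3L) {
    stop("bundle validation error: need exactly 3 perturbed density matrices")
  }
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (!is.matrix(m) || nrow(m) != nao || ncol(m) != nao) {
      stop(sprintf("bundle validation error: %s is not %d x %d (AO dimension from shells)",
                   nm, nao, nao))
    }
    if (!all(is.finite(m))) {
      stop(sprintf("bundle validation error: %s contains non-finite entries", nm))
    }
  }
  if (max(abs(b$density - t(b$density))) > 1e-10) {
    stop("bundle validation error: density not symmetric (tolerance 1e-10)")
  }
  for (i in 1:3) {
    if (max(abs(b$perturbed_density[[i]] + t(b$perturbed_density[[i]]))) > 1e-8) {
      stop(sprintf("bundle validation error: perturbed density %s not antisymmetric (tolerance 1e-8)",
                   c("x", "y", "z")[i]))
    }
  }
  tr <- sum(diag(b$density %*% b$overlap))
  if (abs(tr - b$n_electrons) > 1e-8) {
    stop(sprintf("bundle validation error: tr(D S) = %.10g but n_electrons = %.10g (tolerance 1e-8)",
                 tr, b$n_electrons))
  }
  invisible(b)
}

#' @export
print.response_bundle <- function(x, ...) {
  cat(sprintf("<response_bundle: %d atoms, %d shells, %d AOs, %g electrons>\n",
              n_atoms(x$molecule), length(x$shells), n_ao(x$shells),
              x$n_electrons))
  invisible(x)
}

.num_to_str <- function(x) sprintf("%.17g", x)
.mat_to_list <- function(m) list(dim = dim(m), data = .num_to_str(as.vector(m)))
.list_to_mat <- function(l) matrix(as.numeric(l$data), l$dim[1], l$dim[2])

#' Write a response bundle to a container file
#'
#' The container is a single self-describing JSON file with named datasets
#' (schema string, geometry, shells, matrices). Floating-point values are
#' serialized with 17 significant digits so that a write/read round trip is
#' bit-identical.
#'
#' @param b A [response_bundle()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(b, path) {
  obj <- list(
    schema = .bundle_schema,
    molecule = list(element = b$molecule$element,
                    charge = b$molecule$charge,
                    coords = .mat_to_list(b$molecule$coords)),
    shells = lapply(b$shells, function(s)
      list(center = s$center, l = s$l,
           exponents = .num_to_str(s$exponents),
           coefficients = .num_to_str(s$coefficients))),
    overlap = .mat_to_list(b$overlap),
    density = .mat_to_list(b$density),
    perturbed_density = lapply(b$perturbed_density, .mat_to_list),
    n_electrons = .num_to_str(b$n_electrons),
    metadata = b$metadata)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read a response bundle from a container file
#'
#' Reads a container written by [write_bundle()] (or an engine adapter using
#' the same schema) and validates every bundle invariant.
#'
#' @param path Path to the container file.
#' @return A validated [response_bundle()].
#' @export
read_bundle <- function(path) {
  if (!file.exists(path)) stop("bundle container not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!identical(obj$schema, .bundle_schema)) {
    stop("unsupported bundle schema: ", obj$schema %||% "<missing>")
  }
  for (ds in c("molecule", "shells", "overlap", "density",
               "perturbed_density", "n_electrons")) {
    if (is.null(obj[[ds]])) stop("bundle container missing dataset: ", ds)
  }
  mol <- molecule(unlist(obj$molecule$element),
                  .list_to_mat(obj$molecule$coords),
                  unlist(obj$molecule$charge))
  shells <- lapply(obj$shells, function(s)
    gaussian_shell(s$center, s$l, as.numeric(s$exponents),
                   as.numeric(s$coefficients)))
  response_bundle(mol, shells,
                  .list_to_mat(obj$overlap), .list_to_mat(obj$density),
                  lapply(obj$perturbed_density, .list_to_mat),
                  as.numeric(obj$n_electrons),
                  metadata = obj$metadata %||% list())
}

#' Adapt raw engine output to the canonical bundle conventions
#'
#' Engines expose GIAO density and perturbed density matrices in their own
#' conventions. This adapter converts a raw engine handle into a validated
#' [response_bundle()]. The handle is a plain list with fields:
#'
#' * `molecule`, `shells`, `overlap`, `density`, `n_electrons`: as in
#'   [response_bundle()], in the engine's AO ordering;
#' * `perturbed_density`: list of three matrices, `Im(dD/dB)` in the engine's
#'   sign convention (missing or `NULL` means the engine run had no magnetic
#'   response data);
#' * `ao_permutation`: optional integer vector, canonical AO i comes from
#'   engine AO `ao_permutation[i]`;
#' * `field_sign`: `"+B"` (engine differentiates along +B; default) or
#'   `"-B"` (signs of the perturbed matrices are flipped on import);
#' * `ao_ordering`: label of the engine AO convention; must be
#'   `"solid-harmonic"` (possibly combined with `ao_permutation`), anything
#'   else is rejected as unsupported;
#' * `analytic_shielding`: optional numeric vector of the engine's analytic
#'   isotropic shieldings (ppm) per atom, stored in the bundle metadata for
#'   later quadrature-vs-analytic comparison.
#'
#' @param engine Raw engine handle (list, see Details).
#' @return A validated [response_bundle()].
#' @export
adapt_engine <- function(engine) {
  ordering <- engine$ao_ordering %||% "solid-harmonic"
  if (!identical(ordering, "solid-harmonic")) {
    stop("unsupported engine AO ordering convention: ", ordering,
         " (supported: solid-harmonic, optionally with ao_permutation)")
  }
  if (is.null(engine$perturbed_density)) {
    stop("perturbed densities unavailable: engine run has no magnetic response data")
  }
  perm <- engine$ao_permutation
  adapt_mat <- function(m) {
    m <- as.matrix(m)
    if (!is.null(perm)) m <- m[perm, perm, drop = FALSE]
    m
  }
  sgn <- switch(engine$field_sign %||% "+B", `+B` = 1, `-B` = -1,
                stop("unsupported field sign convention: ", engine$field_sign))
  meta <- list(method = engine$method %||% "unknown",
               engine = engine$engine %||% "unknown",
               ao_ordering = "canonical solid-harmonic (shell order, m = -l..l)",
               field_convention = "+B, atomic units")
  if (!is.null(engine$analytic_shielding)) {
    meta$analytic_shielding <- as.numeric(engine$analytic_shielding)
  }
  response_bundle(engine$molecule, engine$shells,
                  adapt_mat(engine$overlap), adapt_mat(engine$density),
                  lapply(engine$perturbed_density,
                         function(m) sgn * adapt_mat(m)),
                  engine$n_electrons, metadata = meta)
}
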