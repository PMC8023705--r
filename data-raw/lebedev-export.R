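# Freeze solved orbit parameters into R/lebedev_data.R
lo <- readRDS("/root/pkg/scratch/lebedev_varpro.rds")
hi_path <- "/root/pkg/scratch/lebedev_high.rds"
if (file.exists(hi_path)) lo <- c(lo, readRDS(hi_path))
lo <- lo[order(as.integer(names(lo)))]

orbit_mult <- c(a1 = 6, a2 = 12, a3 = 8, b = 24, c = 24, d = 48)
n_par <- c(a1 = 0, a2 = 0, a3 = 0, b = 1, c = 1, d = 2)

lines <- c(
  "# Generated by data-raw/lebedev-solve.R -- do not edit by hand.",
  "# Orbit parameters and weights of the Lebedev-type angular grids,",
  "# solved from the spherical moment equations and frozen here.",
  ".lebedev_params <- list(")
entries <- character(0)
for (key in names(lo)) {
  s <- lo[[key]]
  npts <- sum(orbit_mult[s$comp])
  orbs <- character(0)
  ei <- 1
  for (oi in seq_along(s$comp)) {
    ty <- s$comp[oi]
    w <- s$w[oi]
    ps <- ""
    if (n_par[[ty]] >= 1) { ps <- sprintf(", a = %.17g", s$theta[ei]); ei <- ei + 1 }
    if (n_par[[ty]] == 2) { ps <- paste0(ps, sprintf(", b = %.17g", s$theta[ei])); ei <- ei + 1 }
    orbs <- c(orbs, sprintf("      list(type = \"%s\", w = %.17g%s)", ty, w, ps))
  }
  entries <- c(entries, sprintf("  `%d` = list(degree = %s,\n    orbits = list(\n%s))",
                                npts, key, paste(orbs, collapse = ",\n")))
}
lines <- c(lines, paste(entries, collapse = ",\n"), ")")
writeLines(lines, "/root/pkg/R/lebedev_data.R")
cat("wrote", length(lo), "grids:", paste(names(lo), collapse = " "), "\n")
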