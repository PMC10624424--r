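#' Extinction (specific absorption) tables for HbO2, HHb and oxCCO
#'
#' An extinction table maps wavelength to the specific extinction coefficient
#' of each chromophore, in OD per (micromolar x cm). The chromophore order is
#' fixed as HbO2, HHb, oxCCO and must be full rank over the fit range for the
#' multiwavelength inversion to be solvable.
#'
#' `synthetic_extinction()` builds a deterministic table of three smooth,
#' linearly independent curves; every forward/inverse round-trip test uses it
#' so results are independent of any bundled asset. `default_extinction()`
#' loads the bundled synthetic approximation of the compiled literature
#' spectra (see `inst/extdata/extinction_synthetic.csv`; constructed, not
#' measured).
#'
#' @param wavelengths_nm Wavelength grid in nm.
#' @return An `extinction_table`: list with `wavelengths_nm` and `epsilon`
#'   (length(wavelengths) x 3 matrix, columns HbO2, HHb, oxCCO).
#' @export
synthetic_extinction <- function(wavelengths_nm = seq(780, 900, length.out = 120)) {
  w <- (wavelengths_nm - 780) / 120
  eps <- cbind(
    HbO2 = (0.7 + 0.6 * w) / 1000,
    HHb = (1.1 - 0.5 * w + 0.2 * w^2) / 1000,
    oxCCO = (0.6 + 2.4 * exp(-((wavelengths_nm - 830) / 40)^2)) / 1000
  )
  extinction_table(wavelengths_nm, eps)
}

#' @rdname synthetic_extinction
#' @export
default_extinction <- function() {
  path <- system.file("extdata", "extinction_synthetic.csv", package = "bnirseeg")
  read_extinction(path)
}

#' @rdname synthetic_extinction
#' @param epsilon Matrix (wavelength x 3) of extinction coefficients in
#'   OD / (uM cm), columns ordered HbO2, HHb, oxCCO.
#' @export
extinction_table <- function(wavelengths_nm, epsilon) {
  epsilon <- as.matrix(epsilon)
  stop_if_not(length(wavelengths_nm) == nrow(epsilon),
              "wavelength grid and epsilon rows must match")
  stop_if_not(ncol(epsilon) == 3, "epsilon must have 3 chromophore columns")
  stop_if_not(!is.unsorted(wavelengths_nm, strictly = TRUE),
              "wavelengths must be strictly increasing")
  stop_if_not(all(epsilon[, 1:2] >= 0), "haemoglobin extinctions must be non-negative")
  colnames(epsilon) <- CHROMOPHORES
  structure(list(wavelengths_nm = as.numeric(wavelengths_nm), epsilon = epsilon),
            class = "extinction_table")
}

#' Read / write an extinction table CSV
#'
#' Columns: `wavelength_nm`, `eps_hbo2`, `eps_hhb`, `eps_oxcco` in OD/(uM cm).
#' @param path File path.
#' @export
read_extinction <- function(path) {
  d <- utils::read.csv(path)
  need <- c("wavelength_nm", "eps_hbo2", "eps_hhb", "eps_oxcco")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("extinction file lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  extinction_table(d$wavelength_nm,
                   cbind(d$eps_hbo2, d$eps_hhb, d$eps_oxcco))
}

#' @rdname read_extinction
#' @param ext An `extinction_table`.
#' @export
write_extinction <- function(ext, path) {
  utils::write.csv(
    data.frame(wavelength_nm = ext$wavelengths_nm,
               eps_hbo2 = ext$epsilon[, 1], eps_hhb = ext$epsilon[, 2],
               eps_oxcco = ext$epsilon[, 3]),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Restrict a table to a wavelength window; errors if a requested wavelength is
# not tabulated.
subset_extinction <- function(ext, wavelengths_nm, tol = 1e-6) {
  idx <- vapply(wavelengths_nm, function(w) {
    j <- which(abs(ext$wavelengths_nm - w) < tol)
    if (!length(j)) stop(sprintf(
      "wavelength %.2f nm is not covered by the extinction table", w),
      call. = FALSE)
    j[1]
  }, integer(1))
  extinction_table(ext$wavelengths_nm[idx], ext$epsilon[idx, , drop = FALSE])
}
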