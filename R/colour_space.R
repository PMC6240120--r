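# Avian tetrahedral colour space: reflectance spectra -> quantum catches ->
# chromatic coordinates (x, y, z) and double-cone brightness (a).

#' Standard wavelength grid for reflectance spectra
#'
#' The package works on a fixed grid of 300--700 nm in 5-nm steps (81 points),
#' covering the absorption range of the four avian single-cone classes.
#'
#' @return Numeric vector of wavelengths in nm.
#' @export
spectral_grid <- function() seq(300, 700, by = 5)

.GRID_STEP <- 5

#' Construct a reflectance spectrum
#'
#' @param wavelengths Numeric vector, must equal `spectral_grid()`.
#' @param reflectance Numeric vector of non-negative reflectance fractions,
#'   same length as `wavelengths`.
#' @return An object of class `reflectance_spectrum`.
#' @export
reflectance_spectrum <- function(wavelengths, reflectance) {
  grid <- spectral_grid()
  if (length(wavelengths) != length(reflectance))
    stop("wavelengths and reflectance must have equal length")
  if (length(wavelengths) != length(grid) || any(wavelengths != grid))
    stop("wavelengths must be the complete 300-700 nm grid in 5-nm steps")
  if (any(!is.finite(reflectance)) || any(reflectance < 0))
    stop("reflectance values must be finite and >= 0")
  structure(list(wavelengths = wavelengths, reflectance = reflectance),
            class = "reflectance_spectrum")
}

# Visual pigment absorbance template (A1 chromophore): alpha band as a
# lognormal-type sum of exponentials plus the short-wavelength beta band.
# This is the standard parametric template of visual ecology; measured cone
# sensitivities can be supplied instead via `receptor_set_from_curves()`.
.pigment_template_a1 <- function(lambda, lambda_max) {
  x <- lambda_max / lambda
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  lm_b <- 189 + 0.315 * lambda_max
  b_b <- -40.5 + 0.195 * lambda_max
  beta <- 0.26 * exp(-((lambda - lm_b) / b_b)^2)
  pmax(alpha + beta, 0)
}

.pigment_template_gaussian <- function(lambda, lambda_max, sd = 40) {
  exp(-(lambda - lambda_max)^2 / (2 * sd^2))
}

#' Build a receptor set from pigment templates
#'
#' Generates the four single-cone sensitivity curves (uvs, sws, mws, lws) and
#' the double-cone curve on the standard grid from a parametric visual-pigment
#' template, each normalized to unit area. Defaults approximate the
#' ultraviolet-sensitive (UVS) passerine visual system of the blue tit
#' (single-cone peaks near 371, 449, 502 and 563 nm; double cone near 563 nm).
#' Oil-droplet filtering is not modelled explicitly; the curves are to be read
#' as effective sensitivities.
#'
#' @param lambda_max Named or unnamed numeric vector of four single-cone peak
#'   wavelengths (nm), strictly increasing in the order uvs, sws, mws, lws.
#' @param double_max Peak wavelength of the double cone (nm).
#' @param template `"a1"` (visual-pigment template, default) or `"gaussian"`.
#' @return An object of class `receptor_set`: list with `wavelengths`,
#'   `S` (81 x 4 matrix, columns uvs/sws/mws/lws), `double` (length-81 vector),
#'   `lambda_max`, `double_max`.
#' @export
make_receptors <- function(lambda_max = c(uvs = 371, sws = 449, mws = 502,
                                          lws = 563),
                           double_max = 563, template = c("a1", "gaussian")) {
  template <- match.arg(template)
  grid <- spectral_grid()
  nm <- c("uvs", "sws", "mws", "lws")
  if (length(lambda_max) != 4) stop("lambda_max must have four entries")
  lambda_max <- stats::setNames(as.numeric(lambda_max), nm)
  for (r in nm) {
    if (lambda_max[r] < 300 || lambda_max[r] > 700)
      stop(sprintf("lambda_max for receptor '%s' outside the 300-700 nm grid", r))
  }
  if (any(diff(lambda_max) <= 0))
    stop("lambda_max must be strictly increasing across uvs < sws < mws < lws")
  tfun <- switch(template, a1 = .pigment_template_a1,
                 gaussian = .pigment_template_gaussian)
  S <- vapply(lambda_max, function(lm) tfun(grid, lm), numeric(length(grid)))
  dbl <- tfun(grid, double_max)
  norm1 <- function(s) s / sum(s * .GRID_STEP)
  S <- apply(S, 2, norm1)
  colnames(S) <- nm
  structure(list(wavelengths = grid, S = S, double = norm1(dbl),
                 lambda_max = lambda_max, double_max = double_max,
                 template = template),
            class = "receptor_set")
}

#' Build a receptor set from tabulated sensitivity curves
#'
#' @param S 81 x 4 matrix of single-cone sensitivities on `spectral_grid()`,
#'   columns in the order uvs, sws, mws, lws.
#' @param double Length-81 double-cone sensitivity.
#' @return A `receptor_set`; curves are renormalized to unit area.
#' @export
receptor_set_from_curves <- function(S, double) {
  grid <- spectral_grid()
  S <- as.matrix(S)
  if (nrow(S) != length(grid) || ncol(S) != 4)
    stop("S must be an 81 x 4 matrix on the standard grid")
  if (any(S < 0) || any(double < 0)) stop("sensitivities must be non-negative")
  norm1 <- function(s) s / sum(s * .GRID_STEP)
  S <- apply(S, 2, norm1)
  colnames(S) <- c("uvs", "sws", "mws", "lws")
  peaks <- grid[apply(S, 2, which.max)]
  structure(list(wavelengths = grid, S = S, double = norm1(double),
                 lambda_max = stats::setNames(peaks, colnames(S)),
                 double_max = grid[which.max(double)], template = "tabulated"),
            class = "receptor_set")
}

#' @export
print.receptor_set <- function(x, ...) {
  cat("Receptor set (", x$template, " template)\n", sep = "")
  cat("  single-cone peaks (nm):",
      paste(names(x$lambda_max), round(x$lambda_max), collapse = ", "), "\n")
  cat("  double-cone peak (nm):", round(x$double_max), "\n")
  invisible(x)
}

#' Quantum catches of a reflectance spectrum
#'
#' Photon capture of each receptor: the integral of reflectance x sensitivity
#' x illuminant over wavelength (rectangle rule on the 5-nm grid). Relative
#' catches are the raw single-cone catches divided by their sum; the
#' double-cone catch is computed identically with the double-cone curve.
#'
#' @param spectrum A `reflectance_spectrum` (or a numeric reflectance vector
#'   on the standard grid).
#' @param receptors A `receptor_set`.
#' @param illuminant `"flat"` (ideal equal-energy illuminant, default) or a
#'   non-negative numeric irradiance vector on the standard grid.
#' @return An object of class `cone_catch`: list with `raw` (named u/s/m/l),
#'   `rel` (on the 3-simplex), `double_raw`, and `double_perfect` (double-cone
#'   catch of a perfect reflector under the same illuminant).
#' @export
quantum_catches <- function(spectrum, receptors, illuminant = "flat") {
  if (inherits(spectrum, "reflectance_spectrum")) {
    R <- spectrum$reflectance
  } else {
    R <- as.numeric(spectrum)
    if (length(R) != length(spectral_grid()))
      stop("reflectance vector must be on the standard 81-point grid")
    if (any(R < 0)) stop("reflectance values must be >= 0")
  }
  stopifnot(inherits(receptors, "receptor_set"))
  n <- length(spectral_grid())
  if (identical(illuminant, "flat")) {
    I <- rep(1, n)
  } else {
    I <- as.numeric(illuminant)
    if (length(I) != n) stop("illuminant must be on the standard grid")
    if (any(I < 0) || all(I == 0))
      stop("illuminant must be non-negative and not all zero")
  }
  w <- R * I * .GRID_STEP
  raw <- as.numeric(crossprod(receptors$S, w))
  names(raw) <- c("u", "s", "m", "l")
  tot <- sum(raw)
  if (tot <= 0) stop("degenerate spectrum: zero total quantum catch")
  dbl <- sum(receptors$double * w)
  dbl_perfect <- sum(receptors$double * I * .GRID_STEP)
  structure(list(raw = raw, rel = raw / tot, double_raw = dbl,
                 double_perfect = dbl_perfect),
            class = "cone_catch")
}

#' Construct a cone catch directly from relative catches
#'
#' Convenience constructor for synthetic catches (e.g. when simulating colours
#' without spectra).
#'
#' @param rel Length-4 non-negative vector summing to 1 (u, s, m, l).
#' @param double_raw,double_perfect Optional double-cone catches.
#' @return A `cone_catch`.
#' @export
cone_catch <- function(rel, double_raw = NA_real_, double_perfect = 1) {
  rel <- as.numeric(rel)
  if (length(rel) != 4 || any(rel < -1e-9))
    stop("rel must be four non-negative relative catches")
  if (abs(sum(rel) - 1) > 1e-6) stop("relative catches must sum to 1")
  rel <- pmax(rel, 0); rel <- rel / sum(rel)
  names(rel) <- c("u", "s", "m", "l")
  structure(list(raw = rel, rel = rel, double_raw = double_raw,
                 double_perfect = double_perfect),
            class = "cone_catch")
}

#' Vertex coordinates of the avian colour tetrahedron
#'
#' Regular tetrahedron with circumradius 0.75; rows u, s, m, l. The
#' orientation places the uvs vertex at +z, lws towards +x (red), mws towards
#' +y (green) and sws towards -x/-y (blue/purple), so equal stimulation maps
#' to the origin (achromatic point). Other published parameterizations differ
#' from this one only by a rigid rotation.
#'
#' @return 4 x 3 numeric matrix with rownames u, s, m, l and colnames x, y, z.
#' @export
tetra_vertices <- function() {
  h <- 0.75 * 2 * sqrt(2) / 3               # horizontal circumradius of base
  V <- rbind(u = c(0, 0, 0.75),
             s = c(-h / 2, -h * sqrt(3) / 2, -0.25),
             m = c(-h / 2,  h * sqrt(3) / 2, -0.25),
             l = c(h, 0, -0.25))
  colnames(V) <- c("x", "y", "z")
  V
}

#' Map a cone catch to tetrahedral colour coordinates
#'
#' The colour point is the barycentric mixture of the four vertices weighted
#' by the relative catches, so every valid catch maps inside (or onto) the
#' tetrahedron and equal catches map exactly to the origin. Chromaticity `r`
#' is the Euclidean distance to the achromatic point.
#'
#' @param catch A `cone_catch` (or length-4 relative-catch vector).
#' @return Named numeric vector `c(x, y, z, r)`.
#' @export
to_tetra <- function(catch) {
  if (!inherits(catch, "cone_catch")) catch <- cone_catch(catch)
  rel <- catch$rel
  if (abs(sum(rel) - 1) > 1e-6 || any(rel < -1e-9))
    stop("relative catches are off the simplex")
  xyz <- as.numeric(rel %*% tetra_vertices())
  c(x = xyz[1], y = xyz[2], z = xyz[3],
    r = sqrt(sum(xyz^2)))
}

#' Double-cone brightness of a cone catch
#'
#' Achromatic brightness `a`: the double-cone catch normalized by the catch of
#' a perfect reflector (reflectance identically 1) under the same illuminant,
#' so `a` is scale-free and lies in (0, 1] for physical reflectances. High
#' values mean the fruit is perceived as bright, low values as dark.
#'
#' @param catch A `cone_catch` produced by [quantum_catches()].
#' @return Scalar brightness.
#' @export
brightness <- function(catch) {
  stopifnot(inherits(catch, "cone_catch"))
  if (!is.finite(catch$double_raw))
    stop("cone catch carries no double-cone component")
  catch$double_raw / catch$double_perfect
}

#' Map spectra to colour coordinates and brightness
#'
#' Convenience wrapper running [quantum_catches()], [to_tetra()] and
#' [brightness()] over a table of spectra.
#'
#' @param spectra Data frame in long format with columns `species`,
#'   `wavelength_nm`, `reflectance`, or a species x wavelength matrix whose
#'   columns are the standard grid.
#' @param receptors A `receptor_set` (default blue-tit-like templates).
#' @param illuminant See [quantum_catches()].
#' @return Data frame with columns `species`, `x`, `y`, `z`, `a`, `r`.
#' @export
spectra_to_colours <- function(spectra, receptors = make_receptors(),
                               illuminant = "flat") {
  M <- .spectra_matrix(spectra)
  out <- do.call(rbind, lapply(rownames(M), function(sp) {
    q <- quantum_catches(M[sp, ], receptors, illuminant)
    tc <- to_tetra(q)
    data.frame(species = sp, x = tc["x"], y = tc["y"], z = tc["z"],
               a = brightness(q), r = tc["r"], row.names = NULL)
  }))
  out
}

.spectra_matrix <- function(spectra) {
  grid <- spectral_grid()
  if (is.matrix(spectra)) {
    if (ncol(spectra) != length(grid))
      stop("spectra matrix must have one column per grid wavelength")
    if (is.null(rownames(spectra)))
      rownames(spectra) <- paste0("sp", seq_len(nrow(spectra)))
    return(spectra)
  }
  spectra <- as.data.frame(spectra)
  need <- c("species", "wavelength_nm", "reflectance")
  if (!all(need %in% names(spectra)))
    stop("long-format spectra need columns species, wavelength_nm, reflectance")
  sp <- unique(spectra$species)
  M <- matrix(NA_real_, length(sp), length(grid),
              dimnames = list(sp, grid))
  for (s in sp) {
    sub <- spectra[spectra$species == s, ]
    sub <- sub[order(sub$wavelength_nm), ]
    if (nrow(sub) != length(grid) || any(sub$wavelength_nm != grid))
      stop(sprintf("species '%s' does not cover the complete grid", s))
    M[s, ] <- sub$reflectance
  }
  M
}

#' Read spectra from CSV
#'
#' Accepts the long format (columns `species`, `wavelength_nm`,
#' `reflectance`) or a wide species-by-wavelength table whose first column is
#' the species name and remaining column names are wavelengths.
#'
#' @param path File path.
#' @return Long-format data frame.
#' @export
read_spectra <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (all(c("species", "wavelength_nm", "reflectance") %in% names(df)))
    return(df[, c("species", "wavelength_nm", "reflectance")])
  wl <- suppressWarnings(as.numeric(names(df)[-1]))
  if (any(is.na(wl))) stop("unrecognized spectra layout")
  data.frame(species = rep(df[[1]], times = length(wl)),
             wavelength_nm = rep(wl, each = nrow(df)),
             reflectance = as.numeric(as.matrix(df[, -1])))
}

#' Write colour coordinates to CSV
#'
#' @param colours Data frame from [spectra_to_colours()].
#' @param path File path.
#' @export
write_colours <- function(colours, path) {
  utils::write.csv(colours[, c("species", "x", "y", "z", "a")], path,
                   row.names = FALSE)
}
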