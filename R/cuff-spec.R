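#' Tapered perivascular cuff specification
#'
#' Describes the rigid flow-modifying cuff whose bore narrows linearly
#' between its two ends.  The default dimensions are the 500 to 250 micron
#' taper over 1.5 mm used throughout this package.
#'
#' The longitudinal coordinate convention used everywhere in the package
#' places `x = 0` at the cuff's *narrow* end, with `x` increasing in the
#' flow direction.  A `forward` cuff (wide end upstream) therefore spans
#' `[-length, 0]`; a `reversed` cuff (narrow end upstream) spans
#' `[0, length]`.
#'
#' @param length Cuff length in micron (default 1500).
#' @param wide_diameter Bore diameter at the wide end, micron (default 500).
#' @param narrow_diameter Bore diameter at the narrow end, micron
#'   (default 250).
#' @param orientation `"forward"` (wide end upstream, the conventional
#'   placement) or `"reversed"` (narrow end upstream).
#' @return An object of class `cuff_spec`.
#' @examples
#' cuff <- cuff_spec()
#' cuff_bore_diameter(cuff, c(-1500, -750, 0))
#' @export
cuff_spec <- function(length = 1500, wide_diameter = 500,
                      narrow_diameter = 250,
                      orientation = c("forward", "reversed")) {
  orientation <- match.arg(orientation)
  stopifnot(is.numeric(length), length > 0)
  if (!(wide_diameter > narrow_diameter && narrow_diameter > 0))
    stop("cuff_spec: require wide_diameter > narrow_diameter > 0")
  structure(
    list(length = length, wide_diameter = wide_diameter,
         narrow_diameter = narrow_diameter, orientation = orientation),
    class = "cuff_spec")
}

#' @export
print.cuff_spec <- function(x, ...) {
  cat(sprintf("Tapered cuff: %g -> %g um bore over %g um (%s orientation)\n",
              x$wide_diameter, x$narrow_diameter, x$length, x$orientation))
  invisible(x)
}

#' Longitudinal extent of the cuff in the package coordinate frame
#'
#' @param cuff A [cuff_spec()].
#' @return Numeric length-2 vector `c(upstream_end, downstream_end)` in
#'   micron; `x = 0` is always the narrow end.
#' @export
cuff_extent <- function(cuff) {
  stopifnot(inherits(cuff, "cuff_spec"))
  if (cuff$orientation == "forward") c(-cuff$length, 0) else c(0, cuff$length)
}

#' Cuff bore diameter at longitudinal positions
#'
#' The bore varies linearly from the wide to the narrow end; positions
#' outside the cuff return `NA`.
#'
#' @param cuff A [cuff_spec()].
#' @param x Positions in micron (cuff frame, narrow end at 0).
#' @return Bore diameters in micron, `NA` outside the cuff.
#' @export
cuff_bore_diameter <- function(cuff, x) {
  ext <- cuff_extent(cuff)
  inside <- x >= ext[1] & x <= ext[2]
  d <- rep(NA_real_, length(x))
  # |x| is the distance from the narrow end for either orientation
  d[inside] <- cuff$narrow_diameter +
    (cuff$wide_diameter - cuff$narrow_diameter) * abs(x[inside]) / cuff$length
  d
}

#' Blood fluid properties
#'
#' Newtonian fluid constants used by the hemodynamic calculations.
#'
#' @param mu Dynamic viscosity in kg/(m s); default 0.004.
#' @param rho Density in kg/m^3; default 1015.
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(mu = 0.004, rho = 1015) {
  stopifnot(mu > 0, rho > 0)
  structure(list(mu = mu, rho = rho), class = "fluid_properties")
}

# Run an expression with a locally seeded RNG, restoring prior state.
# All generators funnel through this so same (config, seed) is bit-identical
# and callers' RNG streams are untouched.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
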