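#' Egg volume from axis measurements
#'
#' Predator eggs are prolate spheroids measured by their semi-major axis
#' `a` and semi-minor axis `b` (two equal minor axes); prey eggs are
#' spheres measured by their radius `r`.  Volumes (in um^3) are
#' \deqn{V = \tfrac{4}{3}\pi a b^2 \quad\text{or}\quad
#'       V = \tfrac{4}{3}\pi r^3.}
#'
#' @param shape `"ellipsoid"` or `"sphere"`.
#' @param a_um,b_um semi-major and semi-minor axes in um (ellipsoid).
#' @param r_um radius in um (sphere).
#' @return Volume(s) in um^3.  Vectorized over the axis arguments.
#' @examples
#' egg_volume("sphere", r_um = 70)           # ~1.437e6 um^3
#' egg_volume("ellipsoid", a_um = 100, b_um = 80)
#' @export
egg_volume <- function(shape = c("ellipsoid", "sphere"),
                       a_um = NULL, b_um = NULL, r_um = NULL) {
  shape <- match.arg(shape)
  if (shape == "sphere") {
    if (is.null(r_um)) stop("sphere geometry needs 'r_um'", call. = FALSE)
    if (any(r_um <= 0)) stop("radius must be positive", call. = FALSE)
    4 / 3 * pi * r_um^3
  } else {
    if (is.null(a_um) || is.null(b_um))
      stop("ellipsoid geometry needs 'a_um' and 'b_um'", call. = FALSE)
    if (any(a_um <= 0) || any(b_um <= 0))
      stop("axes must be positive", call. = FALSE)
    if (any(a_um < b_um))
      stop("semi-major axis must be >= semi-minor axis", call. = FALSE)
    4 / 3 * pi * a_um * b_um^2
  }
}

#' Daily sexing subsample of deposited eggs
#'
#' Emulates the sex-determination protocol: each day, up to `k` eggs per
#' ovipositing female are drawn uniformly at random without replacement for
#' rearing to adulthood (where the sex becomes observable); if a female laid
#' `k` or fewer eggs that day, all of them are taken.  Selection ignores
#' egg size, so the subsample is size-unbiased.
#'
#' @param eggs data frame of candidate egg rows with at least columns
#'   `female_id` and `day`.
#' @param k maximum eggs selected per female-day (default 2).
#' @return The selected rows of `eggs` (possibly zero rows).  Uses the
#'   current RNG state; seed upstream for reproducibility.
#' @export
sexing_subsample <- function(eggs, k = 2L) {
  stopifnot(is.data.frame(eggs), k >= 1)
  if (!all(c("female_id", "day") %in% names(eggs)))
    stop("eggs table needs 'female_id' and 'day' columns", call. = FALSE)
  if (!nrow(eggs)) return(eggs)
  key <- interaction(eggs$female_id, eggs$day, drop = TRUE)
  idx <- unlist(lapply(split(seq_len(nrow(eggs)), key), function(i) {
    if (length(i) <= k) i else sample(i, k)
  }), use.names = FALSE)
  eggs[sort(idx), , drop = FALSE]
}
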