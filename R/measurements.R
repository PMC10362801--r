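#' Single-distance change (background-subtracted intensity)
#'
#' @param i_t intensity at time t (nA or mW mm^-2).
#' @param i_0 baseline intensity in the same units.
#' @return `i_t - i_0`.
#' @export
delta_sd <- function(i_t, i_0) i_t - i_0

#' Single ratio of long- over short-distance intensities
#'
#' @param i_long,i_short intensities measured at the long and short
#'   source-detector distances; `i_short` must be positive.
#' @return `i_long / i_short`.
#' @export
single_ratio <- function(i_long, i_short) {
  if (any(i_short <= 0)) stop_invalid("short-distance intensity must be > 0")
  i_long / i_short
}

#' @rdname single_ratio
#' @param i_long_0,i_short_0 baseline intensities.
#' @return `delta_sr()`: the current ratio minus the baseline ratio.
#' @export
delta_sr <- function(i_long, i_short, i_long_0, i_short_0) {
  single_ratio(i_long, i_short) - single_ratio(i_long_0, i_short_0)
}

#' Intensity quartet for a dual-ratio measurement
#'
#' The four source-detector intensities entering a DR, in the fixed pair
#' order `A1, A2, B1, B2` (detector letter, source number). With the
#' default symmetric layout A1 and B2 are the short-distance pairs
#' (`s,I` and `s,II`) and A2 and B1 the long-distance pairs (`l,I` and
#' `l,II`).
#'
#' @param A1,A2,B1,B2 positive intensities (any common unit).
#' @return Named numeric vector of class `intensity_quartet`.
#' @export
intensity_quartet <- function(A1, A2, B1, B2) {
  q <- c(A1 = A1, A2 = A2, B1 = B1, B2 = B2)
  if (any(!is.finite(q)) || any(q <= 0))
    stop_invalid("all four intensities must be positive and finite")
  structure(q, class = "intensity_quartet")
}

# accept a quartet object, a named vector, or a 4-column matrix of draws
as_quartet_matrix <- function(q) {
  if (is.matrix(q)) {
    if (ncol(q) != 4L) stop_invalid("quartet matrix must have 4 columns")
    if (!is.null(colnames(q))) q <- q[, c("A1", "A2", "B1", "B2"), drop = FALSE]
    return(q)
  }
  q <- unclass(q)
  if (!is.null(names(q))) q <- q[c("A1", "A2", "B1", "B2")]
  if (length(q) != 4L || any(is.na(q)))
    stop_invalid("quartet must supply A1, A2, B1, B2")
  matrix(q, nrow = 1, dimnames = list(NULL, c("A1", "A2", "B1", "B2")))
}

#' Dual ratio of an intensity quartet
#'
#' The geometric mean of the two single ratios of a symmetric optode
#' arrangement:
#' `DR = sqrt( (I_l,I * I_l,II) / (I_s,I * I_s,II) )`
#' ` = sqrt( (I_A2 * I_B1) / (I_A1 * I_B2) )`.
#' All multiplicative factors attached to a single optode cancel exactly.
#'
#' @param q an [intensity_quartet()], a named vector with elements
#'   `A1, A2, B1, B2`, or a matrix of draws with those columns.
#' @return The DR value(s), dimensionless.
#' @export
dual_ratio <- function(q) {
  m <- as_quartet_matrix(q)
  if (any(m <= 0)) stop_invalid("dual ratio requires positive intensities")
  unname(sqrt((m[, "A2"] * m[, "B1"]) / (m[, "A1"] * m[, "B2"])))
}

#' @rdname dual_ratio
#' @param q_t,q_0 current and baseline quartets.
#' @return `delta_dr()`: current DR minus baseline DR.
#' @export
delta_dr <- function(q_t, q_0) dual_ratio(q_t) - dual_ratio(q_0)

#' Measurement geometry of two sources and two detectors
#'
#' The default layout places detector A at `-3.5` mm, detector B at
#' `+3.5` mm, source 1 at `-0.5` mm, and source 2 at `+0.5` mm along x on
#' the surface, giving short distances rho(A1) = rho(B2) = 3 mm and long
#' distances rho(A2) = rho(B1) = 4 mm.
#'
#' @param sources named list of two source [optode()]s (default `1`, `2`).
#' @param detectors named list of two detector [optode()]s (default
#'   `A`, `B`).
#' @param det_na numerical aperture used for the default detectors.
#' @return A `measurement_geometry`: the optodes plus a data frame of the
#'   four pairs with their distances `rho_mm`.
#' @export
measurement_geometry <- function(sources = NULL, detectors = NULL,
                                 det_na = 0.5) {
  if (is.null(sources))
    sources <- list(`1` = optode(c(-0.5, 0), "source", name = "1"),
                    `2` = optode(c(0.5, 0), "source", name = "2"))
  if (is.null(detectors))
    detectors <- list(A = optode(c(-3.5, 0), "detector", na = det_na, name = "A"),
                      B = optode(c(3.5, 0), "detector", na = det_na, name = "B"))
  if (length(sources) != 2L || length(detectors) != 2L)
    stop_invalid("exactly two sources and two detectors are required")
  pairs <- expand.grid(detector = names(detectors), source = names(sources),
                       stringsAsFactors = FALSE)
  pairs$pair <- paste0(pairs$detector, pairs$source)
  pairs$rho_mm <- mapply(function(d, s) {
    sqrt(sum((detectors[[d]]$position[1:2] - sources[[s]]$position[1:2])^2))
  }, pairs$detector, pairs$source)
  structure(list(sources = sources, detectors = detectors, pairs = pairs),
            class = "measurement_geometry")
}

#' @export
print.measurement_geometry <- function(x, ...) {
  cat("<measurement_geometry>\n")
  print(x$pairs[, c("pair", "rho_mm")], row.names = FALSE)
  invisible(x)
}

#' Validate the dual-ratio symmetry of an optode layout
#'
#' A valid DR layout requires that the optodes forming the short distance
#' of one single ratio form the long distance of the other and vice versa:
#' the four source-detector distances must collapse (within `tol`) to one
#' short value shared by two disjoint pairs and one strictly longer value
#' shared by the complementary pairs.
#'
#' @param geom a [measurement_geometry()].
#' @param tol distance tolerance, mm.
#' @return A list: `valid` flag; when valid, `assignment` naming the
#'   `s_I, l_I, s_II, l_II` pairs and `rho_short_mm` / `rho_long_mm`;
#'   otherwise a `diagnostic` message.
#' @export
validate_dr_layout <- function(geom, tol = 1e-6) {
  stopifnot(inherits(geom, "measurement_geometry"))
  p <- geom$pairs
  rho <- setNames(p$rho_mm, p$pair)
  dets <- names(geom$detectors)
  srcs <- names(geom$sources)
  # candidate: detector I = first detector; its shorter pair is s,I
  invalid <- function(msg) list(valid = FALSE, diagnostic = msg)
  pA <- paste0(dets[1], srcs)   # pairs of detector I
  pB <- paste0(dets[2], srcs)   # pairs of detector II
  oA <- order(rho[pA]); oB <- order(rho[pB])
  s_I <- pA[oA[1]]; l_I <- pA[oA[2]]
  s_II <- pB[oB[1]]; l_II <- pB[oB[2]]
  if (abs(rho[s_I] - rho[l_I]) <= tol || abs(rho[s_II] - rho[l_II]) <= tol)
    return(invalid("degenerate layout: no long/short distinction"))
  # symmetry: the source of s,I must be the source of l,II and vice versa
  src_of <- function(pair) substring(pair, 2)
  if (src_of(s_I) != src_of(l_II) || src_of(s_II) != src_of(l_I))
    return(invalid("short-distance source of one ratio must form the long distance of the other"))
  if (abs(rho[s_I] - rho[s_II]) > tol || abs(rho[l_I] - rho[l_II]) > tol)
    return(invalid(sprintf(
      "asymmetric distances: short %g vs %g mm, long %g vs %g mm",
      rho[s_I], rho[s_II], rho[l_I], rho[l_II])))
  list(valid = TRUE,
       assignment = c(s_I = s_I, l_I = l_I, s_II = s_II, l_II = l_II),
       rho_short_mm = unname(rho[s_I]), rho_long_mm = unname(rho[l_I]))
}

#' Read an intensity quartet time series from CSV
#'
#' Expects columns `time`, `I_A1`, `I_A2`, `I_B1`, `I_B2` (one header
#' line).
#'
#' @param path CSV file path.
#' @return Data frame with those columns.
#' @export
read_quartets <- function(path) {
  df <- read.csv(path)
  need <- c("time", "I_A1", "I_A2", "I_B1", "I_B2")
  if (!all(need %in% names(df)))
    stop_invalid("quartet CSV must have columns %s", paste(need, collapse = ", "))
  df[, need]
}
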