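#' Generate a quasi-uniform whole-head sensor layout
#'
#' Places `n_sensors` points on the upper unit hemisphere with the
#' Fibonacci-sphere construction (golden-angle azimuths, uniform spacing in
#' the vertical coordinate), emulating a whole-head gradiometer helmet such
#' as a 160-channel system. A 2D azimuthal-equidistant projection (radius =
#' polar angle) is attached for plotting and triangulation; positive
#' projected y is taken as anterior, so "posterior" sensors have `py < 0`.
#'
#' The construction is deterministic; `jitter > 0` adds seeded angular noise
#' for robustness testing.
#'
#' @param n_sensors number of sensors (>= 4, needed for triangulation).
#' @param jitter sd of optional angular jitter (radians), default 0.
#' @param seed seed for the jitter draws (unused when `jitter = 0`).
#' @return a data.frame of class `sensor_layout` with columns `sensor`
#'   (ids `S001`, ...), `x`, `y`, `z` (unit sphere, `z >= 0`), `px`, `py`
#'   (2D projection).
#' @examples
#' lay <- make_layout(160)
#' all(lay$z >= 0)
#' @export
make_layout <- function(n_sensors = 160, jitter = 0, seed = 1L) {
  if (n_sensors < 4)
    stop("cannot triangulate a layout with fewer than 4 sensors")
  i <- seq_len(n_sensors)
  z <- (i - 0.5) / n_sensors          # uniform in height over (0, 1)
  golden <- pi * (3 - sqrt(5))
  az <- (i - 1) * golden
  theta <- acos(z)                     # polar angle from vertex
  if (jitter > 0) {
    set.seed(as.integer(seed))
    az <- az + rnorm(n_sensors, 0, jitter)
    theta <- pmin(pmax(theta + rnorm(n_sensors, 0, jitter), 0), pi / 2)
  }
  out <- data.frame(
    sensor = sprintf("S%03d", i),
    x = sin(theta) * cos(az),
    y = sin(theta) * sin(az),
    z = cos(theta),
    px = theta * cos(az),
    py = theta * sin(az))
  if (anyDuplicated(round(out[, c("x", "y", "z")], 12)))
    stop("degenerate layout: duplicated sensor positions")
  class(out) <- c("sensor_layout", "data.frame")
  out
}

#' Read / write a sensor layout as delimited text
#'
#' Layouts are stored as tab-delimited text with columns `sensor`, `x`,
#' `y`, `z` and optionally `px`, `py`; if the projection columns are absent
#' they are recomputed with the azimuthal-equidistant projection.
#'
#' @param path file path.
#' @return `read_layout`: a `sensor_layout`; `write_layout`: `path`,
#'   invisibly.
#' @export
read_layout <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sensor", "x", "y", "z")
  if (!all(need %in% names(tab)))
    stop("layout file needs columns ", paste(need, collapse = ", "))
  if (!all(c("px", "py") %in% names(tab))) {
    r <- sqrt(tab$x^2 + tab$y^2 + tab$z^2)
    theta <- acos(pmin(pmax(tab$z / r, -1), 1))
    az <- atan2(tab$y, tab$x)
    tab$px <- theta * cos(az)
    tab$py <- theta * sin(az)
  }
  class(tab) <- c("sensor_layout", "data.frame")
  tab
}

#' @rdname read_layout
#' @param layout a `sensor_layout`.
#' @export
write_layout <- function(layout, path) {
  write.table(as.data.frame(layout), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Smooth spatial weight patch over a sensor layout
#'
#' Builds a per-sensor weight vector in `[0, 1]` that is 1 at the `n_core`
#' sensors nearest (3D great-circle distance) to a centre sensor and decays
#' with a Gaussian profile outside, or a hard 0/1 patch when
#' `soft = FALSE`. Used to seed spatially restricted oddball responses.
#'
#' @param layout a `sensor_layout`.
#' @param center sensor id or index of the patch centre; default: the most
#'   posterior sensor (minimum projected y).
#' @param n_core number of sensors with weight 1.
#' @param soft logical; smooth Gaussian skirt (default) or binary patch.
#' @param sigma decay scale (radians of great-circle distance) for the skirt.
#' @return numeric weight vector, one per sensor.
#' @export
patch_topography <- function(layout, center = NULL, n_core = 10,
                             soft = TRUE, sigma = 0.3) {
  P <- as.matrix(layout[, c("x", "y", "z")])
  if (is.null(center)) {
    ci <- which.min(layout$py)
  } else if (is.character(center)) {
    ci <- match(center, layout$sensor)
    if (is.na(ci)) stop("unknown sensor id: ", center)
  } else ci <- as.integer(center)
  cosd <- pmin(pmax(P %*% P[ci, ], -1), 1)
  d <- acos(cosd)[, 1]                 # great-circle distance to centre
  core <- order(d)[seq_len(min(n_core, nrow(P)))]
  w <- numeric(nrow(P))
  w[core] <- 1
  if (soft) {
    edge <- max(d[core])
    out <- setdiff(seq_len(nrow(P)), core)
    w[out] <- exp(-((d[out] - edge)^2) / (2 * sigma^2))
  }
  w
}

#' @export
print.sensor_layout <- function(x, ...) {
  cat("<sensor_layout> ", nrow(x), " sensors on the upper hemisphere\n",
      sep = "")
  print.data.frame(head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}
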