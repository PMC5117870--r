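#' Analytic Gaussian odour field
#'
#' A planar odour concentration landscape modelled as a scaled bivariate
#' normal density: `C(x, y) = c * M(x, y)` where `M` is the bivariate normal
#' density with mean `(mu_x, mu_y)`, spreads `(sigma_x, sigma_y)` and
#' correlation `rho`. This is the standard virtual odour source used by both
#' agents; `c` sets the peak concentration scale (concentration * mm^2).
#'
#' An optional rectangular arena (`xlim`, `ylim`) defines the boundary the
#' agents react to: queries outside it return `NA`, the out-of-bounds signal
#' consumed by the agents' boundary rule. Without limits the field is
#' unbounded (it is strictly positive everywhere).
#'
#' @param mu_x,mu_y source position (mm).
#' @param sigma_x,sigma_y spreads (mm, > 0).
#' @param rho correlation of the two coordinates, in (-1, 1).
#' @param c amplitude scale (concentration * mm^2).
#' @param xlim,ylim optional length-2 numeric arena bounds (mm); `NULL` for an
#'   unbounded field.
#' @return an object of class `c("gaussian_field", "odour_field")`.
#' @examples
#' f <- gaussian_field(0, 0, 10, 10, rho = 1/5, c = 1e3)
#' field_value(f, 5, 5)
#' @export
gaussian_field <- function(mu_x = 0, mu_y = 0, sigma_x = 10, sigma_y = 10,
                           rho = 0, c = 1, xlim = NULL, ylim = NULL) {
  for (v in list(mu_x, mu_y, sigma_x, sigma_y, rho, c)) stopifnot_scalar(v, "field parameter")
  if (sigma_x <= 0 || sigma_y <= 0) stop("sigma_x and sigma_y must be > 0", call. = FALSE)
  if (abs(rho) >= 1) stop("rho must lie strictly inside (-1, 1)", call. = FALSE)
  if (c < 0) stop("amplitude scale c must be >= 0", call. = FALSE)
  if (!is.null(xlim)) stopifnot(length(xlim) == 2L, xlim[1] < xlim[2])
  if (!is.null(ylim)) stopifnot(length(ylim) == 2L, ylim[1] < ylim[2])
  structure(list(mu_x = mu_x, mu_y = mu_y, sigma_x = sigma_x, sigma_y = sigma_y,
                 rho = rho, c = c, xlim = xlim, ylim = ylim),
            class = c("gaussian_field", "odour_field"))
}

#' Evaluate the scaled bivariate normal concentration
#'
#' Direct evaluation of the scaled density; vectorised over coordinates.
#' Strictly positive for finite inputs.
#'
#' @param field a `gaussian_field`.
#' @param x,y coordinates (mm).
#' @return concentration values.
#' @export
gaussian_concentration <- function(field, x, y) {
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("coordinates must be finite", call. = FALSE)
  dx <- (x - field$mu_x) / field$sigma_x
  dy <- (y - field$mu_y) / field$sigma_y
  r <- field$rho
  q <- (dx^2 + dy^2 - 2 * r * dx * dy) / (2 * (1 - r^2))
  field$c * exp(-q) / (2 * pi * field$sigma_x * field$sigma_y * sqrt(1 - r^2))
}

#' Gridded odour field
#'
#' A rectangular map of non-negative concentrations sampled at regularly
#' spaced cell centres, queried by bilinear interpolation inside the convex
#' hull of the cell centres. Queries outside the hull return `NA` (the
#' out-of-bounds signal); the field never extrapolates or clamps, so the
#' agent owns the boundary reaction.
#'
#' @param values numeric matrix of concentrations; rows index x, columns y.
#' @param origin length-2 numeric, position (mm) of the cell centre
#'   `values[1, 1]`.
#' @param cell_size grid spacing (mm, > 0).
#' @return an object of class `c("grid_field", "odour_field")`.
#' @export
grid_field <- function(values, origin = c(0, 0), cell_size = 1) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("grid values must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("grid cells must be finite and >= 0", call. = FALSE)
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("grid must be at least 2 x 2", call. = FALSE)
  stopifnot(length(origin) == 2L, is.finite(origin))
  stopifnot_scalar(cell_size)
  if (cell_size <= 0) stop("cell_size must be > 0", call. = FALSE)
  structure(list(values = values, origin = as.numeric(origin), cell_size = cell_size),
            class = c("grid_field", "odour_field"))
}

#' Query an odour field
#'
#' Returns the concentration at planar positions. Analytic Gaussian fields
#' delegate to [gaussian_concentration()]; grid fields interpolate
#' bilinearly. Out-of-bounds queries (outside the arena limits of a Gaussian
#' field, or outside the hull of grid cell centres) return `NA_real_` — a
#' distinguished signal, not a value — which the simulators translate into
#' the boundary rule.
#'
#' @param field an `odour_field`.
#' @param x,y coordinates (mm), vectorised.
#' @return numeric vector of concentrations, `NA` where out of bounds.
#' @export
field_value <- function(field, x, y) UseMethod("field_value")

#' @export
field_value.gaussian_field <- function(field, x, y) {
  v <- gaussian_concentration(field, x, y)
  oob <- field_oob(field, x, y)
  v[oob] <- NA_real_
  v
}

#' @export
field_value.grid_field <- function(field, x, y) {
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("coordinates must be finite", call. = FALSE)
  gx <- (x - field$origin[1]) / field$cell_size   # 0-based continuous index
  gy <- (y - field$origin[2]) / field$cell_size
  nx <- nrow(field$values); ny <- ncol(field$values)
  out <- rep(NA_real_, length(gx))
  ok <- gx >= 0 & gx <= nx - 1 & gy >= 0 & gy <= ny - 1
  if (any(ok)) {
    i0 <- pmin(floor(gx[ok]), nx - 2); j0 <- pmin(floor(gy[ok]), ny - 2)
    fx <- gx[ok] - i0; fy <- gy[ok] - j0
    v00 <- field$values[cbind(i0 + 1, j0 + 1)]
    v10 <- field$values[cbind(i0 + 2, j0 + 1)]
    v01 <- field$values[cbind(i0 + 1, j0 + 2)]
    v11 <- field$values[cbind(i0 + 2, j0 + 2)]
    out[ok] <- v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
      v01 * (1 - fx) * fy + v11 * fx * fy
  }
  out
}

#' Spatial gradient of an odour field
#'
#' Used by the continuous agent to form dC/dt along the path by the chain
#' rule. Analytic for Gaussian fields; piecewise-bilinear (cellwise) for
#' grids. Out of bounds yields `NA` components.
#'
#' @inheritParams field_value
#' @return list with numeric vectors `dx`, `dy`.
#' @export
field_gradient <- function(field, x, y) UseMethod("field_gradient")

#' @export
field_gradient.gaussian_field <- function(field, x, y) {
  v <- field_value(field, x, y)
  dx <- (x - field$mu_x) / field$sigma_x
  dy <- (y - field$mu_y) / field$sigma_y
  r <- field$rho
  # d/dx of the quadratic form in the exponent
  qx <- (dx / field$sigma_x - r * dy / field$sigma_x) / (1 - r^2)
  qy <- (dy / field$sigma_y - r * dx / field$sigma_y) / (1 - r^2)
  list(dx = -v * qx, dy = -v * qy)
}

#' @export
field_gradient.grid_field <- function(field, x, y) {
  h <- field$cell_size
  gx <- (x - field$origin[1]) / h
  gy <- (y - field$origin[2]) / h
  nx <- nrow(field$values); ny <- ncol(field$values)
  ddx <- rep(NA_real_, length(gx)); ddy <- ddx
  ok <- gx >= 0 & gx <= nx - 1 & gy >= 0 & gy <= ny - 1
  if (any(ok)) {
    i0 <- pmin(floor(gx[ok]), nx - 2); j0 <- pmin(floor(gy[ok]), ny - 2)
    fx <- gx[ok] - i0; fy <- gy[ok] - j0
    v00 <- field$values[cbind(i0 + 1, j0 + 1)]
    v10 <- field$values[cbind(i0 + 2, j0 + 1)]
    v01 <- field$values[cbind(i0 + 1, j0 + 2)]
    v11 <- field$values[cbind(i0 + 2, j0 + 2)]
    ddx[ok] <- ((v10 - v00) * (1 - fy) + (v11 - v01) * fy) / h
    ddy[ok] <- ((v01 - v00) * (1 - fx) + (v11 - v10) * fx) / h
  }
  list(dx = ddx, dy = ddy)
}

#' Rescale an odour field
#'
#' Multiplies all concentrations by a non-negative factor, emulating a change
#' of odour source strength. Commutes exactly with [field_value()].
#'
#' @param field an `odour_field`.
#' @param factor dimensionless scale, >= 0.
#' @return a field of the same class.
#' @export
scale_field <- function(field, factor) {
  stopifnot_scalar(factor)
  if (factor < 0) stop("scale factor must be >= 0", call. = FALSE)
  if (inherits(field, "gaussian_field")) {
    field$c <- field$c * factor
  } else if (inherits(field, "grid_field")) {
    field$values <- field$values * factor
  } else stop("not an odour field", call. = FALSE)
  field
}

# Arena membership. Grid fields are bounded by their cell-centre hull;
# Gaussian fields by their optional xlim/ylim.
field_oob <- function(field, x, y) {
  if (inherits(field, "grid_field")) {
    nx <- nrow(field$values); ny <- ncol(field$values)
    xr <- field$origin[1] + c(0, (nx - 1) * field$cell_size)
    yr <- field$origin[2] + c(0, (ny - 1) * field$cell_size)
    return(x < xr[1] | x > xr[2] | y < yr[1] | y > yr[2])
  }
  oob <- rep(FALSE, length(x))
  if (!is.null(field$xlim)) oob <- oob | x < field$xlim[1] | x > field$xlim[2]
  if (!is.null(field$ylim)) oob <- oob | y < field$ylim[1] | y > field$ylim[2]
  oob
}

#' Read / write a grid odour map
#'
#' Grid maps are stored as a plain CSV matrix of concentrations (rows = x
#' index, columns = y index, no header) with a JSON sidecar
#' (`<path>.json`) holding `origin` and `cell_size` in mm.
#'
#' @param path CSV file path.
#' @return `read_grid_field` returns a `grid_field`;
#'   `write_grid_field` returns `path` invisibly.
#' @export
read_grid_field <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(side))
    stop("grid map needs both the CSV matrix and its .json sidecar", call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  vals <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(vals) <- NULL
  if (!is.numeric(vals)) stop("malformed grid map: non-numeric cells", call. = FALSE)
  grid_field(vals, origin = as.numeric(meta$origin), cell_size = as.numeric(meta$cell_size))
}

#' @rdname read_grid_field
#' @param field a `grid_field`.
#' @export
write_grid_field <- function(field, path) {
  stopifnot(inherits(field, "grid_field"))
  utils::write.table(field$values, path, sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(origin = field$origin, cell_size = field$cell_size,
                            units = "mm"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
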