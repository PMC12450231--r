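#' Generate a synthetic two-region patch landscape
#'
#' Builds the model environment: a `width` x `height` lattice of patches split
#' into two regions (Tian Shan to the left of `boundary_col`, Altai to the
#' right). Ordinary patches receive uniform-integer resources on
#' `[0, resource_max]` with cap `resource_max`; the requested number of
#' attractor patches per region start full at cap `attractor_cap`. Attractor
#' patches are placed uniformly at random within their region subject to a
#' minimum pairwise spacing (in km), mirroring the spacing rule for shelters.
#'
#' Each patch represents 0.5 km2, so the patch edge is `sqrt(0.5) ~ 0.7071` km;
#' all km-denominated rules use this scale. Elevation is carried as metadata
#' only and has no dynamical effect.
#'
#' @param width,height Grid dimensions in patches (defaults 534 x 328).
#' @param n_attractors_per_region Number of attractor patches per region.
#' @param boundary_col Last column of the Tian Shan region (default mid-grid).
#' @param patch_edge_km Km per patch edge (default `sqrt(0.5)`).
#' @param resource_max Resource cap of ordinary patches (default 50).
#' @param attractor_cap Resource cap of attractor patches (default 100).
#' @param cap_multiplier Multiplier on both caps (S4 uses 0.5 to model an
#'   arid, resource-limited environment).
#' @param min_spacing_km Minimum pairwise distance between attractor patches.
#' @param seed Optional integer seed; the generator is bit-reproducible under
#'   a fixed seed and leaves the caller's RNG state untouched.
#' @return A `coop_landscape`: a list holding the dimensions, the boundary
#'   column, the patch scale and `height x width` matrices `resource`, `cap`,
#'   `attractor` (logical) and `elevation` (NA unless set).
#' @export
#' @examples
#' grid <- synthetic_landscape(40, 20, n_attractors_per_region = 2, seed = 1)
#' grid
synthetic_landscape <- function(width = 534L, height = 328L,
                                n_attractors_per_region = 3L,
                                boundary_col = width %/% 2L,
                                patch_edge_km = sqrt(0.5),
                                resource_max = 50,
                                attractor_cap = 100,
                                cap_multiplier = 1,
                                min_spacing_km = 5,
                                seed = NULL) {
  if (width < 2 || height < 2) {
    stop("invalid argument: grid dimensions must be at least 2 x 2")
  }
  if (n_attractors_per_region < 0) {
    stop("invalid argument: n_attractors_per_region must be >= 0")
  }
  if (boundary_col < 1 || boundary_col >= width) {
    stop("invalid argument: boundary_col must leave both regions non-empty")
  }
  if (!is.null(seed)) withr::local_seed(seed)

  cap_ord <- resource_max * cap_multiplier
  cap_att <- attractor_cap * cap_multiplier
  resource <- matrix(
    as.numeric(sample.int(floor(cap_ord) + 1L, width * height, replace = TRUE) - 1L),
    nrow = height, ncol = width
  )
  cap <- matrix(cap_ord, nrow = height, ncol = width)
  attractor <- matrix(FALSE, nrow = height, ncol = width)

  grid <- structure(
    list(width = as.integer(width), height = as.integer(height),
         boundary_col = as.integer(boundary_col),
         patch_edge_km = patch_edge_km,
         resource = resource, cap = cap, attractor = attractor,
         elevation = NULL),
    class = "coop_landscape"
  )

  if (n_attractors_per_region > 0) {
    placed <- matrix(numeric(0), ncol = 2)  # (x, y) accepted so far
    min_d2 <- (min_spacing_km / patch_edge_km)^2
    for (reg_cols in list(seq_len(boundary_col),
                          seq.int(boundary_col + 1L, width))) {
      cells <- expand.grid(x = reg_cols, y = seq_len(height))
      cells <- cells[sample.int(nrow(cells)), , drop = FALSE]
      n_got <- 0L
      for (i in seq_len(nrow(cells))) {
        if (n_got == n_attractors_per_region) break
        x <- cells$x[i]; y <- cells$y[i]
        if (nrow(placed) == 0 ||
            all((placed[, 1] - x)^2 + (placed[, 2] - y)^2 >= min_d2)) {
          placed <- rbind(placed, c(x, y))
          n_got <- n_got + 1L
        }
      }
      if (n_got < n_attractors_per_region) {
        stop("could not place ", n_attractors_per_region,
             " attractor patches at ", min_spacing_km, " km spacing; ",
             "the region is too small")
      }
    }
    grid$attractor[cbind(placed[, 2], placed[, 1])] <- TRUE
    grid$cap[cbind(placed[, 2], placed[, 1])] <- cap_att
    grid$resource[cbind(placed[, 2], placed[, 1])] <- cap_att
  }
  grid
}

#' @export
print.coop_landscape <- function(x, ...) {
  cat("<coop_landscape>", x$width, "x", x$height, "patches,",
      "boundary at column", x$boundary_col, "\n")
  cat("  patch edge:", round(x$patch_edge_km, 4), "km;",
      sum(x$attractor), "attractor patches\n")
  invisible(x)
}

#' Region of a column position
#'
#' @param grid A `coop_landscape`.
#' @param x Column positions (vectorized).
#' @return `"TianShan"` for columns up to the boundary, `"Altai"` beyond.
#' @export
region_of <- function(grid, x) {
  .regions[(round(x) > grid$boundary_col) + 1L]
}

#' @method as_tibble coop_landscape
#' @export
as_tibble.coop_landscape <- function(x, ...) {
  tibble::tibble(
    col = rep(seq_len(x$width), each = x$height),
    row = rep(seq_len(x$height), times = x$width),
    region = region_of(x, rep(seq_len(x$width), each = x$height)),
    elevation = if (is.null(x$elevation)) NA_real_ else as.vector(x$elevation),
    resource = as.vector(x$resource),
    cap = as.vector(x$cap),
    is_attractor_patch = as.vector(x$attractor)
  )
}

#' Read an Esri ASCII grid raster
#'
#' Parses the plain-text Esri ASCII dialect (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, optional `NODATA_value`, then `nrows` rows of
#' `ncols` values). NODATA cells become `NA`. Malformed input raises a format
#' error naming the offending line.
#'
#' @param path Path to the `.asc` file.
#' @return A numeric `nrows x ncols` matrix with header fields attached as
#'   attributes (`xllcorner`, `yllcorner`, `cellsize`, `nodata_value`).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    val <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(val)) {
      stop("format error in ASCII grid header, line ", i, ": ", lines[i])
    }
    header[[key]] <- val
    i <- i + 1L
  }
  required <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  missing <- setdiff(required, names(header))
  if (length(missing) > 0) {
    stop("format error: ASCII grid header missing ",
         paste(missing, collapse = ", "))
  }
  ncols <- as.integer(header$ncols)
  nrows <- as.integer(header$nrows)
  nodata <- header$nodata_value
  body <- lines[seq.int(i, length.out = length(lines) - i + 1L)]
  if (length(body) != nrows) {
    stop("format error: expected ", nrows, " data rows, found ", length(body))
  }
  out <- matrix(NA_real_, nrow = nrows, ncol = ncols)
  for (r in seq_len(nrows)) {
    vals <- suppressWarnings(
      as.numeric(strsplit(trimws(body[r]), "\\s+")[[1]])
    )
    if (length(vals) != ncols || anyNA(vals)) {
      stop("format error in ASCII grid, line ", i + r - 1L,
           ": expected ", ncols, " numeric values")
    }
    out[r, ] <- vals
  }
  if (!is.null(nodata)) out[out == nodata] <- NA_real_
  attr(out, "xllcorner") <- header$xllcorner
  attr(out, "yllcorner") <- header$yllcorner
  attr(out, "cellsize") <- header$cellsize
  attr(out, "nodata_value") <- nodata
  out
}

#' Attach an elevation lattice to a landscape
#'
#' Elevation is informational metadata (it has no dynamical effect).
#'
#' @param grid A `coop_landscape`.
#' @param elevation A `height x width` numeric matrix, e.g. from
#'   [read_ascii_grid()].
#' @return The landscape with elevation set.
#' @export
set_elevation <- function(grid, elevation) {
  stopifnot(inherits(grid, "coop_landscape"))
  if (!is.matrix(elevation) ||
      nrow(elevation) != grid$height || ncol(elevation) != grid$width) {
    stop("elevation must be a ", grid$height, " x ", grid$width, " matrix")
  }
  grid$elevation <- elevation
  grid
}

#' Read a site table (CSV of x, y, kind)
#'
#' Reads site coordinates used to seed attractor-patch placement. Valid kinds
#' are `"archaeological"` and `"resource_attractive"`. If a landscape is
#' supplied, out-of-bounds rows are dropped with a warning; the number of
#' rejected rows is attached as attribute `rejected`.
#'
#' @param path CSV path with columns `x`, `y`, `kind`.
#' @param grid Optional `coop_landscape` for bounds checking.
#' @return A tibble of sites.
#' @export
read_sites <- function(path, grid = NULL) {
  sites <- readr::read_csv(path, col_types = readr::cols(
    x = readr::col_double(), y = readr::col_double(),
    kind = readr::col_character()
  ))
  if (!all(c("x", "y", "kind") %in% names(sites))) {
    stop("site table must have columns x, y, kind")
  }
  bad <- setdiff(unique(sites$kind), c("archaeological", "resource_attractive"))
  if (length(bad) > 0) {
    stop("unknown site kind: ", paste(bad, collapse = ", "))
  }
  rejected <- 0L
  if (!is.null(grid)) {
    inb <- sites$x >= 1 & sites$x <= grid$width &
      sites$y >= 1 & sites$y <= grid$height
    rejected <- sum(!inb)
    if (rejected > 0) {
      warning(rejected, " site(s) outside the grid were dropped")
      sites <- sites[inb, ]
    }
  }
  attr(sites, "rejected") <- rejected
  sites
}

#' Regenerate attractor-patch resources
#'
#' Only attractor patches regenerate (ordinary patches never do): resources on
#' attractor patches grow by `rate` per call, clipped at the patch cap, and
#' optionally shrink by a climate `decay` (also restricted to attractor
#' patches; 0 disables it).
#'
#' @param grid A `coop_landscape`.
#' @param rate Regeneration per tick (>= 0).
#' @param decay Climate decay per tick applied to attractor patches (>= 0).
#' @return The updated landscape.
#' @export
regenerate_resources <- function(grid, rate, decay = 0) {
  stopifnot(rate >= 0, decay >= 0)
  sel <- grid$attractor
  grid$resource[sel] <- pmax(0, pmin(grid$resource[sel] + rate - decay,
                                     grid$cap[sel]))
  grid
}

#' Consume resource from one patch
#'
#' Removes up to `amount` from the patch at (`col`, `row`); the patch floor is
#' zero and the amount actually taken is returned.
#'
#' @param grid A `coop_landscape`.
#' @param col,row Patch indices.
#' @param amount Requested amount (>= 0).
#' @return A list with the updated `grid` and the `consumed` amount.
#' @export
consume_resource <- function(grid, col, row, amount) {
  if (amount < 0) stop("invalid argument: amount must be >= 0")
  avail <- grid$resource[row, col]
  taken <- min(amount, avail)
  grid$resource[row, col] <- avail - taken
  list(grid = grid, consumed = taken)
}

# Vectorized multi-agent consumption: demands aggregated per patch, each
# patch floored at zero.
consume_resources <- function(grid, cols, rows, amounts) {
  if (length(cols) == 0) return(grid)
  idx <- cbind(rows, cols)
  key <- (cols - 1L) * grid$height + rows
  demand <- rowsum(amounts, key)
  ukey <- as.integer(rownames(demand))
  urow <- ((ukey - 1L) %% grid$height) + 1L
  ucol <- ((ukey - 1L) %/% grid$height) + 1L
  uidx <- cbind(urow, ucol)
  avail <- grid$resource[uidx]
  grid$resource[uidx] <- pmax(0, avail - demand[, 1])
  grid
}

#' @method autoplot coop_landscape
#' @export
autoplot.coop_landscape <- function(object, ...) {
  df <- as_tibble.coop_landscape(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$resource)) +
    ggplot2::geom_point(data = df[df$is_attractor_patch, ],
                        shape = 24, fill = "white", size = 2) +
    ggplot2::geom_vline(xintercept = object$boundary_col + 0.5,
                        linetype = "dashed", colour = "grey30") +
    ggplot2::scale_fill_viridis_c(name = "resource") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column (Tian Shan | Altai)", y = "row")
}
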