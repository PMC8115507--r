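# Synthetic model domain: elevation, soils, stream corridor, farm parcels,
# and D8 flow directions. Stands in for the real valley: a gently sloping
# floodplain drained by a perennial stream, clay-rich flats that pond easily,
# freely draining uplands, and four contiguous irrigated farm parcels.

# D8 direction codes, row/col offsets. 0 = pit/outlet (no lower neighbour).
# Tie-break on equal descent gradient: the lowest code wins.
D8_CODES <- 1:8
D8_DROW <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)  # N NE E SE S SW W NW
D8_DCOL <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
D8_DIST <- sqrt(D8_DROW^2 + D8_DCOL^2)

# Iterated 3x3 box blur with replicated edges; cheap smooth random fields.
smooth_matrix <- function(m, passes = 3L) {
  for (i in seq_len(passes)) {
    nr <- nrow(m); nc <- ncol(m)
    p <- m[c(1, 1:nr, nr), c(1, 1:nc, nc)]
    m <- (p[1:nr, 1:nc] + p[1:nr, 2:(nc + 1)] + p[1:nr, 3:(nc + 2)] +
          p[2:(nr + 1), 1:nc] + p[2:(nr + 1), 2:(nc + 1)] +
          p[2:(nr + 1), 3:(nc + 2)] +
          p[3:(nr + 2), 1:nc] + p[3:(nr + 2), 2:(nc + 1)] +
          p[3:(nr + 2), 3:(nc + 2)]) / 9
  }
  m
}

# Steepest-descent D8 directions from an elevation matrix. Only strictly
# lower neighbours are eligible, so the drainage graph is acyclic; cells
# with no lower neighbour are pits/outlets (code 0).
d8_flow_dir <- function(elevation, cell_size = 50) {
  nr <- nrow(elevation); nc <- ncol(elevation)
  best_grad <- matrix(0, nr, nc)
  dir <- matrix(0L, nr, nc)
  for (k in D8_CODES) {
    shifted <- matrix(NA_real_, nr, nc)
    r_src <- pmax(1L, 1L - D8_DROW[k]):pmin(nr, nr - D8_DROW[k])
    c_src <- pmax(1L, 1L - D8_DCOL[k]):pmin(nc, nc - D8_DCOL[k])
    shifted[r_src, c_src] <- elevation[r_src + D8_DROW[k], c_src + D8_DCOL[k]]
    grad <- (elevation - shifted) / (D8_DIST[k] * cell_size)
    better <- !is.na(grad) & grad > best_grad + 1e-12
    best_grad[better] <- grad[better]
    dir[better] <- k
  }
  dir
}

# Linear index (column-major) of each cell's downslope neighbour; NA at pits.
downslope_index <- function(flow_dir) {
  nr <- nrow(flow_dir); nc <- ncol(flow_dir)
  idx <- matrix(NA_integer_, nr, nc)
  has <- flow_dir > 0L
  k <- flow_dir[has]
  rows <- row(flow_dir)[has] + D8_DROW[k]
  cols <- col(flow_dir)[has] + D8_DCOL[k]
  idx[has] <- (cols - 1L) * nr + rows
  idx
}

#' Generate a synthetic model domain
#'
#' Builds a valley-shaped elevation surface drained by a meandering perennial
#' stream, assigns soil classes (`SLOW` clay-rich flats on the valley floor,
#' `FAST` freely draining soils elsewhere, `RIPARIAN` along the channel),
#' places four contiguous rectangular farm parcels over the flat valley
#' floor, and derives D8 flow directions by steepest descent (deterministic
#' tie-break: lowest direction code).
#'
#' @param n_rows,n_cols Grid dimensions (each at least 8). Row 1 is the
#'   northernmost row; the valley drains southward.
#' @param seed Integer seed; identical seeds give bit-identical domains.
#' @param farm_fraction Target fraction of all grid cells covered by the four
#'   farm parcels combined.
#' @param cell_size Cell edge length in metres.
#' @return An object of class `domain_grid` with matrices `elevation` (m),
#'   `soil_class` (character), `farm_id` (integer, 0 outside farms),
#'   `flow_dir` (D8 codes, 0 = pit), `stream_mask_static` (logical channel
#'   cells), plus `n_rows`, `n_cols`, `cell_size`.
#' @examples
#' dom <- make_domain(40, 30, seed = 1)
#' table(dom$soil_class)
#' @export
make_domain <- function(n_rows, n_cols, seed = 1L, farm_fraction = 0.25,
                        cell_size = 50) {
  if (length(n_rows) != 1L || length(n_cols) != 1L ||
      is.na(n_rows) || is.na(n_cols) || n_rows < 8 || n_cols < 8) {
    stop("n_rows and n_cols must each be at least 8")
  }
  if (farm_fraction <= 0 || farm_fraction >= 1) {
    stop("farm_fraction must be in (0, 1)")
  }
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)

  with_seed(derive_seed(seed, "domain"), {
    # Meandering channel column per row (smoothed random walk).
    steps <- rnorm(n_rows, 0, 0.6)
    path <- cumsum(steps) - mean(cumsum(steps))
    path <- stats::filter(path, rep(1 / 5, 5), sides = 2, circular = TRUE)
    chan_col <- round(n_cols / 2 + as.numeric(path))
    chan_col <- pmin(pmax(chan_col, 3L), n_cols - 2L)

    rows <- row(matrix(0, n_rows, n_cols))
    cols <- col(matrix(0, n_rows, n_cols))
    dist_chan <- abs(cols - matrix(chan_col[rows], n_rows, n_cols))

    # Valley cross-profile: flat floor near the channel, steeper margins.
    floor_hw <- max(3L, round(n_cols * 0.28))
    cross <- pmax(0, dist_chan - floor_hw)
    elevation <- 0.0015 * cell_size * (n_rows - rows) +        # down-valley
      0.006 * cell_size * cross +                              # valley walls
      0.0004 * cell_size * dist_chan +                         # gentle floor tilt
      smooth_matrix(matrix(rnorm(n_rows * n_cols, 0, 1.2), n_rows, n_cols), 4L)

    # Carve the channel, strictly decreasing downstream so it drains.
    chan_idx <- cbind(seq_len(n_rows), chan_col)
    chan_elev <- elevation[chan_idx] - 2
    chan_elev <- rev(cummin(rev(chan_elev + 0.01 * seq_len(n_rows))))
    elevation[chan_idx] <- chan_elev - 0.005 * seq_len(n_rows)

    stream_mask_static <- matrix(FALSE, n_rows, n_cols)
    stream_mask_static[chan_idx] <- TRUE

    # Clay-rich (SLOW) soil occurs in patches across the low-lying valley
    # floor; the rest of the floor and all higher ground drain freely, so
    # farm parcels straddle both soil types, as the real plantation does.
    patch <- smooth_matrix(matrix(rnorm(n_rows * n_cols), n_rows, n_cols), 5L)
    soil_class <- matrix("FAST", n_rows, n_cols)
    clay <- dist_chan <= floor_hw & patch > quantile(patch, 0.35)
    soil_class[clay] <- "SLOW"
    soil_class[dist_chan <= 1] <- "RIPARIAN"

    # Four contiguous parcels: one super-rectangle centred on the valley
    # floor, quartered. Parcels may straddle the stream corridor, as the
    # real plantation does; channel statistics are handled by masking.
    target <- round(farm_fraction * n_rows * n_cols)
    width <- min(n_cols - 2L, max(2L, round(sqrt(target * n_cols / n_rows))))
    height <- min(n_rows - 2L, max(2L, ceiling(target / width)))
    width <- min(n_cols - 2L, max(2L, ceiling(target / height)))
    r0 <- max(1L, round((n_rows - height) / 2))
    c0 <- max(1L, min(n_cols - width, round(mean(chan_col) - width / 2)))
    farm_id <- matrix(0L, n_rows, n_cols)
    r_mid <- r0 + height %/% 2L
    c_mid <- c0 + width %/% 2L
    rr <- r0:(r0 + height - 1L)
    cc <- c0:(c0 + width - 1L)
    farm_id[rr[rr < r_mid], cc[cc < c_mid]] <- 1L
    farm_id[rr[rr < r_mid], cc[cc >= c_mid]] <- 2L
    farm_id[rr[rr >= r_mid], cc[cc < c_mid]] <- 3L
    farm_id[rr[rr >= r_mid], cc[cc >= c_mid]] <- 4L

    flow_dir <- d8_flow_dir(elevation, cell_size)

    structure(
      list(
        n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
        elevation = elevation, soil_class = soil_class, farm_id = farm_id,
        flow_dir = flow_dir, stream_mask_static = stream_mask_static
      ),
      class = "domain_grid"
    )
  })
}

#' @export
print.domain_grid <- function(x, ...) {
  cat(sprintf("<domain_grid> %d x %d cells at %g m\n", x$n_rows, x$n_cols,
              x$cell_size))
  cat("  soil:", paste(sprintf("%s=%d", names(table(x$soil_class)),
                               as.integer(table(x$soil_class))),
                       collapse = ", "), "\n")
  cat(sprintf("  farms: %d cells (%.1f%%), channel cells: %d\n",
              sum(x$farm_id > 0), 100 * mean(x$farm_id > 0),
              sum(x$stream_mask_static)))
  invisible(x)
}

# Local downslope gradient (m/m); 0 at pits. Used to scale drainage.
local_slope <- function(domain) {
  ds <- downslope_index(domain$flow_dir)
  slope <- matrix(0, domain$n_rows, domain$n_cols)
  has <- !is.na(ds)
  k <- domain$flow_dir[has]
  slope[has] <- (domain$elevation[has] - domain$elevation[ds[has]]) /
    (D8_DIST[k] * domain$cell_size)
  slope
}
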