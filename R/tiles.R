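#' Tile layout for position-dependent correction
#'
#' Describes the segmentation of the field of view into `m_rows x m_cols`
#' tiles whose non-overlapping cores partition the field exactly; each
#' tile's analysis window is enlarged by an overlap margin (windows are kept
#' square and shifted inward at the field edges), and corrected tile images
#' are blended with linear feathering across the overlaps.
#'
#' @param m_rows,m_cols Tile counts per axis; must divide the grid evenly.
#' @param grid The field [grid_spec()].
#' @param overlap Overlap fraction in `[0, 0.5)`: the window side is
#'   `core * (1 + overlap)` (rounded to even).
#' @return A `tile_layout` object with per-tile core and window index
#'   ranges.
#' @export
tile_layout <- function(m_rows, m_cols, grid, overlap = 0.25) {
  n <- grid$n
  if (overlap < 0 || overlap >= 0.5)
    stop("overlap fraction must lie in [0, 0.5)", call. = FALSE)
  if (n %% m_rows != 0 || n %% m_cols != 0)
    stop("tile counts must divide the grid size evenly", call. = FALSE)
  core_r <- n %/% m_rows; core_c <- n %/% m_cols
  if (core_r < 8 || core_c < 8)
    stop(sprintf("tile core %d x %d px is below the 8 x 8 minimum (pupil sampling too coarse)",
                 core_r, core_c), call. = FALSE)
  win_side <- function(core) {
    w <- ceiling(core * (1 + overlap))
    w <- min(w + w %% 2, n)             # even, no larger than the field
    max(w, core)
  }
  wr <- win_side(core_r); wc <- win_side(core_c)
  w <- max(wr, wc)                      # square analysis windows
  tiles <- list()
  for (tc in seq_len(m_cols)) for (tr in seq_len(m_rows)) {
    r0 <- (tr - 1) * core_r + 1; r1 <- tr * core_r
    c0 <- (tc - 1) * core_c + 1; c1 <- tc * core_c
    wr0 <- max(1, min(r0 - (w - core_r) %/% 2, n - w + 1))
    wc0 <- max(1, min(c0 - (w - core_c) %/% 2, n - w + 1))
    tiles[[length(tiles) + 1]] <-
      list(row = tr, col = tc, core_rows = r0:r1, core_cols = c0:c1,
           win_rows = wr0:(wr0 + w - 1), win_cols = wc0:(wc0 + w - 1))
  }
  structure(list(m_rows = m_rows, m_cols = m_cols, grid = grid,
                 overlap = overlap, window = w, tiles = tiles),
            class = "tile_layout")
}

#' @export
print.tile_layout <- function(x, ...) {
  cat(sprintf("<tile_layout> %d x %d tiles, cores %d x %d px, windows %d px, overlap %.2f\n",
              x$m_rows, x$m_cols, x$grid$n %/% x$m_rows, x$grid$n %/% x$m_cols,
              x$window, x$overlap))
  invisible(x)
}

#' Segment a position-basis reflection matrix into tile sub-matrices
#'
#' Tile `i` receives exactly the rows and columns of the full matrix whose
#' `r_o` and `r_i` fall inside tile `i`'s analysis window (core plus overlap
#' margin); the union of the non-overlapping cores reconstitutes the field.
#' Each sub-matrix gets a tile-local [grid_spec()] (same pitch and optics,
#' window-sized), so its pupil is the tile-local discrete frequency grid.
#'
#' @param m A [reflection_matrix()] with both axes in the position basis.
#' @param layout A [tile_layout()] consistent with `m`'s grid.
#' @return List of tiles; each holds `matrix` (a position/position
#'   [reflection_matrix()] on the tile window), the layout indices, and the
#'   core location within the window.
#' @export
segment_field <- function(m, layout) {
  if (m$basis_out != "position" || m$basis_in != "position")
    stop("segment_field needs both axes in the position basis", call. = FALSE)
  if (!same_grid(m$grid, layout$grid))
    stop("layout grid does not match the matrix grid", call. = FALSE)
  n <- m$grid$n
  lin <- function(rows, cols) as.vector(outer(rows, (cols - 1) * n, "+"))
  tgrid <- grid_spec(layout$window, m$grid$pitch, m$grid$wavelength,
                     m$grid$na, m$grid$n_medium)
  lapply(layout$tiles, function(t) {
    sel <- lin(t$win_rows, t$win_cols)
    sub <- reflection_matrix(m$data[sel, sel, drop = FALSE], tgrid,
                             basis_out = "position", basis_in = "position",
                             tau0 = m$tau0)
    list(matrix = sub, row = t$row, col = t$col,
         win_rows = t$win_rows, win_cols = t$win_cols,
         core_rows = t$core_rows, core_cols = t$core_cols)
  })
}

## trapezoidal feathering weight for one tile window within the field
feather_weight <- function(t, n) {
  w1 <- function(win, core) {
    lead <- core[1] - win[1]            # margin before the core
    trail <- win[length(win)] - core[length(core)]
    v <- rep(1, length(win))
    if (lead > 0) v[seq_len(lead)] <- seq_len(lead) / (lead + 1)
    if (trail > 0) v[length(win) - seq_len(trail) + 1] <- seq_len(trail) / (trail + 1)
    v
  }
  outer(w1(t$win_rows, t$core_rows), w1(t$win_cols, t$core_cols))
}

#' Correct tiles independently and stitch the full-field image
#'
#' Runs [run_class()] on every tile sub-matrix, then blends the corrected
#' tile confocal images into the full field: weight 1 on each tile core,
#' linear feathering across overlap margins, normalized by the accumulated
#' weight (so with no correction applied the stitched image reproduces the
#' unsegmented confocal image). A tile whose correction fails is passed
#' through uncorrected and flagged in the failure mask rather than aborting
#' the reconstruction.
#'
#' @param tiles Output of [segment_field()].
#' @param layout The [tile_layout()] used for segmentation.
#' @param tol,max_iter Passed to [run_class()].
#' @param correct Set `FALSE` to stitch the tiles without any correction
#'   (useful to verify that blending is conservative: the result then
#'   reproduces the unsegmented confocal image).
#' @return List: `image` (stitched corrected confocal image),
#'   `corrections` (per-tile `class_correction` in layout order, `NULL`
#'   where failed), `failed` (`m_rows x m_cols` logical matrix).
#' @export
correct_and_stitch <- function(tiles, layout, tol = 1e-3, max_iter = 30L,
                               correct = TRUE) {
  n <- layout$grid$n
  img <- matrix(0, n, n)
  wsum <- matrix(0, n, n)
  failed <- matrix(FALSE, layout$m_rows, layout$m_cols)
  corrections <- vector("list", length(tiles))
  for (i in seq_along(tiles)) {
    t <- tiles[[i]]
    res <- if (!correct) NULL else
      tryCatch(run_class(t$matrix, tol = tol, max_iter = max_iter),
               error = function(e) e)
    if (is.null(res)) {
      tile_img <- confocal_image(t$matrix)
    } else if (inherits(res, "error")) {
      failed[t$row, t$col] <- TRUE
      tile_img <- confocal_image(t$matrix)
    } else {
      corrections[[i]] <- res
      tile_img <- confocal_image(res$corrected)
    }
    wt <- feather_weight(t, n)
    img[t$win_rows, t$win_cols] <- img[t$win_rows, t$win_cols] + wt * tile_img
    wsum[t$win_rows, t$win_cols] <- wsum[t$win_rows, t$win_cols] + wt
  }
  list(image = img / pmax(wsum, .Machine$double.eps),
       corrections = corrections, failed = failed)
}
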