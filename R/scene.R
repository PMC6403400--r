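#' Depth-labelled scene
#'
#' A scene is a per-pixel reflectance map in `[0, 1]` plus a per-pixel object
#' depth map in meters (`NA` where only the featureless background is
#' visible) and a scalar background level. Matrices are indexed
#' `[row, col]`; event coordinates are 0-based with `x = col - 1`,
#' `y = row - 1`, origin at the top-left.
#'
#' @param reflectance Numeric matrix in `[0, 1]`.
#' @param depth Numeric matrix of object depths (m), same shape; `NA` marks
#'   background pixels with no ground-truth depth.
#' @param background_level Scalar reflectance in `[0, 1]` of the featureless
#'   background.
#' @return An object of class `dff_scene`.
#' @export
dff_scene <- function(reflectance, depth, background_level = 0.5) {
  if (!is.matrix(reflectance) || !is.matrix(depth) ||
      !all(dim(reflectance) == dim(depth))) {
    abort("`reflectance` and `depth` must be matrices of identical shape.")
  }
  if (any(reflectance < 0 | reflectance > 1, na.rm = TRUE)) {
    abort("`reflectance` must lie in [0, 1].")
  }
  if (any(depth <= 0, na.rm = TRUE)) abort("all depths must be > 0.")
  if (background_level < 0 || background_level > 1) {
    abort("`background_level` must lie in [0, 1].")
  }
  structure(
    list(reflectance = reflectance, depth = depth,
         background_level = background_level),
    class = "dff_scene"
  )
}

#' @export
print.dff_scene <- function(x, ...) {
  zs <- sort(unique(stats::na.omit(as.vector(x$depth))))
  cat(sprintf("<dff_scene> %d x %d, %d depth layer(s): %s m\n",
              nrow(x$depth), ncol(x$depth), length(zs),
              paste(signif(zs, 4), collapse = ", ")))
  invisible(x)
}

# 2-px checkerboard texture between two reflectance levels; fine texture keeps
# every object pixel within ~1 px of a contrast edge so that focus-time
# detection is sharp everywhere on the object.
checker_texture <- function(rows, cols, low = 0.2, high = 0.8, cell = 2L) {
  ri <- (seq_len(rows) - 1L) %/% cell
  ci <- (seq_len(cols) - 1L) %/% cell
  par <- outer(ri, ci, function(a, b) (a + b) %% 2L)
  low + (high - low) * par
}

#' Generate a synthetic test scene
#'
#' Deterministic (given `seed`) scene generators that mirror the stimuli the
#' method was characterized on: a textured sphere (disc) sweeping through
#' focus, a single bar, a full-frame textured plane, a pair of bars whose
#' blur discs either stay separated (`two_edges_far`) or overlap during the
#' sweep (`two_edges_near`, the documented failure mode), and a multi-object
#' scene with planes at several depths.
#'
#' All fixtures default to a 64 x 64 frame for test speed; the full sensor
#' format of the emulated camera is 640 x 480. Textured fixtures use a 2-px
#' checkerboard (reflectance 0.2 / 0.8) on a 0.5 background, `textured_plane`
#' uses seeded random binary 2-px blocks.
#'
#' @param kind One of `"sphere"`, `"bar"`, `"textured_plane"`,
#'   `"two_edges_far"`, `"two_edges_near"`, `"multi_depth"`, or `"uniform"`
#'   (a featureless full-frame plane: a static stimulus that emits no
#'   events during a sweep).
#' @param shape Frame shape `c(rows, cols)`.
#' @param z Object depth in meters (`sphere`, `bar`, `textured_plane`).
#' @param z1,z2 Depths of the two bars for the two-edge fixtures (m).
#' @param depths Depths of the planes for `multi_depth` (m), 3 to 5 values.
#' @param radius Disc radius in pixels (`sphere`).
#' @param textured Apply the fine checker texture to object surfaces
#'   (`sphere`, `multi_depth`).
#' @param seed Integer seed for the random texture; fixtures are
#'   deterministic given `seed`.
#' @return A [dff_scene()].
#' @examples
#' sc <- make_fixture("sphere", z = 0.3)
#' @export
make_fixture <- function(kind = c("sphere", "bar", "textured_plane",
                                  "two_edges_far", "two_edges_near",
                                  "multi_depth", "uniform"),
                         shape = c(64L, 64L),
                         z = 0.3, z1 = 0.3, z2 = 0.45,
                         depths = c(0.3, 0.6, 1.2),
                         radius = 20L, textured = TRUE, seed = 1L) {
  kind <- match.arg(kind)
  if (missing(shape) && kind %in% c("two_edges_far", "two_edges_near")) {
    shape <- c(64L, 96L) # wide frame to fit two 20-px bars plus margins
  }
  rows <- shape[1]; cols <- shape[2]
  bg <- if (kind %in% c("bar", "two_edges_far", "two_edges_near")) 0.1 else 0.5
  refl <- matrix(bg, rows, cols)
  dep <- matrix(NA_real_, rows, cols)

  place_rect <- function(r0, r1, c0, c1, zobj, tex) {
    if (r0 < 1 || c0 < 1 || r1 > rows || c1 > cols) {
      abort("fixture geometry exceeds the sensor.")
    }
    refl[r0:r1, c0:c1] <<- tex[r0:r1 - r0 + 1, c0:c1 - c0 + 1]
    dep[r0:r1, c0:c1] <<- zobj
  }

  tex_full <- if (textured) checker_texture(rows, cols) else
    matrix(0.9, rows, cols)

  if (kind == "uniform") {
    refl[] <- 0.5
    dep[] <- z
  } else if (kind == "sphere") {
    if (2 * radius + 2 > min(rows, cols)) {
      abort("fixture geometry exceeds the sensor.")
    }
    cy <- (rows + 1) / 2; cx <- (cols + 1) / 2
    rr <- outer(seq_len(rows) - cy, seq_len(cols) - cx,
                function(a, b) sqrt(a^2 + b^2))
    inside <- rr <= radius
    refl[inside] <- tex_full[inside]
    dep[inside] <- z
  } else if (kind == "bar") {
    c0 <- floor(cols / 2) - 5L; c1 <- c0 + 11L
    place_rect(1L, rows, c0, c1, z, matrix(0.9, rows, cols))
  } else if (kind == "textured_plane") {
    set.seed(seed)
    blk <- matrix(sample(c(0.2, 0.8), ceiling(rows / 2) * ceiling(cols / 2),
                         replace = TRUE),
                  ceiling(rows / 2), ceiling(cols / 2))
    refl <- blk[rep(seq_len(nrow(blk)), each = 2)[seq_len(rows)],
                rep(seq_len(ncol(blk)), each = 2)[seq_len(cols)]]
    dep[] <- z
  } else if (kind %in% c("two_edges_far", "two_edges_near")) {
    plain <- matrix(0.9, rows, cols)
    # Full-height bars: the stimulus is one-dimensional in x (as in the
    # classic x-time view with the y dimension collapsed), so every pixel
    # sees pure vertical-edge geometry. Bars are 20 px wide so that each
    # bar's far edge is beyond the blur reach of its near edge's flank
    # pixels; narrower bars make flank intensity non-monotone (the
    # concentrating far-edge tail) and spuriously flip polarities.
    w <- 20L
    if (cols < 4L * w + 16L) abort("fixture geometry exceeds the sensor.")
    if (kind == "two_edges_far") {
      # inner edges ~40 px apart: blur discs never overlap during the sweep
      place_rect(1L, rows, 9L, 8L + w, z1, plain)
      place_rect(1L, rows, cols - 7L - w, cols - 8L, z2, plain)
    } else {
      # inner edges 5 px apart: blur discs superimpose opposite polarities
      mid <- floor(cols / 2)
      place_rect(1L, rows, mid - w - 2L, mid - 3L, z1, plain)
      place_rect(1L, rows, mid + 3L, mid + 2L + w, z2, plain)
    }
  } else { # multi_depth
    k <- length(depths)
    if (k < 3 || k > 5) abort("`multi_depth` expects 3 to 5 depths.")
    set.seed(seed)
    # spread square patches over the frame, far-to-near left-to-right
    side <- min(floor((cols - 2L * (k + 1L)) / k), rows - 8L, 20L)
    if (side < 6L) abort("fixture geometry exceeds the sensor.")
    gap <- floor((cols - k * side) / (k + 1))
    if (gap < 1) abort("fixture geometry exceeds the sensor.")
    for (i in seq_len(k)) {
      c0 <- i * gap + (i - 1L) * side + 1L
      r0 <- max(1L, floor(rows / 2 - side / 2) + ((i %% 2) * 2L - 1L) *
                  floor(rows / 6))
      r0 <- min(max(r0, 1L), rows - side + 1L)
      tex <- if (textured) checker_texture(side, side) else
        matrix(0.9, side, side)
      place_rect(r0, r0 + side - 1L, c0, c0 + side - 1L, depths[i],
                 tex)
    }
  }
  dff_scene(refl, dep, background_level = bg)
}
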