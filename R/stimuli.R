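#' @useDynLib dualpath, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Fixed shape catalog; any image uses a single shape type for all its shapes.
SHAPE_CATALOG <- c("circle", "square", "triangle", "star", "cross")

# Pixel maps at the reference 224 px canvas (scaled for other sides):
# normalized size in [0,1] -> enclosing-circle diameter in [12, 70] px,
# normalized color in [0,1] -> gray level in [0, 0.78] on a white (1.0)
# background, so the faintest shape never vanishes.
.DIAM_MIN_PX <- 12
.DIAM_MAX_PX <- 70
.GRAY_MAX <- 0.78
.REF_SIDE <- 224

#' Configuration of an order-discrimination task
#'
#' Defines a stream of image pairs in which exactly one scalar feature (the
#' *predictive feature*) changes between the left and the right image by the
#' rule parameter `alpha`, while all remaining features are resampled per pair
#' but held constant within a pair. `alpha` is expressed in normalized feature
#' units, so `alpha = 1` is the maximal possible difference and `alpha = 0`
#' means the feature does not change.
#'
#' @param predictive one of `"size"`, `"color"`, `"number"`.
#' @param alpha signed rule parameter in `[-1, 1]`. When `predictive =
#'   "number"` it must be a multiple of 1/8 (the feature takes 9 levels).
#' @param n_train_pairs,n_test_pairs number of training and held-out test
#'   pairs in a phase.
#' @param image_side image side length in pixels.
#' @param seed integer seed making [make_phase()] reproducible.
#' @return an object of class `task_config`.
#' @examples
#' cfg <- task_config("size", alpha = 0.5, seed = 1)
#' cfg
#' @export
task_config <- function(predictive = c("size", "color", "number"),
                        alpha = 0.5,
                        n_train_pairs = 160L,
                        n_test_pairs = 32L,
                        image_side = 224L,
                        seed = NULL) {
  predictive <- match.arg(predictive)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (abs(alpha) > 1) {
    stop("`alpha` must lie in [-1, 1]; got ", alpha)
  }
  if (predictive == "number" && abs(alpha * 8 - round(alpha * 8)) > 1e-9) {
    stop("with predictive = \"number\", `alpha` must be a multiple of 1/8")
  }
  stopifnot(n_train_pairs >= 0, n_test_pairs >= 0, image_side >= 12)
  structure(
    list(predictive = predictive, alpha = alpha,
         n_train_pairs = as.integer(n_train_pairs),
         n_test_pairs = as.integer(n_test_pairs),
         image_side = as.integer(image_side),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("Order-discrimination task\n")
  cat(sprintf("  predictive feature: %s   alpha: %+g\n", x$predictive, x$alpha))
  cat(sprintf("  pairs: %d train / %d test   image side: %d px\n",
              x$n_train_pairs, x$n_test_pairs, x$image_side))
  if (!is.null(x$seed)) cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Read a task configuration from a JSON or YAML file
#'
#' @param path file with fields matching the arguments of [task_config()].
#' @return a `task_config` object.
#' @export
read_task_config <- function(path) {
  fields <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(task_config, fields[intersect(names(fields), names(formals(task_config)))])
}

# Normalized value of the `number` feature: counts 1..9 map to [0, 1].
norm_number <- function(n) (n - 1) / 8

# Sample the predictive feature for one pair: the left value is uniform over
# the interval for which the partner value (left + alpha) stays in [0, 1].
sample_predictive <- function(predictive, alpha) {
  if (predictive == "number") {
    steps <- as.integer(round(alpha * 8))
    lo <- 1L + max(0L, -steps)
    hi <- 9L - max(0L, steps)
    left_n <- if (lo == hi) lo else sample(lo:hi, 1L)
    list(left = left_n, right = left_n + steps)
  } else {
    lo <- max(0, -alpha)
    hi <- min(1, 1 - alpha)
    left <- stats::runif(1, lo, hi)
    list(left = left, right = left + alpha)
  }
}

#' Sample one image pair under a task rule
#'
#' Draws the predictive feature of the left image uniformly over its feasible
#' interval (so that the right value, offset by `alpha`, stays in range),
#' draws all non-predictive features once and shares them between the two
#' images, and renders both images. Uses R's global random-number stream.
#'
#' @param config a [task_config()].
#' @param render if `FALSE`, skip rasterization and leave the images `NULL`.
#' @return an object of class `image_pair`: list with `left_image`,
#'   `right_image` (matrices in `[0,1]`, white background 1), `left_features`,
#'   `right_features`, and the realized `alpha`.
#' @export
sample_pair <- function(config, render = TRUE) {
  stopifnot(inherits(config, "task_config"))
  pf <- config$predictive
  pred <- sample_predictive(pf, config$alpha)

  color <- if (pf == "color") NULL else stats::runif(1)
  size  <- if (pf == "size") NULL else stats::runif(1)
  shape <- sample(SHAPE_CATALOG, 1L)

  if (pf == "number") {
    n_left <- pred$left; n_right <- pred$right
    # Arrangements are nested so that the shared cells coincide: the larger
    # image's cells are uniform over the grid and the smaller image occupies
    # a uniform subset of them.
    n_big <- max(n_left, n_right)
    big <- sort(sample.int(9L, n_big))
    small <- sort(sample(big, min(n_left, n_right)))
    arr_left <- if (n_left == n_big) big else small
    arr_right <- if (n_right == n_big) big else small
    f_left <- list(color = color, number = n_left, size = size,
                   arrangement = arr_left, shape = shape)
    f_right <- list(color = color, number = n_right, size = size,
                    arrangement = arr_right, shape = shape)
  } else {
    number <- sample.int(9L, 1L)
    arrangement <- sort(sample.int(9L, number))
    f_left <- list(color = color, number = number, size = size,
                   arrangement = arrangement, shape = shape)
    f_right <- f_left
    f_left[[pf]] <- pred$left
    f_right[[pf]] <- pred$right
  }

  structure(
    list(left_image = if (render) render_image(f_left, config$image_side) else NULL,
         right_image = if (render) render_image(f_right, config$image_side) else NULL,
         left_features = f_left, right_features = f_right,
         alpha = config$alpha),
    class = "image_pair")
}

#' Render one stimulus image
#'
#' Draws `number` filled shapes, one per occupied cell of the 3x3 grid, each
#' inscribed in a circle whose diameter is the (scaled) pixel image of the
#' normalized size. Rasterization is hard-edged (a pixel is filled iff its
#' center lies inside the shape), so rendering is deterministic and
#' bit-exact for identical feature vectors.
#'
#' @param features list with `color`, `number`, `size`, `arrangement`
#'   (occupied cells, 1..9 column-major), `shape` (one of
#'   `r paste(SHAPE_CATALOG, collapse = ", ")`).
#' @param side image side in pixels.
#' @return a `side` x `side` matrix in `[0,1]`; background is 1 (white).
#' @export
render_image <- function(features, side = 224L) {
  stopifnot(length(features$arrangement) == features$number,
            features$color >= 0, features$color <= 1,
            features$size >= 0, features$size <= 1,
            features$shape %in% SHAPE_CATALOG)
  side <- as.integer(side)
  scale <- side / .REF_SIDE
  diam <- (.DIAM_MIN_PX + features$size * (.DIAM_MAX_PX - .DIAM_MIN_PX)) * scale
  cell <- side / 3
  if (diam > cell) {
    stop("shape diameter (", round(diam, 2), " px) exceeds the grid-cell extent")
  }
  gray <- .GRAY_MAX * features$color
  img <- matrix(1, side, side)
  R <- diam / 2
  for (cell_id in features$arrangement) {
    cx <- ((cell_id - 1L) %/% 3L + 0.5) * cell  # column position
    cy <- ((cell_id - 1L) %% 3L + 0.5) * cell   # row position
    x0 <- max(1L, floor(cx - R)); x1 <- min(side, ceiling(cx + R))
    y0 <- max(1L, floor(cy - R)); y1 <- min(side, ceiling(cy + R))
    xs <- seq.int(x0, x1); ys <- seq.int(y0, y1)
    # pixel centers relative to the shape center (y axis pointing up)
    dx <- rep(xs - 0.5 - cx, each = length(ys))
    dy <- rep(-(ys - 0.5 - cy), times = length(xs))
    inside <- shape_mask(features$shape, dx, dy, R)
    block <- img[ys, xs, drop = FALSE]
    block[inside] <- gray
    img[ys, xs] <- block
  }
  img
}

# Vectorized inside-shape test for pixel offsets (dx, dy) from the center of
# a shape inscribed in a circle of radius R.
shape_mask <- function(shape, dx, dy, R) {
  switch(shape,
    circle = dx * dx + dy * dy <= R * R,
    square = {
      h <- R / sqrt(2)
      abs(dx) <= h & abs(dy) <= h
    },
    triangle = {
      ang <- c(90, 210, 330) * pi / 180
      point_in_polygon(dx, dy, R * cos(ang), R * sin(ang))
    },
    star = {
      ang <- (90 + 36 * (0:9)) * pi / 180
      rad <- rep(c(R, 0.5 * R), 5)
      point_in_polygon(dx, dy, rad * cos(ang), rad * sin(ang))
    },
    cross = {
      # clipped by the enclosing circle so the arm corners stay inscribed
      w <- 0.3 * R
      ((abs(dx) <= w & abs(dy) <= R) | (abs(dy) <= w & abs(dx) <= R)) &
        dx * dx + dy * dy <= R * R
    },
    stop("unknown shape: ", shape))
}

# Even-odd (crossing-number) point-in-polygon test, vectorized over points.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Generate a full task phase
#'
#' Produces an ordered training sequence and a held-out test set, all drawn
#' under the same rule. Reproducible from `config$seed`; the global RNG state
#' is restored on exit.
#'
#' @param config a [task_config()].
#' @param render rasterize images (needed for training agents).
#' @return an object of class `order_phase`: list with `train` and `test`
#'   (lists of [sample_pair()] results) and `config`.
#' @export
make_phase <- function(config, render = TRUE) {
  stopifnot(inherits(config, "task_config"))
  if (!is.null(config$seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old))
    set.seed(config$seed)
  }
  train <- replicate(config$n_train_pairs, sample_pair(config, render), simplify = FALSE)
  test <- replicate(config$n_test_pairs, sample_pair(config, render), simplify = FALSE)
  structure(list(train = train, test = test, config = config),
            class = "order_phase")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Stack the rendered images of a list of pairs into side x side x n arrays.
pair_arrays <- function(pairs) {
  n <- length(pairs)
  if (n == 0L) return(list(left = array(0, c(0, 0, 0)), right = array(0, c(0, 0, 0))))
  side <- nrow(pairs[[1]]$left_image)
  left <- array(0, c(side, side, n))
  right <- array(0, c(side, side, n))
  for (i in seq_len(n)) {
    left[, , i] <- pairs[[i]]$left_image
    right[, , i] <- pairs[[i]]$right_image
  }
  list(left = left, right = right)
}

#' Write a phase to disk as PNG images plus a manifest
#'
#' @param phase an [make_phase()] result (rendered).
#' @param dir output directory, created if missing.
#' @return invisibly, the manifest data frame (one row per pair with feature
#'   values, realized alpha, and image paths). Also writes `manifest.csv` and
#'   `config.json`.
#' @export
write_phase <- function(phase, dir) {
  stopifnot(inherits(phase, "order_phase"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  dump_one <- function(pair, role, i) {
    paths <- c(left = file.path(dir, sprintf("%s_%03d_left.png", role, i)),
               right = file.path(dir, sprintf("%s_%03d_right.png", role, i)))
    png::writePNG(pair$left_image, paths["left"])
    png::writePNG(pair$right_image, paths["right"])
    fl <- pair$left_features; fr <- pair$right_features
    data.frame(role = role, index = i, alpha = pair$alpha,
               left_color = fl$color, right_color = fr$color,
               left_number = fl$number, right_number = fr$number,
               left_size = fl$size, right_size = fr$size,
               shape = fl$shape,
               left_arrangement = paste(fl$arrangement, collapse = "+"),
               right_arrangement = paste(fr$arrangement, collapse = "+"),
               left_path = paths[["left"]], right_path = paths[["right"]])
  }
  for (i in seq_along(phase$train)) rows[[length(rows) + 1L]] <- dump_one(phase$train[[i]], "train", i)
  for (i in seq_along(phase$test)) rows[[length(rows) + 1L]] <- dump_one(phase$test[[i]], "test", i)
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  cfg <- phase$config
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(manifest)
}

# Normalized scalar value of the predictive feature of a feature vector.
predictive_value <- function(features, predictive) {
  v <- features[[predictive]]
  if (predictive == "number") norm_number(v) else v
}
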