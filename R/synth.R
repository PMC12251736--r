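# Seeded synthetic leaf-disease scenes: textured elliptical leaves over
# simple or cluttered backgrounds, class-distinct lesion blobs with tight
# ground-truth boxes, occlusion / illumination / small-lesion controls,
# and the standard augmentation suite.

#' Specification of a synthetic leaf-disease scene
#'
#' The generator emulates the scene factors that make field imagery hard:
#' cluttered multi-colour backgrounds, overlapping leaves, illumination
#' gradients, and lesions spanning large to very small fractions of the
#' image. Lesions are stylized class-distinct coloured blobs; the point is
#' the statistical structure (scale, occlusion, clutter), not botany.
#'
#' @param image_size square image side in pixels.
#' @param n_leaves number of leaves.
#' @param background_kind `"simple"` (near-uniform) or `"complex"`
#'   (multi-colour clutter).
#' @param lesion_classes integer ids (0-based) of the disease classes that
#'   may appear; at least 3 available by default.
#' @param lesions_per_leaf inclusive integer range.
#' @param lesion_area_fraction range of per-lesion area as a fraction of
#'   the image area.
#' @param occlusion_level target pairwise leaf-mask overlap in `[0, 1]`.
#' @param illumination_gradient multiplicative brightness-ramp amplitude in
#'   `[0, 1]`.
#' @param max_box_area_fraction optional cap on each annotation box's area
#'   as a fraction of the image (used by the small-lesion subset, whose
#'   defining quantity is the labelled box, not the raw mask).
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(image_size = 320L, n_leaves = 2L,
                       background_kind = c("simple", "complex"),
                       lesion_classes = 0:2,
                       lesions_per_leaf = c(1L, 2L),
                       lesion_area_fraction = c(0.005, 0.04),
                       occlusion_level = 0,
                       illumination_gradient = 0,
                       max_box_area_fraction = NULL) {
  background_kind <- match.arg(background_kind)
  stopifnot(image_size >= 64L, n_leaves >= 1L,
            all(lesion_area_fraction > 0),
            occlusion_level >= 0, occlusion_level <= 1,
            illumination_gradient >= 0, illumination_gradient <= 1)
  if (occlusion_level > 0 && n_leaves < 2L)
    stop("occlusion requires at least two leaves")
  structure(list(image_size = as.integer(image_size),
                 n_leaves = as.integer(n_leaves),
                 background_kind = background_kind,
                 lesion_classes = as.integer(lesion_classes),
                 lesions_per_leaf = as.integer(lesions_per_leaf),
                 lesion_area_fraction = lesion_area_fraction,
                 occlusion_level = occlusion_level,
                 illumination_gradient = illumination_gradient,
                 max_box_area_fraction = max_box_area_fraction),
            class = "scene_spec")
}

# class-distinct lesion palettes (base RGB + texture contrast)
lesion_palette <- function(class_id) {
  pals <- list(c(0.45, 0.26, 0.13),   # brown necrotic
               c(0.75, 0.73, 0.70),   # pale grey blight
               c(0.85, 0.30, 0.25),   # rust red
               c(0.92, 0.88, 0.55),   # chlorotic yellow
               c(0.25, 0.22, 0.35))   # dark algal spot
  pals[[class_id %% length(pals) + 1L]]
}

# filled rotated-ellipse mask on an H x W grid
ellipse_mask <- function(H, W, cx, cy, a, b, theta, wobble = 0) {
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  yy <- matrix(seq_len(H), H, W) - cy
  xr <- xx * cos(theta) + yy * sin(theta)
  yr <- -xx * sin(theta) + yy * cos(theta)
  r2 <- (xr / a)^2 + (yr / b)^2
  if (wobble > 0) {
    ang <- atan2(yr, xr)
    r2 <- r2 * (1 + wobble * sin(3 * ang + theta) * 0.5 +
                wobble * 0.3 * sin(5 * ang))
  }
  r2 <= 1
}

# low-frequency value noise (sum of random smooth cosine waves)
smooth_noise <- function(H, W, n_waves = 6L, scale = 0.1) {
  out <- matrix(0, H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) / W
  yy <- matrix(seq_len(H), H, W) / H
  for (i in seq_len(n_waves)) {
    fx <- stats::runif(1, 1, 8); fy <- stats::runif(1, 1, 8)
    ph <- stats::runif(2, 0, 2 * pi)
    out <- out + cos(2 * pi * fx * xx + ph[1]) *
      cos(2 * pi * fy * yy + ph[2])
  }
  out / n_waves * scale
}

paint <- function(img, mask, rgb_col) {
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[mask] <- rgb_col[ch]
    img[, , ch] <- pl
  }
  img
}

#' Render one synthetic scene
#'
#' Deterministic given `(spec, seed)`: the same pair reproduces the image
#' and annotations bit for bit. Each lesion's annotation is the tight
#' bounding box of its rendered (visible) pixel mask.
#'
#' @param spec a [scene_spec()].
#' @param seed integer seed.
#' @param return_masks also return the per-lesion pixel masks (for
#'   audits; off by default to keep scenes light).
#' @return A list with `image` (`[S, S, 3]` in `[0, 1]`), `annotations`
#'   (matrix `class, cx, cy, w, h`, YOLO-normalized) and `metadata`
#'   (achieved max pairwise leaf overlap, per-lesion area fractions,
#'   background kind).
#' @export
generate_scene <- function(spec, seed = 0L, return_masks = FALSE) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(seed)
  S <- spec$image_size
  leaf_r <- S * stats::runif(spec$n_leaves, 0.26, 0.34)
  if (spec$n_leaves * pi * mean(leaf_r)^2 * (1 - spec$occlusion_level) >
      4 * S^2)
    stop("generate_scene: spec infeasible - too many leaves for the canvas")

  # background
  img <- array(0, c(S, S, 3))
  if (spec$background_kind == "simple") {
    base <- c(0.62, 0.60, 0.50) + stats::runif(3, -0.05, 0.05)
    for (ch in 1:3) img[, , ch] <- base[ch] + smooth_noise(S, S, 4L, 0.015)
  } else {
    base <- stats::runif(3, 0.2, 0.7)
    for (ch in 1:3) img[, , ch] <- base[ch]
    for (i in seq_len(40L)) {          # clutter: random colour patches
      m <- ellipse_mask(S, S, stats::runif(1, 1, S), stats::runif(1, 1, S),
                        stats::runif(1, S / 40, S / 6),
                        stats::runif(1, S / 40, S / 6),
                        stats::runif(1, 0, pi), wobble = 0.4)
      img <- paint(img, m, stats::runif(3, 0.05, 0.95))
    }
    for (ch in 1:3)
      img[, , ch] <- img[, , ch] +
        matrix(stats::rnorm(S * S, 0, 0.06), S, S)
  }

  # leaves: place to hit the requested pairwise overlap
  masks <- vector("list", spec$n_leaves)
  cx <- numeric(spec$n_leaves); cy <- numeric(spec$n_leaves)
  for (i in seq_len(spec$n_leaves)) {
    if (i == 1L || spec$occlusion_level == 0) {
      cx[i] <- stats::runif(1, 0.3 * S, 0.7 * S)
      cy[i] <- stats::runif(1, 0.3 * S, 0.7 * S)
      if (i > 1L) { # keep apart when no occlusion requested
        cx[i] <- min(max(cx[i], leaf_r[i]), S - leaf_r[i])
        cy[i] <- min(max(cy[i], leaf_r[i]), S - leaf_r[i])
      }
    } else {
      # distance between centres controls mask overlap
      d <- (1 - spec$occlusion_level) * (leaf_r[i] + leaf_r[i - 1L])
      ang <- stats::runif(1, 0, 2 * pi)
      cx[i] <- min(max(cx[i - 1L] + d * cos(ang), leaf_r[i] * 0.7),
                   S - leaf_r[i] * 0.7)
      cy[i] <- min(max(cy[i - 1L] + d * sin(ang), leaf_r[i] * 0.7),
                   S - leaf_r[i] * 0.7)
    }
    theta <- stats::runif(1, 0, pi)
    masks[[i]] <- ellipse_mask(S, S, cx[i], cy[i], leaf_r[i],
                               leaf_r[i] * stats::runif(1, 0.45, 0.7),
                               theta, wobble = 0.15)
  }
  overlaps <- 0
  if (spec$n_leaves > 1L) {
    for (i in 2:spec$n_leaves) for (j in 1:(i - 1))
      overlaps <- max(overlaps,
                      sum(masks[[i]] & masks[[j]]) /
                        max(min(sum(masks[[i]]), sum(masks[[j]])), 1))
  }

  ann <- NULL
  areas <- numeric(0)
  lesion_masks <- list()
  # draw leaves back-to-front; lesions belong to their leaf's visible part
  for (i in seq_len(spec$n_leaves)) {
    leaf_col <- c(stats::runif(1, 0.10, 0.22), stats::runif(1, 0.38, 0.55),
                  stats::runif(1, 0.10, 0.20))
    m <- masks[[i]]
    img <- paint(img, m, leaf_col)
    tex <- smooth_noise(S, S, 5L, 0.05)
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[m] <- pmin(pmax(pl[m] + tex[m], 0), 1)
      img[, , ch] <- pl
    }
    nles <- sample(spec$lesions_per_leaf[1]:spec$lesions_per_leaf[2], 1L)
    for (l in seq_len(nles)) {
      cls <- spec$lesion_classes[sample.int(length(spec$lesion_classes), 1L)]
      frac <- stats::runif(1, spec$lesion_area_fraction[1],
                           spec$lesion_area_fraction[2])
      area_px <- frac * S^2
      ecc <- stats::runif(1, 0.6, 1)
      a <- sqrt(area_px / (pi * ecc)); b <- a * ecc
      inside <- which(m, arr.ind = TRUE)
      if (!nrow(inside)) next
      p <- inside[sample.int(nrow(inside), 1L), ]
      lm <- ellipse_mask(S, S, p[2], p[1], a, b,
                         stats::runif(1, 0, pi), wobble = 0.25) & m
      if (sum(lm) < 4L) next
      # the annotation is the mask's bounding box, whose area exceeds the
      # mask area; cap it when the spec bounds the box area fraction
      idx <- which(lm, arr.ind = TRUE)
      bb_frac <- (diff(range(idx[, 1])) + 1) * (diff(range(idx[, 2])) + 1) /
        S^2
      if (!is.null(spec$max_box_area_fraction) &&
          bb_frac > spec$max_box_area_fraction) next
      col <- lesion_palette(cls) + stats::runif(3, -0.04, 0.04)
      img <- paint(img, lm, pmin(pmax(col, 0), 1))
      spot_tex <- smooth_noise(S, S, 3L, 0.04)
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[lm] <- pmin(pmax(pl[lm] + spot_tex[lm], 0), 1)
        img[, , ch] <- pl
      }
      idx <- which(lm, arr.ind = TRUE)
      x1 <- min(idx[, 2]) - 1L; x2 <- max(idx[, 2])
      y1 <- min(idx[, 1]) - 1L; y2 <- max(idx[, 1])
      ann <- rbind(ann, c(cls, (x1 + x2) / 2 / S, (y1 + y2) / 2 / S,
                          (x2 - x1) / S, (y2 - y1) / S))
      areas <- c(areas, sum(lm) / S^2)
      if (return_masks) lesion_masks[[length(lesion_masks) + 1L]] <- lm
    }
  }

  illum_angle <- NA_real_
  if (spec$illumination_gradient > 0) {
    g <- spec$illumination_gradient
    ang <- illum_angle <- stats::runif(1, 0, 2 * pi)
    xx <- matrix(seq_len(S), S, S, byrow = TRUE) / S - 0.5
    yy <- matrix(seq_len(S), S, S) / S - 0.5
    t <- (xx * cos(ang) + yy * sin(ang)) + 0.5   # 0..1 along ramp
    ramp <- 1 - g / 2 + g * t
    for (ch in 1:3) img[, , ch] <- img[, , ch] * ramp
  }
  img <- pmin(pmax(img, 0), 1)
  if (!is.null(ann))
    colnames(ann) <- c("class", "cx", "cy", "w", "h")
  list(image = img,
       annotations = if (is.null(ann))
         matrix(numeric(0), 0, 5,
                dimnames = list(NULL, c("class", "cx", "cy", "w", "h")))
       else ann,
       metadata = list(achieved_occlusion = overlaps,
                       lesion_area_fractions = areas,
                       background_kind = spec$background_kind,
                       illumination_angle = illum_angle),
       lesion_masks = if (return_masks) lesion_masks)
}

#' Challenge-scene presets
#'
#' `easy`: one or two well-separated leaves on a simple background with
#' large lesions. `occlusion`: overlapping leaves (target overlap 0.5).
#' `lowlight`: strong illumination gradient (amplitude 0.6) plus post-hoc
#' brightness/contrast perturbation at dataset build time.
#' `smalllesion`: every lesion at most 0.5% of the image area.
#'
#' @param preset one of `"easy"`, `"occlusion"`, `"lowlight"`,
#'   `"smalllesion"`.
#' @param image_size image side in pixels.
#' @param lesion_classes class ids available to the generator.
#' @return A [scene_spec()].
#' @export
challenge_spec <- function(preset = c("easy", "occlusion", "lowlight",
                                      "smalllesion"),
                           image_size = 320L, lesion_classes = 0:2) {
  preset <- match.arg(preset)
  switch(preset,
    easy = scene_spec(image_size, n_leaves = 1L,
                      background_kind = "simple",
                      lesion_classes = lesion_classes,
                      lesions_per_leaf = c(1L, 2L),
                      lesion_area_fraction = c(0.015, 0.06)),
    occlusion = scene_spec(image_size, n_leaves = 3L,
                           background_kind = "complex",
                           lesion_classes = lesion_classes,
                           occlusion_level = 0.5),
    lowlight = scene_spec(image_size, n_leaves = 2L,
                          background_kind = "complex",
                          lesion_classes = lesion_classes,
                          illumination_gradient = 0.6),
    smalllesion = scene_spec(image_size, n_leaves = 2L,
                             background_kind = "complex",
                             lesion_classes = lesion_classes,
                             lesions_per_leaf = c(1L, 3L),
                             lesion_area_fraction = c(0.0008, 0.0035),
                             max_box_area_fraction = 0.005))
}

#' Generate a dataset in YOLO layout
#'
#' Renders `n_images` scenes (cycling over the given spec or list of
#' specs), splits them 7:2:1 into train/validation/test (val and test
#' sizes are `round(0.2 n)` and the remainder after train
#' `n - round(0.7 n) - round(0.2 n)`), and writes
#' `images/<split>/*.png`, `labels/<split>/*.txt` and `dataset.yaml`.
#' For `lowlight` presets a post-hoc brightness/contrast perturbation is
#' applied to each image.
#'
#' @param specs a [scene_spec()] or list of them, cycled over images.
#' @param n_images total images (>= 10).
#' @param seed master seed; per-image seeds are derived deterministically.
#' @param out_dir output directory (created).
#' @param split length-3 proportions, default `c(0.7, 0.2, 0.1)`.
#' @param class_names names for the manifest (defaults to
#'   `lesion_class_<id>`).
#' @param perturb_brightness apply the brightness/contrast perturbation.
#' @return The manifest path (invisibly, with the per-split counts as an
#'   attribute).
#' @export
generate_dataset <- function(specs, n_images, seed = 0L, out_dir,
                             split = c(0.7, 0.2, 0.1),
                             class_names = NULL,
                             perturb_brightness = FALSE) {
  if (n_images < 10L) stop("generate_dataset: need at least 10 images")
  if (inherits(specs, "scene_spec")) specs <- list(specs)
  stopifnot(abs(sum(split) - 1) < 1e-9)
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("generate_dataset: cannot create ", out_dir)
  n_train <- round(split[1] * n_images)
  n_val <- round(split[2] * n_images)
  n_test <- n_images - n_train - n_val
  assign_split <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
  for (s in unique(assign_split)) {
    dir.create(file.path(out_dir, "images", s), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(out_dir, "labels", s), recursive = TRUE,
               showWarnings = FALSE)
  }
  all_classes <- sort(unique(unlist(lapply(specs, `[[`, "lesion_classes"))))
  if (is.null(class_names))
    class_names <- paste0("lesion_class_", seq_len(max(all_classes) + 1L) - 1L)
  for (i in seq_len(n_images)) {
    sp <- specs[[(i - 1L) %% length(specs) + 1L]]
    sc <- generate_scene(sp, seed = (seed * 100003 + i) %% 2147483647)
    img <- sc$image
    if (perturb_brightness) {
      set.seed(seed + 7L * i)
      img <- pmin(pmax((img - 0.5) * stats::runif(1, 0.7, 1.3) + 0.5 +
                       stats::runif(1, -0.15, 0.15), 0), 1)
    }
    s <- assign_split[i]
    stem <- sprintf("img_%05d", i)
    write_image(img, file.path(out_dir, "images", s,
                               paste0(stem, ".png")))
    write_yolo_labels(sc$annotations,
                      file.path(out_dir, "labels", s, paste0(stem, ".txt")))
  }
  path <- write_dataset_yaml(out_dir, class_names)
  attr(path, "split_sizes") <- c(train = n_train, val = n_val, test = n_test)
  invisible(path)
}

## ---- augmentation suite -------------------------------------------------

hsv2rgb_mat <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h); f <- h - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

#' Augment an image and its annotations
#'
#' Applies the requested operations in a fixed order (geometric first:
#' mirror, rotation, translation; then photometric: sharpness, noise,
#' color_dither; then cutout). Geometric operations transform boxes
#' consistently with pixels — rotation replaces each box by the
#' axis-aligned bounding box of its rotated corners; photometric
#' operations and cutout leave annotations unchanged. Boxes that fall
#' fully outside the canvas are dropped and counted. Deterministic given
#' `seed`.
#'
#' Default parameter ranges: rotation +/-15 degrees, translation up to 10%
#' of the image, up to 3 cutout patches of at most 10% area each, HSV
#' jitter up to 0.2.
#'
#' @param image `[H, W, 3]` array in `[0, 1]`.
#' @param annotations matrix `class, cx, cy, w, h` (YOLO-normalized).
#' @param ops character subset of `rotation, translation, mirror,
#'   sharpness, noise, cutout, color_dither`.
#' @param seed integer seed.
#' @param params optional overrides: `rotation_deg, translate_frac,
#'   noise_sd, cutout_n, cutout_frac, hsv_jitter, sharpness_amount`.
#' @return A list with `image`, `annotations` and `dropped` (count of
#'   annotations lost to geometry).
#' @export
augment <- function(image, annotations, ops, seed = 0L, params = list()) {
  allowed <- c("rotation", "translation", "mirror", "sharpness", "noise",
               "cutout", "color_dither")
  if (length(setdiff(ops, allowed)))
    stop("augment: unknown ops: ", paste(setdiff(ops, allowed),
                                         collapse = ", "))
  pdef <- list(rotation_deg = 15, translate_frac = 0.1, noise_sd = 0.03,
               cutout_n = 3L, cutout_frac = 0.1, hsv_jitter = 0.2,
               sharpness_amount = 0.7)
  pdef[names(params)] <- params
  set.seed(seed)
  H <- dim(image)[1]; W <- dim(image)[2]
  ann <- as.matrix(annotations)
  dropped <- 0L

  if ("mirror" %in% ops) {
    image <- image[, W:1, , drop = FALSE]
    if (nrow(ann)) ann[, 2] <- 1 - ann[, 2]
  }
  if ("rotation" %in% ops) {
    th <- stats::runif(1, -pdef$rotation_deg, pdef$rotation_deg) * pi / 180
    # inverse nearest-neighbour mapping about the centre
    xx <- matrix(seq_len(W), H, W, byrow = TRUE) - (W + 1) / 2
    yy <- matrix(seq_len(H), H, W) - (H + 1) / 2
    xs <- as.vector(round(xx * cos(-th) + yy * sin(-th) + (W + 1) / 2))
    ys <- as.vector(round(-xx * sin(-th) + yy * cos(-th) + (H + 1) / 2))
    valid <- xs >= 1 & xs <= W & ys >= 1 & ys <= H
    idx <- cbind(pmin(pmax(ys, 1), H), pmin(pmax(xs, 1), W))
    out <- array(0.5, dim(image))
    for (ch in 1:3) {
      pl <- matrix(0.5, H, W)
      src <- image[, , ch]
      pl[valid] <- src[idx][valid]
      out[, , ch] <- pl
    }
    image <- out
    if (nrow(ann)) {
      newann <- NULL
      for (r in seq_len(nrow(ann))) {
        cxp <- ann[r, 2] * W; cyp <- ann[r, 3] * H
        wp <- ann[r, 4] * W; hp <- ann[r, 5] * H
        corners <- cbind(c(cxp - wp / 2, cxp + wp / 2, cxp - wp / 2,
                           cxp + wp / 2) - (W + 1) / 2,
                         c(cyp - hp / 2, cyp - hp / 2, cyp + hp / 2,
                           cyp + hp / 2) - (H + 1) / 2)
        rx <- corners[, 1] * cos(th) + corners[, 2] * sin(th) + (W + 1) / 2
        ry <- -corners[, 1] * sin(th) + corners[, 2] * cos(th) + (H + 1) / 2
        x1 <- max(min(rx), 0); x2 <- min(max(rx), W)
        y1 <- max(min(ry), 0); y2 <- min(max(ry), H)
        if (x2 <= 0 || y2 <= 0 || x1 >= W || y1 >= H || x2 <= x1 ||
            y2 <= y1) { dropped <- dropped + 1L; next }
        newann <- rbind(newann, c(ann[r, 1], (x1 + x2) / 2 / W,
                                  (y1 + y2) / 2 / H, (x2 - x1) / W,
                                  (y2 - y1) / H))
      }
      ann <- if (is.null(newann)) ann[0, , drop = FALSE] else newann
    }
  }
  if ("translation" %in% ops) {
    dx <- round(stats::runif(1, -pdef$translate_frac, pdef$translate_frac) * W)
    dy <- round(stats::runif(1, -pdef$translate_frac, pdef$translate_frac) * H)
    out <- array(0.5, dim(image))
    sx <- seq_len(W) - dx; sy <- seq_len(H) - dy
    okx <- sx >= 1 & sx <= W; oky <- sy >= 1 & sy <= H
    out[which(oky), which(okx), ] <-
      image[sy[oky], sx[okx], , drop = FALSE]
    image <- out
    if (nrow(ann)) {
      ann[, 2] <- ann[, 2] + dx / W
      ann[, 3] <- ann[, 3] + dy / H
      inside <- ann[, 2] + ann[, 4] / 2 > 0 & ann[, 2] - ann[, 4] / 2 < 1 &
                ann[, 3] + ann[, 5] / 2 > 0 & ann[, 3] - ann[, 5] / 2 < 1
      dropped <- dropped + sum(!inside)
      ann <- ann[inside, , drop = FALSE]
    }
  }
  if ("sharpness" %in% ops) {
    blur <- image
    for (ch in 1:3)
      blur[, , ch] <- conv2_replicate(image[, , ch],
                                      matrix(1 / 9, 3, 3))
    image <- pmin(pmax(image + pdef$sharpness_amount * (image - blur), 0), 1)
  }
  if ("noise" %in% ops) {
    image <- pmin(pmax(image + array(stats::rnorm(length(image), 0,
                                                  pdef$noise_sd),
                                     dim(image)), 0), 1)
  }
  if ("color_dither" %in% ops) {
    j <- pdef$hsv_jitter
    hsv <- grDevices::rgb2hsv(rbind(as.vector(image[, , 1]),
                                    as.vector(image[, , 2]),
                                    as.vector(image[, , 3])), maxColorValue = 1)
    h <- hsv[1, ] + stats::runif(1, -j / 2, j / 2)
    s <- pmin(pmax(hsv[2, ] * (1 + stats::runif(1, -j, j)), 0), 1)
    v <- pmin(pmax(hsv[3, ] * (1 + stats::runif(1, -j, j)), 0), 1)
    rgb <- hsv2rgb_mat(h, s, v)
    image[, , 1] <- matrix(rgb$r, H, W)
    image[, , 2] <- matrix(rgb$g, H, W)
    image[, , 3] <- matrix(rgb$b, H, W)
  }
  if ("cutout" %in% ops) {
    k <- sample.int(pdef$cutout_n, 1L)
    for (i in seq_len(k)) {
      cw <- round(stats::runif(1, 0.03, sqrt(pdef$cutout_frac)) * W)
      chh <- round(stats::runif(1, 0.03, sqrt(pdef$cutout_frac)) * H)
      x0 <- sample.int(max(W - cw, 1L), 1L)
      y0 <- sample.int(max(H - chh, 1L), 1L)
      image[y0:(y0 + chh - 1L), x0:(x0 + cw - 1L), ] <- 0.5
    }
  }
  list(image = image, annotations = ann, dropped = dropped)
}
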