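# Dataset I/O: YOLO-format labels, dataset manifests, PNG images.

#' Read and write YOLO-format label files
#'
#' One object per line: `class cx cy w h`, all but `class` normalized to
#' `[0, 1]`. An empty or missing file yields a zero-row matrix.
#'
#' @param path label file path.
#' @return A matrix with columns `class, cx, cy, w, h`.
#' @export
read_yolo_labels <- function(path) {
  empty <- matrix(numeric(0), 0, 5,
                  dimnames = list(NULL, c("class", "cx", "cy", "w", "h")))
  if (!file.exists(path) || file.size(path) == 0) return(empty)
  m <- as.matrix(utils::read.table(path, col.names = c("class", "cx", "cy",
                                                       "w", "h")))
  if (any(m[, 2:5] < -1e-9) || any(m[, 2:5] > 1 + 1e-9))
    stop("labels in ", path, " are not normalized to [0, 1]")
  m
}

#' @rdname read_yolo_labels
#' @param labels matrix/data.frame with columns `class, cx, cy, w, h`.
#' @export
write_yolo_labels <- function(labels, path) {
  labels <- as.matrix(labels)
  lines <- if (nrow(labels)) apply(labels, 1, function(r)
    sprintf("%d %.6f %.6f %.6f %.6f", as.integer(r[1]), r[2], r[3], r[4],
            r[5])) else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Write a dataset manifest
#'
#' Standard YOLO dataset YAML: root path, per-split image directories and
#' the class-name map.
#'
#' @param out_dir dataset root.
#' @param class_names character vector of class names (index 0 first).
#' @param splits named list of split image directories, relative to root.
#' @return The manifest path.
#' @export
write_dataset_yaml <- function(out_dir, class_names,
                               splits = list(train = "images/train",
                                             val = "images/val",
                                             test = "images/test")) {
  names(class_names) <- NULL
  manifest <- c(list(path = normalizePath(out_dir)), splits,
                list(nc = length(class_names),
                     names = as.list(class_names)))
  path <- file.path(out_dir, "dataset.yaml")
  yaml::write_yaml(manifest, path)
  path
}

#' Read / write an RGB image
#'
#' Images are `[H, W, 3]` double arrays in `[0, 1]`; files are PNG.
#' @param path file path; @param img image array.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' @rdname read_image
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

# List a split's images together with their label paths.
split_files <- function(dataset_dir, split = "train") {
  manifest <- yaml::read_yaml(file.path(dataset_dir, "dataset.yaml"))
  img_dir <- file.path(dataset_dir, manifest[[split]])
  imgs <- sort(list.files(img_dir, pattern = "\\.png$", full.names = TRUE))
  labs <- file.path(dataset_dir, "labels", basename(img_dir),
                    sub("\\.png$", ".txt", basename(imgs)))
  list(images = imgs, labels = labs, nc = manifest$nc,
       names = unlist(manifest$names))
}

#' Read a predictions file
#'
#' Plain-text predictions: one detection per line,
#' `image_id class confidence x1 y1 x2 y2` (whitespace-separated), or a
#' JSON array of objects with those fields.
#'
#' @param path predictions file.
#' @return A data.frame with columns `image_id, class, confidence,
#'   x1, y1, x2, y2`.
#' @export
read_predictions <- function(path) {
  if (grepl("\\.json$", path)) {
    df <- jsonlite::fromJSON(path)
    return(df[, c("image_id", "class", "confidence", "x1", "y1", "x2", "y2")])
  }
  utils::read.table(path, col.names = c("image_id", "class", "confidence",
                                        "x1", "y1", "x2", "y2"))
}
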