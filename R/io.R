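# Readers for class-per-directory image trees (PNG/JPEG via EBImage).

#' Read a class-labelled image directory tree
#'
#' Supported layouts:
#' \describe{
#'   \item{`flat`}{`root/<class>/<image>` — one directory per class.}
#'   \item{`breakhis`}{`root/<class>/.../<magnification>/<image>` — binary or
#'     subtype breast-histology trees; the top-level directory gives the
#'     label and a path component like `40X` is recorded as magnification.}
#'   \item{`bach`}{`root/<class>/<image>` with exactly four class
#'     directories (four-class microscopy layout).}
#' }
#' Labels are assigned from class-directory names sorted lexicographically
#' (0-based). Images are resized to `image_size` with bilinear
#' interpolation; undecodable files are skipped with a warning.
#'
#' @param root Directory containing the class subdirectories.
#' @param layout One of `"flat"`, `"breakhis"`, `"bach"`.
#' @param image_size Target side length in pixels (default 224); `NULL`
#'   keeps original sizes (all images must then agree).
#' @param manifest Optional path; if given, a CSV of
#'   `filepath,label,class_name,magnification` is written there.
#' @return A `labeled_image_set` with per-image `metadata`.
#' @export
read_image_folder <- function(root, layout = c("flat", "breakhis", "bach"),
                              image_size = 224L, manifest = NULL) {
  layout <- match.arg(layout)
  if (!dir.exists(root)) stop("read_image_folder: root directory not found: ", root)
  class_dirs <- sort(list.dirs(root, recursive = FALSE, full.names = TRUE))
  if (layout == "bach" && length(class_dirs) != 4L) {
    stop("bach layout expects exactly four class directories, found ",
         length(class_dirs))
  }
  if (length(class_dirs) == 0L) stop("no class directories under ", root)
  class_names <- basename(class_dirs)
  pat <- "\\.(png|jpg|jpeg)$"
  images <- list()
  labels <- integer(0)
  meta <- list()
  for (k in seq_along(class_dirs)) {
    files <- sort(list.files(class_dirs[k], pattern = pat, recursive = TRUE,
                             full.names = TRUE, ignore.case = TRUE))
    for (f in files) {
      img <- tryCatch(load_rgb_image(f, image_size), error = function(e) {
        warning("skipping undecodable image: ", f, call. = FALSE)
        NULL
      })
      if (is.null(img)) next
      images[[length(images) + 1L]] <- img
      labels[length(labels) + 1L] <- k - 1L
      mag <- NA_character_
      if (layout == "breakhis") {
        parts <- strsplit(dirname(f), .Platform$file.sep)[[1L]]
        hit <- grep("^[0-9]+[Xx]$", parts, value = TRUE)
        if (length(hit) > 0L) mag <- toupper(hit[length(hit)])
      }
      meta[[length(meta) + 1L]] <- tibble::tibble(
        filepath = f, label = k - 1L, class_name = class_names[k],
        magnification = mag)
    }
  }
  if (length(images) == 0L) stop("no decodable images found under ", root)
  metadata <- do.call(rbind, meta)
  if (!is.null(manifest)) {
    utils::write.csv(metadata, manifest, row.names = FALSE)
  }
  labeled_image_set(images, labels, class_names, source = "folder",
                    metadata = metadata)
}

# read one file as an (H, W, 3) array in [0,1], optionally resized (bilinear)
load_rgb_image <- function(path, image_size = NULL) {
  img <- EBImage::readImage(path)
  if (!is.null(image_size)) {
    img <- EBImage::resize(img, w = image_size, h = image_size)
  }
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3] == 1L) a <- array(rep(a, 3L), c(dim(a)[1:2], 3L))
  # EBImage stores x (width) first; convert to (row, column, channel)
  a <- aperm(a, c(2, 1, 3))
  pmin(pmax(a, 0), 1)
}

# write a labeled_image_set as root/<class>/<name>.png (used by the CLI)
write_image_folder <- function(data, root, manifest = NULL) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  counter <- integer(length(data$class_names))
  for (i in seq_along(data$images)) {
    k <- data$labels[i] + 1L
    cn <- data$class_names[k]
    dir.create(file.path(root, cn), showWarnings = FALSE)
    counter[k] <- counter[k] + 1L
    f <- file.path(root, cn, sprintf("%s_%04d.png", cn, counter[k]))
    img <- aperm(data$images[[i]], c(2, 1, 3))  # back to x-first for EBImage
    EBImage::writeImage(EBImage::Image(img, colormode = "Color"), f)
    rows[[i]] <- tibble::tibble(filepath = f, label = data$labels[i],
                                class_name = cn, magnification = NA_character_)
  }
  md <- do.call(rbind, rows)
  if (!is.null(manifest)) utils::write.csv(md, manifest, row.names = FALSE)
  invisible(md)
}
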