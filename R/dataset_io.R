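# Annotation writers and readers: COCO detection JSON, YOLO txt labels
# (one file per image, "cls cx cy w h" normalized to [0, 1]), PNG images,
# and a YAML manifest tying paths, class names and split lists together.

#' Write a dataset to disk
#'
#' @param samples list of samples; each a list with `id` (basename), `boxes`
#'   (data.frame x1, y1, x2, y2, cls in pixels), `size` (image side) and
#'   optionally `image` (array, written as PNG when `write_images = TRUE`).
#' @param format `"coco_json"` or `"yolo_labels"`.
#' @param out_dir output directory (created).
#' @param write_images write PNG images for samples that carry one.
#' @param split optional list of index vectors (e.g. from [split_dataset()])
#'   recorded in the manifest.
#' @param classes class table, see [ripeness_classes()].
#' @return the manifest (also written as `manifest.yaml`), including the
#'   per-class instance histogram `class_counts`.
#' @export
write_dataset <- function(samples, format = c("coco_json", "yolo_labels"),
                          out_dir, write_images = TRUE, split = NULL,
                          classes = ripeness_classes()) {
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  img_dir <- file.path(out_dir, "images")
  if (write_images) dir.create(img_dir, showWarnings = FALSE)

  counts <- integer(nrow(classes))
  names(counts) <- classes$name
  img_files <- character(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    img_files[i] <- paste0(s$id, ".png")
    if (write_images && !is.null(s$image)) {
      png::writePNG(s$image, file.path(img_dir, img_files[i]))
    }
    if (nrow(s$boxes)) {
      counts <- counts + tabulate(s$boxes$cls + 1L, nbins = nrow(classes))
    }
  }

  if (format == "coco_json") {
    images <- lapply(seq_along(samples), function(i) {
      list(id = i, file_name = img_files[i],
           width = samples[[i]]$size, height = samples[[i]]$size)
    })
    ann_id <- 0L
    annotations <- list()
    for (i in seq_along(samples)) {
      b <- samples[[i]]$boxes
      for (j in seq_len(nrow(b))) {
        ann_id <- ann_id + 1L
        annotations[[ann_id]] <- list(
          id = ann_id, image_id = i,
          category_id = b$cls[j] + 1L,
          bbox = c(b$x1[j], b$y1[j], b$x2[j] - b$x1[j], b$y2[j] - b$y1[j]),
          area = (b$x2[j] - b$x1[j]) * (b$y2[j] - b$y1[j]),
          iscrowd = 0L)
      }
    }
    categories <- lapply(seq_len(nrow(classes)), function(k) {
      list(id = classes$id[k] + 1L, name = classes$name[k],
           supercategory = "tomato")
    })
    jsonlite::write_json(
      list(images = images, annotations = annotations, categories = categories),
      file.path(out_dir, "annotations.json"), auto_unbox = TRUE, digits = NA)
  } else {
    lbl_dir <- file.path(out_dir, "labels")
    dir.create(lbl_dir, showWarnings = FALSE)
    for (i in seq_along(samples)) {
      s <- samples[[i]]
      b <- s$boxes
      lines <- character(0)
      if (nrow(b)) {
        cx <- (b$x1 + b$x2) / 2 / s$size
        cy <- (b$y1 + b$y2) / 2 / s$size
        w <- (b$x2 - b$x1) / s$size
        h <- (b$y2 - b$y1) / s$size
        lines <- sprintf("%d %.6g %.6g %.6g %.6g", b$cls, cx, cy, w, h)
      }
      writeLines(lines, file.path(lbl_dir, paste0(s$id, ".txt")))
    }
  }

  manifest <- list(
    format = format,
    classes = classes$name,
    n_images = length(samples),
    class_counts = as.list(counts),
    images = img_files,
    split = if (!is.null(split)) lapply(split, as.integer)
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  manifest
}

#' Read a COCO-JSON dataset written by [write_dataset()]
#'
#' @param path dataset directory.
#' @return list of samples (id, size, boxes) in image-id order.
#' @export
read_dataset_coco <- function(path) {
  j <- jsonlite::read_json(file.path(path, "annotations.json"))
  anns_by_img <- split(j$annotations,
                       vapply(j$annotations, function(a) a$image_id, numeric(1)))
  lapply(j$images, function(im) {
    anns <- anns_by_img[[as.character(im$id)]]
    boxes <- if (is.null(anns)) {
      data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                 y2 = numeric(0), cls = integer(0))
    } else {
      do.call(rbind, lapply(anns, function(a) {
        bb <- unlist(a$bbox)
        data.frame(x1 = bb[1], y1 = bb[2], x2 = bb[1] + bb[3],
                   y2 = bb[2] + bb[4], cls = a$category_id - 1L)
      }))
    }
    rownames(boxes) <- NULL
    list(id = sub("\\.png$", "", im$file_name), size = im$width, boxes = boxes)
  })
}

#' Read one YOLO label file back into pixel boxes
#'
#' @param file label txt path.
#' @param size image side in pixels.
#' @return data.frame x1, y1, x2, y2, cls.
#' @export
read_yolo_labels <- function(file, size) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), cls = integer(0)))
  }
  m <- do.call(rbind, lapply(strsplit(lines, "\\s+"), as.numeric))
  data.frame(x1 = (m[, 2] - m[, 4] / 2) * size,
             y1 = (m[, 3] - m[, 5] / 2) * size,
             x2 = (m[, 2] + m[, 4] / 2) * size,
             y2 = (m[, 3] + m[, 5] / 2) * size,
             cls = as.integer(m[, 1]))
}
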