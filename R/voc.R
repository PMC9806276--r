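# PASCAL VOC XML annotation I/O (the dialect exported by the CVAT
# annotation tool), PNG image I/O, and the seeded train/val/test split.

#' Write a PASCAL VOC annotation file
#'
#' @param path output XML path.
#' @param filename image file name recorded in the annotation.
#' @param width,height image size in pixels.
#' @param boxes a [pred_boxes()] data.frame; `class_id` is mapped
#'   through `class_names`.
#' @param class_names character vector naming class ids (id 0 is the
#'   first element).
#' @param depth channel count recorded in the annotation.
#' @return `path`, invisibly.
#' @export
write_voc_xml <- function(path, filename, width, height, boxes,
                          class_names = "weed", depth = 3) {
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", "images")
  xml2::xml_add_child(doc, "filename", filename)
  src <- xml2::xml_add_child(doc, "source")
  xml2::xml_add_child(src, "database", "synthetic")
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(as.integer(width)))
  xml2::xml_add_child(size, "height", as.character(as.integer(height)))
  xml2::xml_add_child(size, "depth", as.character(as.integer(depth)))
  xml2::xml_add_child(doc, "segmented", "0")
  for (i in seq_len(nrow(boxes))) {
    ob <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(ob, "name", class_names[boxes$class_id[i] + 1L])
    xml2::xml_add_child(ob, "pose", "Unspecified")
    xml2::xml_add_child(ob, "truncated", "0")
    xml2::xml_add_child(ob, "difficult", "0")
    bb <- xml2::xml_add_child(ob, "bndbox")
    xml2::xml_add_child(bb, "xmin", as.character(round(boxes$x1[i])))
    xml2::xml_add_child(bb, "ymin", as.character(round(boxes$y1[i])))
    xml2::xml_add_child(bb, "xmax", as.character(round(boxes$x2[i])))
    xml2::xml_add_child(bb, "ymax", as.character(round(boxes$y2[i])))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a PASCAL VOC annotation file
#'
#' @param path XML path.
#' @param class_names class name vector mapping names to 0-based ids;
#'   unknown names are appended in order of appearance.
#' @return list with `filename`, `width`, `height`, `boxes`
#'   (a [pred_boxes()] data.frame), `class_names`.
#' @export
read_voc_xml <- function(path, class_names = "weed") {
  doc <- xml2::read_xml(path)
  filename <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  width <- as.integer(xml2::xml_text(xml2::xml_find_first(doc, "./size/width")))
  height <- as.integer(xml2::xml_text(xml2::xml_find_first(doc, "./size/height")))
  objs <- xml2::xml_find_all(doc, "./object")
  boxes <- no_boxes()
  for (ob in objs) {
    nm <- xml2::xml_text(xml2::xml_find_first(ob, "./name"))
    if (!nm %in% class_names) class_names <- c(class_names, nm)
    num <- function(tag) as.numeric(
      xml2::xml_text(xml2::xml_find_first(ob, paste0("./bndbox/", tag))))
    boxes <- rbind(boxes, pred_boxes(num("xmin"), num("ymin"),
                                     num("xmax"), num("ymax"),
                                     class_id = match(nm, class_names) - 1L))
  }
  class(boxes) <- c("pred_box", "data.frame")
  list(filename = filename, width = width, height = height,
       boxes = boxes, class_names = class_names)
}

#' Split sample ids into train/validation/test sets
#'
#' Random split at the given ratio (default 8:1:1), deterministic for a
#' fixed seed.
#'
#' @param ids vector of sample identifiers.
#' @param ratio length-3 non-negative weights for train/val/test.
#' @param seed RNG seed.
#' @return list with `train`, `val`, `test`.
#' @export
split_dataset <- function(ids, ratio = c(8, 1, 1), seed = 0) {
  stopifnot(length(ratio) == 3, all(ratio >= 0), sum(ratio) > 0)
  set.seed(derive_seed(seed, "split"))
  n <- length(ids)
  shuffled <- sample(ids)
  frac <- ratio / sum(ratio)
  n_tr <- floor(n * frac[1])
  n_va <- floor(n * frac[2])
  list(train = shuffled[seq_len(n_tr)],
       val = shuffled[n_tr + seq_len(n_va)],
       test = shuffled[-seq_len(n_tr + n_va)])
}

#' Read / write PNG images as (H, W, C) arrays
#'
#' Thin wrappers over the png package keeping the package's `(H, W, C)`
#' array convention with values in `[0, 1]`.
#'
#' @param path PNG file path.
#' @return `read_image()`: an `(H, W, C)` array.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) dim(img) <- c(dim(img), 1)
  img
}

#' @rdname read_image
#' @param image `(H, W, C)` array in `[0, 1]`.
#' @export
write_image <- function(path, image) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}
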