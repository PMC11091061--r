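# Reading and writing polygon annotations in the VGG Image Annotator (VIA)
# export dialect (JSON and its CSV twin).

#' Canonical annotation classes
#'
#' The seven classes used throughout: plant root, the five AMF structures
#' (arbuscule `arb`, extraradical hypha `exH`, intraradical hypha `inH`,
#' vesicle `ves`, spore `sp`), and `other` for non-AM structures.
#'
#' @param amf_only return only the five AMF structure classes?
#' @return character vector of class labels.
#' @export
amf_classes <- function(amf_only = FALSE) {
  cls <- c("root", "arb", "exH", "inH", "ves", "sp", "other")
  if (amf_only) cls[2:6] else cls
}

#' Normalize annotation class labels to the canonical vocabulary
#'
#' Maps the label spellings seen in annotation exports (full names,
#' abbreviations, "external"/"internal" variants, "non-AM") onto the seven
#' canonical labels; anything unrecognized is mapped to `"other"` with a
#' warning.
#'
#' @param labels character vector of raw labels.
#' @return character vector of canonical labels.
#' @export
normalize_class_label <- function(labels) {
  key <- tolower(trimws(as.character(labels)))
  key <- gsub("[ _-]+", " ", key)
  map <- c(
    "root" = "root", "plant root" = "root", "sorghum root" = "root",
    "arb" = "arb", "arbuscule" = "arb", "amf arbuscule" = "arb",
    "exh" = "exH", "extraradical hypha" = "exH", "external hypha" = "exH",
    "extradical hypha" = "exH", "amf external hypha" = "exH",
    "inh" = "inH", "intraradical hypha" = "inH", "internal hypha" = "inH",
    "amf internal hypha" = "inH",
    "ves" = "ves", "vesicle" = "ves", "amf vesicle" = "ves",
    "sp" = "sp", "spore" = "sp", "amf spore" = "sp",
    "other" = "other", "others" = "other", "non am" = "other",
    "nonam" = "other", "non am fungal structure" = "other")
  out <- unname(map[key])
  bad <- is.na(out) & !is.na(key) & nzchar(key)
  if (any(bad)) {
    warning(sprintf("unknown class label(s) mapped to 'other': %s",
                    paste(unique(labels[bad]), collapse = ", ")))
    out[bad] <- "other"
  }
  out[is.na(out)] <- "other"
  out
}

# convert one VIA shape_attributes record to a vertex matrix, or NULL when
# the shape type is removed by the cleaning rules
.via_shape_to_polygon <- function(sa, circle_points = 64L) {
  type <- sa$name
  if (is.null(type)) return(NULL)
  if (type %in% c("polygon", "polyline")) {
    xs <- unlist(sa$all_points_x); ys <- unlist(sa$all_points_y)
    if (length(xs) < 3L || length(xs) != length(ys)) return(NULL)
    return(cbind(as.numeric(xs), as.numeric(ys)))
  }
  if (type == "circle") {
    th <- seq(0, 2 * pi, length.out = circle_points + 1L)[-(circle_points + 1L)]
    return(cbind(sa$cx + sa$r * cos(th), sa$cy + sa$r * sin(th)))
  }
  # point, rect and ellipse are removed during cleaning
  NULL
}

.region_class <- function(ra) {
  if (is.null(ra) || !length(ra)) return(NA_character_)
  for (k in c("class", "label", "type", "name"))
    if (!is.null(ra[[k]])) return(as.character(ra[[k]]))
  as.character(ra[[1L]])
}

#' Parse a VIA annotation export
#'
#' Reads the VGG Image Annotator JSON export (or its CSV twin) and applies
#' the cleaning rules: polygons are kept, polylines are closed into
#' polygons, circles are resampled to 64-gon approximations; point,
#' rectangle and ellipse shapes as well as empty/undefined segmentations are
#' removed; class labels are normalized to the canonical vocabulary
#' (unknown labels merge into `"other"` with a warning); self-intersecting
#' polygons are dissected into simple pieces; vertices are clamped to the
#' image frame when dimensions are known.
#'
#' @param path annotation file (`.json` or `.csv`).
#' @param default_size `c(width, height)` used when the export does not
#'   record image dimensions; defaults to the per-image vertex extent.
#' @param repair dissect self-intersecting polygons? (default `TRUE`)
#' @return list of [annotated_image()] objects.
#' @export
parse_annotations <- function(path, default_size = NULL, repair = TRUE) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    .parse_via_json(path) else .parse_via_csv(path)
  out <- list()
  for (img_id in names(raw)) {
    rec <- raw[[img_id]]
    shapes <- list()
    for (reg in rec$regions) {
      V <- tryCatch(.via_shape_to_polygon(reg$shape_attributes),
                    error = function(e)
                      stop("unparseable region in image '", img_id, "': ",
                           conditionMessage(e)))
      if (is.null(V)) next
      cls <- normalize_class_label(.region_class(reg$region_attributes))
      shapes[[length(shapes) + 1L]] <- polygon_shape(V, cls)
    }
    wh <- if (!is.null(default_size)) default_size else {
      if (length(shapes)) {
        allv <- do.call(rbind, lapply(shapes, `[[`, "vertices"))
        c(max(allv[, 1L]), max(allv[, 2L]))
      } else c(1, 1)
    }
    if (!is.null(rec$width) && !is.na(rec$width)) wh <- c(rec$width, rec$height)
    # clamp to frame, then repair
    cleaned <- list()
    for (sh in shapes) {
      V <- sh$vertices
      V[, 1L] <- pmin(pmax(V[, 1L], 0), wh[1L])
      V[, 2L] <- pmin(pmax(V[, 2L], 0), wh[2L])
      parts <- if (repair) repair_polygon(polygon_shape(V, sh$class_label))
               else list(polygon_shape(V, sh$class_label))
      cleaned <- c(cleaned, parts)
    }
    out[[length(out) + 1L]] <-
      annotated_image(img_id, wh[1L], wh[2L], cleaned)
  }
  out
}

.parse_via_json <- function(path) {
  js <- tryCatch(jsonlite::read_json(path),
                 error = function(e) stop("unreadable annotation JSON '",
                                          path, "': ", conditionMessage(e)))
  if (!is.null(js[["_via_img_metadata"]])) js <- js[["_via_img_metadata"]]
  out <- list()
  for (k in names(js)) {
    rec <- js[[k]]
    if (is.null(rec$filename)) next
    regions <- rec$regions
    if (!is.null(regions) && !is.null(regions$shape_attributes))
      regions <- list(regions)  # single-region edge case
    out[[rec$filename]] <- list(regions = regions,
                                width = rec$width, height = rec$height)
  }
  out
}

.parse_via_csv <- function(path) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("filename", "region_shape_attributes", "region_attributes")
  if (!all(need %in% names(tb)))
    stop("annotation CSV '", path, "' lacks required columns: ",
         paste(setdiff(need, names(tb)), collapse = ", "))
  out <- list()
  for (i in seq_len(nrow(tb))) {
    fn <- tb$filename[i]
    sa <- tryCatch(jsonlite::fromJSON(tb$region_shape_attributes[i]),
                   error = function(e)
                     stop("unparseable region_shape_attributes in row ", i,
                          " of '", path, "'"))
    ra <- tryCatch(jsonlite::fromJSON(tb$region_attributes[i]),
                   error = function(e) list())
    if (is.null(out[[fn]])) out[[fn]] <- list(regions = list())
    if (length(sa))
      out[[fn]]$regions[[length(out[[fn]]$regions) + 1L]] <-
        list(shape_attributes = as.list(sa), region_attributes = as.list(ra))
  }
  out
}

#' Write annotated images as a VIA JSON export
#'
#' @param images list of [annotated_image()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(images, path) {
  js <- list()
  for (img in images) {
    regions <- lapply(img$shapes, function(sh) list(
      shape_attributes = list(
        name = "polygon",
        all_points_x = as.numeric(sh$vertices[, 1L]),
        all_points_y = as.numeric(sh$vertices[, 2L])),
      region_attributes = list(class = sh$class_label)))
    js[[img$image_id]] <- list(filename = img$image_id, size = -1L,
                               width = img$width, height = img$height,
                               regions = regions)
  }
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Per-image polygon summary table
#'
#' @param images list of [annotated_image()] objects.
#' @param path optional path; when given the table is written tab-delimited.
#' @return data.frame with one row per polygon: image id, class, vertex
#'   count, shoelace area.
#' @export
polygon_summary <- function(images, path = NULL) {
  rows <- list()
  for (img in images) for (sh in img$shapes)
    rows[[length(rows) + 1L]] <- data.frame(
      image_id = img$image_id, class_label = sh$class_label,
      n_vertices = nrow(sh$vertices), area = polygon_area(sh$vertices),
      stringsAsFactors = FALSE)
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(image_id = character(0), class_label = character(0),
               n_vertices = integer(0), area = numeric(0))
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' Deterministic train/validation/test split
#'
#' Seeded random partition of ids at a fixed ratio (default 8:1:1).
#'
#' @param ids character vector of image ids.
#' @param ratio three non-negative weights for train/validation/test.
#' @param seed integer seed.
#' @return list with elements `train`, `validation`, `test`.
#' @export
split_train_val_test <- function(ids, ratio = c(8, 1, 1), seed = 1L) {
  stopifnot(length(ratio) == 3L, all(ratio >= 0), sum(ratio) > 0)
  n <- length(ids)
  perm <- with_seed(seed, sample.int(n))
  cum <- cumsum(ratio) / sum(ratio)
  n_train <- round(cum[1L] * n)
  n_val <- round(cum[2L] * n) - n_train
  list(train = ids[perm[seq_len(n_train)]],
       validation = ids[perm[n_train + seq_len(n_val)]],
       test = ids[perm[setdiff(seq_len(n), seq_len(n_train + n_val))]])
}
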