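#' Read a 3D volume from NIfTI or MetaImage
#'
#' Recognized by extension: NIfTI (`.nii`, `.nii.gz`) through \pkg{RNifti}
#' (any rescale slope/intercept present in the header is applied), MetaImage
#' (`.mha`, `.mhd`) through the package's own reader. Spacing and origin are
#' populated from the header; volumes are treated as axis aligned.
#'
#' @param path Input file.
#' @return An [image_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  ext <- volume_format(path)
  if (ext == "nifti") {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    if (length(dim(arr)) != 3L) {
      stop("format error: expected a 3D NIfTI volume, got ",
           length(dim(arr)), " dimensions", call. = FALSE)
    }
    xf <- RNifti::xform(img)
    spacing <- sqrt(colSums(xf[1:3, 1:3]^2))
    origin <- xf[1:3, 4]
    # our files are written axis aligned with positive orientation; accept
    # axis-aligned negative orientations by absolute spacing
    image_volume(arr, spacing = abs(spacing), origin = origin)
  } else {
    read_metaimage(path)
  }
}

#' Write a 3D volume to NIfTI or MetaImage
#'
#' @param volume An [image_volume()].
#' @param path Output file (`.nii`, `.nii.gz`, `.mha` or `.mhd`).
#' @param datatype Storage type: `"float"` (default), `"double"`, `"uint8"`
#'   or `"int16"`.
#' @return The path, invisibly.
#' @export
write_volume <- function(volume, path, datatype = "float") {
  stopifnot(inherits(volume, "image_volume"))
  ext <- volume_format(path)
  if (ext == "nifti") {
    arr <- volume$values
    attr(arr, "pixdim") <- volume$spacing
    img <- RNifti::asNifti(arr, datatype = datatype)
    xf <- diag(4)
    diag(xf)[1:3] <- volume$spacing
    xf[1:3, 4] <- volume$origin
    RNifti::qform(img) <- structure(xf, code = 2L)
    RNifti::writeNifti(img, path)
  } else {
    write_metaimage(volume, path, datatype = datatype)
  }
  invisible(path)
}

#' Read or write a binary segmentation mask
#'
#' Masks are stored as uint8 volumes (0/1) in NIfTI or MetaImage; any
#' non-zero voxel counts as foreground when reading.
#'
#' @param mask A [segmentation_mask()].
#' @param path File path (`.nii`, `.nii.gz`, `.mha`, `.mhd`).
#' @return `write_mask` the path invisibly; `read_mask` a
#'   [segmentation_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "segmentation_mask"))
  vol <- image_volume(array(as.numeric(mask$grid), dim = dim(mask$grid)),
                      spacing = mask$spacing, origin = mask$origin)
  write_volume(vol, path, datatype = "uint8")
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  vol <- read_volume(path)
  segmentation_mask(vol$values != 0, spacing = vol$spacing,
                    origin = vol$origin)
}

volume_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  if (grepl("\\.mha$", low) || grepl("\\.mhd$", low)) return("metaimage")
  stop("unknown format: '", path,
       "' (supported: .nii, .nii.gz, .mha, .mhd)", call. = FALSE)
}

# --- MetaImage (.mha local data / .mhd + .raw) ------------------------------

meta_types <- c(float = "MET_FLOAT", double = "MET_DOUBLE",
                uint8 = "MET_UCHAR", int16 = "MET_SHORT")
meta_sizes <- c(MET_FLOAT = 4L, MET_DOUBLE = 8L, MET_UCHAR = 1L,
                MET_SHORT = 2L)

write_metaimage <- function(volume, path, datatype = "float") {
  if (!datatype %in% names(meta_types)) {
    stop("unsupported MetaImage datatype: ", datatype, call. = FALSE)
  }
  mtype <- meta_types[[datatype]]
  d <- dim(volume$values)
  local_data <- grepl("\\.mha$", tolower(path))
  raw_name <- paste0(sub("\\.mhd$", "", basename(path)), ".raw")
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %.17g %.17g %.17g",
            volume$spacing[1], volume$spacing[2], volume$spacing[3]),
    sprintf("Offset = %.17g %.17g %.17g",
            volume$origin[1], volume$origin[2], volume$origin[3]),
    sprintf("ElementType = %s", mtype),
    sprintf("ElementDataFile = %s", if (local_data) "LOCAL" else raw_name))
  vals <- as.vector(volume$values)
  write_payload <- function(con) {
    if (mtype %in% c("MET_FLOAT", "MET_DOUBLE")) {
      writeBin(as.double(vals), con, size = meta_sizes[[mtype]],
               endian = "little")
    } else {
      writeBin(as.integer(round(vals)), con, size = meta_sizes[[mtype]],
               endian = "little")
    }
  }
  if (local_data) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con)
    write_payload(con)
  } else {
    writeLines(header, path)
    con <- file(file.path(dirname(path), raw_name), "wb")
    on.exit(close(con))
    write_payload(con)
  }
  invisible(path)
}

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) {
      stop("format error: MetaImage header ended before ElementDataFile",
           call. = FALSE)
    }
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) {
      stop("format error: malformed MetaImage header line: '", line, "'",
           call. = FALSE)
    }
    key <- trimws(kv[1]); val <- trimws(kv[2])
    fields[[key]] <- val
    if (key == "ElementDataFile") break
  }
  required <- c("DimSize", "ElementType", "ElementDataFile")
  for (f in required) {
    if (is.null(fields[[f]])) {
      stop("format error: MetaImage header missing field '", f, "'",
           call. = FALSE)
    }
  }
  d <- as.integer(strsplit(fields$DimSize, "\\s+")[[1]])
  if (length(d) != 3L || any(is.na(d))) {
    stop("format error: bad DimSize '", fields$DimSize, "'", call. = FALSE)
  }
  spacing <- if (is.null(fields$ElementSpacing)) c(1, 1, 1) else
    as.numeric(strsplit(fields$ElementSpacing, "\\s+")[[1]])
  origin <- if (is.null(fields$Offset)) c(0, 0, 0) else
    as.numeric(strsplit(fields$Offset, "\\s+")[[1]])
  mtype <- fields$ElementType
  if (!mtype %in% names(meta_sizes)) {
    stop("format error: unsupported ElementType '", mtype, "'",
         call. = FALSE)
  }
  if (!is.null(fields$BinaryDataByteOrderMSB) &&
      tolower(fields$BinaryDataByteOrderMSB) == "true") {
    stop("format error: big-endian MetaImage data is not supported",
         call. = FALSE)
  }
  n <- prod(d)
  if (identical(fields$ElementDataFile, "LOCAL")) {
    payload_con <- con
  } else {
    payload_con <- file(file.path(dirname(path), fields$ElementDataFile), "rb")
    on.exit(close(payload_con), add = TRUE)
  }
  vals <- if (mtype %in% c("MET_FLOAT", "MET_DOUBLE")) {
    readBin(payload_con, "double", n = n, size = meta_sizes[[mtype]],
            endian = "little")
  } else {
    readBin(payload_con, "integer", n = n, size = meta_sizes[[mtype]],
            signed = mtype != "MET_UCHAR", endian = "little")
  }
  if (length(vals) != n) {
    stop("format error: MetaImage payload truncated (expected ", n,
         " voxels, read ", length(vals), ")", call. = FALSE)
  }
  image_volume(array(vals, dim = d), spacing = spacing, origin = origin)
}

# --- mesh export ------------------------------------------------------------

#' Write a triangle mesh to OBJ, PLY or STL
#'
#' Plain-text formats, recognized by extension.
#'
#' @param mesh A `triangle_mesh`.
#' @param path Output file (`.obj`, `.ply` or `.stl`).
#' @return The path, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  low <- tolower(path)
  if (grepl("\\.obj$", low)) {
    lines <- c(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]))
  } else if (grepl("\\.ply$", low)) {
    lines <- c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header",
               sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
               sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L))
  } else if (grepl("\\.stl$", low)) {
    a <- v[f[, 1], , drop = FALSE]
    b <- v[f[, 2], , drop = FALSE]
    cc <- v[f[, 3], , drop = FALSE]
    u <- b - a; w <- cc - a
    nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                 u[, 3] * w[, 1] - u[, 1] * w[, 3],
                 u[, 1] * w[, 2] - u[, 2] * w[, 1])
    len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
    nrm <- nrm / len
    lines <- c("solid mesh",
               as.vector(rbind(
                 sprintf("facet normal %.9g %.9g %.9g",
                         nrm[, 1], nrm[, 2], nrm[, 3]),
                 "  outer loop",
                 sprintf("    vertex %.9g %.9g %.9g", a[, 1], a[, 2], a[, 3]),
                 sprintf("    vertex %.9g %.9g %.9g", b[, 1], b[, 2], b[, 3]),
                 sprintf("    vertex %.9g %.9g %.9g",
                         cc[, 1], cc[, 2], cc[, 3]),
                 "  endloop",
                 "endfacet")),
               "endsolid mesh")
  } else {
    stop("unknown mesh format: '", path,
         "' (supported: .obj, .ply, .stl)", call. = FALSE)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a triangle mesh from OBJ
#'
#' Minimal reader for the meshes this package writes (`v`/`f` lines,
#' triangular faces).
#'
#' @param path An `.obj` file.
#' @return A `triangle_mesh`.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x)
    as.numeric(x[2:4])))
  f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x)
    as.integer(sub("/.*", "", x[2:4]))))
  triangle_mesh(v, f)
}

# --- contour JSON -----------------------------------------------------------

#' Read manual slice contours from JSON
#'
#' The contour dialect is a JSON object
#' `{"contours": [{"slice": k, "frame": "pixel", "points": [[x, y], ...]},
#' ...]}` with 1-based slice indices, closed polygons (first point repeated
#' last) and 0-based pixel coordinates (or world mm with
#' `"frame": "world"`).
#'
#' @param path JSON file.
#' @return A list of contours suitable for [voxelize_contours()].
#' @export
read_contours <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$contours)) {
    stop("contour-format error: top-level 'contours' array missing",
         call. = FALSE)
  }
  raw <- doc$contours
  if (is.data.frame(raw)) {
    raw <- lapply(seq_len(nrow(raw)), function(i) as.list(raw[i, ]))
  }
  lapply(raw, function(cnt) {
    pts <- cnt$points
    if (is.list(pts) && !is.matrix(pts)) pts <- do.call(rbind, pts)
    if (is.list(pts)) pts <- pts[[1]]
    list(slice = cnt$slice, points = as.matrix(pts),
         frame = if (is.null(cnt$frame)) "pixel" else cnt$frame)
  })
}
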