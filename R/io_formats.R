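# File formats: NIfTI-1 (.nii/.nii.gz) and MetaImage (.mha/.mhd+.raw) for
# images, masks and 3-component displacement fields; OBJ and PLY (ascii)
# for meshes.  Only axis-aligned geometries are represented (direction
# cosines beyond axis permutation/flip are out of scope); all world
# coordinates are mm.

nifti_datatypes <- c(`2` = "uint8", `4` = "int16", `8` = "int32",
                     `16` = "float32", `64` = "float64")

open_conn <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

# write a NIfTI-1 header + data; `arr` is dims nx,ny,nz or c(nx,ny,nz,3)
# (vector field, stored as dim[0]=5 with dim[5]=3, intent VECTOR)
write_nifti_raw <- function(arr, spacing, origin, path) {
  d <- dim(arr)
  is_vec <- length(d) == 4L
  con <- open_conn(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  wc <- function(n) writeBin(raw(n), con)
  wi(348L, 4)                      # sizeof_hdr
  wc(35)                           # data_type..regular
  wc(1)                            # dim_info
  dimv <- if (is_vec) c(5L, d[1:3], 1L, 3L, 1L, 1L) else
    c(3L, d[1:3], 1L, 1L, 1L, 1L)
  wi(dimv, 2)                      # dim[8]
  wf(c(0, 0, 0))                   # intent_p1..3
  wi(if (is_vec) 1007L else 0L, 2) # intent_code (NIFTI_INTENT_VECTOR)
  wi(16L, 2)                       # datatype float32
  wi(32L, 2)                       # bitpix
  wi(0L, 2)                        # slice_start
  wf(c(1, spacing, 1, 1, 1, 1))    # pixdim[8] (qfac = 1)
  wf(352)                          # vox_offset
  wf(1); wf(0)                     # scl_slope, scl_inter
  wi(0L, 2); wc(1)                 # slice_end, slice_code
  writeBin(as.raw(2L), con)        # xyzt_units: mm
  wf(c(0, 0, 0, 0))                # cal_max, cal_min, slice_dur, toffset
  wi(c(0L, 0L), 4)                 # glmax, glmin
  wc(80); wc(24)                   # descrip, aux_file
  wi(0L, 2); wi(2L, 2)             # qform_code, sform_code
  wf(c(0, 0, 0, 0, 0, 0))          # quatern b,c,d + qoffset x,y,z
  wf(c(spacing[1], 0, 0, origin[1]))   # srow_x
  wf(c(0, spacing[2], 0, origin[2]))   # srow_y
  wf(c(0, 0, spacing[3], origin[3]))   # srow_z
  wc(16)                           # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  wc(4)                            # extension flag
  writeBin(as.numeric(arr), con, size = 4L, endian = "little")
  invisible(path)
}

read_nifti_raw <- function(path) {
  con <- open_conn(path, "rb")
  on.exit(close(con))
  ri <- function(n, size) readBin(con, "integer", n = n, size = size,
                                  endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4L,
                            endian = "little")
  hdr_size <- ri(1, 4)
  if (!identical(hdr_size, 348L)) stop("not a little-endian NIfTI-1 file")
  readBin(con, "raw", 36)
  dimv <- ri(8, 2)
  rf(3); ri(1, 2)
  datatype <- ri(1, 2)
  ri(1, 2); ri(1, 2)
  pixdim <- rf(8)
  vox_offset <- rf(1)
  scl_slope <- rf(1); scl_inter <- rf(1)
  ri(1, 2); readBin(con, "raw", 2)
  rf(4); ri(2, 4)
  readBin(con, "raw", 104)
  qform <- ri(1, 2); sform <- ri(1, 2)
  rf(6)
  srow <- matrix(rf(12), 3, 4, byrow = TRUE)
  readBin(con, "raw", 20)
  type <- nifti_datatypes[as.character(datatype)]
  if (is.na(type)) stop("unsupported NIfTI datatype ", datatype)
  seek(con, vox_offset)
  ndim <- dimv[1]
  dims <- dimv[2:(1 + ndim)]
  n <- prod(dims)
  dat <- switch(type,
    uint8 = as.numeric(readBin(con, "integer", n, size = 1L, signed = FALSE)),
    int16 = as.numeric(readBin(con, "integer", n, size = 2L,
                               endian = "little")),
    int32 = as.numeric(readBin(con, "integer", n, size = 4L,
                               endian = "little")),
    float32 = readBin(con, "numeric", n, size = 4L, endian = "little"),
    float64 = readBin(con, "numeric", n, size = 8L, endian = "little"))
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    dat <- dat * scl_slope + scl_inter
  spacing <- pixdim[2:4]
  origin <- c(0, 0, 0)
  if (sform > 0) {
    if (max(abs(srow[, 1:3] - diag(spacing))) > 1e-4 * max(spacing))
      warning("oblique/rotated sform not supported; using spacing + offset only")
    origin <- srow[, 4]
  }
  list(data = dat, dims = dims, spacing = spacing, origin = origin)
}

# ---- MetaImage -------------------------------------------------------------

met_types <- c(MET_UCHAR = "uint8", MET_SHORT = "int16", MET_INT = "int32",
               MET_FLOAT = "float32", MET_DOUBLE = "float64")

write_metaimage_raw <- function(arr, spacing, origin, path) {
  d <- dim(arr)
  is_vec <- length(d) == 4L
  if (is_vec) arr <- aperm(arr, c(4, 1, 2, 3))  # channels fastest
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
           sprintf("ElementSpacing = %s", paste(spacing, collapse = " ")),
           sprintf("Offset = %s", paste(origin, collapse = " ")),
           sprintf("ElementNumberOfChannels = %d", if (is_vec) 3L else 1L),
           "ElementType = MET_FLOAT")
  if (grepl("\\.mha$", path)) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c(hdr, "ElementDataFile = LOCAL"), con)
    writeBin(as.numeric(arr), con, size = 4L, endian = "little")
  } else if (grepl("\\.mhd$", path)) {
    rawname <- sub("\\.mhd$", ".raw", basename(path))
    writeLines(c(hdr, paste("ElementDataFile =", rawname)), path)
    con <- file(file.path(dirname(path), rawname), "wb")
    on.exit(close(con))
    writeBin(as.numeric(arr), con, size = 4L, endian = "little")
  } else stop("MetaImage path must end in .mha or .mhd")
  invisible(path)
}

read_metaimage_raw <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  nl <- which(bytes == as.raw(10L))
  hdr_lines <- character(0)
  pos <- 1L
  data_start <- NA_integer_
  for (e in nl) {
    line <- rawToChar(bytes[pos:(e - 1L)])
    line <- sub("\r$", "", line)
    hdr_lines <- c(hdr_lines, line)
    pos <- e + 1L
    if (grepl("^ElementDataFile", line)) { data_start <- pos; break }
  }
  kv <- strsplit(hdr_lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " "), "")
  getv <- function(k, default = NA) if (k %in% keys) vals[match(k, keys)]
    else default
  dims <- as.integer(strsplit(getv("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(getv("ElementSpacing", "1 1 1"), "\\s+")[[1]])
  origin_s <- getv("Offset", getv("Origin", getv("Position", "0 0 0")))
  origin <- as.numeric(strsplit(origin_s, "\\s+")[[1]])
  channels <- as.integer(getv("ElementNumberOfChannels", "1"))
  type <- met_types[getv("ElementType", "MET_FLOAT")]
  if (is.na(type)) stop("unsupported MetaImage ElementType")
  datafile <- vals[match("ElementDataFile", keys)]
  n <- prod(dims) * channels
  size <- switch(type, uint8 = 1L, int16 = 2L, int32 = 4L,
                 float32 = 4L, float64 = 8L)
  if (identical(datafile, "LOCAL")) {
    payload <- bytes[data_start:length(bytes)]
  } else {
    payload <- readBin(file.path(dirname(path), datafile), "raw",
                       n * size)
  }
  dat <- readBin(payload, switch(type, uint8 = "integer", int16 = "integer",
                                 int32 = "integer", "numeric"),
                 n = n, size = size, endian = "little",
                 signed = !identical(type, "uint8"))
  dat <- as.numeric(dat)
  if (channels == 3L) {
    arr <- array(dat, c(3L, dims))
    dat <- as.numeric(aperm(arr, c(2, 3, 4, 1)))
    dims <- c(dims, 3L)
  }
  list(data = dat, dims = dims, spacing = spacing, origin = origin)
}

# ---- public interface ------------------------------------------------------

is_metaimage <- function(path) grepl("\\.(mha|mhd)$", path)

#' Read / write images, masks and displacement fields
#'
#' Formats are selected by extension: `.nii` / `.nii.gz` (NIfTI-1) or
#' `.mha` / `.mhd` (MetaImage).  Fields are stored as 3-component volumes
#' (NIfTI 5-D vector intent / MetaImage 3-channel).
#'
#' @param image,mask,field,path objects and file path.
#' @name dirprop_io
#' @export
write_image <- function(image, path) {
  if (is_metaimage(path))
    write_metaimage_raw(image$values, image$grid$spacing,
                        image$grid$origin, path)
  else write_nifti_raw(image$values, image$grid$spacing,
                       image$grid$origin, path)
}

#' @rdname dirprop_io
#' @export
read_image <- function(path) {
  r <- if (is_metaimage(path)) read_metaimage_raw(path)
       else read_nifti_raw(path)
  if (length(r$dims) != 3L) stop("expected a 3-D scalar volume")
  scalar_image(array(r$data, r$dims),
               image_grid(r$dims, r$spacing, r$origin))
}

#' @rdname dirprop_io
#' @export
write_mask <- function(mask, path) {
  if (is_metaimage(path))
    write_metaimage_raw(mask$labels + 0, mask$grid$spacing,
                        mask$grid$origin, path)
  else write_nifti_raw(mask$labels + 0, mask$grid$spacing,
                       mask$grid$origin, path)
}

#' @rdname dirprop_io
#' @param name ROI name to attach on read.
#' @export
read_mask <- function(path, name = "ROI") {
  img <- read_image(path)
  roi_mask(array(as.integer(img$values >= 0.5), img$grid$dims), img$grid,
           name)
}

#' @rdname dirprop_io
#' @export
write_field <- function(field, path) {
  if (is_metaimage(path))
    write_metaimage_raw(field$vectors, field$grid$spacing,
                        field$grid$origin, path)
  else write_nifti_raw(field$vectors, field$grid$spacing,
                       field$grid$origin, path)
}

#' @rdname dirprop_io
#' @export
read_field <- function(path) {
  r <- if (is_metaimage(path)) read_metaimage_raw(path)
       else read_nifti_raw(path)
  dims <- r$dims
  if (length(dims) == 5L && dims[4] == 1L) dims <- dims[c(1:3, 5)]
  if (length(dims) != 4L || dims[4] != 3L)
    stop("expected a 3-component vector volume")
  displacement_field(array(r$data, dims),
                     image_grid(dims[1:3], r$spacing, r$origin))
}

# ---- meshes ----------------------------------------------------------------

#' Read / write triangle meshes (OBJ or ascii PLY, world mm)
#'
#' @param mesh a `contour_mesh`; `path` selects the format by extension.
#' @param path file path ending in .obj or .ply.
#' @name mesh_io
#' @export
write_mesh <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  if (grepl("\\.obj$", path)) {
    lines <- c(sprintf("v %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]))
    writeLines(lines, path)
  } else if (grepl("\\.ply$", path)) {
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(v)),
             "property float x", "property float y", "property float z",
             sprintf("element face %d", nrow(f)),
             "property list uchar int vertex_indices", "end_header")
    lines <- c(hdr, sprintf("%.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]),
               sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L))
    writeLines(lines, path)
  } else stop("mesh path must end in .obj or .ply")
  invisible(path)
}

#' @rdname mesh_io
#' @param frame frame tag for the mesh on read.
#' @export
read_mesh <- function(path, frame = "moving") {
  lines <- readLines(path)
  if (grepl("\\.obj$", path)) {
    vl <- lines[startsWith(lines, "v ")]
    fl <- lines[startsWith(lines, "f ")]
    v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x)
      as.numeric(x[2:4])))
    f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x)
      as.integer(sub("/.*", "", x[2:4]))))
  } else if (grepl("\\.ply$", path)) {
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", lines, value = TRUE)))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face", lines, value = TRUE)))
    at <- which(lines == "end_header")
    v <- do.call(rbind, lapply(strsplit(trimws(lines[at + seq_len(nv)]),
                                        "\\s+"),
                               function(x) as.numeric(x[1:3])))
    f <- do.call(rbind, lapply(strsplit(trimws(lines[at + nv + seq_len(nf)]),
                                        "\\s+"),
                               function(x) as.integer(x[2:4]) + 1L))
  } else stop("mesh path must end in .obj or .ply")
  contour_mesh(v, f, frame = frame)
}
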