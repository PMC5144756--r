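#' Read streamlines from VTK polydata or TrackVis files
#'
#' Supported formats: VTK legacy ASCII polydata (`.vtk`), VTK XML polydata
#' (`.vtp`, ascii-encoded arrays) and TrackVis (`.trk`).  All coordinates
#' are returned in world RAS millimetres.  TrackVis streamlines are stored
#' in "voxmm" (voxel indices scaled by voxel size); they are divided by the
#' header voxel size and mapped through the header `vox_to_ras` affine, so a
#' point at voxel (0,0,0) lands on the affine's translation column.  A TRK
#' header without a valid affine (all zeros, as written by old tools) falls
#' back to interpreting voxmm as world mm, with a message.
#'
#' @param path file to read.
#' @param format one of `"auto"` (from the file extension), `"vtk"`,
#'   `"vtp"`, `"trk"`.
#' @return A [tractogram] in `"subject"` frame.  If the file carries a
#'   per-line integer array named `"ClusterId"`, it is attached as
#'   attribute `"labels"`.
#' @seealso [write_tractogram()]
#' @export
read_tractogram <- function(path, format = c("auto", "vtk", "vtp", "trk")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- guess_format(path)
  out <- switch(format,
    vtk = read_vtk_polydata(path),
    vtp = read_vtp_polydata(path),
    trk = read_trk(path),
    stop("unsupported tractogram format: ", format))
  if (length(out$fibers) == 0L)
    warning("no streamlines found in ", path)
  out
}

#' Write streamlines to VTK polydata or TrackVis files
#'
#' Per-fiber integer labels are stored as a per-line (cell) integer array
#' named `"ClusterId"` in polydata outputs, and as a single per-track
#' property in TrackVis outputs.
#'
#' @param tractogram a [tractogram].
#' @param path output file.
#' @param format `"auto"`, `"vtk"`, `"vtp"` or `"trk"`.
#' @param labels optional integer vector, one label per fiber.
#' @return `path`, invisibly.
#' @export
write_tractogram <- function(tractogram, path, format = c("auto", "vtk", "vtp", "trk"),
                             labels = NULL) {
  stopifnot(inherits(tractogram, "tractogram"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != length(tractogram$fibers))
      stop("labels must have one entry per fiber")
  }
  switch(format,
    vtk = write_vtk_polydata(tractogram, path, labels),
    vtp = write_vtp_polydata(tractogram, path, labels),
    trk = write_trk(tractogram, path, labels),
    stop("unsupported tractogram format: ", format))
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("vtk", "vtp", "trk")) ext
  else stop("cannot infer tractogram format from extension '.", ext, "'")
}

num_fmt <- function(x) formatC(x, format = "g", digits = 9)

## ---- VTK legacy ASCII polydata ----

write_vtk_polydata <- function(tg, path, labels = NULL) {
  fibers <- tg$fibers
  npts <- vapply(fibers, nrow, integer(1))
  n <- sum(npts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "tractatlas streamlines", "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", n)), con)
  if (n > 0) {
    pts <- do.call(rbind, fibers)
    writeLines(paste(num_fmt(pts[, 1]), num_fmt(pts[, 2]), num_fmt(pts[, 3])), con)
  }
  writeLines(sprintf("LINES %d %d", length(fibers), length(fibers) + n), con)
  if (length(fibers)) {
    offs <- cumsum(c(0L, npts[-length(npts)]))
    conn <- mapply(function(np, o) paste(c(np, seq.int(o, length.out = np)), collapse = " "),
                   npts, offs)
    writeLines(conn, con)
  }
  if (!is.null(labels) && length(labels)) {
    writeLines(c(sprintf("CELL_DATA %d", length(labels)),
                 "SCALARS ClusterId int 1", "LOOKUP_TABLE default",
                 paste(labels, collapse = " ")), con)
  }
}

read_vtk_polydata <- function(path) {
  first <- readLines(path, n = 4L, warn = FALSE)
  if (!length(first) || !grepl("^# vtk DataFile", first[1]))
    stop("not a VTK legacy file: ", path)
  if (any(grepl("^BINARY", first)))
    stop("binary VTK legacy files are not supported; use ASCII or .vtp")
  tok <- scan(path, what = "character", quiet = TRUE, skip = 2L)
  if (!any(tok == "POLYDATA")) stop("VTK file is not DATASET POLYDATA: ", path)
  ip <- match("POINTS", tok)
  fibers <- list()
  labels <- NULL
  pts <- NULL
  if (!is.na(ip)) {
    n <- as.integer(tok[ip + 1L])
    vals <- as.numeric(tok[seq.int(ip + 3L, length.out = 3L * n)])
    pts <- matrix(vals, ncol = 3L, byrow = TRUE)
  }
  il <- match("LINES", tok)
  if (!is.na(il) && !is.null(pts)) {
    m <- as.integer(tok[il + 1L])
    sz <- as.integer(tok[il + 2L])
    conn <- as.numeric(tok[seq.int(il + 3L, length.out = sz)])
    pos <- 1L
    fibers <- vector("list", m)
    for (i in seq_len(m)) {
      np <- as.integer(conn[pos])
      idx <- as.integer(conn[seq.int(pos + 1L, length.out = np)]) + 1L
      fibers[[i]] <- pts[idx, , drop = FALSE]
      pos <- pos + np + 1L
    }
  }
  ic <- which(tok == "ClusterId")
  if (length(ic)) {
    ic <- ic[1]
    # SCALARS <name> <type> [components]; values follow LOOKUP_TABLE <name>
    iv <- ic + which(tok[seq.int(ic, length.out = 8L)] == "LOOKUP_TABLE")[1] + 1L
    labels <- as.integer(tok[seq.int(iv, length.out = length(fibers))])
  }
  tg <- tractogram(fibers, subject_id = "", frame = "subject")
  if (!is.null(labels)) attr(tg, "labels") <- labels
  tg
}

## ---- VTK XML polydata (.vtp, ascii arrays) ----

write_vtp_polydata <- function(tg, path, labels = NULL) {
  fibers <- tg$fibers
  npts <- vapply(fibers, nrow, integer(1))
  n <- sum(npts)
  pts_txt <- if (n > 0) {
    pts <- do.call(rbind, fibers)
    paste(num_fmt(t(pts)), collapse = " ")
  } else ""
  conn_txt <- if (n > 0) paste(seq_len(n) - 1L, collapse = " ") else ""
  offs_txt <- if (length(npts)) paste(cumsum(npts), collapse = " ") else ""
  cell_data <- if (!is.null(labels) && length(labels))
    sprintf('   <CellData Scalars="ClusterId">\n    <DataArray type="Int32" Name="ClusterId" format="ascii">%s</DataArray>\n   </CellData>\n',
            paste(labels, collapse = " ")) else ""
  xml <- sprintf(
'<?xml version="1.0"?>
<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">
 <PolyData>
  <Piece NumberOfPoints="%d" NumberOfVerts="0" NumberOfLines="%d" NumberOfStrips="0" NumberOfPolys="0">
   <Points>
    <DataArray type="Float64" NumberOfComponents="3" format="ascii">%s</DataArray>
   </Points>
   <Lines>
    <DataArray type="Int64" Name="connectivity" format="ascii">%s</DataArray>
    <DataArray type="Int64" Name="offsets" format="ascii">%s</DataArray>
   </Lines>
%s  </Piece>
 </PolyData>
</VTKFile>', n, length(fibers), pts_txt, conn_txt, offs_txt, cell_data)
  writeLines(xml, path)
}

parse_numeric_text <- function(txt) {
  as.numeric(strsplit(trimws(txt), "[[:space:]]+")[[1]])
}

read_vtp_polydata <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  if (inherits(piece, "xml_missing")) stop("no <Piece> element in ", path)
  pts_node <- xml2::xml_find_first(piece, ".//Points/DataArray")
  conn_node <- xml2::xml_find_first(piece, ".//Lines/DataArray[@Name='connectivity']")
  offs_node <- xml2::xml_find_first(piece, ".//Lines/DataArray[@Name='offsets']")
  n_lines <- as.integer(xml2::xml_attr(piece, "NumberOfLines"))
  fibers <- list()
  if (!is.na(n_lines) && n_lines > 0) {
    pts <- matrix(parse_numeric_text(xml2::xml_text(pts_node)), ncol = 3L, byrow = TRUE)
    conn <- as.integer(parse_numeric_text(xml2::xml_text(conn_node)))
    offs <- as.integer(parse_numeric_text(xml2::xml_text(offs_node)))
    starts <- c(0L, offs[-length(offs)])
    fibers <- lapply(seq_along(offs), function(i) {
      idx <- conn[seq.int(starts[i] + 1L, offs[i])] + 1L
      pts[idx, , drop = FALSE]
    })
  }
  lab_node <- xml2::xml_find_first(piece, ".//CellData/DataArray[@Name='ClusterId']")
  tg <- tractogram(fibers, subject_id = "", frame = "subject")
  if (!inherits(lab_node, "xml_missing"))
    attr(tg, "labels") <- as.integer(parse_numeric_text(xml2::xml_text(lab_node)))
  tg
}

## ---- TrackVis .trk (binary, little-endian, header version 2) ----

write_trk <- function(tg, path, labels = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  voxel_size <- c(1, 1, 1)
  affine <- diag(4)  # world == voxmm under unit voxels + identity affine
  suppressWarnings(writeChar("TRACK", con, nchars = 6, eos = NULL))  # zero-padded to 6
  seek(con, 6)
  writeBin(as.integer(c(1L, 1L, 1L)), con, size = 2, endian = "little")     # dim
  writeBin(as.numeric(voxel_size), con, size = 4, endian = "little")        # voxel_size
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4, endian = "little")        # origin
  n_props <- if (is.null(labels)) 0L else 1L
  writeBin(0L, con, size = 2, endian = "little")                            # n_scalars
  writeBin(raw(200), con)                                                   # scalar names
  writeBin(n_props, con, size = 2, endian = "little")                       # n_properties
  prop_names <- raw(200)
  if (n_props == 1L) {
    nm <- charToRaw("ClusterId")
    prop_names[seq_along(nm)] <- nm
  }
  writeBin(prop_names, con)
  writeBin(as.numeric(t(affine)), con, size = 4, endian = "little")         # vox_to_ras
  writeBin(raw(444), con)                                                   # reserved
  suppressWarnings(writeChar("RAS", con, nchars = 4, eos = NULL))
  seek(con, 952)
  writeBin(raw(36), con)                                                    # pads + IOP + flags
  writeBin(length(tg$fibers), con, size = 4, endian = "little")             # n_count
  writeBin(2L, con, size = 4, endian = "little")                            # version
  writeBin(1000L, con, size = 4, endian = "little")                         # hdr_size
  for (i in seq_along(tg$fibers)) {
    f <- tg$fibers[[i]]
    writeBin(nrow(f), con, size = 4, endian = "little")
    writeBin(as.numeric(t(f)), con, size = 4, endian = "little")
    if (n_props == 1L)
      writeBin(as.numeric(labels[i]), con, size = 4, endian = "little")
  }
}

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- suppressWarnings(readChar(con, 6, useBytes = TRUE))
  if (!startsWith(id, "TRACK")) stop("not a TrackVis .trk file: ", path)
  readBin(con, "integer", n = 3, size = 2, endian = "little")               # dim
  voxel_size <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  readBin(con, "numeric", n = 3, size = 4, endian = "little")               # origin
  n_scalars <- readBin(con, "integer", n = 1, size = 2, endian = "little")
  readBin(con, "raw", n = 200)
  n_props <- readBin(con, "integer", n = 1, size = 2, endian = "little")
  prop_names <- rawToChar(readBin(con, "raw", n = 200))
  affine <- matrix(readBin(con, "numeric", n = 16, size = 4, endian = "little"),
                   4, 4, byrow = TRUE)
  readBin(con, "raw", n = 444)
  readBin(con, "raw", n = 40)                                               # order..flags
  n_count <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  readBin(con, "integer", n = 1, size = 4, endian = "little")               # version
  hdr_size <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (hdr_size != 1000L)
    stop("unsupported .trk header (size ", hdr_size, "; big-endian files are not supported)")
  if (all(abs(affine) < .Machine$double.eps) || affine[4, 4] == 0) {
    message("trk header has no vox_to_ras affine; interpreting voxmm as world mm")
    affine <- diag(4)
    voxel_size <- c(1, 1, 1)
  }
  if (any(voxel_size <= 0)) {
    message("trk header has non-positive voxel sizes; assuming 1 mm voxels")
    voxel_size <- c(1, 1, 1)
  }
  fibers <- vector("list", max(n_count, 0L))
  labels <- if (grepl("ClusterId", prop_names) && n_props >= 1L)
    numeric(max(n_count, 0L)) else NULL
  i <- 0L
  repeat {
    np <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    if (length(np) == 0L) break
    i <- i + 1L
    vals <- readBin(con, "numeric", n = np * (3L + n_scalars), size = 4, endian = "little")
    voxmm <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    props <- readBin(con, "numeric", n = n_props, size = 4, endian = "little")
    vox <- sweep(voxmm, 2, voxel_size, "/")
    world <- cbind(vox, 1) %*% t(affine)
    fibers[[i]] <- world[, 1:3, drop = FALSE]
    if (!is.null(labels)) labels[i] <- props[1]
    if (n_count > 0L && i >= n_count) break
  }
  length(fibers) <- i
  tg <- tractogram(fibers, subject_id = "", frame = "subject")
  if (!is.null(labels) && i > 0L) attr(tg, "labels") <- as.integer(labels[seq_len(i)])
  tg
}

## ---- NIfTI masks ----

#' Read and write binary NIfTI masks
#'
#' `read_mask()` loads a 3-D NIfTI volume, binarizes it (value > 0 becomes
#' foreground) and attaches the NIfTI voxel-to-world affine.  4-D inputs are
#' rejected with a message asking for a single volume.
#'
#' @param path a `.nii` / `.nii.gz` file.
#' @return A [volume_mask].
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] > 1L)
    stop("4-D NIfTI input: select a single volume (e.g. img[,,,1]) before use")
  if (length(d) == 4L) img <- img[, , , 1]
  if (length(dim(img)) != 3L) stop("mask must be a 3-D volume")
  volume_mask(img > 0, RNifti::xform(img))
}

#' @rdname read_mask
#' @param mask a [volume_mask].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "volume_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$data), dim = dim(mask$data)))
  img <- RNifti::`sform<-`(img, structure(mask$voxel_to_world, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

## ---- JSON transform files ----

#' Read and write transforms as JSON
#'
#' Affines are stored as `{"type": "affine", "matrix": [16 numbers,
#' row-major]}`; b-spline displacement fields as `{"type": "bspline",
#' "grid_shape": [gx, gy, gz], "bounds": [xmin, xmax, ymin, ymax, zmin,
#' zmax], "displacements": [...]}` with displacements flattened in R array
#' order (first grid index fastest, vector component last).  Roundtrips are
#' lossless to full double precision.
#'
#' @param path JSON file.
#' @return A [linear_transform] or [grid_transform].
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$type)) stop("transform JSON is missing required field 'type'")
  if (identical(obj$type, "affine")) {
    if (is.null(obj$matrix)) stop("affine transform JSON is missing required field 'matrix'")
    linear_transform(matrix(as.numeric(obj$matrix), 4, 4, byrow = TRUE))
  } else if (identical(obj$type, "bspline")) {
    for (f in c("grid_shape", "bounds", "displacements"))
      if (is.null(obj[[f]])) stop("bspline transform JSON is missing required field '", f, "'")
    gs <- as.integer(obj$grid_shape)
    grid_transform(array(as.numeric(obj$displacements), dim = c(gs, 3L)),
                   as.numeric(obj$bounds))
  } else stop("unknown transform type: ", obj$type)
}

#' @rdname read_transform
#' @param transform a [linear_transform] or [grid_transform].
#' @export
write_transform <- function(transform, path) {
  obj <- if (inherits(transform, "linear_transform")) {
    list(type = "affine", matrix = as.numeric(t(transform$matrix)))
  } else if (inherits(transform, "grid_transform")) {
    list(type = "bspline",
         grid_shape = as.integer(transform$grid_shape),
         bounds = as.numeric(transform$domain_bounds),
         displacements = as.numeric(transform$control_displacements))
  } else stop("transform must be a linear_transform or grid_transform")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
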