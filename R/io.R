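#' Read a triangulated surface from PLY, OBJ or STL
#'
#' ASCII variants of the three formats are supported (binary files are
#' rejected with an informative error). The format is taken from the file
#' extension.
#'
#' @param path file path ending in `.ply`, `.obj` or `.stl`.
#' @param organ organ tag for the result.
#' @return a [Surface-class].
#' @export
readSurface <- function(path, organ = "generic") {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ply = readPLY(path, organ),
    obj = readOBJ(path, organ),
    stl = readSTL(path, organ),
    stop("unsupported mesh format: ", ext))
}

#' Write a surface to PLY, OBJ or STL (ASCII)
#'
#' @param surface a [Surface-class].
#' @param path output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
writeSurface <- function(surface, path) {
  stopifnot(is(surface, "Surface"))
  ext <- tolower(tools::file_ext(path))
  v <- surface@vertices
  f <- surface@faces
  con <- file(path, "w")
  on.exit(close(con))
  if (ext == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(v)),
                 "property float x", "property float y", "property float z",
                 paste("element face", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(apply(v, 1, paste, collapse = " "), con)
    writeLines(paste(3, f[, 1] - 1, f[, 2] - 1, f[, 3] - 1), con)
  } else if (ext == "obj") {
    writeLines(paste("v", v[, 1], v[, 2], v[, 3]), con)
    writeLines(paste("f", f[, 1], f[, 2], f[, 3]), con)
  } else if (ext == "stl") {
    writeLines("solid surface", con)
    for (t in seq_len(nrow(f))) {
      tri <- v[f[t, ], , drop = FALSE]
      n <- crossProd3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
      nn <- sqrt(sum(n^2))
      if (nn > 0) n <- n / nn
      writeLines(c(paste("facet normal", n[1], n[2], n[3]),
                   "  outer loop",
                   paste("    vertex", tri[, 1], tri[, 2], tri[, 3]),
                   "  endloop", "endfacet"), con)
    }
    writeLines("endsolid surface", con)
  } else stop("unsupported mesh format: ", ext)
  invisible(path)
}

readPLY <- function(path, organ) {
  head <- readLines(path, n = 100)
  if (!identical(head[1], "ply")) stop("not a PLY file: ", path)
  if (!any(grepl("^format ascii", head)))
    stop("only ASCII PLY is supported")
  endIdx <- which(head == "end_header")[1]
  if (is.na(endIdx)) stop("PLY header not terminated")
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", head, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face", head, value = TRUE)[1]))
  body <- readLines(path)[-seq_len(endIdx)]
  vparts <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  v <- t(vapply(vparts, function(p) as.numeric(p[1:3]), numeric(3)))
  fparts <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  f <- t(vapply(fparts, function(p) as.integer(p[2:4]) + 1L, integer(3)))
  Surface(v, f, organ)
}

readOBJ <- function(path, organ) {
  lines <- readLines(path)
  vlines <- grep("^v ", lines, value = TRUE)
  flines <- grep("^f ", lines, value = TRUE)
  v <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                function(p) as.numeric(p[2:4]), numeric(3)))
  f <- t(vapply(strsplit(trimws(flines), "\\s+"), function(p) {
    idx <- sub("/.*", "", p[2:4])          # drop texture/normal refs
    as.integer(idx)
  }, integer(3)))
  Surface(v, f, organ)
}

readSTL <- function(path, organ) {
  first <- readBin(path, "raw", n = 5)
  if (!identical(rawToChar(first), "solid"))
    stop("only ASCII STL is supported")
  lines <- readLines(path)
  vlines <- grep("^\\s*vertex", lines, value = TRUE)
  pts <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                  function(p) as.numeric(p[2:4]), numeric(3)))
  # weld identical vertices so the mesh closes
  key <- apply(pts, 1, paste, collapse = ",")
  uk <- !duplicated(key)
  v <- pts[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  f <- matrix(idx, ncol = 3, byrow = TRUE)
  Surface(v, f, organ)
}

#' Read a segmented label volume (NIfTI or MetaImage)
#'
#' NIfTI (`.nii`, `.nii.gz`) is read through RNifti; MetaImage
#' (`.mhd`/`.mha`, uncompressed local data only) through a small built-in
#' reader. Voxels greater than `threshold` become foreground.
#'
#' @param path file path.
#' @param organ organ tag for the result.
#' @param threshold binarization threshold on the stored intensities.
#' @return a [LabelVolume-class].
#' @export
readLabelVolume <- function(path, organ = "liver", threshold = 0.5) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    img <- RNifti::readNifti(path)
    spacing <- RNifti::pixdim(img)[1:3]
    arr <- array(as.numeric(img > threshold), dim(img)[1:3])
    return(LabelVolume(arr, spacing = spacing, origin = c(0, 0, 0),
                       organ = organ))
  }
  if (ext %in% c("mhd", "mha")) return(readMetaImage(path, organ, threshold))
  stop("unsupported volume format: ", ext)
}

#' Write a label volume to NIfTI
#'
#' @param volume a [LabelVolume-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeLabelVolume <- function(volume, path) {
  stopifnot(is(volume, "LabelVolume"))
  img <- RNifti::asNifti(array(as.integer(volume@grid), dim(volume@grid)),
                         pixdim = volume@spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# minimal MetaImage reader: ASCII header, uncompressed raw voxels either
# appended (.mha, ElementDataFile = LOCAL) or in a sibling .raw file
readMetaImage <- function(path, organ, threshold) {
  raw <- readBin(path, "raw", n = file.size(path))
  # header ends at the ElementDataFile line
  txt <- rawToChar(raw[seq_len(min(length(raw), 4096))])
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  edfLine <- grep("^ElementDataFile", lines)[1]
  if (is.na(edfLine)) stop("MetaImage header lacks ElementDataFile")
  hdr <- lines[seq_len(edfLine)]
  getField <- function(name) {
    ln <- grep(paste0("^", name, "\\s*="), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    trimws(sub("^[^=]*=", "", ln[1]))
  }
  dims <- as.integer(strsplit(getField("DimSize"), "\\s+")[[1]])
  spacing <- getField("ElementSpacing")
  spacing <- if (is.null(spacing)) rep(1, 3)
             else as.numeric(strsplit(spacing, "\\s+")[[1]])
  etype <- getField("ElementType")
  if (is.null(etype)) etype <- "MET_UCHAR"
  comp <- getField("CompressedData")
  if (!is.null(comp) && toupper(comp) == "TRUE")
    stop("compressed MetaImage is not supported")
  edf <- getField("ElementDataFile")
  nvox <- prod(dims)
  readFrom <- function(con, what, size, signed = TRUE) {
    readBin(con, what, n = nvox, size = size, signed = signed,
            endian = "little")
  }
  readVox <- function(con) {
    switch(etype,
      MET_UCHAR = readFrom(con, "integer", 1, signed = FALSE),
      MET_CHAR = readFrom(con, "integer", 1),
      MET_SHORT = readFrom(con, "integer", 2),
      MET_USHORT = readFrom(con, "integer", 2, signed = FALSE),
      MET_INT = readFrom(con, "integer", 4),
      MET_FLOAT = readFrom(con, "double", 4),
      MET_DOUBLE = readFrom(con, "double", 8),
      stop("unsupported MetaImage ElementType: ", etype))
  }
  if (toupper(edf) == "LOCAL") {
    # data begin right after the header's newline
    hdrBytes <- sum(nchar(lines[seq_len(edfLine)], type = "bytes")) + edfLine
    con <- rawConnection(raw[-seq_len(hdrBytes)])
    on.exit(close(con))
    vox <- readVox(con)
  } else {
    con <- file(file.path(dirname(path), edf), "rb")
    on.exit(close(con))
    vox <- readVox(con)
  }
  arr <- array(as.numeric(vox > threshold), dims)
  LabelVolume(arr, spacing = spacing, origin = c(0, 0, 0), organ = organ)
}

#' Serialize / restore an SSM model as JSON
#'
#' Plain-text archive holding the mean, eigenshapes, eigenvalues, layout,
#' reference id and configuration hash.
#'
#' @param model an [SSMModel-class].
#' @param path output (input) path.
#' @param config optional configuration list; its hash is stored.
#' @return `path` invisibly; `readSSM` returns the [SSMModel-class].
#' @export
writeSSM <- function(model, path, config = list()) {
  stopifnot(is(model, "SSMModel"))
  obj <- list(mean = model@mean,
              eigenshapes = model@eigenshapes,
              eigenvalues = model@eigenvalues,
              nTrain = model@nTrain,
              layout = model@layout,
              referenceId = model@referenceId,
              vertexCount = model@vertexCount,
              configHash = rlang::hash(config))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeSSM
#' @export
readSSM <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SSMModel", mean = as.numeric(obj$mean),
      eigenshapes = matrix(as.numeric(obj$eigenshapes),
                           nrow = length(obj$mean)),
      eigenvalues = as.numeric(obj$eigenvalues),
      nTrain = as.integer(obj$nTrain), layout = obj$layout,
      referenceId = as.character(obj$referenceId),
      vertexCount = as.integer(obj$vertexCount))
}
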