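# Minimal GIfTI time-series IO for surface-based ROI analyses.
#
# GIfTI is an XML container; functional data are stored as one DataArray per
# time point, each a float vector over mesh vertices. This reader supports
# the Base64Binary, GZipBase64Binary and ASCII encodings with little-endian
# float32/float64 payloads, which covers fMRIPrep-style func.gii output.
# The writer emits Base64Binary float32.

#' Read a GIfTI functional (time series) file
#'
#' @param path path to a `.gii` file containing one data array per time
#'   point with a consistent vertex count.
#' @return A numeric matrix, time points x vertices; vertex index is the
#'   feature index.
#' @export
load_surface_run <- function(path) {
  if (!file.exists(path)) stop("GIfTI file not found: ", path)
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  if (!length(arrays)) stop("GIfTI file ", path, " contains no data arrays")
  rows <- lapply(arrays, gifti_decode_array)
  nv <- lengths(rows)
  if (length(unique(nv)) != 1L)
    stop("GIfTI file ", path, " has inconsistent vertex counts across ",
         "data arrays: ", paste(unique(nv), collapse = ", "))
  do.call(rbind, rows)
}

gifti_decode_array <- function(node) {
  enc <- xml2::xml_attr(node, "Encoding")
  dtype <- xml2::xml_attr(node, "DataType")
  endian <- xml2::xml_attr(node, "Endian")
  data_node <- xml2::xml_find_first(node, ".//Data")
  txt <- xml2::xml_text(data_node)
  size <- switch(dtype,
                 "NIFTI_TYPE_FLOAT32" = 4L,
                 "NIFTI_TYPE_FLOAT64" = 8L,
                 stop("unsupported GIfTI DataType: ", dtype))
  if (identical(enc, "ASCII")) {
    return(as.numeric(strsplit(trimws(txt), "\\s+")[[1L]]))
  }
  raw <- jsonlite::base64_dec(gsub("\\s", "", txt))
  if (identical(enc, "GZipBase64Binary")) {
    raw <- memDecompress(raw, type = "gzip")
  } else if (!identical(enc, "Base64Binary")) {
    stop("unsupported GIfTI Encoding: ", enc)
  }
  readBin(raw, what = "double", n = length(raw) %/% size, size = size,
          endian = if (identical(endian, "BigEndian")) "big" else "little")
}

#' Write a time-by-vertex matrix as a GIfTI functional file
#'
#' Inverse of [load_surface_run()] (up to float32 precision). One
#' `DataArray` is written per row (time point).
#'
#' @param mat numeric matrix, time points x vertices.
#' @param path output `.gii` path.
#' @return `path`, invisibly.
#' @export
write_surface_run <- function(mat, path) {
  mat <- as.matrix(mat)
  if (!nrow(mat)) stop("cannot write a GIfTI file with no time points")
  arr <- vapply(seq_len(nrow(mat)), function(i) {
    payload <- jsonlite::base64_enc(
      writeBin(as.numeric(mat[i, ]), raw(), size = 4L, endian = "little"))
    paste0(
      '<DataArray Intent="NIFTI_INTENT_TIME_SERIES" ',
      'DataType="NIFTI_TYPE_FLOAT32" ArrayIndexingOrder="RowMajorOrder" ',
      'Dimensionality="1" Dim0="', ncol(mat), '" ',
      'Encoding="Base64Binary" Endian="LittleEndian">',
      "<Data>", payload, "</Data></DataArray>")
  }, character(1))
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<GIFTI Version="1.0" NumberOfDataArrays="', nrow(mat), '">\n',
    paste(arr, collapse = "\n"), "\n</GIFTI>\n")
  writeLines(xml, path)
  invisible(path)
}
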