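#' Read and write subject time series
#'
#' Two plain formats are supported.  `"tsv"` is tab-separated text with the
#' matrix oriented time x vertex and metadata in `#`-prefixed header lines
#' (`subject_id`, `tr_seconds`, `run_boundaries`).  `"gifti"` is a GIFTI
#' functional series (`.func.gii`): one DataArray per time point, each
#' holding one map of length v, so t maps of length v yield a t x v matrix.
#' The GIFTI reader accepts ASCII, Base64Binary, and GZipBase64Binary
#' encodings (little-endian float32/float64); the writer emits ASCII.
#' Round trips preserve the data to better than 1e-6 and metadata exactly.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gifti"`; default guessed from the extension.
#' @param ts a [subject_timeseries()].
#' @return `read_timeseries` returns a [subject_timeseries()].
#' @export
read_timeseries <- function(path, format = c("auto", "tsv", "gifti")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gii$", path, ignore.case = TRUE)) "gifti" else "tsv"
  ts <- if (format == "tsv") read_timeseries_tsv(path) else read_timeseries_gifti(path)
  bad <- which(colSums(!is.finite(ts$data)) > 0)
  if (length(bad))
    stop("non-finite values in vertices: ", paste(bad, collapse = ", "))
  ts
}

#' @rdname read_timeseries
#' @export
write_timeseries <- function(ts, path, format = c("auto", "tsv", "gifti")) {
  stopifnot(inherits(ts, "subject_timeseries"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gii$", path, ignore.case = TRUE)) "gifti" else "tsv"
  if (format == "tsv") write_timeseries_tsv(ts, path) else write_timeseries_gifti(ts, path)
  invisible(path)
}

read_timeseries_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list(subject_id = "subj", tr_seconds = 1, run_boundaries = "0")
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([a-z_]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  x <- do.call(rbind, lapply(strsplit(body, "\t", fixed = TRUE), as.numeric))
  subject_timeseries(x, subject_id = meta$subject_id,
                     tr_seconds = as.numeric(meta$tr_seconds),
                     run_boundaries = as.integer(strsplit(meta$run_boundaries,
                                                          ",")[[1]]))
}

write_timeseries_tsv <- function(ts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# subject_id: %s", ts$subject_id),
               sprintf("# tr_seconds: %.17g", ts$tr_seconds),
               sprintf("# run_boundaries: %s",
                       paste(ts$run_boundaries, collapse = ","))), con)
  utils::write.table(format(ts$data, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

gifti_decode_array <- function(node) {
  enc <- xml2::xml_attr(node, "Encoding")
  dtype <- xml2::xml_attr(node, "DataType")
  dims <- as.integer(xml2::xml_attr(node, "Dim0"))
  data_node <- xml2::xml_find_first(node, ".//Data")
  txt <- if (inherits(data_node, "xml_missing")) xml2::xml_text(node)
         else xml2::xml_text(data_node)
  if (identical(enc, "ASCII")) {
    vals <- as.numeric(strsplit(trimws(txt), "\\s+")[[1]])
  } else {
    raw <- jsonlite::base64_dec(gsub("\\s", "", txt))
    if (identical(enc, "GZipBase64Binary")) raw <- memDecompress(raw, "gzip")
    size <- if (identical(dtype, "NIFTI_TYPE_FLOAT64")) 8L else 4L
    vals <- readBin(raw, "double", n = length(raw) / size, size = size,
                    endian = "little")
  }
  if (!is.na(dims) && length(vals) != dims)
    stop("GIFTI DataArray length does not match declared Dim0")
  vals
}

read_timeseries_gifti <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  arrays <- xml2::xml_find_all(doc, "//DataArray")
  if (!length(arrays)) stop("no DataArray elements found in GIFTI file")
  rows <- lapply(arrays, gifti_decode_array)
  vlen <- unique(vapply(rows, length, 1L))
  if (length(vlen) != 1) stop("GIFTI maps have inconsistent lengths")
  x <- do.call(rbind, rows)
  meta <- list(subject_id = "subj", tr_seconds = 1, run_boundaries = "0")
  for (md in xml2::xml_find_all(doc, "//MD")) {
    nm <- xml2::xml_text(xml2::xml_find_first(md, ".//Name"))
    vl <- xml2::xml_text(xml2::xml_find_first(md, ".//Value"))
    if (!is.na(nm) && nm %in% names(meta)) meta[[nm]] <- vl
  }
  subject_timeseries(x, subject_id = meta$subject_id,
                     tr_seconds = as.numeric(meta$tr_seconds),
                     run_boundaries = as.integer(strsplit(meta$run_boundaries,
                                                          ",")[[1]]))
}

write_timeseries_gifti <- function(ts, path) {
  t_time <- nrow(ts$data)
  md <- sprintf("    <MD><Name><![CDATA[%s]]></Name><Value><![CDATA[%s]]></Value></MD>",
                c("subject_id", "tr_seconds", "run_boundaries"),
                c(ts$subject_id, sprintf("%.17g", ts$tr_seconds),
                  paste(ts$run_boundaries, collapse = ",")))
  arr <- vapply(seq_len(t_time), function(i) {
    paste0("  <DataArray Intent=\"NIFTI_INTENT_TIME_SERIES\" ",
           "DataType=\"NIFTI_TYPE_FLOAT64\" ArrayIndexingOrder=\"RowMajorOrder\" ",
           sprintf("Dimensionality=\"1\" Dim0=\"%d\" ", ncol(ts$data)),
           "Encoding=\"ASCII\" Endian=\"LittleEndian\">\n",
           "    <Data>", paste(sprintf("%.17g", ts$data[i, ]), collapse = " "),
           "</Data>\n  </DataArray>")
  }, "")
  xml <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
           sprintf("<GIFTI Version=\"1.0\" NumberOfDataArrays=\"%d\">", t_time),
           "  <MetaData>", md, "  </MetaData>", arr, "</GIFTI>")
  writeLines(xml, path)
}

#' Read or write a region mask as a plain index list
#'
#' One 1-based vertex index per line; lines starting with `#` are ignored.
#' @param path file path.
#' @param mask a [region_mask()].
#' @param name label for the mask read from file.
#' @export
read_mask <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  region_mask(as.integer(lines), name = name)
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  writeLines(c(sprintf("# %s", mask$name), as.character(mask$members)), path)
  invisible(path)
}
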