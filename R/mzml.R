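## Minimal mzML support.
##
## No mzML library is available in this R stack, so the package reads and
## writes a small, strict subset of mzML 1.1: one or more <spectrum> elements
## with uncompressed, 64-bit little-endian float binary arrays for m/z and
## intensity. This is sufficient for round-tripping the synthetic generator's
## output; real vendor files should be converted to two-column tables first.

.encodeDoubles <- function(x) {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8,
                                endian = "little"))
}

.decodeDoubles <- function(b64) {
  raw <- jsonlite::base64_dec(gsub("\\s", "", b64))
  readBin(raw, numeric(), n = length(raw) %/% 8L, size = 8,
          endian = "little")
}

#' Write a spectrum to a minimal mzML file
#'
#' Writes one \code{<spectrum>} with uncompressed 64-bit little-endian m/z
#' and intensity arrays. m/z values round-trip bit-identically through
#' \code{\link{readMzML}}.
#'
#' @param spec A \linkS4class{MassSpectrum}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeMzML <- function(spec, path) {
  stopifnot(is(spec, "MassSpectrum"))
  n <- length(spec@mz)
  tpl <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<run id="%s">\n<spectrumList count="1">\n',
    '<spectrum index="0" id="scan=1" defaultArrayLength="%d">\n',
    '<cvParam accession="MS:1000129" name="negative scan"/>\n',
    '<binaryDataArrayList count="2">\n',
    '<binaryDataArray><cvParam accession="MS:1000514" name="m/z array"/>',
    '<cvParam accession="MS:1000523" name="64-bit float"/>',
    '<cvParam accession="MS:1000576" name="no compression"/>',
    '<binary>%s</binary></binaryDataArray>\n',
    '<binaryDataArray><cvParam accession="MS:1000515" ',
    'name="intensity array"/>',
    '<cvParam accession="MS:1000523" name="64-bit float"/>',
    '<cvParam accession="MS:1000576" name="no compression"/>',
    '<binary>%s</binary></binaryDataArray>\n',
    '</binaryDataArrayList>\n</spectrum>\n</spectrumList>\n</run>\n</mzML>\n')
  xml <- sprintf(tpl, spec@sampleId, n, .encodeDoubles(spec@mz),
                 .encodeDoubles(spec@intensity))
  writeLines(xml, path, sep = "")
  invisible(path)
}

#' Read a minimal mzML file
#'
#' Reads the first spectrum of an mzML file written with uncompressed 64-bit
#' little-endian binary arrays (the subset \code{\link{writeMzML}} emits).
#'
#' @param path mzML file path.
#' @param ... Passed to \code{\link{massSpectrum}}.
#' @return A \linkS4class{MassSpectrum}.
#' @export
readMzML <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  ns <- c(m = "http://psi.hupo.org/ms/mzml")
  spec <- xml2::xml_find_first(doc, ".//m:spectrum", ns)
  if (is.na(xml2::xml_name(spec, ns)) || length(spec) == 0L)
    stop("no <spectrum> element found in ", path, call. = FALSE)
  arrays <- xml2::xml_find_all(spec, ".//m:binaryDataArray", ns)
  if (length(arrays) < 2L)
    stop("expected two binary data arrays", call. = FALSE)
  getArray <- function(accession) {
    for (a in arrays) {
      acc <- xml2::xml_attr(
        xml2::xml_find_all(a, ".//m:cvParam", ns), "accession")
      if (accession %in% acc) {
        cmp <- xml2::xml_attr(
          xml2::xml_find_all(a, ".//m:cvParam", ns), "name")
        if (!"no compression" %in% cmp)
          stop("only uncompressed binary arrays are supported",
               call. = FALSE)
        return(.decodeDoubles(
          xml2::xml_text(xml2::xml_find_first(a, ".//m:binary", ns))))
      }
    }
    stop("binary array ", accession, " not found", call. = FALSE)
  }
  run <- xml2::xml_find_first(doc, ".//m:run", ns)
  sid <- xml2::xml_attr(run, "id")
  massSpectrum(getArray("MS:1000514"), getArray("MS:1000515"),
               sampleId = if (is.na(sid)) "" else sid, ...)
}
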