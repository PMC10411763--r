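# Minimal DICOM codec: uncompressed, explicit-VR little-endian, one
# single-frame secondary-capture-style file per slice. Written by hand
# because quantitation-preserving control over rescale slope/intercept and
# slice geometry is exactly where conversion bugs corrupt counts; the codec
# covers what the pipeline writes plus conforming files of the same shape.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
SOP_SECONDARY_CAPTURE <- "1.2.840.10008.5.1.4.1.1.7"
IMPLEMENTATION_UID <- "1.2.826.0.1.3680043.10.9000.1"

# VR lookup used when reading implicit-VR files (only the tags we emit).
DICOM_DICT <- c(
  "0008,0016" = "UI", "0008,0018" = "UI", "0008,0020" = "DA",
  "0008,0030" = "TM", "0008,0060" = "CS", "0008,103E" = "LO",
  "0018,0050" = "DS", "0018,0088" = "DS",
  "0020,000D" = "UI", "0020,000E" = "UI", "0020,0011" = "IS",
  "0020,0013" = "IS", "0020,0032" = "DS", "0020,0037" = "DS",
  "0028,0002" = "US", "0028,0004" = "CS", "0028,0010" = "US",
  "0028,0011" = "US", "0028,0030" = "DS", "0028,0100" = "US",
  "0028,0101" = "US", "0028,0102" = "US", "0028,0103" = "US",
  "0028,1052" = "DS", "0028,1053" = "DS", "7FE0,0010" = "OW")

uid_counter <- local({
  i <- 0L
  function() {
    i <<- i + 1L
    paste0(IMPLEMENTATION_UID, ".", as.integer(Sys.time()) %% 1e6, ".",
           sample.int(1e6, 1), ".", i)
  }
})

u16le <- function(x) {
  x <- as.integer(x)
  as.raw(c(x %% 256L, x %/% 256L))
}
u32le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

dicom_element <- function(group, element, vr, value_raw) {
  len <- length(value_raw)
  if (len %% 2 == 1) {
    value_raw <- c(value_raw, if (vr %in% c("UI", "OB")) as.raw(0)
                   else charToRaw(" "))
    len <- len + 1
  }
  head <- c(u16le(group), u16le(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN"))
    head <- c(head, as.raw(c(0, 0)), u32le(len))
  else head <- c(head, u16le(len))
  c(head, value_raw)
}

str_el <- function(group, element, vr, s)
  dicom_element(group, element, vr, charToRaw(s))
us_el <- function(group, element, x) dicom_element(group, element, "US", u16le(x))
ds_fmt <- function(x) paste(sprintf("%.8g", x), collapse = "\\")

#' Write a volume as a DICOM series
#'
#' One explicit-VR little-endian single-frame file per transverse slice.
#' The rescale slope and intercept are chosen per slice set so that the full
#' dynamic range maps onto 16-bit unsigned pixels (intercept = minimum,
#' slope = range/65535): reading the series back reproduces the values
#' within that quantization, and the volume total within 0.1%. A constant
#' volume is encoded exactly (slope 1, all pixels 0, intercept = the
#' constant).
#'
#' @param volume a [volume3d()] with `value_kind` set.
#' @param path output directory (created if needed).
#' @param series_description free-text series description.
#' @param modality DICOM modality code (default `"NM"`, `"CT"` for HU).
#' @return invisibly, the vector of file paths written.
#' @export
write_dicom_series <- function(volume, path, series_description = "voxdose",
                               modality = NULL) {
  d <- dim(volume$values)
  if (prod(d) == 0) stop("empty volume", call. = FALSE)
  modality <- modality %||% if (volume$value_kind == "HU") "CT" else "NM"
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  vmin <- min(volume$values); vmax <- max(volume$values)
  slope <- if (vmax > vmin) (vmax - vmin) / 65535 else 1
  # store with the precision the DS string carries, so read-back is exact
  slope <- as.numeric(sprintf("%.8g", slope))
  intercept <- as.numeric(sprintf("%.8g", vmin))
  study_uid <- uid_counter(); series_uid <- uid_counter()
  files <- character(d[3])
  for (k in seq_len(d[3])) {
    pix <- round((volume$values[, , k] - intercept) / slope)
    pix <- pmin(pmax(pix, 0), 65535)
    pos <- drop(index_to_world(volume, c(0, 0, k - 1)))
    sop_uid <- uid_counter()
    meta_body <- c(
      dicom_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
      str_el(0x0002, 0x0002, "UI", SOP_SECONDARY_CAPTURE),
      str_el(0x0002, 0x0003, "UI", sop_uid),
      str_el(0x0002, 0x0010, "UI", TS_EXPLICIT_LE),
      str_el(0x0002, 0x0012, "UI", IMPLEMENTATION_UID))
    meta <- c(dicom_element(0x0002, 0x0000, "UL", u32le(length(meta_body))),
              meta_body)
    ori <- volume$orientation
    body <- c(
      str_el(0x0008, 0x0016, "UI", SOP_SECONDARY_CAPTURE),
      str_el(0x0008, 0x0018, "UI", sop_uid),
      str_el(0x0008, 0x0020, "DA", "20260101"),
      str_el(0x0008, 0x0030, "TM", "000000"),
      str_el(0x0008, 0x0060, "CS", modality),
      str_el(0x0008, 0x103E, "LO", series_description),
      str_el(0x0018, 0x0050, "DS", ds_fmt(volume$spacing[3])),
      str_el(0x0018, 0x0088, "DS", ds_fmt(volume$spacing[3])),
      str_el(0x0020, 0x000D, "UI", study_uid),
      str_el(0x0020, 0x000E, "UI", series_uid),
      str_el(0x0020, 0x0011, "IS", "1"),
      str_el(0x0020, 0x0013, "IS", as.character(k)),
      str_el(0x0020, 0x0032, "DS", ds_fmt(pos)),
      str_el(0x0020, 0x0037, "DS", ds_fmt(c(ori[, 1], ori[, 2]))),
      us_el(0x0028, 0x0002, 1),
      str_el(0x0028, 0x0004, "CS", "MONOCHROME2"),
      us_el(0x0028, 0x0010, d[2]),          # Rows    = second grid axis
      us_el(0x0028, 0x0011, d[1]),          # Columns = first grid axis
      str_el(0x0028, 0x0030, "DS", ds_fmt(volume$spacing[c(2, 1)])),
      us_el(0x0028, 0x0100, 16), us_el(0x0028, 0x0101, 16),
      us_el(0x0028, 0x0102, 15), us_el(0x0028, 0x0103, 0),
      str_el(0x0028, 0x1052, "DS", ds_fmt(intercept)),
      str_el(0x0028, 0x1053, "DS", ds_fmt(slope)),
      dicom_element(0x7FE0, 0x0010, "OW", pix_to_raw(pix)))
    f <- file.path(path, sprintf("slice%04d.dcm", k))
    con <- file(f, "wb")
    writeBin(c(as.raw(rep(0, 128)), charToRaw("DICM"), meta, body), con)
    close(con)
    files[k] <- f
  }
  invisible(files)
}

# 16-bit unsigned pixels, column index fastest = DICOM row-major order for
# Columns = first axis.
pix_to_raw <- function(pix) {
  x <- as.integer(pix)
  as.raw(as.vector(rbind(x %% 256L, x %/% 256L)))
}

raw_to_u16 <- function(r) {
  m <- matrix(as.integer(r), nrow = 2)
  m[1, ] + 256L * m[2, ]
}

parse_dicom_file <- function(f) {
  r <- readBin(f, "raw", n = file.info(f)$size)
  if (length(r) < 140 || rawToChar(r[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", f, call. = FALSE)
  p <- 133L
  elements <- list()
  explicit <- TRUE
  ts <- TS_EXPLICIT_LE
  n <- length(r)
  in_meta <- TRUE
  while (p <= n - 7) {
    group <- as.integer(r[p]) + 256L * as.integer(r[p + 1])
    element <- as.integer(r[p + 2]) + 256L * as.integer(r[p + 3])
    if (in_meta && group != 2L) {
      # file meta group is always explicit; dataset follows transfer syntax
      in_meta <- FALSE
      explicit <- ts == TS_EXPLICIT_LE
      if (!ts %in% c(TS_EXPLICIT_LE, TS_IMPLICIT_LE))
        stop("unsupported transfer syntax ", ts, " in ", f, call. = FALSE)
    }
    key <- sprintf("%04X,%04X", group, element)
    if (explicit || in_meta) {
      vr <- rawToChar(r[(p + 4):(p + 5)])
      if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
        len <- sum(as.integer(r[(p + 8):(p + 11)]) * c(1, 256, 65536, 16777216))
        vstart <- p + 12L
      } else {
        len <- as.integer(r[p + 6]) + 256L * as.integer(r[p + 7])
        vstart <- p + 8L
      }
    } else {
      vr <- if (key %in% names(DICOM_DICT)) DICOM_DICT[[key]] else "UN"
      len <- sum(as.integer(r[(p + 4):(p + 7)]) * c(1, 256, 65536, 16777216))
      vstart <- p + 8L
    }
    if (len < 0 || vstart + len - 1 > n)
      stop("corrupt DICOM element ", key, " in ", f, call. = FALSE)
    raw_val <- if (len > 0) r[vstart:(vstart + len - 1)] else raw(0)
    elements[[key]] <- decode_vr(vr, raw_val)
    if (key == "0002,0010") ts <- elements[[key]]
    p <- vstart + len
  }
  if (in_meta) stop("DICOM file has no dataset: ", f, call. = FALSE)
  elements
}

decode_vr <- function(vr, raw_val) {
  # strings may be padded with a trailing space or NUL byte
  chr <- function(r) {
    while (length(r) && r[length(r)] %in% as.raw(c(0, 32)))
      r <- r[-length(r)]
    rawToChar(r)
  }
  switch(vr,
    US = raw_to_u16(raw_val),
    UL = sum(as.integer(raw_val) * 256^(seq_along(raw_val) - 1)),
    OW = raw_to_u16(raw_val),
    OB = raw_val,
    DS = as.numeric(strsplit(chr(raw_val), "\\\\")[[1]]),
    IS = as.integer(strsplit(chr(raw_val), "\\\\")[[1]]),
    chr(raw_val))
}

#' Read a DICOM series as a volume
#'
#' Reads every DICOM file in a directory, checks that they form one
#' spatially consistent series (single series UID, uniform in-plane
#' geometry, uniform slice spacing within 1%), sorts slices by position
#' along the slice normal, and applies the stored rescale slope and
#' intercept so the returned values are in true stored units.
#'
#' @param path directory containing the series.
#' @param value_kind value kind to stamp on the volume (DICOM modality is
#'   checked for CT/HU consistency but counts vs activity is the caller's
#'   call).
#' @param acquisition_time_h optional acquisition time to attach.
#' @return a [volume3d()].
#' @export
read_dicom_series <- function(path, value_kind = "counts",
                              acquisition_time_h = NA_real_) {
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("no files in ", path, call. = FALSE)
  slices <- lapply(files, parse_dicom_file)
  series_uids <- unique(vapply(slices, function(s)
    s[["0020,000E"]] %||% "", ""))
  if (length(series_uids) > 1)
    stop("directory contains a mixed series (", length(series_uids),
         " series UIDs)", call. = FALSE)
  need <- c("0020,0032", "0020,0037", "0028,0030", "0028,0010", "0028,0011",
            "7FE0,0010")
  for (s in slices)
    if (!all(need %in% names(s)))
      stop("missing geometry or pixel tags: ",
           paste(setdiff(need, names(s)), collapse = ", "), call. = FALSE)
  ori6 <- slices[[1]][["0020,0037"]]
  rowdir <- ori6[1:3]; coldir <- ori6[4:6]
  normal <- c(rowdir[2] * coldir[3] - rowdir[3] * coldir[2],
              rowdir[3] * coldir[1] - rowdir[1] * coldir[3],
              rowdir[1] * coldir[2] - rowdir[2] * coldir[1])
  pos <- t(vapply(slices, function(s) s[["0020,0032"]], numeric(3)))
  proj <- drop(pos %*% normal)
  ord <- order(proj)
  slices <- slices[ord]; pos <- pos[ord, , drop = FALSE]; proj <- proj[ord]
  ps <- slices[[1]][["0028,0030"]]
  nrow_px <- slices[[1]][["0028,0010"]]; ncol_px <- slices[[1]][["0028,0011"]]
  for (s in slices[-1]) {
    if (max(abs(s[["0028,0030"]] - ps)) > 1e-6 ||
        s[["0028,0010"]] != nrow_px || s[["0028,0011"]] != ncol_px)
      stop("inconsistent in-plane geometry across slices", call. = FALSE)
  }
  nz <- length(slices)
  if (nz > 1) {
    gaps <- diff(proj)
    if (any(gaps <= 0))
      stop("duplicate slice positions in series", call. = FALSE)
    med <- stats::median(gaps)
    if (max(abs(gaps - med)) > 0.01 * med)
      stop(sprintf(
        "inconsistent slice spacing: gaps range %.4g-%.4g mm (median %.4g)",
        min(gaps), max(gaps), med), call. = FALSE)
    dz <- med
  } else dz <- slices[[1]][["0018,0050"]] %||% 1
  vals <- array(0, c(ncol_px, nrow_px, nz))
  for (k in seq_len(nz)) {
    s <- slices[[k]]
    slope <- (s[["0028,1053"]] %||% 1)
    intercept <- (s[["0028,1052"]] %||% 0)
    px <- s[["7FE0,0010"]]
    if (length(px) != ncol_px * nrow_px)
      stop("pixel data length mismatch on slice ", k, call. = FALSE)
    vals[, , k] <- matrix(px * slope + intercept, ncol_px, nrow_px)
  }
  orientation <- cbind(rowdir, coldir, normal)
  colnames(orientation) <- NULL
  volume3d(vals, spacing = c(ps[2], ps[1], dz), origin = pos[1, ],
           orientation = orientation, value_kind = value_kind,
           acquisition_time_h = acquisition_time_h)
}
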