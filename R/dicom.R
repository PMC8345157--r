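# Minimal DICOM codec: explicit-VR little-endian only, covering the
# attribute subset needed for RT-Dose and RT Structure Set objects.
# Unsupported dialects are rejected loudly rather than approximated.

UID_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_RTDOSE <- "1.2.840.10008.5.1.4.1.1.481.2"
UID_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
UID_CT <- "1.2.840.10008.5.1.4.1.1.2"
UID_IMPL <- "1.2.826.0.1.3680043.10.1432.1"

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32 <- function(x) {
  x <- as.numeric(x)
  lo <- x %% 65536; hi <- (x - lo) / 65536
  c(u16(lo), u16(hi))
}

dcm_str_payload <- function(s, vr) {
  r <- charToRaw(paste(s, collapse = "\\"))
  if (length(r) %% 2 == 1)
    r <- c(r, if (vr %in% c("UI")) as.raw(0) else charToRaw(" "))
  r
}

dcm_ds <- function(x) dcm_str_payload(sprintf("%.9g", x), "DS")
dcm_is <- function(x) dcm_str_payload(sprintf("%d", as.integer(x)), "IS")

# One data element as raw bytes (explicit VR little endian).
dcm_element <- function(group, element, vr, payload) {
  stopifnot(length(payload) %% 2 == 0)
  head <- c(u16(group), u16(element), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(head, as.raw(c(0, 0)), u32(length(payload)), payload)
  } else {
    if (length(payload) > 65534) stop("payload too long for short VR")
    c(head, u16(length(payload)), payload)
  }
}

el_str <- function(group, element, vr, s) dcm_element(group, element, vr, dcm_str_payload(s, vr))
el_us  <- function(group, element, x) dcm_element(group, element, "US", u16(x))

# Sequence of items, defined lengths throughout.
dcm_sequence <- function(group, element, items) {
  body <- raw()
  for (it in items)
    body <- c(body, u16(0xFFFE), u16(0xE000), u32(length(it)), it)
  dcm_element(group, element, "SQ", body)
}

# Deterministic pseudo-UID derived from content (keeps re-runs byte-identical).
content_uid <- function(root, parts) {
  h <- 0
  for (p in parts) {
    v <- suppressWarnings(as.numeric(p))
    v <- if (is.na(v)) sum(utf8ToInt(as.character(p))) else abs(v) * 1e3
    h <- (h * 31 + sum(v)) %% 1e12
  }
  sprintf("%s.%.0f", root, h)
}

dcm_file <- function(sop_class, sop_instance, dataset_raw, path) {
  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    el_str(0x0002, 0x0002, "UI", sop_class),
    el_str(0x0002, 0x0003, "UI", sop_instance),
    el_str(0x0002, 0x0010, "UI", UID_TS_EXPLICIT_LE),
    el_str(0x0002, 0x0012, "UI", UID_IMPL))
  meta <- c(dcm_element(0x0002, 0x0000, "UL", u32(length(meta))), meta)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, dataset_raw), con)
  invisible(path)
}

# ---- parsing ---------------------------------------------------------------

dcm_parse <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file: ", path)
  parse_dataset(raw, 133, length(raw))$elements
}

rd_u16 <- function(raw, at) as.integer(raw[at]) + 256L * as.integer(raw[at + 1])
rd_u32 <- function(raw, at) rd_u16(raw, at) + 65536 * rd_u16(raw, at + 2)

# Parse elements in raw[from..to]; returns list(elements, next_pos).
# Stops at (and consumes) an item-delimitation tag when `in_item`.
parse_dataset <- function(raw, from, to, in_item = FALSE) {
  els <- list()
  pos <- from
  while (pos + 7 <= to + 1 && pos <= to) {
    grp <- rd_u16(raw, pos); ele <- rd_u16(raw, pos + 2)
    if (grp == 0xFFFE) {
      len <- rd_u32(raw, pos + 4)
      pos <- pos + 8
      if (ele == 0xE00D || ele == 0xE0DD) {
        if (in_item) return(list(elements = els, next_pos = pos))
        next
      }
      stop("unexpected item tag outside a sequence")
    }
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("cannot parse element at byte ", pos, ": implicit VR not supported")
    if (vr %in% LONG_VRS) {
      len <- rd_u32(raw, pos + 8)
      pos <- pos + 12
    } else {
      len <- rd_u16(raw, pos + 6)
      pos <- pos + 8
    }
    key <- sprintf("%04X,%04X", grp, ele)
    if (vr == "SQ") {
      if (len == 4294967295) {
        sq <- parse_sq_undefined(raw, pos, to)
        els[[key]] <- list(vr = vr, value = sq$items)
        pos <- sq$next_pos
      } else {
        els[[key]] <- list(vr = vr, value = parse_sq_defined(raw, pos, pos + len - 1))
        pos <- pos + len
      }
      next
    }
    if (len == 4294967295) stop("undefined length on non-sequence element")
    payload <- if (len > 0) raw[pos:(pos + len - 1)] else raw(0)
    els[[key]] <- list(vr = vr, value = decode_payload(payload, vr))
    pos <- pos + len
  }
  list(elements = els, next_pos = pos)
}

parse_sq_defined <- function(raw, from, to) {
  items <- list(); pos <- from
  while (pos + 7 <= to + 1 && pos <= to) {
    if (rd_u16(raw, pos) != 0xFFFE || rd_u16(raw, pos + 2) != 0xE000)
      stop("malformed sequence item")
    len <- rd_u32(raw, pos + 4)
    pos <- pos + 8
    if (len == 4294967295) {
      it <- parse_dataset(raw, pos, to, in_item = TRUE)
      items[[length(items) + 1L]] <- it$elements
      pos <- it$next_pos
    } else {
      items[[length(items) + 1L]] <- parse_dataset(raw, pos, pos + len - 1)$elements
      pos <- pos + len
    }
  }
  items
}

parse_sq_undefined <- function(raw, from, to) {
  items <- list(); pos <- from
  repeat {
    if (pos + 7 > to + 1) stop("unterminated sequence")
    grp <- rd_u16(raw, pos); ele <- rd_u16(raw, pos + 2)
    len <- rd_u32(raw, pos + 4)
    pos <- pos + 8
    if (grp == 0xFFFE && ele == 0xE0DD) break
    if (!(grp == 0xFFFE && ele == 0xE000)) stop("malformed sequence item")
    if (len == 4294967295) {
      it <- parse_dataset(raw, pos, to, in_item = TRUE)
      items[[length(items) + 1L]] <- it$elements
      pos <- it$next_pos
    } else {
      items[[length(items) + 1L]] <- parse_dataset(raw, pos, pos + len - 1)$elements
      pos <- pos + len
    }
  }
  list(items = items, next_pos = pos)
}

payload_string <- function(payload) {
  while (length(payload) && payload[length(payload)] == as.raw(0))
    payload <- payload[-length(payload)]
  trimws(rawToChar(payload), which = "right")
}

decode_payload <- function(payload, vr) {
  if (vr %in% c("UI", "CS", "LO", "SH", "PN", "DA", "TM", "ST", "LT", "AE"))
    return(strsplit(payload_string(payload), "\\\\")[[1]])
  if (vr == "DS")
    return(as.numeric(strsplit(payload_string(payload), "\\\\")[[1]]))
  if (vr == "IS")
    return(as.integer(strsplit(payload_string(payload), "\\\\")[[1]]))
  if (vr == "US") return(readBin(payload, "integer", n = length(payload) / 2,
                                 size = 2, endian = "little", signed = FALSE))
  if (vr == "UL") {
    v <- readBin(payload, "integer", n = length(payload) / 4,
                 size = 4, endian = "little")
    return(ifelse(v < 0, v + 4294967296, as.numeric(v)))
  }
  payload  # OB/OW/AT/unknown: raw
}

dcm_get <- function(ds, key, required = FALSE, what = key) {
  el <- ds[[key]]
  if (is.null(el)) {
    if (required) stop("missing required DICOM attribute ", what)
    return(NULL)
  }
  el$value
}
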