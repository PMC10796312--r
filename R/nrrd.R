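#' Read a 3D NRRD volume
#'
#' Minimal NRRD0004 reader for the subset of the format the pipeline writes:
#' 3-dimensional double/float data, `raw` or `text` encoding, little-endian,
#' with `space directions` and `space origin` carrying the voxel geometry.
#'
#' @param path Path to a `.nrrd` file.
#' @return A [pet_volume].
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000", magic))
    stop("read_nrrd: not an NRRD file (bad magic line): ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L)
      stop("read_nrrd: unexpected end of header in ", path)
    if (line == "") break       # blank line separates header from data
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L)
      stop("read_nrrd: malformed header line: ", line)
    fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  need <- c("dimension", "sizes", "encoding", "type")
  miss <- setdiff(need, names(fields))
  if (length(miss))
    stop("read_nrrd: header missing field(s): ", paste(miss, collapse = ", "))
  if (as.integer(fields$dimension) != 3L)
    stop("read_nrrd: only 3-dimensional volumes are supported")
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  n <- prod(sizes)
  type <- fields$type
  enc <- fields$encoding
  if (enc %in% c("raw")) {
    bytes <- switch(type, double = 8L, float = 4L,
                    stop("read_nrrd: unsupported type: ", type))
    endian <- if (!is.null(fields$endian) && fields$endian == "big")
      "big" else "little"
    values <- readBin(con, what = "double", n = n, size = bytes,
                      endian = endian)
  } else if (enc %in% c("text", "txt", "ascii")) {
    values <- scan(con, what = double(), n = n, quiet = TRUE)
  } else {
    stop("read_nrrd: unsupported encoding: ", enc)
  }
  if (length(values) != n)
    stop("read_nrrd: data block shorter than header promises in ", path)
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["space directions"]])) {
    rows <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    m <- t(vapply(rows, function(r)
      as.numeric(strsplit(gsub("[()]", "", r), ",")[[1]]), numeric(3)))
    off <- m - diag(diag(m))
    if (any(abs(off) > 1e-9))
      stop("read_nrrd: only axis-aligned space directions are supported")
    spacing <- diag(m)
  } else if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "",
                                       fields[["space origin"]]), ",")[[1]])
  pet_volume(array(values, dim = sizes), spacing_mm = spacing,
             origin_mm = origin,
             subject_id = sub("\\.nrrd$", "", basename(path)))
}

#' Write a 3D NRRD volume
#'
#' Writes the NRRD0004 subset read back by [read_nrrd]: raw little-endian
#' doubles (lossless round trip) or plain text.
#'
#' @param volume A [pet_volume].
#' @param path Output path.
#' @param encoding `"raw"` (default, lossless binary) or `"text"`.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(volume, path, encoding = c("raw", "text")) {
  stopifnot(inherits(volume, "pet_volume"))
  encoding <- match.arg(encoding)
  d <- dim(volume$intensities)
  s <- volume$spacing_mm
  o <- volume$origin_mm
  header <- c(
    "NRRD0004",
    "# generated by petnodcnn",
    "type: double",
    "dimension: 3",
    "space: left-posterior-superior",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("space directions: (%.10g,0,0) (0,%.10g,0) (0,0,%.10g)",
            s[1], s[2], s[3]),
    "kinds: domain domain domain",
    if (encoding == "raw") "endian: little",
    sprintf("encoding: %s", encoding),
    sprintf("space origin: (%.10g,%.10g,%.10g)", o[1], o[2], o[3]),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (encoding == "raw") {
    writeBin(as.vector(volume$intensities), con, size = 8L,
             endian = "little")
  } else {
    writeLines(paste(format(as.vector(volume$intensities), digits = 17,
                            trim = TRUE, scientific = TRUE),
                     collapse = " "), con)
  }
  invisible(path)
}

manifest_columns <- c("subject_id", "path", "label", "center_x_mm",
                      "center_y_mm", "center_z_mm", "diameter_mm")

#' Read a cohort manifest table
#'
#' The manifest is a CSV with one row per subject: `subject_id`, `path` (to
#' the subject's NRRD volume, relative to the manifest's directory unless
#' absolute), `label` (benign/malignant), the physical nodule centre
#' (`center_x_mm`, `center_y_mm`, `center_z_mm`) and `diameter_mm`.
#'
#' @param path Path to the manifest CSV.
#' @return A data frame of class `cohort_manifest` with the columns above;
#'   relative volume paths are resolved against the manifest directory.
#' @export
read_manifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(manifest_columns, names(df))
  if (length(miss))
    stop("read_manifest: missing column(s): ", paste(miss, collapse = ", "))
  df$label <- as.character(as_nodule_label(df$label))
  if (anyDuplicated(df$subject_id))
    stop("read_manifest: duplicated subject_id (one nodule per subject)")
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  class(df) <- c("cohort_manifest", "data.frame")
  df
}

#' Write a cohort manifest table
#'
#' @param manifest A data frame with the columns listed in [read_manifest].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  miss <- setdiff(manifest_columns, names(manifest))
  if (length(miss))
    stop("write_manifest: missing column(s): ", paste(miss, collapse = ", "))
  write.csv(as.data.frame(manifest)[manifest_columns], path,
            row.names = FALSE)
  invisible(path)
}
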