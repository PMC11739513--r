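#' Read an STL surface (binary or ASCII)
#'
#' STL files store an unindexed triangle soup; identical vertex coordinates
#' are merged so that edge connectivity (and hence the watertightness check)
#' is recovered. Units are taken as millimetres.
#'
#' @param path path to an `.stl` file.
#' @param validate passed to [volume_mesh()].
#' @return a [volume_mesh()].
#' @export
read_stl <- function(path, validate = TRUE) {
  con <- file(path, "rb")
  header <- readBin(con, "raw", 80L)
  close(con)
  txt_head <- rawToChar(header[header != as.raw(0)])
  is_ascii <- grepl("^\\s*solid", txt_head) && stl_is_really_ascii(path)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  soup_to_mesh(tri, validate = validate)
}

# binary files may still start with "solid"; check for "facet" keyword
stl_is_really_ascii <- function(path) {
  txt <- readChar(path, min(file.info(path)$size, 4000L), useBytes = TRUE)
  grepl("facet", txt, fixed = TRUE)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  tri <- matrix(0, n * 3L, 3)
  for (i in seq_len(n)) {
    rec <- readBin(con, "numeric", 12L, size = 4L, endian = "little")
    tri[(3L * i - 2L):(3L * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    readBin(con, "raw", 2L)  # attribute byte count
  }
  tri
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vx <- grep("^\\s*vertex", lines, value = TRUE)
  parts <- strsplit(trimws(vx), "\\s+")
  tri <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (nrow(tri) %% 3L != 0L) stop("malformed ASCII STL: vertex count not a multiple of 3",
                                  call. = FALSE)
  tri
}

# merge exactly repeated coordinates into an indexed mesh
soup_to_mesh <- function(tri, validate = TRUE) {
  key <- paste(tri[, 1], tri[, 2], tri[, 3], sep = "|")
  idx <- match(key, unique(key))
  verts <- tri[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  volume_mesh(verts, faces, validate = validate)
}

#' Write a mesh as ASCII STL
#'
#' @param mesh a [volume_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c_ <- v[f[i, 3], ]
    n <- c((b[2] - a[2]) * (c_[3] - a[3]) - (b[3] - a[3]) * (c_[2] - a[2]),
           (b[3] - a[3]) * (c_[1] - a[1]) - (b[1] - a[1]) * (c_[3] - a[3]),
           (b[1] - a[1]) * (c_[2] - a[2]) - (b[2] - a[2]) * (c_[1] - a[1]))
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeLines(c(
      sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
      "    outer loop",
      sprintf("      vertex %.9g %.9g %.9g", a[1], a[2], a[3]),
      sprintf("      vertex %.9g %.9g %.9g", b[1], b[2], b[3]),
      sprintf("      vertex %.9g %.9g %.9g", c_[1], c_[2], c_[3]),
      "    endloop",
      "  endfacet"), con)
  }
  writeLines("endsolid mesh", con)
  invisible(path)
}
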