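#' @include grid.R
NULL

# TrackVis .trk and MRtrix .tck readers/writers, little-endian only.
# TRK stores points in "voxmm": rasmm = vox_to_ras %*% (pt / voxel_size - 0.5).
# We write identity vox_to_ras and unit voxel size so voxmm = world + 0.5.

#' Write a TRK streamline file
#'
#' Coordinates are taken as world mm (RAS); the header carries the
#' voxel-to-ras affine (identity by default) and the TrackVis half-voxel
#' corner convention is applied on write, so mainstream readers recover the
#' same world coordinates.
#'
#' @param bundle a \linkS4class{TractBundle}.
#' @param path output path (.trk).
#' @param dim,voxelSize header grid hints (cosmetic for identity affine).
#' @export
writeTRK <- function(bundle, path, dim = c(1L, 1L, 1L), voxelSize = c(1, 1, 1)) {
  con <- file(path, "wb")
  on.exit(close(con))
  sl <- streamlines(bundle)
  writeBin(charToRaw("TRACK"), con); writeBin(raw(1), con)
  writeBin(as.integer(dim), con, size = 2, endian = "little")
  writeBin(as.numeric(voxelSize), con, size = 4, endian = "little")
  writeBin(numeric(3), con, size = 4, endian = "little")        # origin
  writeBin(0L, con, size = 2, endian = "little")                # n_scalars
  writeBin(raw(200), con)                                       # scalar names
  writeBin(0L, con, size = 2, endian = "little")                # n_properties
  writeBin(raw(200), con)                                       # property names
  writeBin(as.numeric(t(diag(4))), con, size = 4, endian = "little")
  writeBin(raw(444), con)                                       # reserved
  writeBin(c(charToRaw("RAS"), raw(1)), con)                    # voxel_order
  writeBin(raw(4), con)                                         # pad2
  writeBin(numeric(6), con, size = 4, endian = "little")        # orientation
  writeBin(raw(2), con)                                         # pad1
  writeBin(raw(6), con)                                         # invert/swap
  writeBin(length(sl), con, size = 4, endian = "little")        # n_count
  writeBin(2L, con, size = 4, endian = "little")                # version
  writeBin(1000L, con, size = 4, endian = "little")             # hdr_size
  for (s in sl) {
    writeBin(nrow(s), con, size = 4, endian = "little")
    writeBin(as.numeric(t(s + 0.5)), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a TRK streamline file
#'
#' @param path path to a .trk file.
#' @param name bundle name; defaults to the file stem.
#' @return a \linkS4class{TractBundle} with world-mm coordinates.
#' @export
readTRK <- function(path, name = sub("\\.trk$", "", basename(path))) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(rawToChar(magic[1:5]), "TRACK"))
    stop(sprintf("'%s' is not a TRK file (bad magic)", path))
  readBin(con, "integer", 3, size = 2, endian = "little")          # dim
  vs <- readBin(con, "numeric", 3, size = 4, endian = "little")
  readBin(con, "numeric", 3, size = 4, endian = "little")          # origin
  nScalars <- readBin(con, "integer", 1, size = 2, endian = "little")
  readBin(con, "raw", 200)
  nProps <- readBin(con, "integer", 1, size = 2, endian = "little")
  readBin(con, "raw", 200)
  M <- matrix(readBin(con, "numeric", 16, size = 4, endian = "little"),
              4, 4, byrow = TRUE)
  if (all(M == 0)) M <- diag(4)                                    # legacy v1
  readBin(con, "raw", 444 + 4 + 4 + 24 + 2 + 6)
  nCount <- readBin(con, "integer", 1, size = 4, endian = "little")
  readBin(con, "integer", 2, size = 4, endian = "little")          # version, hdr
  if (any(vs <= 0)) vs <- c(1, 1, 1)
  sl <- list()
  repeat {
    n <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(n) == 0L) break
    pts <- matrix(readBin(con, "numeric", n * (3 + nScalars), size = 4,
                          endian = "little"),
                  ncol = 3 + nScalars, byrow = TRUE)[, 1:3, drop = FALSE]
    if (nProps > 0) readBin(con, "numeric", nProps, size = 4, endian = "little")
    vox <- sweep(pts, 2, vs, "/") - 0.5
    sl[[length(sl) + 1L]] <- applyAffine(M, vox)
  }
  if (nCount > 0 && length(sl) != nCount)
    warning(sprintf("TRK header advertised %d streamlines, read %d",
                    nCount, length(sl)))
  tractBundle(name, sl)
}

#' Write a TCK (MRtrix) streamline file
#'
#' @param bundle a \linkS4class{TractBundle} (world-mm coordinates).
#' @param path output path (.tck).
#' @export
writeTCK <- function(bundle, path) {
  sl <- streamlines(bundle)
  hdr <- sprintf("mrtrix tracks\ncount: %010d\ndatatype: Float32LE\n",
                 length(sl))
  offset <- nchar(hdr) + nchar("file: . \nEND\n") + 10L
  hdr <- paste0(hdr, sprintf("file: . %-8d\nEND\n", offset))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  pad <- offset - nchar(hdr)
  if (pad > 0) writeBin(raw(pad), con)
  for (s in sl) {
    writeBin(as.numeric(t(s)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a TCK (MRtrix) streamline file
#'
#' @param path path to a .tck file.
#' @param name bundle name; defaults to the file stem.
#' @return a \linkS4class{TractBundle}.
#' @export
readTCK <- function(path, name = sub("\\.tck$", "", basename(path))) {
  raw <- readBin(path, "raw", file.size(path))
  endHdr <- grepRaw("END\n", raw, fixed = TRUE)
  if (length(endHdr) == 0L) stop(sprintf("'%s': no TCK header terminator", path))
  hdr <- strsplit(rawToChar(raw[1:(endHdr + 3L)]), "\n")[[1]]
  if (hdr[1] != "mrtrix tracks")
    stop(sprintf("'%s' is not a TCK file (bad magic)", path))
  fileLine <- grep("^file:", hdr, value = TRUE)
  offset <- as.integer(sub("^file:\\s*\\.\\s*", "", fileLine))
  dtLine <- grep("^datatype:", hdr, value = TRUE)
  if (!grepl("Float32LE", dtLine))
    stop(sprintf("unsupported TCK datatype: %s", dtLine))
  vals <- readBin(raw[(offset + 1L):length(raw)], "numeric",
                  (length(raw) - offset) %/% 4L, size = 4, endian = "little")
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  isNaN3 <- rowSums(is.na(pts)) == 3L
  isInf3 <- rowSums(is.infinite(pts)) == 3L
  stop_at <- which(isInf3)[1]
  if (!is.na(stop_at)) pts <- pts[seq_len(stop_at - 1L), , drop = FALSE]
  brk <- which(isNaN3[seq_len(nrow(pts))])
  starts <- c(1L, brk + 1L)
  ends <- c(brk - 1L, nrow(pts))
  keep <- starts <= ends
  sl <- Map(function(a, b) pts[a:b, , drop = FALSE], starts[keep], ends[keep])
  tractBundle(name, sl)
}
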