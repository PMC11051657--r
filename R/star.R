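# STAR-format particle tables (RELION 3.1 particle dialect).
#
# A particle table is an ordinary data.frame with the canonical columns
#   tomo   character  tomogram identifier        (_rlnMicrographName)
#   x,y,z  numeric    coordinates in voxels      (_rlnCoordinate{X,Y,Z})
#   rot,tilt,psi      Euler angles, degrees      (_rlnAngle{Rot,Tilt,Psi})
#   cc     numeric    cross-correlation score    (_rlnAutopickFigureOfMerit)
# plus any derived columns (depth_nm, thickness_nm, cc_norm, ...). Unknown
# STAR columns are preserved verbatim under their _rln names.

.star_canonical <- c(
  rlnMicrographName       = "tomo",
  rlnCoordinateX          = "x",
  rlnCoordinateY          = "y",
  rlnCoordinateZ          = "z",
  rlnAngleRot             = "rot",
  rlnAngleTilt            = "tilt",
  rlnAnglePsi             = "psi",
  rlnAutopickFigureOfMerit = "cc"
)

#' Read a RELION-style particle STAR file
#'
#' Parses the first `data_` block containing a `loop_` of per-particle rows.
#' Recognised RELION 3.1 column names are mapped to the package's canonical
#' particle-table columns (`tomo`, `x`, `y`, `z`, `rot`, `tilt`, `psi`, `cc`);
#' all other columns are kept under their original names so that a
#' read-modify-write round trip preserves them.
#'
#' @param path path to a `.star` file.
#' @return a `data.frame`, one row per particle.
#' @seealso [write_particle_star()]
#' @export
read_particle_star <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  loop_at <- which(lines == "loop_")
  if (length(loop_at) == 0L) stop("no loop_ block found in STAR file: ", path)
  i <- loop_at[[1L]] + 1L
  cols <- character()
  while (i <= length(lines) && startsWith(lines[[i]], "_")) {
    tag <- sub("^_([^ \t]+).*$", "\\1", lines[[i]])
    cols <- c(cols, tag)
    i <- i + 1L
  }
  if (length(cols) == 0L) stop("loop_ block declares no columns: ", path)
  body <- lines[seq(i, length(lines))]
  body <- body[nzchar(body)]
  stop_at <- grep("^(data_|loop_)", body)
  if (length(stop_at)) body <- body[seq_len(stop_at[[1L]] - 1L)]
  if (length(body) == 0L) {
    df <- as.data.frame(matrix(nrow = 0L, ncol = length(cols)))
    names(df) <- cols
  } else {
    con <- textConnection(body)
    on.exit(close(con))
    df <- utils::read.table(con, header = FALSE, col.names = cols,
                            colClasses = NA, stringsAsFactors = FALSE,
                            comment.char = "")
  }
  known <- intersect(names(.star_canonical), names(df))
  names(df)[match(known, names(df))] <- .star_canonical[known]
  df
}

#' Write a particle table as a RELION-style STAR file
#'
#' Canonical columns are written back under their RELION 3.1 names; any other
#' columns are written with a `_` prefix added to their name (columns already
#' named `rln...` keep that name). Numeric values are written with full
#' precision.
#'
#' @param table particle-table `data.frame`.
#' @param path output path.
#' @param block_name name of the STAR data block (default `"particles"`).
#' @return `path`, invisibly.
#' @export
write_particle_star <- function(table, path, block_name = "particles") {
  stopifnot(is.data.frame(table))
  back <- names(table)
  canon <- match(back, .star_canonical)
  back[!is.na(canon)] <- names(.star_canonical)[canon[!is.na(canon)]]
  header <- c(
    "", paste0("data_", block_name), "", "loop_",
    sprintf("_%s #%d", back, seq_along(back))
  )
  fmt_col <- function(v) {
    if (is.numeric(v)) format(v, digits = 15, scientific = FALSE, trim = TRUE)
    else as.character(v)
  }
  cells <- vapply(table, fmt_col, character(nrow(table)))
  if (nrow(table) == 1L) cells <- matrix(cells, nrow = 1L)
  rows <- if (nrow(table)) apply(cells, 1L, paste, collapse = "\t") else character()
  writeLines(c(header, rows, ""), path)
  invisible(path)
}

#' Read per-tomogram metadata
#'
#' Plain-text tab- or whitespace-separated table with a header line. Expected
#' columns: `tomo` (identifier), `pixel_size` (Angstrom per voxel), and
#' optionally `thickness_nm` (manually measured local lamella thickness) and
#' `position` (front-to-back label or coordinate along the lamella).
#'
#' @param path path to the metadata file.
#' @return a `data.frame` with one row per tomogram.
#' @export
read_tomogram_meta <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (!"tomo" %in% names(df)) stop("tomogram metadata must have a 'tomo' column")
  if ("pixel_size" %in% names(df) && any(df$pixel_size <= 0))
    stop("pixel_size must be positive")
  df
}

# Internal: validate the minimal particle-table contract.
check_particle_table <- function(table, need = c("tomo", "x", "y", "z")) {
  stopifnot(is.data.frame(table))
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("particle table lacks required column(s): ", paste(miss, collapse = ", "))
  num <- intersect(need, c("x", "y", "z", "cc", "depth_nm", "thickness_nm"))
  for (cn in num) {
    if (!all(is.finite(table[[cn]])))
      stop("non-finite values in particle-table column '", cn, "'")
  }
  invisible(table)
}
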