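# Plain-text exchange formats: two-column tables (spectrum, trace, decay),
# the long NOESY volume table, multi-frame PDB-style coordinates, and a JSON
# manifest recording ground-truth parameters and the seed.

#' Write / read a two-column data table
#'
#' Whitespace-separated text with a header line; used for powder spectra
#' (frequency_khz, intensity), FCS traces (lag_s, g) and TCSPC decays
#' (time_ns, counts).
#'
#' @param x a data frame (first two columns are written).
#' @param path file path.
#' @return \code{read_table2} returns a data frame; \code{write_table2}
#'   returns \code{path} invisibly.
#' @export
write_table2 <- function(x, path) {
  utils::write.table(x[, 1:2], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table2
#' @export
read_table2 <- function(path) {
  utils::read.table(path, header = TRUE)
}

#' Read a powder spectrum from a two-column file
#'
#' @param path file with columns \code{frequency_khz}, \code{intensity}.
#' @return a \code{\link{powder_spectrum}}.
#' @export
read_spectrum <- function(path) {
  tab <- read_table2(path)
  powder_spectrum(tab[[1]], tab[[2]])
}

#' Write a ground-truth manifest
#'
#' Records the parameters behind a synthetic dataset (including the seed) as
#' JSON next to the generated files, so any analysis result can be traced
#' back to its generating truth.
#'
#' @param gt a \code{\link{ground_truth}} object (or any list of parameters).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(gt, path) {
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Write a frame ensemble as a multi-model PDB-style file
#'
#' Coordinates are converted from nm to Angstrom; each frame becomes one
#' MODEL/ENDMDL block and the box is recorded in a CRYST1 record.
#'
#' @param ensemble a \code{\link{frame_ensemble}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_frames_pdb <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  b <- ensemble$box * 10
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1",
                     b[1], b[2], b[3]), con)
  a <- ensemble$atoms
  for (fr in seq_len(ensemble$n_frames)) {
    writeLines(sprintf("MODEL     %4d", fr), con)
    xyz <- ensemble$coords[, , fr] * 10
    lines <- sprintf("ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f",
                     seq_len(nrow(a)) %% 100000, substr(a$name, 1, 4),
                     substr(a$resname, 1, 4), a$resid %% 100000,
                     xyz[, 1], xyz[, 2], xyz[, 3])
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  invisible(path)
}

#' Read a multi-model PDB-style file into a frame ensemble
#'
#' Parses ATOM/HETATM records (fixed columns) and MODEL blocks written by
#' \code{\link{write_frames_pdb}} or exported from standard trajectory
#' tools; coordinates are converted from Angstrom to nm.
#'
#' @param path input path.
#' @param box box dimensions in nm; default read from the CRYST1 record.
#' @return a \code{\link{frame_ensemble}}.
#' @export
read_frames_pdb <- function(path, box = NULL) {
  lines <- readLines(path)
  if (is.null(box)) {
    cr <- grep("^CRYST1", lines, value = TRUE)
    box <- if (length(cr) > 0) {
      as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                   substr(cr[1], 25, 33))) / 10
    } else {
      stop("no CRYST1 record; supply box explicitly")
    }
  }
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_id <- cumsum(grepl("^MODEL", lines))
  if (max(model_id) == 0) model_id <- model_id + 1  # single unmarked frame
  at <- lines[is_atom]
  frame_of <- model_id[is_atom]
  n_frames <- length(unique(frame_of))
  per_frame <- split(seq_along(at), frame_of)
  n_atoms <- length(per_frame[[1]])
  if (any(vapply(per_frame, length, integer(1)) != n_atoms)) {
    stop("frames differ in atom count")
  }
  first <- at[per_frame[[1]]]
  atoms <- data.frame(
    name = trimws(substr(first, 13, 16)),
    resname = trimws(substr(first, 18, 21)),
    resid = as.integer(substr(first, 23, 26)),
    stringsAsFactors = FALSE)
  coords <- array(NA_real_, c(n_atoms, 3, n_frames))
  for (fr in seq_len(n_frames)) {
    ln <- at[per_frame[[fr]]]
    coords[, , fr] <- cbind(as.numeric(substr(ln, 31, 38)),
                            as.numeric(substr(ln, 39, 46)),
                            as.numeric(substr(ln, 47, 54))) / 10
  }
  frame_ensemble(atoms, coords, box)
}
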