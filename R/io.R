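# Plain-text scan I/O: OBJ vertex clouds plus a JSON landmark sidecar.

#' Write / read a labeled scan as OBJ + JSON landmarks
#'
#' The point cloud is stored as OBJ vertex records (`v x y z`, mm) and the
#' landmark heights in a JSON sidecar
#' (`{"neck_height_mm": ..., "buttock_height_mm": ...}`).
#'
#' @param scan a `labeled_scan`.
#' @param obj_path path of the OBJ file.
#' @param landmarks_path path of the JSON sidecar; defaults to the OBJ
#'   path with extension `.landmarks.json`.
#' @param subject_id subject identifier attached on read.
#' @return `write_scan_obj` returns `obj_path` invisibly; `read_scan_obj`
#'   returns a `labeled_scan`.
#' @export
write_scan_obj <- function(scan, obj_path, landmarks_path = NULL) {
  stopifnot(inherits(scan, "labeled_scan"))
  if (is.null(landmarks_path)) {
    landmarks_path <- sub("\\.obj$", "", obj_path)
    landmarks_path <- paste0(landmarks_path, ".landmarks.json")
  }
  con <- file(obj_path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.4f %.4f %.4f", scan$points[, 1L],
                     scan$points[, 2L], scan$points[, 3L]), con)
  jsonlite::write_json(scan$landmarks, landmarks_path, digits = NA,
                       auto_unbox = TRUE)
  invisible(obj_path)
}

#' @rdname write_scan_obj
#' @export
read_scan_obj <- function(obj_path, landmarks_path = NULL, subject_id = NA) {
  if (is.null(landmarks_path)) {
    landmarks_path <- sub("\\.obj$", "", obj_path)
    landmarks_path <- paste0(landmarks_path, ".landmarks.json")
  }
  lines <- readLines(obj_path)
  vlines <- lines[startsWith(lines, "v ")]
  if (!length(vlines)) stop("no vertex records in ", obj_path)
  fields <- do.call(rbind, strsplit(trimws(sub("^v ", "", vlines)), "\\s+"))
  pts <- matrix(as.numeric(fields[, 1:3]), ncol = 3L,
                dimnames = list(NULL, c("x", "y", "z")))
  lmk <- jsonlite::read_json(landmarks_path, simplifyVector = TRUE)
  zr <- range(pts[, 3L])
  if (lmk$neck_height_mm > zr[2L] + 1e-6 ||
      lmk$buttock_height_mm < zr[1L] - 1e-6) {
    stop("landmark heights lie outside the z-range of the cloud")
  }
  scan <- list(points = pts,
               landmarks = list(neck_height_mm = lmk$neck_height_mm,
                                buttock_height_mm = lmk$buttock_height_mm),
               subject_id = subject_id)
  class(scan) <- "labeled_scan"
  scan
}
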