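#' Frame and ground-truth input/output
#'
#' Frames are exchanged as numbered PNG files with a JSON sidecar for
#' ground truth: boxes as \code{[x, y, w, h]} (0-based pixels, \code{null}
#' for absent frames), ellipses as objects with fields
#' \code{cx, cy, a, b, theta_rad}.
#'
#' @param frames list of frames (matrices or h x w x 3 arrays in [0, 1]).
#' @param dir output directory (created if needed).
#' @param boxes optional list of ground-truth \code{\link{BoundingBox}}
#'   (or \code{NULL}) per frame.
#' @param ellipses optional named list of \code{\link{Ellipse}} objects
#'   (e.g. iris, limbus).
#' @return \code{writeFrames} returns the directory invisibly;
#'   \code{readFrames} returns a list with \code{frames} and, when a
#'   sidecar is present, \code{boxes} and \code{ellipses}.
#' @name frame-io
NULL

#' @rdname frame-io
#' @export
writeFrames <- function(frames, dir, boxes = NULL, ellipses = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in seq_along(frames)) {
    png::writePNG(frames[[t]], file.path(dir, sprintf("frame_%05d.png", t)))
  }
  truth <- list()
  if (!is.null(boxes)) {
    truth$boxes <- lapply(boxes, function(b)
      if (is.null(b)) NULL else unname(boxVec(b)))
  }
  if (!is.null(ellipses)) {
    truth$ellipses <- lapply(ellipses, function(e)
      list(cx = e@cx, cy = e@cy, a = e@a, b = e@b, theta_rad = e@theta))
  }
  if (length(truth)) {
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}

#' @rdname frame-io
#' @export
readFrames <- function(dir) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$", full.names = TRUE))
  if (!length(files)) stop("no frame_*.png files in ", dir)
  frames <- lapply(files, png::readPNG)
  out <- list(frames = frames)
  sidecar <- file.path(dir, "ground_truth.json")
  if (file.exists(sidecar)) {
    truth <- jsonlite::read_json(sidecar)
    if (!is.null(truth$boxes)) {
      out$boxes <- lapply(truth$boxes, function(b)
        if (is.null(b)) NULL else BoundingBox(unlist(b)))
    }
    if (!is.null(truth$ellipses)) {
      out$ellipses <- lapply(truth$ellipses, function(e)
        Ellipse(e$cx, e$cy, e$a, e$b, e$theta_rad))
    }
  }
  out
}

#' Write a trajectory as JSON
#'
#' Per-frame records with the box as \code{[x, y, w, h]} or the string
#' \code{"absent"}.
#'
#' @param trajectory list of \code{\link{BoundingBox}} or \code{NULL}.
#' @param path output file.
#' @export
writeTrajectory <- function(trajectory, path) {
  rec <- lapply(trajectory, function(b)
    if (is.null(b)) "absent" else unname(boxVec(b)))
  jsonlite::write_json(rec, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Build a synthetic-data spec from a YAML or JSON file
#'
#' The file holds the constructor arguments of \code{\link{eyeImageSpec}},
#' \code{\link{probeVideoSpec}} or \code{\link{tissueColorModel}}; ellipse
#' arguments are given as objects with fields \code{cx, cy, a, b} and
#' optional \code{theta_rad}, color matrices as row lists.
#'
#' @param path YAML (or JSON) file.
#' @param type one of \code{"eye"}, \code{"video"}, \code{"patches"}.
#' @return the corresponding spec object.
#' @export
specFromConfig <- function(path, type = c("eye", "video", "patches")) {
  type <- match.arg(type)
  raw <- yaml::read_yaml(path)
  asEllipse <- function(x) Ellipse(x$cx, x$cy, x$a, x$b,
                                   if (is.null(x$theta_rad)) 0 else x$theta_rad)
  for (f in intersect(c("iris", "limbus"), names(raw)))
    raw[[f]] <- asEllipse(raw[[f]])
  if (!is.null(raw$trajectory)) raw$trajectory <- do.call(rbind, raw$trajectory)
  if (!is.null(raw$means)) raw$means <- do.call(rbind, raw$means)
  if (!is.null(raw$colors)) raw$colors <- do.call(rbind, raw$colors)
  for (f in intersect(c("imageSize", "frameSize", "probeSize"), names(raw)))
    raw[[f]] <- unlist(raw[[f]])
  fun <- switch(type, eye = eyeImageSpec, video = probeVideoSpec,
                patches = tissueColorModel)
  do.call(fun, raw)
}

#' Load a configuration file
#'
#' Reads a YAML (or JSON) configuration with optional sections
#' \code{eye_detection}, \code{tracking}, \code{grading} and
#' \code{pipeline}, and instantiates the corresponding config objects with
#' the given overrides.
#'
#' @param path YAML or JSON file.
#' @return list with \code{eyeConfig}, \code{trackConfig}, \code{grading}
#'   and \code{pipeline} entries.
#' @export
loadConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  mk <- function(fun, args) do.call(fun, if (is.null(args)) list() else args)
  list(eyeConfig = mk(rhtConfig, raw$eye_detection),
       trackConfig = mk(tldConfig, raw$tracking),
       grading = raw$grading,
       pipeline = raw$pipeline)
}
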