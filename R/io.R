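#' Write / read portable graymap (PGM) images
#'
#' 8-bit grayscale, `P5` (binary, default) or `P2` (plain text). These are
#' the package's canonical frame format: trivially portable and readable
#' without external imaging libraries.
#'
#' @param img integer matrix in `[0, 255]`.
#' @param path output file.
#' @param ascii write plain-text `P2` instead of binary `P5`.
#' @export
write_pgm <- function(img, path, ascii = FALSE) {
  img <- pmin(pmax(round(img), 0), 255)
  nr <- nrow(img); nc <- ncol(img)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(nc, nr), "255"), con)
    write(t(img), con, ncolumns = nc)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P5", paste(nc, nr), "255"), con)
    writeBin(as.raw(as.integer(t(img))), con)
  }
  invisible(path)
}

#' @rdname write_pgm
#' @return `read_pgm`: integer matrix.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- .pnm_token(con)
  nc <- as.integer(.pnm_token(con)); nr <- as.integer(.pnm_token(con))
  maxv <- as.integer(.pnm_token(con))
  if (maxv > 255) .wf_warn("16-bit PGM rescaled to 8-bit")
  if (magic == "P5") {
    v <- as.integer(readBin(con, "raw", nr * nc))
  } else if (magic == "P2") {
    v <- scan(con, integer(), n = nr * nc, quiet = TRUE)
  } else .wf_stop("not a PGM file (magic '%s')", magic)
  if (maxv > 255) v <- as.integer(round(v * 255 / maxv))
  matrix(v, nr, nc, byrow = TRUE)
}

# read one whitespace-delimited token, skipping '#' comments
.pnm_token <- function(con) {
  tok <- ""
  repeat {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (length(ch) == 0 || ch == "") break
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1, useBytes = TRUE)
        if (length(ch) == 0 || ch == "\n") break
      }
      next
    }
    if (grepl("[[:space:]]", ch)) {
      if (nzchar(tok)) break else next
    }
    tok <- paste0(tok, ch)
  }
  tok
}

#' Write / read portable bitmap (PBM) binary masks
#'
#' Plain `P1` format; 1 = exposed (ON) mirror.
#'
#' @param mask a `wf_mask` or a binary matrix.
#' @param path file path.
#' @export
write_pbm <- function(mask, path) {
  px <- if (inherits(mask, "wf_mask")) mask$pixels else mask
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P1", paste(ncol(px), nrow(px))), con)
  write(t(matrix(as.integer(px != 0), nrow(px))), con, ncolumns = ncol(px))
  invisible(path)
}

#' @rdname write_pbm
#' @return `read_pbm`: integer 0/1 matrix.
#' @export
read_pbm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- .pnm_token(con)
  if (magic != "P1") .wf_stop("not a plain PBM file")
  nc <- as.integer(.pnm_token(con)); nr <- as.integer(.pnm_token(con))
  v <- scan(con, integer(), n = nr * nc, quiet = TRUE)
  matrix(v, nr, nc, byrow = TRUE)
}

#' Write a frame sequence as a numbered PGM stack with a frames.csv manifest
#'
#' @param frames a [frame_sequence()].
#' @param dir output directory (created).
#' @param ascii write plain `P2` frames.
#' @return the directory, invisibly.
#' @export
write_frames <- function(frames, dir, ascii = FALSE) {
  stopifnot(inherits(frames, "wf_frames"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(frames$frames)
  files <- sprintf("frame_%05d.pgm", seq_len(n))
  for (i in seq_len(n))
    write_pgm(frames$frames[[i]], file.path(dir, files[i]), ascii = ascii)
  manifest <- data.frame(frame = files, time_s = frames$times)
  attr(manifest, "um_per_px") <- frames$um_per_px
  con <- file(file.path(dir, "frames.csv"), "w")
  writeLines(sprintf("# wormfab frames manifest v1, um_per_px=%g",
                     frames$um_per_px), con)
  write.csv(manifest, con, row.names = FALSE)
  close(con)
  invisible(dir)
}

#' Read a frame stack directory (or single image) into a frame sequence
#'
#' Expects numbered PGM images plus a `frames.csv` manifest (columns
#' `frame`, `time_s`; `um_per_px` in the header comment). Without a
#' manifest, `frame_rate` and `um_per_px` must be given and files are taken
#' in lexicographic order.
#'
#' @param path directory of frames.
#' @param frame_rate fallback frame rate, Hz.
#' @param um_per_px fallback pixel size, um.
#' @return a [frame_sequence()].
#' @export
read_frames <- function(path, frame_rate = NULL, um_per_px = NULL) {
  mf <- file.path(path, "frames.csv")
  if (file.exists(mf)) {
    hdr <- readLines(mf, n = 1)
    if (startsWith(hdr, "#")) {
      m <- regmatches(hdr, regexec("um_per_px=([0-9.eE+-]+)", hdr))[[1]]
      if (length(m) == 2) um_per_px <- as.numeric(m[2])
      manifest <- read.csv(mf, comment.char = "#")
    } else manifest <- read.csv(mf)
    files <- file.path(path, manifest$frame)
    times <- manifest$time_s
  } else {
    files <- list.files(path, pattern = "\\.pgm$", full.names = TRUE)
    if (length(files) == 0) .wf_stop("no frames found in %s", path)
    if (is.null(frame_rate))
      .wf_stop("no frames.csv manifest and no frame_rate given")
    times <- (seq_along(files) - 1) / frame_rate
  }
  if (is.null(um_per_px))
    .wf_stop("um_per_px not in the manifest and not given")
  frame_sequence(lapply(files, read_pgm), times, um_per_px)
}

#' Export mask geometry as a GeoJSON-style polygon file
#'
#' Each 8-connected ON component of the mask becomes a Polygon feature whose
#' exterior ring traces the component's bounding pixels in world um.
#'
#' @param mask a `wf_mask`.
#' @param path output `.geojson` path.
#' @export
write_mask_geojson <- function(mask, path) {
  lab <- .cc_label(mask$pixels > 0)
  n <- attr(lab, "n")
  feats <- lapply(seq_len(n), function(k) {
    px <- which(lab == k, arr.ind = TRUE)
    hull <- grDevices::chull(px[, 2], px[, 1])
    ring <- px[c(hull, hull[1]), , drop = FALSE]
    w <- dmd_to_world(ring, mask$transform)
    list(type = "Feature",
         properties = list(component = k, area_px = nrow(px)),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(w)),
                           function(i) c(w[i, 1], w[i, 2])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a trajectory CSV (versioned schema)
#'
#' Columns: `time_s, x_um, y_um, valid, speed_um_s, accel_um_s2, theta_deg`.
#'
#' @param traj trajectory data.frame.
#' @param path output path.
#' @export
write_trajectory_csv <- function(traj, path) {
  cols <- c("time_s", "x_um", "y_um", "valid", "speed_um_s", "accel_um_s2",
            "theta_deg")
  for (cn in setdiff(cols, names(traj))) traj[[cn]] <- NA_real_
  con <- file(path, "w")
  writeLines("# wormfab trajectory v1", con)
  write.csv(traj[, cols], con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  read.csv(path, comment.char = "#")
}

#' Read a run configuration (JSON)
#'
#' Unknown top-level keys are rejected so that typos in experiment configs
#' fail loudly.
#'
#' @param path JSON file.
#' @return named list of class `wf_config`.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("seed", "camera", "tracker", "calibration", "out_dir",
             "log_level", "scenario", "duration_s", "params")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    .wf_stop("unknown config key(s): %s", paste(unknown, collapse = ", "))
  structure(cfg, class = c("wf_config", class(cfg)))
}

#' Write analysis artifacts plus a run manifest
#'
#' The manifest (`manifest.json`) records the software version, seed, a hash
#' of the configuration and every file written, so runs are auditable and
#' reproducible.
#'
#' @param artifacts named list: each element is written according to its
#'   class (`data.frame` to CSV, `wf_mask` to PBM, `wf_frames` to a stack
#'   directory, character/list to JSON).
#' @param out_dir output directory.
#' @param seed seed recorded in the manifest.
#' @param config configuration list recorded (hashed) in the manifest.
#' @param force overwrite existing files.
#' @return manifest list, invisibly.
#' @export
write_outputs <- function(artifacts, out_dir, seed = NA, config = list(),
                          force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (nm in names(artifacts)) {
    a <- artifacts[[nm]]
    path <- file.path(out_dir, nm)
    if (file.exists(path) && !force)
      .wf_stop("output %s exists (use force = TRUE)", path)
    if (is.data.frame(a)) {
      if (grepl("traj", nm)) write_trajectory_csv(a, path)
      else write.csv(a, path, row.names = FALSE)
    } else if (inherits(a, "wf_mask")) {
      write_pbm(a, path)
    } else if (inherits(a, "wf_frames")) {
      write_frames(a, path)
    } else {
      jsonlite::write_json(a, path, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
    }
    written <- c(written, nm)
  }
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  manifest <- list(
    package = "wormfab",
    version = as.character(utils::packageVersion("wormfab")),
    seed = seed,
    config_hash = sprintf("%08x", sum(utf8ToInt(as.character(cfg_json)) *
                                        seq_len(nchar(cfg_json)))),
    files = written)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
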