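# File formats at the pipeline boundary: ASCII PLY meshes/point clouds,
# 16-bit millimeter PNG depth images (0 = invalid), and the YAML calibration
# file holding per-camera intrinsics and 4x4 row-major poses in meters.

#' Write a mesh or point cloud as ASCII PLY
#'
#' @param mesh a [tri_mesh()] (triangles optional: a cloud writes vertices
#'   only). Normals are written when present.
#' @param path output file.
#' @export
write_ply <- function(mesh, path) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$triangles)
  has_n <- !is.null(mesh$normals)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0", "comment herd3d",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z")
  if (has_n) hdr <- c(hdr, "property float nx", "property float ny", "property float nz")
  hdr <- c(hdr, sprintf("element face %d", nf),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  vdat <- if (has_n) cbind(mesh$vertices, mesh$normals) else mesh$vertices
  writeLines(apply(format(vdat, trim = TRUE, digits = 9, scientific = FALSE),
                   1, paste, collapse = " "), con)
  if (nf > 0)
    writeLines(paste(3, mesh$triangles[, 1] - 1, mesh$triangles[, 2] - 1,
                     mesh$triangles[, 3] - 1), con)
  invisible(path)
}

#' Read an ASCII PLY mesh or point cloud
#'
#' @param path PLY file (ASCII format).
#' @return A [tri_mesh()].
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  end <- match("end_header", lines)
  if (is.na(end)) stop("not a PLY file (no end_header): ", path)
  if (!grepl("ascii", lines[2])) stop("only ASCII PLY is supported: ", path)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
  nf_line <- grep("^element face", lines, value = TRUE)
  nf <- if (length(nf_line)) as.integer(sub("element face ", "", nf_line)) else 0L
  props <- grep("^property (float|double)", lines[seq_len(end)], value = TRUE)
  has_n <- any(grepl("nx", props))
  vdat <- do.call(rbind, lapply(strsplit(lines[end + seq_len(nv)], " "), as.numeric))
  tri <- matrix(integer(), ncol = 3)
  if (nf > 0) {
    fdat <- do.call(rbind, lapply(strsplit(lines[end + nv + seq_len(nf)], " "),
                                  as.integer))
    tri <- fdat[, 2:4, drop = FALSE] + 1L
  }
  tri_mesh(vdat[, 1:3, drop = FALSE], tri,
           normals = if (has_n) vdat[, 4:6, drop = FALSE], validate = FALSE)
}

#' Write a depth image as 16-bit PNG (millimeters)
#'
#' Depth in meters is rounded to millimeters and stored as 16-bit unsigned
#' grayscale; invalid pixels (NA or non-positive) become 0.
#'
#' @param depth height x width matrix in meters (NA = invalid).
#' @param path output file.
#' @export
write_depth_png <- function(depth, path) {
  mm <- round(as.matrix(depth) * 1000)
  mm[!is.finite(mm) | mm < 0] <- 0
  mm[mm > 65535] <- 0  # beyond the encodable range counts as invalid
  storage.mode(mm) <- "integer"
  cpp_png16_write(path.expand(path), mm)
  invisible(path)
}

#' Read a 16-bit millimeter depth PNG
#'
#' @param path PNG file written by [write_depth_png()] (or any 16-bit
#'   grayscale depth-in-millimeters PNG).
#' @return Depth matrix in meters with NA at invalid (zero) pixels.
#' @export
read_depth_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  mm <- round(img * 65535)
  depth <- mm / 1000
  depth[mm == 0] <- NA_real_
  depth
}

#' Write the rig calibration file
#'
#' YAML with one entry per camera: id, intrinsics, and 4x4 row-major poses
#' (meters): the initial (calibrated) pose and, when available, the true
#' pose.
#'
#' @param cameras list of camera entries carrying `id`, `K`, `pose_init`
#'   and optionally `pose_true` / `pose`.
#' @param path output file.
#' @export
write_poses_yaml <- function(cameras, path) {
  enc_pose <- function(T) lapply(1:4, function(i) as.numeric(T$matrix[i, ]))
  out <- list(cameras = lapply(cameras, function(cam) {
    entry <- list(id = as.integer(cam$id),
                  intrinsics = list(fx = cam$K$fx, fy = cam$K$fy,
                                    cx = cam$K$cx, cy = cam$K$cy,
                                    width = cam$K$width, height = cam$K$height),
                  pose_init = enc_pose(cam$pose_init))
    if (!is.null(cam$pose_true)) entry$pose_true <- enc_pose(cam$pose_true)
    if (!is.null(cam$pose)) entry$pose <- enc_pose(cam$pose)
    entry
  }))
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}

#' Read the rig calibration file
#'
#' @param path YAML file written by [write_poses_yaml()].
#' @return List of camera entries with `id`, `K` ([camera_intrinsics()])
#'   and [rigid_transform()] poses.
#' @export
read_poses_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  dec_pose <- function(rows) rigid_transform(do.call(rbind, rows))
  lapply(raw$cameras, function(cam) {
    ki <- cam$intrinsics
    out <- list(id = cam$id,
                K = camera_intrinsics(fx = ki$fx, fy = ki$fy, cx = ki$cx,
                                      cy = ki$cy, width = ki$width,
                                      height = ki$height),
                pose_init = dec_pose(cam$pose_init))
    if (!is.null(cam$pose_true)) out$pose_true <- dec_pose(cam$pose_true)
    if (!is.null(cam$pose)) out$pose <- dec_pose(cam$pose)
    out
  })
}

#' Write a capture set as a scene directory
#'
#' Writes per-camera depth and environment-capture PNGs (16-bit
#' millimeters), label PNGs, and the rig calibration YAML.
#'
#' @param captures a `capture_set` from [perturb_and_degrade()].
#' @param dir output directory (created if needed).
#' @export
write_scene_dir <- function(captures, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cam in captures$cameras) {
    write_depth_png(cam$depth, file.path(dir, sprintf("cam%02d_depth.png", cam$id)))
    write_depth_png(cam$env_depth, file.path(dir, sprintf("cam%02d_env.png", cam$id)))
    lab <- cam$label
    lab[is.na(lab)] <- 2  # 0 env / 1 animal / 2 invalid; shifted +1 on disk
    write_depth_png((lab + 1) / 1000,
                    file.path(dir, sprintf("cam%02d_label.png", cam$id)))
  }
  write_poses_yaml(captures$cameras, file.path(dir, "rig.yaml"))
  invisible(dir)
}

#' Read a scene directory back into a capture set
#'
#' @param dir directory written by [write_scene_dir()].
#' @return A `capture_set`.
#' @export
read_scene_dir <- function(dir) {
  rig_file <- file.path(dir, "rig.yaml")
  if (!file.exists(rig_file)) stop("missing rig.yaml in ", dir)
  cams <- read_poses_yaml(rig_file)
  cams <- lapply(cams, function(cam) {
    depth_file <- file.path(dir, sprintf("cam%02d_depth.png", cam$id))
    env_file <- file.path(dir, sprintf("cam%02d_env.png", cam$id))
    if (!file.exists(depth_file)) stop("missing depth capture for camera ", cam$id)
    if (!file.exists(env_file))
      stop("missing environment capture for camera ", cam$id)
    cam$depth <- read_depth_png(depth_file)
    cam$env_depth <- read_depth_png(env_file)
    lab_file <- file.path(dir, sprintf("cam%02d_label.png", cam$id))
    if (file.exists(lab_file)) {
      lab <- round(read_depth_png(lab_file) * 1000) - 1
      lab[!is.finite(lab) | lab > 1 | lab < 0] <- NA
      cam$label <- lab
    }
    cam
  })
  structure(list(cameras = cams, params = list(), seed = NA_integer_),
            class = "capture_set")
}
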