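# Two-animal pose post-processing: interpolation + Savitzky-Golay smoothing
# of 6-node skeleton tracks, and the seven per-frame features used for
# behavioral-state discovery. Features are built from sums and absolute
# differences across the two animals (agent invariance) and from the
# port-thorax-nose angle folded to [0, 180] (rotation invariance).

POSE_NODES <- c("nose", "forehead", "left_ear", "right_ear", "thorax", "tail_base")

FEATURE_NAMES <- c("velocity_sum", "velocity_absdiff",
                   "port_nose_dist_sum", "port_nose_dist_absdiff",
                   "angle_sum", "angle_absdiff",
                   "thorax_thorax_dist")

#' Construct a two-animal pose recording
#'
#' @param coords numeric array `[2 animals, 6 nodes, frames, 2 (x, y)]` of
#'   pixel coordinates; `NA` marks missing detections. Node order must be
#'   nose, forehead, left_ear, right_ear, thorax, tail_base.
#' @param port length-2 numeric, the reward-port landmark in pixels.
#' @param fps frames per second (default 30).
#' @param state_truth optional per-frame ground-truth state labels
#'   (synthetic recordings).
#' @param id recording identifier.
#' @return An object of class `pose_recording`.
#' @export
pose_recording <- function(coords, port, fps = 30, state_truth = NULL,
                           id = "rec") {
  d <- dim(coords)
  if (length(d) != 4 || d[1] != 2 || d[2] != length(POSE_NODES) || d[4] != 2) {
    stop_validation("coords must be a [2 x 6 x frames x 2] array")
  }
  if (length(port) != 2 || anyNA(port)) stop_validation("port must be (x, y)")
  if (!is.null(state_truth) && length(state_truth) != d[3]) {
    stop_validation("state_truth must have one label per frame")
  }
  dimnames(coords) <- list(c("animal1", "animal2"), POSE_NODES, NULL, c("x", "y"))
  structure(list(coords = coords, port = as.numeric(port), fps = fps,
                 frames = d[3], state_truth = state_truth, id = id),
            class = "pose_recording")
}

#' @export
print.pose_recording <- function(x, ...) {
  cat("Pose recording '", x$id, "': 2 animals x ", length(POSE_NODES),
      " nodes x ", x$frames, " frames @ ", x$fps, " fps\n", sep = "")
  cat("port: (", x$port[1], ", ", x$port[2], "); missing coordinates: ",
      sum(is.na(x$coords)), "\n", sep = "")
  invisible(x)
}

# Linear interpolation over interior gaps, nearest-value fill at the edges.
fill_track <- function(v) {
  ok <- which(!is.na(v))
  if (length(ok) == 0) return(v)
  if (length(ok) == 1) return(rep(v[ok], length(v)))
  approx(ok, v[ok], xout = seq_along(v), method = "linear", rule = 2)$y
}

#' Interpolate missing detections and smooth pose tracks
#'
#' Per animal, node and axis: missing frames are filled by linear
#' interpolation (edge gaps by the nearest present value), then the track is
#' smoothed with a Savitzky-Golay filter. The filter fits local
#' least-squares polynomials, so constant and polynomial tracks up to
#' `polyorder` pass through unchanged.
#'
#' @param rec a [pose_recording()].
#' @param window odd filter window in frames (default 25). For recordings
#'   shorter than the window it shrinks, with a warning, to the largest odd
#'   length that fits.
#' @param polyorder polynomial order of the filter (default 3); must be
#'   less than `window`.
#' @return A `pose_recording` with no missing coordinates.
#' @export
interpolate_and_smooth <- function(rec, window = 25, polyorder = 3) {
  stopifnot(inherits(rec, "pose_recording"))
  if (window %% 2 == 0) stop_validation("window must be odd")
  if (polyorder >= window) stop_validation("window must exceed polyorder")
  n <- rec$frames
  if (window > n) {
    window <- max(polyorder + 1 + (polyorder %% 2), n - 1 + (n %% 2))
    window <- min(window, if (n %% 2) n else n - 1)
    if (window <= polyorder) {
      stop_validation("recording too short to smooth at this polyorder")
    }
    warning("window longer than recording; shrunk to ", window, " frames")
  }
  coords <- rec$coords
  for (a in 1:2) for (k in seq_along(POSE_NODES)) for (ax in 1:2) {
    v <- coords[a, k, , ax]
    if (all(is.na(v))) {
      stop_validation("all-missing track: animal ", a, ", node ",
                      POSE_NODES[k], ", axis ", c("x", "y")[ax])
    }
    if (sum(!is.na(v)) < 2) {
      stop_validation("track needs at least 2 present values: animal ", a,
                      ", node ", POSE_NODES[k])
    }
    v <- fill_track(v)
    coords[a, k, , ax] <- signal::sgolayfilt(v, p = polyorder, n = window)
  }
  rec$coords <- coords
  rec
}

#' Orientation angle at the thorax between port and nose
#'
#' The angle at the thorax vertex between the ray to the port and the ray to
#' the nose, folded to `[0, 180]` degrees so clockwise and counterclockwise
#' configurations coincide (rotation invariance). 0 means the animal faces
#' the port; 180 means it faces directly away.
#'
#' @param port,thorax,nose length-2 numeric points (pixels).
#' @return Degrees in `[0, 180]`, or `NA` for degenerate (coincident-point)
#'   geometry.
#' @examples
#' orientation_angle(c(0, 0), c(1, 0), c(1, 1))   # 90
#' orientation_angle(c(0, 0), c(1, 0), c(1, -1))  # 90 as well
#' @export
orientation_angle <- function(port, thorax, nose) {
  u <- port - thorax; v <- nose - thorax
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0 || anyNA(c(nu, nv))) return(NA_real_)
  cosang <- sum(u * v) / (nu * nv)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# Replace NA entries by the value at the nearest non-NA index.
impute_nearest <- function(v) {
  ok <- which(!is.na(v))
  if (length(ok) == 0) return(v)
  idx <- vapply(seq_along(v), function(i) ok[which.min(abs(ok - i))], 0L)
  v[idx]
}

#' Seven agent- and rotation-invariant features per frame
#'
#' From a smoothed (gap-free) recording computes, per frame:
#' 1. `velocity_sum` — sum of the two thorax speeds (pixels/frame);
#' 2. `velocity_absdiff` — absolute difference of the thorax speeds;
#' 3. `port_nose_dist_sum` — sum of the two port-to-nose distances;
#' 4. `port_nose_dist_absdiff` — their absolute difference;
#' 5. `angle_sum` — sum of the two [orientation_angle()]s;
#' 6. `angle_absdiff` — their absolute difference;
#' 7. `thorax_thorax_dist` — distance between the two thoraxes.
#'
#' Sums and absolute differences make every feature invariant to swapping
#' the two animals' identities. Speeds are displacements of the smoothed
#' thorax between consecutive frames; the first frame repeats the second
#' frame's speed so rows stay aligned with frames. Degenerate angles are
#' imputed from the nearest valid frame.
#'
#' @param rec a smoothed `pose_recording` (no missing coordinates).
#' @param per_second if `TRUE` scale velocities by `fps` to pixels/second
#'   (default `FALSE`: pixels/frame).
#' @return A data frame with columns `frame` and the seven features.
#' @export
compute_features <- function(rec, per_second = FALSE) {
  stopifnot(inherits(rec, "pose_recording"))
  if (anyNA(rec$coords)) {
    stop_validation("recording has missing coordinates; run interpolate_and_smooth first")
  }
  n <- rec$frames
  if (n < 2) stop_validation("at least 2 frames required")
  port <- rec$port
  th <- rec$coords[, "thorax", , , drop = FALSE]
  no <- rec$coords[, "nose", , , drop = FALSE]
  vel <- matrix(0, 2, n)
  for (a in 1:2) {
    dx <- diff(th[a, 1, , 1]); dy <- diff(th[a, 1, , 2])
    v <- sqrt(dx^2 + dy^2)
    vel[a, ] <- c(v[1], v) # backfill first frame
  }
  if (per_second) vel <- vel * rec$fps
  pd <- matrix(0, 2, n)
  ang <- matrix(NA_real_, 2, n)
  for (a in 1:2) {
    pd[a, ] <- sqrt((no[a, 1, , 1] - port[1])^2 + (no[a, 1, , 2] - port[2])^2)
    for (f in seq_len(n)) {
      ang[a, f] <- orientation_angle(port, th[a, 1, f, ], no[a, 1, f, ])
    }
    ang[a, ] <- impute_nearest(ang[a, ])
  }
  ttd <- sqrt((th[1, 1, , 1] - th[2, 1, , 1])^2 +
              (th[1, 1, , 2] - th[2, 1, , 2])^2)
  data.frame(frame = seq_len(n),
             velocity_sum = vel[1, ] + vel[2, ],
             velocity_absdiff = abs(vel[1, ] - vel[2, ]),
             port_nose_dist_sum = pd[1, ] + pd[2, ],
             port_nose_dist_absdiff = abs(pd[1, ] - pd[2, ]),
             angle_sum = ang[1, ] + ang[2, ],
             angle_absdiff = abs(ang[1, ] - ang[2, ]),
             thorax_thorax_dist = ttd)
}

#' Pool recordings, subsample frames, and z-score features
#'
#' Keeps every `step`-th frame of each recording (frames 1, 1+step, ...),
#' pools the kept rows across recordings, and z-scores each feature column
#' over the pooled rows. Pooled (not per-recording) normalization is used
#' because state discovery clusters frames from all recordings together;
#' set `per_recording = TRUE` to normalize within each recording instead.
#'
#' @param features named list of per-recording feature data frames from
#'   [compute_features()].
#' @param step subsampling stride in frames (default 3).
#' @param per_recording z-score within recordings instead of over the pool.
#' @return An object of class `feature_matrix`: list with `x` (rows x 7
#'   z-scored matrix), `provenance` (data frame `recording, frame`),
#'   `center`, `scale`.
#' @export
pool_zscore_subsample <- function(features, step = 3, per_recording = FALSE) {
  if (length(features) == 0) stop_validation("no recordings supplied")
  if (is.null(names(features)) || any(!nzchar(names(features)))) {
    names(features) <- paste0("rec", seq_along(features))
  }
  kept <- lapply(names(features), function(nm) {
    df <- features[[nm]]
    idx <- seq(1, nrow(df), by = step)
    cbind(recording = nm, df[idx, , drop = FALSE])
  })
  pooled <- do.call(rbind, kept)
  if (nrow(pooled) == 0) stop_validation("empty frame pool")
  x <- as.matrix(pooled[, FEATURE_NAMES])
  zscore <- function(m) {
    mu <- colMeans(m)
    sdev <- apply(m, 2, sd)
    zero <- !is.finite(sdev) | sdev == 0
    if (any(zero)) {
      warning("zero-variance feature(s) mapped to 0: ",
              paste(FEATURE_NAMES[zero], collapse = ", "))
      sdev[zero] <- 1
      mu[zero] <- mu[zero] # centered, so the column becomes all zeros
    }
    list(x = sweep(sweep(m, 2, mu), 2, sdev, "/"), center = mu, scale = sdev)
  }
  if (per_recording) {
    parts <- split(seq_len(nrow(x)), pooled$recording)
    for (idx in parts) x[idx, ] <- zscore(x[idx, , drop = FALSE])$x
    center <- NULL; scl <- NULL
  } else {
    z <- zscore(x)
    x <- z$x; center <- z$center; scl <- z$scale
  }
  rownames(x) <- NULL
  structure(list(x = x,
                 provenance = data.frame(recording = pooled$recording,
                                         frame = pooled$frame,
                                         stringsAsFactors = FALSE),
                 center = center, scale = scl, step = step),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix: ", nrow(x$x), " frames x ", ncol(x$x),
      " z-scored features from ", length(unique(x$provenance$recording)),
      " recording(s) (stride ", x$step, ")\n", sep = "")
  invisible(x)
}

#' Write a pose recording as long-format CSV
#'
#' Columns `frame, animal, node, x, y`; missing coordinates are empty
#' fields. A header comment line carries `port` and `fps`.
#'
#' @param rec a `pose_recording`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(rec, path) {
  n <- rec$frames
  grid <- expand.grid(animal = 1:2, node = POSE_NODES, frame = seq_len(n),
                      stringsAsFactors = FALSE)
  xs <- ys <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    xs[i] <- rec$coords[grid$animal[i], grid$node[i], grid$frame[i], 1]
    ys[i] <- rec$coords[grid$animal[i], grid$node[i], grid$frame[i], 2]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# port_x=%g port_y=%g fps=%g id=%s",
                     rec$port[1], rec$port[2], rec$fps, rec$id), con)
  df <- data.frame(frame = grid$frame, animal = grid$animal, node = grid$node,
                   x = xs, y = ys)
  write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a pose recording from long-format CSV
#'
#' @param path CSV written by [write_pose_csv()], or any long table with
#'   columns `frame, animal, node, x, y` plus an optional leading comment
#'   line `# port_x=.. port_y=.. fps=.. id=..`.
#' @param port,fps override the sidecar metadata when the comment line is
#'   absent.
#' @return A `pose_recording`.
#' @export
read_pose_csv <- function(path, port = NULL, fps = NULL) {
  first <- readLines(path, n = 1)
  meta <- list()
  if (startsWith(first, "#")) {
    kv <- regmatches(first, gregexpr("[a-z_]+=[^ ]+", first))[[1]]
    for (pair in kv) {
      parts <- strsplit(pair, "=", fixed = TRUE)[[1]]
      meta[[parts[1]]] <- parts[2]
    }
  }
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (col in c("frame", "animal", "node", "x", "y")) {
    if (is.null(df[[col]])) stop_format("pose CSV missing column: ", col)
  }
  n <- max(df$frame)
  coords <- array(NA_real_, c(2, length(POSE_NODES), n, 2))
  ai <- as.integer(df$animal)
  ni <- match(df$node, POSE_NODES)
  if (anyNA(ni)) stop_format("unknown node name(s) in pose CSV")
  coords[cbind(ai, ni, df$frame, 1L)] <- df$x
  coords[cbind(ai, ni, df$frame, 2L)] <- df$y
  port <- port %||% c(as.numeric(meta$port_x), as.numeric(meta$port_y))
  if (length(port) != 2 || anyNA(port)) {
    stop_format("port coordinate not found in sidecar header; pass port=")
  }
  pose_recording(coords, port = port,
                 fps = fps %||% as.numeric(meta$fps %||% 30),
                 id = meta$id %||% basename(path))
}

#' Read a pose recording from a SLEAP-analysis-style HDF5 file
#'
#' Expects datasets `tracks` (animal x 2 x node x frame, the layout SLEAP's
#' analysis export uses) and `node_names`. Requires the `rhdf5` package.
#'
#' @param path HDF5 file.
#' @param port length-2 numeric, the port landmark (from a sidecar config).
#' @param fps frames per second.
#' @return A `pose_recording`.
#' @export
read_pose_h5 <- function(path, port, fps = 30) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("reading HDF5 pose files requires the rhdf5 package")
  }
  tracks <- rhdf5::h5read(path, "tracks")
  node_names <- as.character(rhdf5::h5read(path, "node_names"))
  d <- dim(tracks)
  # stored as frames x node x xy x animal or animal x xy x node x frames
  # depending on writer; normalize on the animal axis being length 2 first.
  if (d[1] != 2 && d[4] == 2) {
    tracks <- aperm(tracks, c(4, 3, 2, 1))
    d <- dim(tracks)
  }
  if (d[1] != 2) stop_format("expected exactly 2 animals in tracks")
  # now animal x xy x node x frame -> animal x node x frame x xy
  coords <- aperm(tracks, c(1, 3, 4, 2))
  ord <- match(POSE_NODES, node_names)
  if (anyNA(ord)) {
    stop_format("node_names must include: ", paste(POSE_NODES, collapse = ", "))
  }
  coords <- coords[, ord, , , drop = FALSE]
  pose_recording(coords, port = port, fps = fps, id = basename(path))
}
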