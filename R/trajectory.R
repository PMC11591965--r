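#' Trajectory container
#'
#' A `trajectory` holds an ordered series of C-alpha coordinate frames for a
#' fixed set of residues. Coordinates are in Angstrom.
#'
#' @param coords numeric array of dimension `frames x residues x 3`.
#' @param residue_ids data frame with columns `chain`, `resno`, `resname`
#'   (one row per residue), or a character/integer vector of residue labels.
#' @param frame_times optional numeric vector of frame times (ns).
#'
#' @return An object of class `trajectory` with elements `coords`,
#'   `residue_ids` and `frame_times`.
#' @export
trajectory <- function(coords, residue_ids = NULL, frame_times = NULL) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop_nd("'coords' must be a frames x residues x 3 array")
  if (any(!is.finite(coords)))
    stop_nd("trajectory coordinates contain non-finite values")
  n_res <- dim(coords)[2]
  if (is.null(residue_ids)) {
    residue_ids <- data.frame(chain = "A", resno = seq_len(n_res),
                              resname = "ALA", stringsAsFactors = FALSE)
  } else if (!is.data.frame(residue_ids)) {
    residue_ids <- data.frame(chain = "A", resno = seq_len(n_res),
                              resname = as.character(residue_ids),
                              stringsAsFactors = FALSE)
  }
  if (nrow(residue_ids) != n_res)
    stop_nd("'residue_ids' must have one row per residue")
  if (!is.null(frame_times) && length(frame_times) != dim(coords)[1])
    stop_nd("'frame_times' must have one value per frame")
  structure(list(coords = coords, residue_ids = residue_ids,
                 frame_times = frame_times),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<trajectory> %d frames x %d residues (Angstrom)\n", d[1], d[2]))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]
n_residues <- function(traj) dim(traj$coords)[2]

residue_labels <- function(traj) {
  with(traj$residue_ids, paste0(resname, " ", resno,
                                ifelse(chain == "A" | is.na(chain), "", paste0("/", chain))))
}

# frames x 3N matrix view (x1 y1 z1 x2 y2 z2 ...), the layout bio3d uses
flatten_coords <- function(traj) {
  d <- dim(traj$coords)
  m <- matrix(0, d[1], d[2] * 3L)
  for (k in 1:3) m[, seq(k, by = 3L, length.out = d[2])] <- traj$coords[, , k]
  m
}

unflatten_coords <- function(m, n_res) {
  a <- array(0, c(nrow(m), n_res, 3L))
  for (k in 1:3) a[, , k] <- m[, seq(k, by = 3L, length.out = n_res), drop = FALSE]
  a
}

#' Read a C-alpha trajectory
#'
#' Reads an ordered set of coordinate frames from a multi-model PDB file
#' (MODEL/ENDMDL blocks, C-alpha atoms extracted) or a plain-text XYZ file
#' (per frame: an atom-count line, a comment line, then one
#' `label x y z` line per residue).
#'
#' @param path file path.
#' @param format `"pdb"` or `"xyz"`. Guessed from the file extension when
#'   missing.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  if (!file.exists(path)) stop_nd("file not found: ", path)
  switch(format, pdb = read_trajectory_pdb(path), xyz = read_trajectory_xyz(path))
}

read_trajectory_pdb <- function(path) {
  lines <- readLines(path)
  model_idx <- grep("^MODEL", lines)
  # Validate per-model CA counts before handing the file to the parser, so a
  # truncated model is reported by its MODEL number.
  is_ca <- grepl("^ATOM", lines) & substr(lines, 13, 16) == " CA "
  if (length(model_idx) > 1L) {
    model_no <- as.integer(sub("^MODEL\\s+(\\d+).*", "\\1", lines[model_idx]))
    model_of <- findInterval(seq_along(lines), model_idx)
    counts <- tapply(is_ca, factor(model_of, levels = seq_along(model_idx)), sum)
    counts[is.na(counts)] <- 0L
    if (length(unique(counts)) > 1L) {
      bad <- which(counts != counts[1])[1]
      stop_nd(sprintf(
        "inconsistent C-alpha count across models: MODEL %d has %d atoms, MODEL %d has %d",
        model_no[bad], counts[bad], model_no[1], counts[1]))
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  sel <- bio3d::atom.select(pdb, "calpha", verbose = FALSE)
  if (length(sel$atom) == 0L) stop_nd("no C-alpha atoms found in ", path)
  at <- pdb$atom[sel$atom, , drop = FALSE]
  xyz <- pdb$xyz[, sel$xyz, drop = FALSE]
  rid <- data.frame(chain = ifelse(is.na(at$chain), "A", at$chain),
                    resno = at$resno, resname = at$resid,
                    stringsAsFactors = FALSE)
  trajectory(unflatten_coords(xyz, nrow(rid)), rid)
}

read_trajectory_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  i <- 1L; frames <- list(); labels <- NULL
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop_nd("malformed XYZ frame header at line ", i)
    block <- lines[(i + 2L):(i + 1L + nat)]
    if (length(block) < nat || anyNA(block))
      stop_nd("truncated XYZ frame starting at line ", i)
    parts <- strsplit(trimws(block), "\\s+")
    lab <- vapply(parts, `[`, "", 1L)
    co <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(labels)) labels <- lab
    if (length(lab) != length(labels))
      stop_nd(sprintf("frame %d has %d atoms, expected %d",
                      length(frames) + 1L, length(lab), length(labels)))
    frames[[length(frames) + 1L]] <- co
    i <- i + 2L + nat
  }
  coords <- array(0, c(length(frames), length(labels), 3L))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  trajectory(coords, data.frame(chain = "A",
                                resno = seq_along(labels),
                                resname = labels, stringsAsFactors = FALSE))
}

#' Write a trajectory
#'
#' Writes all frames either as a multi-model PDB (via \pkg{bio3d}) or as
#' plain XYZ text blocks with millionth-Angstrom precision truncated to
#' three decimals (XYZ is therefore a lossy, human-readable interchange
#' format; round-trips agree to 1e-3 Angstrom).
#'
#' @param traj a [trajectory()].
#' @param path output file.
#' @param format `"pdb"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  if (format == "pdb") {
    rid <- traj$residue_ids
    bio3d::write.pdb(file = path, xyz = flatten_coords(traj),
                     resno = rid$resno, resid = rid$resname,
                     chain = rid$chain,
                     elety = rep("CA", nrow(rid)))
  } else {
    n <- n_residues(traj)
    con <- file(path, "w"); on.exit(close(con))
    lab <- paste0(traj$residue_ids$resname, traj$residue_ids$resno)
    for (f in seq_len(n_frames(traj))) {
      writeLines(c(as.character(n), sprintf("frame %d", f)), con)
      writeLines(sprintf("%s %.3f %.3f %.3f", lab,
                         traj$coords[f, , 1], traj$coords[f, , 2],
                         traj$coords[f, , 3]), con)
    }
  }
  invisible(path)
}

kabsch_rotation <- function(P, Q) {
  # rotation R minimizing ||P R - Q||_F for centered P, Q (n x 3)
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Superpose trajectory frames
#'
#' Rigid-body least-squares (Kabsch) fit of every frame onto a reference.
#' With `reference = "mean"` (the default) the reference is the converged
#' mean structure: frames are fitted, the mean is recomputed, and the cycle
#' repeats until the mean moves by less than `tol` Angstrom (at most
#' `max_iter` iterations). With `reference = "first"` frames are fitted onto
#' frame 1, the convention for stability plots of deviation from the
#' starting structure.
#'
#' @param traj a [trajectory()] with at least two frames.
#' @param reference `"mean"` or `"first"`.
#' @param tol convergence tolerance on the mean structure (Angstrom).
#' @param max_iter maximum mean-fitting iterations.
#' @return An object of class `superposition`: `aligned` (trajectory),
#'   `reference` (residues x 3 matrix) and `per_frame_rmsd` (Angstrom).
#' @export
superpose <- function(traj, reference = c("mean", "first"),
                      tol = 1e-6, max_iter = 50L) {
  reference <- match.arg(reference)
  if (n_frames(traj) < 2L) stop_nd("superposition needs at least 2 frames")
  if (n_residues(traj) < 3L)
    stop_nd("superposition needs at least 3 residues (rotation underdetermined)")
  m <- flatten_coords(traj)
  ref <- m[1L, ]
  m <- fit_frames(m, ref)
  if (reference == "mean") {
    for (it in seq_len(max_iter)) {
      new_ref <- colMeans(m)
      m <- fit_frames(m, new_ref)
      if (max(abs(new_ref - ref)) < tol) { ref <- new_ref; break }
      ref <- new_ref
    }
  }
  aligned <- trajectory(unflatten_coords(m, n_residues(traj)),
                        traj$residue_ids, traj$frame_times)
  ref_mat <- matrix(ref, ncol = 3L, byrow = TRUE)
  res <- structure(list(aligned = aligned, reference = ref_mat,
                        per_frame_rmsd = frame_rmsd_to(m, ref)),
                   class = "superposition")
  res
}

# least-squares fit every row of m (frames x 3N) onto reference vector
fit_frames <- function(m, ref) {
  n_res <- length(ref) / 3L
  R <- matrix(ref, ncol = 3L, byrow = TRUE)
  Rc <- scale(R, scale = FALSE)
  r_center <- attr(Rc, "scaled:center")
  out <- m
  for (f in seq_len(nrow(m))) {
    P <- matrix(m[f, ], ncol = 3L, byrow = TRUE)
    Pc <- scale(P, scale = FALSE)
    rot <- kabsch_rotation(Pc, Rc)
    fitted <- Pc %*% rot
    fitted <- sweep(fitted, 2L, r_center, "+")
    out[f, ] <- as.numeric(t(fitted))
  }
  out
}

frame_rmsd_to <- function(m, ref) {
  n_res <- length(ref) / 3L
  sqrt(rowSums(sweep(m, 2L, ref)^2) / n_res)
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d frames, %d residues; mean frame RMSD %.3f A\n",
              n_frames(x$aligned), n_residues(x$aligned),
              mean(x$per_frame_rmsd)))
  invisible(x)
}

#' Per-frame RMSD series
#'
#' Root-mean-square deviation of each superposed frame from the reference:
#' `sqrt(mean_i |r_i(t) - r_i(ref)|^2)`.
#'
#' @param sup a [superpose()] result.
#' @return numeric vector, one Angstrom value per frame.
#' @export
rmsd_series <- function(sup) {
  stopifnot(inherits(sup, "superposition"))
  frame_rmsd_to(flatten_coords(sup$aligned), as.numeric(t(sup$reference)))
}

#' Per-residue RMSF profile
#'
#' Root-mean-square fluctuation of each residue about its time-average
#' position in the superposed trajectory:
#' `sqrt(mean_t |r_i(t) - <r_i>|^2)`.
#'
#' @param sup a [superpose()] result.
#' @return numeric vector, one Angstrom value per residue.
#' @export
rmsf_profile <- function(sup) {
  stopifnot(inherits(sup, "superposition"))
  co <- sup$aligned$coords
  mu <- apply(co, c(2, 3), mean)
  dev2 <- (co[, , 1] - matrix(mu[, 1], nrow(co), ncol(co), byrow = TRUE))^2 +
          (co[, , 2] - matrix(mu[, 2], nrow(co), ncol(co), byrow = TRUE))^2 +
          (co[, , 3] - matrix(mu[, 3], nrow(co), ncol(co), byrow = TRUE))^2
  sqrt(colMeans(dev2))
}
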