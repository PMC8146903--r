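# In-memory coordinate trajectory container, atom selections, and
# multi-frame GRO / PDB readers and writers.
#
# Coordinates are stored in angstrom with orthorhombic box lengths per
# frame; GRO files (nm) are converted on read/write.

#' Construct a coordinate trajectory
#'
#' @param atoms data.frame with columns `name`, `resname`, `resid` and
#'   optionally `element`, `mass` (amu).  Missing elements are guessed from
#'   the atom name, missing masses from the element.
#' @param coords numeric array `n_atoms x 3 x n_frames`, angstrom.
#' @param box numeric `3 x n_frames` matrix (or length-3 vector recycled to
#'   all frames) of orthorhombic box lengths, angstrom.
#' @return an `md_trajectory` list with elements `atoms`, `coords`, `box`.
#' @export
md_trajectory <- function(atoms, coords, box) {
  stopifnot(is.data.frame(atoms), is.array(coords), length(dim(coords)) == 3L)
  n_atoms <- nrow(atoms); n_frames <- dim(coords)[3]
  if (dim(coords)[1] != n_atoms || dim(coords)[2] != 3L)
    stop_param("coords must be n_atoms x 3 x n_frames")
  if (is.vector(box)) box <- matrix(rep(box, n_frames), nrow = 3)
  if (nrow(box) != 3L || ncol(box) != n_frames)
    stop_param("box must be 3 x n_frames")
  if (any(box <= 0)) stop_param("box lengths must be positive")
  if (is.null(atoms$element)) atoms$element <- element_from_name(atoms$name)
  if (is.null(atoms$mass)) atoms$mass <- mass_from_element(atoms$element)
  if (any(atoms$mass <= 0)) stop_param("atom masses must be positive")
  structure(list(atoms = atoms, coords = coords, box = box),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d atoms, %d frames, box %.1f x %.1f x %.1f A\n",
              nrow(x$atoms), dim(x$coords)[3],
              x$box[1, 1], x$box[2, 1], x$box[3, 1]))
  cat("  residues:", paste(unique(x$atoms$resname), collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an [md_trajectory()].
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Select atom indices by residue name, atom name and/or element
#'
#' All given filters are combined with AND; each accepts a vector of allowed
#' values.
#'
#' @param traj an [md_trajectory()].
#' @param resname,name,element optional character vectors.
#' @param resid optional integer vector of residue ids.
#' @return integer vector of atom indices.
#' @export
select_atoms <- function(traj, resname = NULL, name = NULL, element = NULL,
                         resid = NULL) {
  keep <- rep(TRUE, nrow(traj$atoms))
  if (!is.null(resname)) keep <- keep & traj$atoms$resname %in% resname
  if (!is.null(name)) keep <- keep & traj$atoms$name %in% name
  if (!is.null(element)) keep <- keep & traj$atoms$element %in% element
  if (!is.null(resid)) keep <- keep & traj$atoms$resid %in% resid
  which(keep)
}

#' Acyl-chain topology for order-parameter analysis
#'
#' @param chains list of integer vectors; each vector holds the atom indices
#'   of one chain's carbons C1..Cn in order.
#' @param double_bonds list of length-2 integer vectors of carbon numbers
#'   (n, n+1) joined by a double bond (applies to every chain).
#' @param sn_position "sn1" or "sn2" bookkeeping tag.
#' @return a `chain_topology` list.
#' @export
chain_topology <- function(chains, double_bonds = list(), sn_position = "sn1") {
  stopifnot(is.list(chains), length(chains) >= 1L)
  for (ch in chains) {
    if (anyDuplicated(ch)) stop_param("chain carbon ids must be distinct")
    if (length(ch) < 3L) stop_param("chains need >= 3 carbons")
  }
  for (db in double_bonds) {
    if (length(db) != 2L || abs(db[2] - db[1]) != 1L)
      stop_param("double-bond pairs must be adjacent carbon numbers")
  }
  structure(list(chains = chains, double_bonds = double_bonds,
                 sn_position = sn_position),
            class = "chain_topology")
}

#' Write a trajectory as a multi-frame GRO file
#'
#' Fixed-column GRO records (positions in nm, 3 decimals); frames are
#' concatenated.  Atom and residue numbers are wrapped at 100000/100000 as
#' the format requires.
#'
#' @param traj an [md_trajectory()].
#' @param path output file path.
#' @param title title string written on each frame header.
#' @return `path`, invisibly.
#' @export
write_gro <- function(traj, path, title = "bilox trajectory") {
  at <- traj$atoms
  n <- nrow(at)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$coords[, , f, drop = FALSE] / 10  # A -> nm
    lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     at$resid %% 100000L, substr(at$resname, 1, 5),
                     substr(at$name, 1, 5), seq_len(n) %% 100000L,
                     xyz[, 1, 1], xyz[, 2, 1], xyz[, 3, 1])
    writeLines(c(title, sprintf("%5d", n), lines,
                 sprintf("%10.5f%10.5f%10.5f", traj$box[1, f] / 10,
                         traj$box[2, f] / 10, traj$box[3, f] / 10)), con)
  }
  invisible(path)
}

#' Read a multi-frame GRO file into a trajectory
#'
#' @param path GRO file (possibly many concatenated frames).
#' @return an [md_trajectory()] (coordinates converted nm -> angstrom).
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  pos <- 1L
  frames <- list(); boxes <- list(); atoms <- NULL
  while (pos + 1L <= length(lines) && nzchar(trimws(lines[pos + 1L]))) {
    n <- as.integer(trimws(lines[pos + 1L]))
    rec <- lines[pos + 1L + seq_len(n)]
    if (is.null(atoms)) {
      atoms <- data.frame(
        resid = as.integer(substr(rec, 1, 5)),
        resname = trimws(substr(rec, 6, 10)),
        name = trimws(substr(rec, 11, 15)))
    }
    frames[[length(frames) + 1L]] <-
      cbind(as.numeric(substr(rec, 21, 28)),
            as.numeric(substr(rec, 29, 36)),
            as.numeric(substr(rec, 37, 44))) * 10
    bx <- as.numeric(strsplit(trimws(lines[pos + n + 2L]), "\\s+")[[1]])
    if (length(bx) < 3L || any(!is.finite(bx[1:3])))
      stop_param("malformed GRO box line at line %d", pos + n + 2L)
    boxes[[length(boxes) + 1L]] <- bx[1:3] * 10
    pos <- pos + n + 3L
    if (pos > length(lines)) break
  }
  if (length(frames) == 0L) stop_param("no frames found in %s", path)
  coords <- array(unlist(frames), dim = c(nrow(atoms), 3, length(frames)))
  md_trajectory(atoms, coords, box = do.call(cbind, boxes))
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame with a CRYST1 record carrying the
#' orthorhombic box.
#'
#' @param traj an [md_trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(traj, path) {
  at <- traj$atoms
  n <- nrow(at)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      traj$box[1, f], traj$box[2, f], traj$box[3, f], 90, 90, 90), con)
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s%-4s%5d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(n) %% 100000L, substr(at$name, 1, 4),
      substr(at$resname, 1, 4), at$resid %% 100000L,
      traj$coords[, 1, f], traj$coords[, 2, f], traj$coords[, 3, f],
      at$element), con)
    writeLines("ENDMDL", con)
  }
  invisible(path)
}

#' Read a multi-model PDB file into a trajectory
#'
#' Fixed-column parsing of ATOM/HETATM records; MODEL blocks become frames
#' (a file without MODEL records is a single frame).  The box is taken from
#' CRYST1 (orthorhombic only).
#'
#' @param path PDB file path.
#' @return an [md_trajectory()].
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  cryst <- grep("^CRYST1", lines, value = TRUE)
  if (length(cryst) == 0L) stop_param("PDB file has no CRYST1 box record")
  box1 <- c(as.numeric(substr(cryst[1], 7, 15)),
            as.numeric(substr(cryst[1], 16, 24)),
            as.numeric(substr(cryst[1], 25, 33)))
  angles <- c(as.numeric(substr(cryst[1], 34, 40)),
              as.numeric(substr(cryst[1], 41, 47)),
              as.numeric(substr(cryst[1], 48, 54)))
  if (any(abs(angles - 90) > 1e-3))
    stop_param("only orthorhombic boxes are supported (CRYST1 angles != 90)")
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0L) model_starts <- 1L
  ends <- c(model_starts[-1] - 1L, length(lines))
  frames <- list(); atoms <- NULL
  for (i in seq_along(model_starts)) {
    rng <- model_starts[i]:ends[i]
    rec <- lines[rng][is_atom[rng]]
    if (length(rec) == 0L) next
    if (is.null(atoms)) {
      el <- trimws(substr(rec, 77, 78))
      atoms <- data.frame(
        name = trimws(substr(rec, 13, 16)),
        resname = trimws(substr(rec, 18, 21)),
        resid = as.integer(substr(rec, 23, 26)))
      if (all(nzchar(el))) atoms$element <- el
    }
    frames[[length(frames) + 1L]] <-
      cbind(as.numeric(substr(rec, 31, 38)),
            as.numeric(substr(rec, 39, 46)),
            as.numeric(substr(rec, 47, 54)))
  }
  if (length(frames) == 0L) stop_param("no coordinates found in %s", path)
  coords <- array(unlist(frames), dim = c(nrow(atoms), 3, length(frames)))
  md_trajectory(atoms, coords, box = box1)
}
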